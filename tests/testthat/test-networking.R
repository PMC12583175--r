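test_that("modified cosine: self-similarity, disjoint pairs, symmetry", {
  s <- make_spec("a", 300, c(100, 150, 200), c(500, 300, 100))
  self <- modified_cosine(s, s)
  expect_equal(unname(self["cosine"]), 1, tolerance = 1e-12)
  expect_equal(unname(self["matched_peaks"]), 3)

  t <- make_spec("b", 300, c(80.123, 130.456, 180.789))
  none <- modified_cosine(s, t)
  expect_equal(unname(none["cosine"]), 0)
  expect_equal(unname(none["matched_peaks"]), 0)

  expect_error(modified_cosine(s, spectrum("e", 100, NULL)), "non-empty")
})

test_that("precursor-shifted matching links modified analogs", {
  # same ladder structure offset by a methoxylation-like precursor shift
  sco <- synth_spectrum(spectrum_recipe("scopoletin", "C10H8O4"))
  iso <- synth_spectrum(spectrum_recipe("isofraxidin", "C11H10O5"))
  shifted <- modified_cosine(sco, iso, precursor_shift = TRUE)
  expect_gt(unname(shifted["cosine"]), 0.6)
  expect_gte(unname(shifted["matched_peaks"]), 5)
  direct <- modified_cosine(sco, iso, precursor_shift = FALSE)
  expect_lt(unname(direct["cosine"]), unname(shifted["cosine"]))
})

test_that("peak assignment matches the exhaustive oracle on random pairs", {
  set.seed(37)
  tol <- fragment_tolerance()
  for (rep in 1:60) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- random_spectrum("a", na)
    b <- random_spectrum("b", nb, precursor = a$precursor_mz + runif(1, -30, 30))
    # overlap some peaks (direct and shifted) to force contested matches
    n_shared <- min(sample(1:4, 1), na, nb)
    bmz <- b$peaks[, "mz"]
    bmz[seq_len(n_shared)] <-
      a$peaks[seq_len(n_shared), "mz"] + runif(n_shared, -0.005, 0.005)
    b <- spectrum("b", b$precursor_mz, cbind(bmz, b$peaks[, "intensity"]))
    got <- modified_cosine(a, b, tol)
    want <- oracle_modified_cosine(a, b, tol)
    expect_equal(unname(got["cosine"]), unname(want["cosine"]),
                 tolerance = 1e-9)
  }
})

test_that("modified cosine is symmetric and bounded", {
  set.seed(41)
  tol <- fragment_tolerance()
  for (rep in 1:20) {
    a <- random_spectrum("a", sample(2:10, 1))
    b <- random_spectrum("b", sample(2:10, 1))
    ab <- modified_cosine(a, b, tol)
    ba <- modified_cosine(b, a, tol)
    expect_equal(unname(ab["cosine"]), unname(ba["cosine"]), tolerance = 1e-12)
    expect_gte(unname(ab["cosine"]), 0)
    expect_lte(unname(ab["cosine"]), 1)
  }
})

test_that("network edges obey thresholds and families partition nodes", {
  sco <- synth_spectrum(spectrum_recipe("scopoletin", "C10H8O4"),
                        node_id = "n1")
  sco2 <- synth_spectrum(spectrum_recipe("scopoletin", "C10H8O4"),
                         node_id = "n2")
  iso <- synth_spectrum(spectrum_recipe("isofraxidin", "C11H10O5"),
                        node_id = "n3")
  far <- make_spec("n4", 450, c(77.7, 310.2, 411.9))
  net <- build_network(list(sco, sco2, iso, far))
  expect_true(all(net$edges$cosine > 0.6))
  expect_true(all(net$edges$matched_peaks >= 5))
  expect_true(all(net$edges$node_a < net$edges$node_b))
  # duplicate spectra are connected; the shared-ladder pair links too
  key <- paste(net$edges$node_a, net$edges$node_b)
  expect_true("n1 n2" %in% key)
  expect_true(any(grepl("n3", key)))
  fam <- net$families
  expect_setequal(fam$node_id, c("n1", "n2", "n3", "n4"))
  # n4 is a singleton family
  f4 <- fam$family_id[fam$node_id == "n4"]
  expect_equal(sum(fam$family_id == f4), 1L)
  # edge endpoints share a family
  for (k in seq_len(nrow(net$edges)))
    expect_identical(fam$family_id[fam$node_id == net$edges$node_a[k]],
                     fam$family_id[fam$node_id == net$edges$node_b[k]])
})

test_that("raising thresholds never adds edges", {
  set.seed(43)
  spectra <- c(
    lapply(1:4, function(i) {
      s <- synth_spectrum(
        spectrum_recipe(paste0("c", i), sprintf("C1%dH10O4", i),
                        peak_dropout_prob = 0.2, seed = i))
      s$node_id <- paste0("c", i); s
    }),
    lapply(1:4, function(i) random_spectrum(paste0("r", i), 10)))
  loose <- build_network(spectra, min_cosine = 0.3, min_matched = 2)
  tight_cos <- build_network(spectra, min_cosine = 0.7, min_matched = 2)
  tight_n <- build_network(spectra, min_cosine = 0.3, min_matched = 6)
  ekey <- function(net) paste(net$edges$node_a, net$edges$node_b)
  expect_true(all(ekey(tight_cos) %in% ekey(loose)))
  expect_true(all(ekey(tight_n) %in% ekey(loose)))
  expect_gte(nrow(loose$edges), nrow(tight_cos$edges))
})

test_that("all-dissimilar corpora give zero edges and singleton families", {
  set.seed(47)
  spectra <- lapply(1:5, function(i)
    make_spec(paste0("s", i), 200 + 37 * i, 50 + 13 * i + c(0, 17.3, 29.1)))
  net <- build_network(spectra)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(length(unique(net$families$family_id)), 5L)
})

test_that("class labels propagate onto families with support counts", {
  fam <- data.frame(node_id = c("a", "b", "c", "d"),
                    family_id = c("F1", "F1", "F1", "F2"),
                    stringsAsFactors = FALSE)
  ann <- data.frame(node_id = c("a", "b", "c", "d"),
                    class_call = c("coumarin", "coumarin;cinnamic_acid",
                                   "cinnamic_acid", ""),
                    stringsAsFactors = FALSE)
  lab <- propagate_class(fam, ann)
  f1 <- lab[lab$family_id == "F1", ]
  expect_setequal(f1$class, c("coumarin", "cinnamic_acid"))
  expect_equal(f1$support[f1$class == "coumarin"], 2L)
  expect_equal(f1$support[f1$class == "cinnamic_acid"], 1L)
  expect_equal(unique(f1$family_size), 3L)
  expect_false("F2" %in% lab$family_id)  # unannotated family: no label
})

test_that("GraphML export is loadable and carries attributes", {
  sco <- synth_spectrum(spectrum_recipe("scopoletin", "C10H8O4"),
                        node_id = "n1")
  iso <- synth_spectrum(spectrum_recipe("isofraxidin", "C11H10O5"),
                        node_id = "n2")
  net <- build_network(list(sco, iso))
  ann <- annotations_to_df(screen_corpus(list(sco, iso), toy_library()))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f, spectra = list(sco, iso), annotations = ann)
  g <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("n1", "n2"))
  expect_true("precursor_mz" %in% igraph::vertex_attr_names(g))
  expect_true("tier" %in% igraph::vertex_attr_names(g))
  if (nrow(net$edges))
    expect_true("cosine" %in% igraph::edge_attr_names(g))
})
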