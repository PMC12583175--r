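test_that("noiseless library compounds screen to library_confirmed at score 1", {
  lib <- toy_library()
  s <- synth_spectrum(spectrum_recipe("scopoletin", "C10H8O4"))
  res <- screen_spectrum(s, lib)
  expect_identical(res$tier, "library_confirmed")
  expect_identical(res$library_matches$name[1], "scopoletin")
  expect_equal(res$diagnostic_score, 1.0)
  expect_identical(res$class_call[1], "coumarin")
  expect_false(res$needs_manual_review)
})

test_that("glycoside-like spectra resolve to base compound plus modification", {
  lib <- toy_library()  # has scopoletin but not scopolin
  sco_mh <- adduct_mz(monoisotopic_mass("C10H8O4"))
  hex <- monoisotopic_mass("C6H10O5")
  peaks <- c(sco_mh, ladder_rungs(sco_mh, class_loss_sequences("coumarin")))
  glyco <- make_spec("g", sco_mh + hex, peaks)
  res <- screen_spectrum(glyco, lib)
  expect_identical(res$tier, "class_plus_modification")
  expect_identical(res$modification_call$base, "scopoletin")
  expect_identical(res$modification_call$modifications, "hexosylation")
  # and the same precursor with scopolin present is library-confirmed
  full <- starter_library()
  sc_mh <- adduct_mz(monoisotopic_mass("C16H18O9"))
  glyco2 <- synth_spectrum(spectrum_recipe("scopolin", "C16H18O9"),
                           node_id = "g2")
  res2 <- screen_spectrum(glyco2, full)
  expect_identical(res2$tier, "library_confirmed")
  expect_identical(res2$library_matches$name[1], "scopolin")
})

test_that("modification inference assembles structural units within tolerance", {
  lib <- starter_library()
  sco <- lib$compounds[lib$compounds$name == "scopoletin", ]
  hexo <- infer_modification(355.1024, sco)
  expect_identical(hexo$modifications[1], "hexosylation")
  meth <- infer_modification(sco$mh_mz + 14.01565, sco)
  expect_identical(meth$modifications[1], "methylation")
  expect_equal(nrow(infer_modification(500.0, sco)), 0L)
  # two-step assembly
  two <- infer_modification(sco$mh_mz + 162.05282 + 14.01565, sco)
  expect_true("hexosylation+methylation" %in% two$modifications)
})

test_that("modification inference is inverse-consistent with the catalog", {
  lib <- starter_library()
  mods <- modification_catalog()
  for (i in seq_len(nrow(lib$compounds))) {
    base <- lib$compounds[i, ]
    for (j in seq_len(nrow(mods))) {
      calls <- infer_modification(base$mh_mz + mods$mass[j], base)
      expect_true(mods$label[j] %in% calls$modifications)
    }
  }
})

test_that("the score threshold is strict: exactly 60% fails", {
  lib <- toy_library()
  sco_mh <- adduct_mz(monoisotopic_mass("C10H8O4"))
  rungs <- ladder_rungs(sco_mh, class_loss_sequences("coumarin"))
  expect_length(rungs, 13L)
  cfg5 <- screening_config(score_threshold = 0.6)
  # 8 of the 13 diagnostic rungs is 0.615 > 0.6 (passes); 7 of 13 is
  # 0.538 (fails) -- the cutoff is a strict inequality
  s_pass <- make_spec("p", sco_mh, rungs[1:8])
  s_fail <- make_spec("f", sco_mh, rungs[1:7])
  expect_identical(screen_spectrum(s_pass, lib, cfg = cfg5)$tier,
                   "library_confirmed")
  expect_false(identical(screen_spectrum(s_fail, lib, cfg = cfg5)$tier,
                         "library_confirmed"))
  # exact boundary with a 5-ion set via diagnostic_ion_score semantics
  s3 <- make_spec("b", 300, c(100, 150, 200))
  expect_false(diagnostic_ion_score(s3, c(100, 150, 200, 250, 275)) > 0.6)
})

test_that("degenerate spectra are unassigned, never errors", {
  lib <- toy_library()
  noise <- make_spec("w", 287.31, c(61.2, 99.8, 143.7, 201.4))
  expect_identical(screen_spectrum(noise, lib)$tier, "unassigned")
  empty <- spectrum("e", 200, NULL)
  expect_identical(screen_spectrum(empty, lib)$tier, "unassigned")
})

test_that("isomeric matches are all reported and flagged for review", {
  lib <- starter_library()
  s <- synth_spectrum(spectrum_recipe("chimsalicifoliusin B", "C20H14O8"))
  res <- screen_spectrum(s, lib)
  expect_identical(res$tier, "library_confirmed")
  expect_setequal(res$library_matches$name,
                  c("chimsalicifoliusin B", "arteminorin A"))
  expect_true(res$needs_manual_review)
})

test_that("corpus screening is order-independent and summarized", {
  lib <- toy_library()
  planted <- lapply(c("scopoletin", "isofraxidin"), function(nm) {
    f <- c(scopoletin = "C10H8O4", isofraxidin = "C11H10O5")[[nm]]
    synth_spectrum(spectrum_recipe(nm, f), node_id = nm)
  })
  decoys <- lapply(1:3, function(i)
    synth_decoy_spectrum(paste0("d", i), seed = 100 + i))
  corpus <- c(planted, decoys)
  out <- screen_corpus(corpus, lib)
  expect_equal(out$summary$n, 5L)
  expect_equal(unname(out$summary$tiers["library_confirmed"]), 2L)
  expect_equal(out$summary$fraction_annotated,
               mean(vapply(out$results, function(r) r$tier, "") != "unassigned"))
  # permuted corpus gives identical ordered results
  out2 <- screen_corpus(rev(corpus), lib)
  expect_identical(annotations_to_df(out), annotations_to_df(out2))
  expect_error(screen_corpus(list(), lib), "empty corpus")
})

test_that("screening is deterministic given identical inputs", {
  bench <- synth_benchmark(n_compounds = 5, n_decoys = 5, seed = 9)
  a <- annotations_to_df(screen_corpus(bench$spectra, bench$library))
  b <- annotations_to_df(screen_corpus(bench$spectra, bench$library))
  expect_identical(a, b)
})
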