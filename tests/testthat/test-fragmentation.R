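iso_mh <- adduct_mz(monoisotopic_mass("C11H10O5"))
sco_mh <- adduct_mz(monoisotopic_mass("C10H8O4"))

test_that("ladders reproduce both published isofraxidin branches", {
  lad1 <- generate_ladder(iso_mh, c("CH3", "CHO", "CO2", "CO"))
  expect_equal(lad1$rungs, c(208.0366, 179.0339, 135.0441, 107.0491),
               tolerance = 1e-4)
  expect_equal(lad1$display, c(208.04, 179.03, 135.04, 107.05))
  lad2 <- generate_ladder(iso_mh, c("CH3", "CO2", "CH3", "C2H2"))
  expect_equal(lad2$display, c(208.04, 164.05, 149.02, 123.01))
  empty <- generate_ladder(sco_mh, character())
  expect_length(empty$rungs, 0L)
  expect_error(generate_ladder(60, c("CO2", "CO2")), "step 2")
})

test_that("total loss is independent of step order", {
  set.seed(5)
  cat <- loss_catalog()
  for (rep in 1:20) {
    steps <- sample(cat$label, sample(2:5, 1), replace = TRUE)
    lad_a <- generate_ladder(500, steps)
    lad_b <- generate_ladder(500, sample(steps))
    expect_equal(tail(lad_a$rungs, 1), tail(lad_b$rungs, 1), tolerance = 1e-9)
  }
})

test_that("the optional radical-H step reproduces the odd printed scopoletin ions", {
  # published 133.03/107.01/81.00 sit ~1.008 Da below their nominal loss
  # annotations; with an explicit extra H step the ladder reaches them
  cat_h <- loss_catalog(include_radical_h = TRUE)
  lad <- generate_ladder(sco_mh, c("CH3", "CO2", "H"), cat_h)
  expect_equal(tail(lad$display, 1), 133.03)
  lad2 <- generate_ladder(sco_mh, c("CH3", "CO2", "H", "C2H2"), cat_h)
  expect_equal(tail(lad2$display, 1), 107.01)
})

test_that("neutral losses are detected from precursor and between fragments", {
  s <- make_spec("n", 223.0601, c(208.0366, 179.0339, 135.0441))
  det <- detect_neutral_losses(s)
  expect_true("CH3" %in% detected_loss_labels(det))   # precursor -> 208.04
  expect_true("CO2" %in% detected_loss_labels(det))   # 179.03 -> 135.04
  ch3 <- det[det$label == "CH3", ]
  expect_true(any(ch3$from_precursor))
  co2 <- det[det$label == "CO2", ]
  expect_true(any(!co2$from_precursor & abs(co2$from_mz - 179.0339) < 1e-6))

  lone <- make_spec("n", 400, 123.4)
  expect_length(detected_loss_labels(detect_neutral_losses(lone)), 0L)
})

test_that("loss detection agrees with the all-pairs brute-force oracle", {
  set.seed(23)
  cat <- loss_catalog()
  tol <- fragment_tolerance()
  for (rep in 1:30) {
    s <- random_spectrum("n", sample(3:30, 1))
    # salt in real loss pairs so the oracle has something to find
    base <- s$peaks[sample(nrow(s$peaks), 1), "mz"]
    extra <- base - sample(cat$mass, 2)
    extra <- extra[extra > 50]
    if (length(extra))
      s <- spectrum("n", s$precursor_mz,
                    rbind(s$peaks, cbind(extra, 100)))
    got <- sort(detected_loss_labels(detect_neutral_losses(s, cat, tol)))
    expect_identical(got, oracle_detect_losses(s, cat, tol))
  }
})

test_that("diagnostic score is the fraction of expected ions present", {
  s <- make_spec("n", 300, c(100, 150, 200))
  expect_equal(diagnostic_ion_score(s, c(100, 150, 200, 250, 275)), 0.6)
  expect_equal(diagnostic_ion_score(s, c(100, 150, 200)), 1.0)
  expect_error(diagnostic_ion_score(s, numeric()), "empty")
  # self-consistency with the ladder generator
  rungs <- ladder_rungs(iso_mh, class_loss_sequences("coumarin"))
  synth <- make_spec("n", iso_mh, rungs)
  expect_equal(diagnostic_ion_score(synth, rungs), 1.0)
})

test_that("diagnostic score is monotone under added peaks and wider tolerance", {
  set.seed(29)
  dset <- c(120.05, 151.21, 180.3, 240.8, 261.0)
  for (rep in 1:20) {
    s <- random_spectrum("n", sample(2:10, 1), precursor = 300)
    s_more <- spectrum("n", 300, rbind(s$peaks, cbind(runif(3, 50, 299), 10)))
    expect_gte(diagnostic_ion_score(s_more, dset),
               diagnostic_ion_score(s, dset))
    expect_gte(diagnostic_ion_score(s, dset, mass_tolerance(dalton = 0.05)),
               diagnostic_ion_score(s, dset, mass_tolerance(dalton = 0.01)))
  }
})

test_that("class rules call coumarins on CH3+CO and rank cinnamic acids by soft evidence", {
  cou <- make_spec("n", 223.0601,
                   c(208.0366, 180.0417))  # -CH3 then -CO
  calls <- classify_class(cou)
  expect_true("coumarin" %in% calls$class)

  caffeic_mh <- adduct_mz(monoisotopic_mass("C9H8O4"))
  cin <- spectrum("n", caffeic_mh,
                  cbind(c(caffeic_mh - 18.0105646, caffeic_mh - 27.9949146),
                        c(900, 400)))
  calls2 <- classify_class(cin)
  expect_identical(calls2$class[1], "cinnamic_acid")
  expect_false("coumarin" %in% calls2$class)
  expect_equal(calls2$soft_score[1], 1)

  none <- make_spec("n", 400, c(91.3, 212.7))
  expect_equal(nrow(classify_class(none)), 0L)
})

test_that("dimer linkage is read from the dominant fragment pattern", {
  lib <- starter_library()
  monomers <- lib$compounds$mh_mz[lib$compounds$subclass == "hydroxycoumarin"]
  # C-O linked: continuous CH3/CH2/CO2 small-loss ladder dominates
  prec_a <- adduct_mz(monoisotopic_mass("C21H16O9"))  # 413.09
  co_rungs <- generate_ladder(prec_a, c("CH3", "CH2", "CO2"))$rungs
  spec_a <- make_spec("4248", prec_a, c(co_rungs, 101.1, 155.5),
                      c(900, 700, 500, 20, 20))
  call_a <- classify_dimer_linkage(spec_a, monomers)
  expect_identical(call_a$call, "CO_linked")

  # C-C linked: abundant ions mirror a single-coumarin ladder
  prec_b <- adduct_mz(monoisotopic_mass("C20H14O8"))  # 383.08
  mono_rungs <- c(sco_mh, ladder_rungs(sco_mh, class_loss_sequences("coumarin")))
  spec_b <- make_spec("4036", prec_b, c(mono_rungs[1:5], 300.1),
                      c(900, 800, 700, 600, 500, 30))
  call_b <- classify_dimer_linkage(spec_b, monomers)
  expect_identical(call_b$call, "CC_linked")
  expect_equal(call_b$monomer_mh, sco_mh, tolerance = 1e-6)

  neither <- make_spec("x", 380, c(111.1, 222.2, 333.3))
  expect_identical(classify_dimer_linkage(neither, monomers)$call,
                   "undetermined")
  small <- make_spec("y", 250, c(235, 222))
  expect_identical(classify_dimer_linkage(small, monomers)$call,
                   "undetermined")
})
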