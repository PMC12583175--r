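two_group_table <- function(n_features = 40, n_planted = 4, fold = 8,
                            cv = 0.1, n_per_group = 3, seed = 1) {
  synth_feature_table(table_recipe(
    n_features = n_features,
    groups = setNames(c(n_per_group, n_per_group), c("A", "B")),
    planted_effects = data.frame(feature = seq_len(n_planted), group = "A",
                                 fold = fold),
    noise_cv = cv, seed = seed))
}

test_that("PCA reconstructs the scaled data with all components", {
  tbl <- two_group_table(n_features = 20, seed = 3)
  m <- pca_features(tbl, n_components = 5)
  full <- pca_features(tbl, n_components = nrow(t(tbl$areas)) - 1)
  X <- scale(t(tbl$areas))
  recon <- full$scores %*% t(full$loadings)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_true(all(diff(m$explained) <= 1e-12))
  expect_lte(sum(m$explained), 1 + 1e-12)
})

test_that("PCA rejects constant matrices and separates planted groups", {
  flat <- feature_table(c("f1", "f2"), c(NA, NA), c(NA, NA),
                        matrix(5, 2, 4, dimnames = list(NULL, paste0("s", 1:4))),
                        setNames(rep(c("A", "B"), each = 2), paste0("s", 1:4)))
  expect_error(pca_features(flat), "no variance")

  tbl <- two_group_table(n_features = 50, n_planted = 15, fold = 10,
                         cv = 0.05, seed = 5)
  m <- pca_features(tbl)
  pc1 <- m$scores[, 1]
  ga <- pc1[tbl$groups == "A"]; gb <- pc1[tbl$groups == "B"]
  # between-group separation on PC1 exceeds within-group spread
  expect_gt(abs(mean(ga) - mean(gb)),
            2 * max(stats::sd(ga), stats::sd(gb)))
})

test_that("mean squared VIP is exactly 1 (algebraic identity)", {
  set.seed(13)
  for (rep in 1:10) {
    tbl <- two_group_table(n_features = sample(10:60, 1),
                           n_planted = sample(1:5, 1),
                           cv = runif(1, 0.05, 0.4), seed = rep)
    vip <- plsda_vip(tbl)$vip
    expect_equal(mean(vip^2), 1, tolerance = 1e-9)
  }
})

test_that("an informative feature gets the maximum VIP", {
  tbl <- synth_feature_table(table_recipe(
    n_features = 30, groups = c(A = 4, B = 4),
    planted_effects = data.frame(feature = 17, group = "A", fold = 12),
    noise_cv = 0.05, seed = 7))
  fit <- plsda_vip(tbl)
  expect_identical(names(which.max(fit$vip)), "FT0017")
  expect_gt(max(fit$vip), 1)
})

test_that("PLS-DA demands proper group structure", {
  tbl <- two_group_table(seed = 11)
  lone <- tbl
  lone$groups[] <- c("A", rep("B", 5))
  expect_error(plsda_vip(lone), ">= 2 samples")
  mono <- tbl
  mono$groups[] <- "A"
  expect_error(plsda_vip(mono), ">= 2 groups")
})

test_that("PLS-DA scores agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  tbl <- two_group_table(n_features = 25, n_planted = 5, seed = 17)
  fit <- plsda_vip(tbl, n_components = 2)
  ref <- mixOmics::plsda(scale(t(tbl$areas)), factor(tbl$groups),
                         ncomp = 2, scale = FALSE)
  for (a in 1:2) {
    r <- stats::cor(fit$model$scores[, a], ref$variates$X[, a])
    expect_gt(abs(r), 0.999)
  }
})

test_that("volcano classifies clear effects and is mirror-symmetric", {
  tbl <- two_group_table(n_features = 30, n_planted = 3, fold = 4,
                         cv = 0.01, seed = 19)
  res <- volcano(tbl, "A", "B")
  expect_identical(res$direction[1:3], rep("up", 3))
  flipped <- volcano(tbl, "B", "A")
  expect_equal(res$p_value, flipped$p_value, tolerance = 1e-12)
  expect_equal(res$log2_fc, -flipped$log2_fc, tolerance = 1e-12)
  expect_identical(flipped$direction[1:3], rep("down", 3))
  expect_error(volcano(tbl, "A", "Z"), "group not in table")
})

test_that("identical groups are ns with zero fold change", {
  areas <- matrix(rep(c(100, 200, 300), 4), nrow = 3,
                  dimnames = list(NULL, paste0("s", 1:4)))
  tbl <- feature_table(paste0("f", 1:3), rep(NA, 3), rep(NA, 3), areas,
                       setNames(rep(c("A", "B"), each = 2), paste0("s", 1:4)))
  res <- volcano(tbl, "A", "B")
  expect_identical(res$direction, rep("ns", 3))
  expect_equal(res$log2_fc, rep(0, 3))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("planted up/down features are recovered exactly at high effect size", {
  rec <- table_recipe(
    n_features = 200, groups = c(A = 3, B = 3),
    planted_effects = data.frame(
      feature = 1:30, group = rep(c("A", "B"), c(20, 10)), fold = 8),
    noise_cv = 0.1, seed = 23)
  tbl <- synth_feature_table(rec)
  res <- volcano(tbl, "A", "B")
  expect_identical(which(res$direction == "up"), 1:20)
  expect_identical(which(res$direction == "down"), 21:30)
})

test_that("selection intersects volcano with the VIP criterion", {
  volc <- data.frame(feature_id = paste0("f", 1:5),
                     group_pair = "A_vs_B",
                     mean_a = c(80, 90, 10, 10, 50),
                     mean_b = c(10, 10, 80, 50, 49),
                     log2_fc = c(3, 3.2, -3, -2.3, 0.03),
                     p_value = c(0.001, 0.002, 0.004, 0.3, 0.9),
                     direction = c("up", "up", "down", "ns", "ns"),
                     stringsAsFactors = FALSE)
  vip <- setNames(c(2.5, 0.4, 1.9, 3.0, 0.1), paste0("f", 1:5))
  sel <- select_differential(volc, vip)
  expect_setequal(sel$selected, c("f1", "f3"))
  expect_equal(sel$n_up, 1L)
  expect_equal(sel$n_down, 1L)
  expect_error(select_differential(volc, vip[1:3]), "no VIP for")
  # tightening the VIP threshold never enlarges the selection
  sel_tight <- select_differential(volc, vip, vip_threshold = 2)
  expect_true(all(sel_tight$selected %in% sel$selected))
})
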