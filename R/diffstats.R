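.scale_matrix <- function(X, scaling) {
  X <- scale(X, center = TRUE, scale = FALSE)
  if (scaling == "unit_variance") {
    s <- apply(X, 2, stats::sd)
    X <- sweep(X, 2, ifelse(s > 0, s, 1), "/")
  } else if (scaling == "pareto") {
    s <- sqrt(apply(X, 2, stats::sd))
    X <- sweep(X, 2, ifelse(s > 0, s, 1), "/")
  }
  X
}

#' Principal component analysis of a feature table
#'
#' Mean-centered (optionally scaled) PCA of the samples-by-features
#' matrix via singular value decomposition. Unit-variance scaling is
#' the default, matching common metabolomics practice.
#'
#' @param tbl A [feature_table()].
#' @param n_components Number of components to keep.
#' @param scaling `"unit_variance"` (default), `"pareto"` or `"none"`.
#' @return A `latent_model`: `scores` (samples x components),
#'   `loadings` (features x components), `explained` (variance
#'   fractions, non-increasing), `groups`, `method = "pca"`.
#' @export
pca_features <- function(tbl, n_components = 2L,
                         scaling = c("unit_variance", "pareto", "none")) {
  stopifnot(inherits(tbl, "feature_table"))
  scaling <- match.arg(scaling)
  X <- t(tbl$areas)
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need >= 2 samples and >= 2 features")
  v <- apply(X, 2, stats::var)
  if (all(v < .Machine$double.eps)) stop("no variance in feature table")
  keep <- v > .Machine$double.eps
  if (!all(keep) && scaling != "none") {
    X <- X[, keep, drop = FALSE]
  } else keep <- rep(TRUE, ncol(X))
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  fit <- stats::prcomp(X, center = TRUE,
                       scale. = scaling == "unit_variance")
  if (scaling == "pareto") {
    Xs <- .scale_matrix(t(tbl$areas)[, keep, drop = FALSE], "pareto")
    fit <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  }
  comp <- seq_len(n_components)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x[, comp, drop = FALSE],
                 loadings = fit$rotation[, comp, drop = FALSE],
                 explained = expl[comp],
                 all_sdev = fit$sdev,
                 kept_features = tbl$feature_id[keep],
                 groups = tbl$groups,
                 method = "pca"),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("%s model: %d component(s); explained: %s\n",
              toupper(x$method), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' PLS-DA with variable importance in projection (VIP)
#'
#' NIPALS PLS2 regression of the (centered, scaled) feature matrix on a
#' one-hot group-membership matrix, the discriminant analysis behind
#' the VIP > 1 feature-selection criterion. VIP for feature j is
#' `sqrt(p * sum_a(w_ja^2 * SSY_a) / sum_a(SSY_a))` with p the feature
#' count, w the normalized component weights and SSY_a the Y-variance
#' captured by component a; mean squared VIP is exactly 1.
#'
#' @param tbl A [feature_table()] with at least two groups, each with
#'   at least two samples.
#' @param n_components Number of latent components (default 2).
#' @param scaling X scaling, as in [pca_features()].
#' @return List with `model` (a `latent_model` carrying scores,
#'   loadings, weights, `y_encoding` and per-component captured
#'   Y-variance) and `vip` (named vector over features).
#' @export
plsda_vip <- function(tbl, n_components = 2L,
                      scaling = c("unit_variance", "pareto", "none")) {
  stopifnot(inherits(tbl, "feature_table"))
  scaling <- match.arg(scaling)
  groups <- factor(tbl$groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L))
    stop("every group needs >= 2 samples; offending: ",
         paste(names(which(table(groups) < 2L)), collapse = ", "))
  X <- .scale_matrix(t(tbl$areas), scaling)
  Y <- stats::model.matrix(~ groups - 1)
  colnames(Y) <- levels(groups)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(X); p <- ncol(X)
  A <- min(n_components, n - 1L, p)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); Q <- matrix(0, ncol(Y), A)
  ssy <- numeric(A)
  Xa <- X; Ya <- Y
  a_done <- 0L
  for (a in seq_len(A)) {
    if (sum(Xa^2) < 1e-12 || sum(Ya^2) < 1e-12) break
    u <- Ya[, which.max(colSums(Ya^2))]
    t_old <- rep(Inf, n)
    for (iter in seq_len(500L)) {
      w <- crossprod(Xa, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_ <- Xa %*% w
      q <- crossprod(Ya, t_)[, 1] / sum(t_^2)
      u <- (Ya %*% q)[, 1] / sum(q^2)
      if (sum((t_ - t_old)^2) / max(sum(t_^2), 1e-300) < 1e-24) break
      t_old <- t_
    }
    p_load <- crossprod(Xa, t_)[, 1] / sum(t_^2)
    W[, a] <- w; P[, a] <- p_load; Tm[, a] <- t_; Q[, a] <- q
    ssy[a] <- sum(t_^2) * sum(q^2)   # Frobenius norm of t q'
    Xa <- Xa - t_ %*% t(p_load)
    Ya <- Ya - t_ %*% t(q)
    a_done <- a
  }
  if (a_done == 0L) stop("PLS-DA failed: no usable component")
  keep <- seq_len(a_done)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; Q <- Q[, keep, drop = FALSE]
  ssy <- ssy[keep]
  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  names(vip) <- tbl$feature_id
  rownames(W) <- rownames(P) <- tbl$feature_id
  rownames(Tm) <- tbl$samples
  model <- structure(list(scores = Tm, loadings = P, weights = W,
                          y_loadings = Q, y_encoding = Y,
                          explained = ssy / sum(Y^2),
                          groups = tbl$groups, method = "plsda"),
                     class = "latent_model")
  list(model = model, vip = vip)
}

#' Volcano analysis between two sample groups
#'
#' Fold change on arithmetic group means of raw areas; p-values from a
#' two-sided Welch t-test on log2 areas. When the table contains
#' nonpositive areas, half the smallest positive area is added
#' throughout before ratios and logs. A feature is `up` when
#' `FC >= fc_threshold` and `p < p_threshold`, `down` when the inverse
#' ratio clears the threshold, otherwise `ns`.
#'
#' @param tbl A [feature_table()].
#' @param group_a,group_b Group labels (numerator / denominator).
#' @param fc_threshold Fold-change cutoff (inclusive; default 2).
#' @param p_threshold Significance cutoff (strict; default 0.05).
#' @param p_adjust Optional multiple-testing correction method passed
#'   to [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, matching
#'   the raw-p criterion.
#' @return data.frame with `feature_id`, `group_pair`, `mean_a`,
#'   `mean_b`, `log2_fc`, `p_value`, `direction`.
#' @export
volcano <- function(tbl, group_a, group_b, fc_threshold = 2,
                    p_threshold = 0.05, p_adjust = "none") {
  stopifnot(inherits(tbl, "feature_table"))
  for (g in c(group_a, group_b))
    if (!g %in% tbl$groups) stop("group not in table: ", g)
  ia <- tbl$groups == group_a
  ib <- tbl$groups == group_b
  if (sum(ia) < 2L || sum(ib) < 2L) stop("both groups need >= 2 samples")
  areas <- tbl$areas
  offset <- if (any(areas <= 0)) {
    pos <- areas[areas > 0]
    if (!length(pos)) stop("all areas are zero")
    min(pos) / 2
  } else 0
  areas <- areas + offset
  mean_a <- rowMeans(areas[, ia, drop = FALSE])
  mean_b <- rowMeans(areas[, ib, drop = FALSE])
  la <- log2(areas[, ia, drop = FALSE])
  lb <- log2(areas[, ib, drop = FALSE])
  pvals <- vapply(seq_len(nrow(areas)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12) {
      if (abs(mean(xa) - mean(xb)) < 1e-12) return(1)
      return(.Machine$double.xmin)
    }
    tryCatch(stats::t.test(xa, xb)$p.value,
             error = function(e) 1)
  }, 0)
  if (p_adjust != "none") pvals <- stats::p.adjust(pvals, method = p_adjust)
  fc <- mean_a / mean_b
  direction <- rep("ns", nrow(areas))
  direction[fc >= fc_threshold & pvals < p_threshold] <- "up"
  direction[1 / fc >= fc_threshold & pvals < p_threshold] <- "down"
  data.frame(feature_id = tbl$feature_id,
             group_pair = paste0(group_a, "_vs_", group_b),
             mean_a = mean_a, mean_b = mean_b,
             log2_fc = log2(fc), p_value = pvals, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect volcano significance with the VIP criterion
#'
#' The differential-metabolite call of the workflow: a feature is
#' selected when it is volcano-significant (direction `up` or `down`)
#' and its PLS-DA VIP strictly exceeds the threshold (default VIP > 1).
#'
#' @param volcano_results data.frame from [volcano()].
#' @param vip Named VIP vector from [plsda_vip()] covering every
#'   volcano feature.
#' @param vip_threshold Strict VIP cutoff (default 1).
#' @return List with `results` (the volcano data.frame plus `vip` and
#'   `selected` columns), `n_up`, `n_down`, `selected` (feature ids).
#' @export
select_differential <- function(volcano_results, vip, vip_threshold = 1) {
  missing <- setdiff(volcano_results$feature_id, names(vip))
  if (length(missing))
    stop("no VIP for feature(s): ", paste(utils::head(missing, 10),
                                          collapse = ", "))
  res <- volcano_results
  res$vip <- unname(vip[res$feature_id])
  res$selected <- res$direction != "ns" & res$vip > vip_threshold
  list(results = res,
       n_up = sum(res$selected & res$log2_fc > 0),
       n_down = sum(res$selected & res$log2_fc < 0),
       selected = res$feature_id[res$selected])
}

#' Collapse adduct-redundant features
#'
#' When several features are annotated as the same compound (different
#' adducts of one metabolite), keeps the feature with the highest total
#' area per compound.
#'
#' @param tbl A [feature_table()].
#' @param compound_of Named character vector feature_id -> compound
#'   name (unannotated features are kept as-is).
#' @return A [feature_table()] with redundant rows removed.
#' @export
collapse_adducts <- function(tbl, compound_of) {
  stopifnot(inherits(tbl, "feature_table"))
  comp <- compound_of[tbl$feature_id]
  totals <- rowSums(tbl$areas)
  keep <- rep(TRUE, length(tbl$feature_id))
  for (cname in unique(stats::na.omit(comp))) {
    idx <- which(!is.na(comp) & comp == cname)
    if (length(idx) > 1L) keep[idx[-which.max(totals[idx])]] <- FALSE
  }
  feature_table(tbl$feature_id[keep], tbl$mz[keep], tbl$rt[keep],
                tbl$areas[keep, , drop = FALSE], tbl$groups)
}
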