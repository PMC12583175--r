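## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Recipe for a synthetic MS2 spectrum
#'
#' Describes how to synthesize a positive-mode protonated spectrum of a
#' compound: which branching neutral-loss pathways to realize, how rung
#' intensities decay, and how much jitter / dropout / uniform noise to
#' apply. Defaults are noiseless. Rung intensities follow the
#' qualitative pattern of real coumarin spectra (earlier rungs more
#' intense): rung intensity is `1000 * 0.8^(branch-1) * 0.6^(depth-1)`.
#'
#' @param name Compound name (ground-truth label).
#' @param formula Molecular formula (protonated to get the precursor).
#' @param compound_class `"coumarin"` or `"cinnamic_acid"`.
#' @param loss_sequences List of loss-label vectors; default:
#'   [class_loss_sequences()] for the class.
#' @param methoxylated For cinnamic acids: include CH3-loss branches.
#' @param mz_jitter_ppm Uniform m/z jitter half-width (ppm).
#' @param peak_dropout_prob Per-rung dropout probability in `[0, 1]`.
#' @param n_noise_peaks Number of uniform noise peaks to add.
#' @param include_precursor Also emit the (residual) precursor peak.
#' @param seed Integer seed fixing all randomness.
#' @return A `spectrum_recipe`.
#' @export
spectrum_recipe <- function(name, formula,
                            compound_class = c("coumarin", "cinnamic_acid"),
                            loss_sequences = NULL, methoxylated = FALSE,
                            mz_jitter_ppm = 0, peak_dropout_prob = 0,
                            n_noise_peaks = 0L, include_precursor = FALSE,
                            seed = 1L) {
  compound_class <- match.arg(compound_class)
  if (is.null(loss_sequences))
    loss_sequences <- class_loss_sequences(compound_class, methoxylated)
  stopifnot(peak_dropout_prob >= 0, peak_dropout_prob <= 1,
            mz_jitter_ppm >= 0, n_noise_peaks >= 0)
  structure(list(name = name, formula = formula,
                 compound_class = compound_class,
                 loss_sequences = loss_sequences,
                 mz_jitter_ppm = mz_jitter_ppm,
                 peak_dropout_prob = peak_dropout_prob,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 include_precursor = include_precursor,
                 seed = as.integer(seed)),
            class = "spectrum_recipe")
}

#' Synthesize an MS2 spectrum from a recipe
#'
#' The precursor is the compound's `[M+H]+`; signal peaks are the
#' unique rungs of the recipe's loss sequences (deduplicated across
#' branches), with intensity decaying along each branch. Jitter is
#' uniform in +/- `mz_jitter_ppm`; dropout removes each rung
#' independently; noise peaks are uniform over m/z 50 to precursor - 1
#' with intensities below the 10th percentile of the surviving signal
#' rungs. The same seed always yields the same spectrum, and the
#' ground-truth label rides along as `attr(x, "truth")`.
#'
#' @param recipe A [spectrum_recipe()].
#' @param node_id Node id for the resulting spectrum (default: the
#'   compound name).
#' @param catalog Loss catalog.
#' @return A [spectrum()] with a `truth` attribute (`name`, `class`,
#'   `formula`, `is_decoy = FALSE`).
#' @export
synth_spectrum <- function(recipe, node_id = recipe$name,
                           catalog = loss_catalog()) {
  stopifnot(inherits(recipe, "spectrum_recipe"))
  mh <- adduct_mz(monoisotopic_mass(parse_formula(recipe$formula)))
  rungs <- list()
  for (b in seq_along(recipe$loss_sequences)) {
    lad <- generate_ladder(mh, recipe$loss_sequences[[b]], catalog)
    for (d in seq_along(lad$rungs))
      rungs[[length(rungs) + 1L]] <- c(mz = lad$rungs[d],
                                       intensity = 1000 * 0.8^(b - 1) * 0.6^(d - 1))
  }
  rungs <- do.call(rbind, rungs)
  if (!is.null(rungs)) {
    ord <- order(rungs[, "mz"], -rungs[, "intensity"])
    rungs <- rungs[ord, , drop = FALSE]
    dup <- c(FALSE, diff(rungs[, "mz"]) < 1e-9)
    rungs <- rungs[!dup, , drop = FALSE]
  } else rungs <- matrix(numeric(), ncol = 2,
                         dimnames = list(NULL, c("mz", "intensity")))
  with_seed(recipe$seed, {
    keep <- stats::runif(nrow(rungs)) >= recipe$peak_dropout_prob
    rungs <- rungs[keep, , drop = FALSE]
    if (recipe$mz_jitter_ppm > 0 && nrow(rungs)) {
      jit <- stats::runif(nrow(rungs), -recipe$mz_jitter_ppm,
                          recipe$mz_jitter_ppm) * 1e-6
      rungs[, "mz"] <- rungs[, "mz"] * (1 + jit)
    }
    pk <- rungs
    if (recipe$include_precursor)
      pk <- rbind(pk, c(mh, 1000))
    if (recipe$n_noise_peaks > 0L) {
      cap <- if (nrow(rungs)) stats::quantile(rungs[, "intensity"], 0.1)
      else 50
      noise <- cbind(mz = stats::runif(recipe$n_noise_peaks, 50, mh - 1),
                     intensity = stats::runif(recipe$n_noise_peaks, 0.1 * cap, cap))
      pk <- rbind(pk, noise)
    }
    spec <- spectrum(node_id, mh, pk)
    attr(spec, "truth") <- list(name = recipe$name,
                                class = recipe$compound_class,
                                formula = recipe$formula, is_decoy = FALSE)
    spec
  })
}

#' Synthesize a decoy spectrum
#'
#' A structurally unrelated spectrum: a random precursor with uniform
#' random peaks, used to measure the false-annotation rate of the
#' screening pipeline.
#'
#' @param node_id Node id.
#' @param precursor_mz Precursor m/z (default drawn in 150-500).
#' @param n_peaks Number of random peaks (default drawn in 15-30).
#' @param seed Integer seed.
#' @return A [spectrum()] with `truth$is_decoy = TRUE`.
#' @export
synth_decoy_spectrum <- function(node_id, precursor_mz = NULL, n_peaks = NULL,
                                 seed = 1L) {
  with_seed(seed, {
    if (is.null(precursor_mz)) precursor_mz <- stats::runif(1, 150, 500)
    if (is.null(n_peaks)) n_peaks <- sample(15:30, 1)
    pk <- cbind(mz = stats::runif(n_peaks, 50, precursor_mz - 1),
                intensity = stats::runif(n_peaks, 50, 1000))
    spec <- spectrum(node_id, precursor_mz, pk)
    attr(spec, "truth") <- list(name = NA_character_, class = "decoy",
                                formula = NA_character_, is_decoy = TRUE)
    spec
  })
}

#' Random in-silico compound library
#'
#' Random CHO formulas in the coumarin mass range with systematic
#' names, for planted-truth benchmarking.
#'
#' @param n Number of compounds.
#' @param compound_class Class label for all entries.
#' @param seed Integer seed.
#' @return A `compound_library`.
#' @export
random_compound_library <- function(n, compound_class = "coumarin", seed = 1L) {
  with_seed(seed, {
    formulas <- character(n)
    seen <- character()
    for (i in seq_len(n)) {
      repeat {
        f <- sprintf("C%dH%dO%d", sample(10:22, 1), sample(8:24, 1),
                     sample(4:10, 1))
        if (!f %in% seen) break
      }
      seen <- c(seen, f)
      formulas[i] <- f
    }
    df <- data.frame(
      name = sprintf("SYN-%s-%03d", toupper(substr(compound_class, 1, 3)),
                     seq_len(n)),
      formula = formulas, class = compound_class,
      stringsAsFactors = FALSE)
    build_library(df)
  })
}

#' Planted-truth screening benchmark
#'
#' A seeded corpus of `n_compounds` spectra synthesized from a random
#' in-silico library (with jitter and dropout) plus `n_decoys`
#' structurally unrelated decoy spectra, with ground truth attached:
#' the closed loop used to measure screening sensitivity and
#' false-annotation rate.
#'
#' @param n_compounds Planted compounds (default 50).
#' @param n_decoys Decoy spectra (default 150).
#' @param mz_jitter_ppm Jitter on planted rungs (default 5 ppm).
#' @param peak_dropout_prob Per-rung dropout (default 0.2).
#' @param compound_class Class of planted compounds.
#' @param seed Integer master seed.
#' @return List with `spectra`, `library`, `truth` (data.frame
#'   `node_id`, `name`, `class`, `is_planted`).
#' @export
synth_benchmark <- function(n_compounds = 50L, n_decoys = 150L,
                            mz_jitter_ppm = 5, peak_dropout_prob = 0.2,
                            compound_class = "coumarin", seed = 1L) {
  lib <- random_compound_library(n_compounds, compound_class, seed = seed)
  cmp <- lib$compounds
  spectra <- vector("list", n_compounds + n_decoys)
  truth <- vector("list", n_compounds + n_decoys)
  # library is mass-sorted; iterate in that fixed order for determinism
  for (i in seq_len(nrow(cmp))) {
    rec <- spectrum_recipe(cmp$name[i], cmp$formula[i],
                           compound_class = compound_class,
                           mz_jitter_ppm = mz_jitter_ppm,
                           peak_dropout_prob = peak_dropout_prob,
                           seed = seed + i)
    id <- sprintf("P%03d", i)
    spectra[[i]] <- synth_spectrum(rec, node_id = id)
    truth[[i]] <- data.frame(node_id = id, name = cmp$name[i],
                             class = compound_class, is_planted = TRUE,
                             stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_decoys)) {
    id <- sprintf("D%03d", j)
    spectra[[n_compounds + j]] <- synth_decoy_spectrum(id,
                                                       seed = seed + 10000L + j)
    truth[[n_compounds + j]] <- data.frame(node_id = id, name = NA_character_,
                                           class = "decoy",
                                           is_planted = FALSE,
                                           stringsAsFactors = FALSE)
  }
  list(spectra = spectra, library = lib, truth = do.call(rbind, truth))
}

#' Recipe for a synthetic multi-group feature table
#'
#' @param n_features Number of features.
#' @param groups Named integer vector: group label -> sample count.
#' @param planted_effects data.frame with columns `feature` (index),
#'   `group` (label) and `fold` (> 0 multiplier applied to that
#'   feature's baseline in that group).
#' @param noise_cv Multiplicative log-normal noise (sdlog; approx. the
#'   coefficient of variation for small values). 0 gives exact means.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline area
#'   distribution across features.
#' @param seed Integer seed.
#' @return A `table_recipe`.
#' @export
table_recipe <- function(n_features = 1000L, groups = c(A = 3L, B = 3L),
                         planted_effects = NULL, noise_cv = 0.1,
                         baseline_meanlog = log(1e5), baseline_sdlog = 1,
                         seed = 1L) {
  if (is.null(planted_effects))
    planted_effects <- data.frame(feature = integer(), group = character(),
                                  fold = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "group", "fold") %in% names(planted_effects)),
            all(planted_effects$fold > 0), noise_cv >= 0,
            !is.null(names(groups)), all(groups >= 1))
  if (nrow(planted_effects)) {
    if (any(planted_effects$feature < 1 |
              planted_effects$feature > n_features))
      stop("planted effect references a nonexistent feature")
    if (!all(planted_effects$group %in% names(groups)))
      stop("planted effect references a nonexistent group: ",
           paste(setdiff(planted_effects$group, names(groups)), collapse = ", "))
  }
  structure(list(n_features = as.integer(n_features), groups = groups,
                 planted_effects = planted_effects, noise_cv = noise_cv,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
            class = "table_recipe")
}

#' Synthesize a feature table with planted fold changes
#'
#' Log-normal baseline areas per feature; each sample's area is the
#' baseline times the planted fold (if that feature is planted in the
#' sample's group) times multiplicative log-normal noise. The truth
#' mask of planted feature indices is attached as `attr(x, "truth")`.
#'
#' @param recipe A [table_recipe()].
#' @return A [feature_table()] with a `truth` attribute (data.frame of
#'   the planted effects plus the feature ids).
#' @export
synth_feature_table <- function(recipe) {
  stopifnot(inherits(recipe, "table_recipe"))
  with_seed(recipe$seed, {
    nf <- recipe$n_features
    groups_vec <- rep(names(recipe$groups), recipe$groups)
    samples <- paste0(groups_vec, "_", unlist(lapply(recipe$groups, seq_len)))
    baseline <- stats::rlnorm(nf, recipe$baseline_meanlog,
                              recipe$baseline_sdlog)
    fold <- matrix(1, nf, length(samples))
    pe <- recipe$planted_effects
    for (k in seq_len(nrow(pe)))
      fold[pe$feature[k], groups_vec == pe$group[k]] <-
        fold[pe$feature[k], groups_vec == pe$group[k]] * pe$fold[k]
    noise <- if (recipe$noise_cv > 0)
      matrix(stats::rlnorm(nf * length(samples), 0, recipe$noise_cv),
             nf, length(samples))
    else matrix(1, nf, length(samples))
    areas <- baseline * fold * noise
    colnames(areas) <- samples
    ids <- sprintf("FT%04d", seq_len(nf))
    tbl <- feature_table(ids, mz = rep(NA_real_, nf), rt = rep(NA_real_, nf),
                         areas = areas,
                         groups = stats::setNames(groups_vec, samples))
    truth <- pe
    truth$feature_id <- ids[pe$feature]
    attr(tbl, "truth") <- truth
    tbl
  })
}
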