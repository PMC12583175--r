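#' Screening configuration
#'
#' Tolerances and thresholds of the automatic screening pipeline.
#' Precursor matching uses 10 ppm; fragment matching the wider of
#' 20 ppm and 0.01 Da (mirroring 2-decimal reporting precision). A
#' candidate is retained only when strictly more than
#' `score_threshold` of its characteristic ions are observed ("over
#' 60 percent" is a strict inequality here: a score of exactly 0.6
#' fails).
#'
#' @param precursor_tol Precursor-level [mass_tolerance()].
#' @param fragment_tol Fragment-level [mass_tolerance()].
#' @param score_threshold Diagnostic-ion score cutoff in `(0, 1]`.
#' @param min_diagnostic_set_size Minimum rung count of a usable
#'   diagnostic set.
#' @param modification_max_steps Maximum modifications combined when
#'   assembling structural units (bounds the combinatorics).
#' @param dimer_min_mz Precursor gate for dimer-linkage analysis.
#' @return A `screening_config` list.
#' @export
screening_config <- function(precursor_tol = precursor_tolerance(),
                             fragment_tol = fragment_tolerance(),
                             score_threshold = 0.6,
                             min_diagnostic_set_size = 3L,
                             modification_max_steps = 2L,
                             dimer_min_mz = 300) {
  stopifnot(inherits(precursor_tol, "mass_tolerance"),
            inherits(fragment_tol, "mass_tolerance"),
            score_threshold >= 0, score_threshold <= 1,
            min_diagnostic_set_size >= 1, modification_max_steps >= 1)
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 score_threshold = score_threshold,
                 min_diagnostic_set_size = as.integer(min_diagnostic_set_size),
                 modification_max_steps = as.integer(modification_max_steps),
                 dimer_min_mz = dimer_min_mz),
            class = "screening_config")
}

.annotation_result <- function(node_id, precursor_mz, class_call = character(),
                               diagnostic_score = NA_real_,
                               losses_detected = character(),
                               library_matches = NULL,
                               modification_call = NULL,
                               tier = "unassigned") {
  matches <- if (is.null(library_matches))
    data.frame(name = character(), delta_ppm = numeric(),
               stringsAsFactors = FALSE)
  else library_matches
  stopifnot(tier %in% c("library_confirmed", "class_plus_modification",
                        "class_only", "unassigned"))
  if (tier == "library_confirmed" && !nrow(matches))
    stop("library_confirmed requires at least one library match")
  structure(list(node_id = node_id, precursor_mz = precursor_mz,
                 class_call = class_call,
                 diagnostic_score = diagnostic_score,
                 losses_detected = losses_detected,
                 library_matches = matches,
                 modification_call = modification_call,
                 tier = tier,
                 needs_manual_review = nrow(matches) >= 2L),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("node %s (m/z %.4f): tier=%s", as.character(x$node_id),
              x$precursor_mz, x$tier))
  if (nrow(x$library_matches))
    cat(", matches:", paste(x$library_matches$name, collapse = "; "))
  if (length(x$class_call)) cat(", class:", paste(x$class_call, collapse = "+"))
  if (!is.null(x$modification_call))
    cat(sprintf(", %s + %s", x$modification_call$base,
                paste(x$modification_call$modifications, collapse = "+")))
  cat("\n")
  invisible(x)
}

#' Explain a precursor as a library compound plus modifications
#'
#' Enumerates single- and multi-step combinations of catalog
#' modifications whose summed mass matches the difference between the
#' node precursor and the base compound's `[M+H]+` within the precursor
#' tolerance (structural-unit assembly). Combinations are unordered
#' with repetition, capped at `cfg$modification_max_steps` steps.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param base One-row data.frame (a library compound) or list with
#'   `name` and `mh_mz`.
#' @param mods Modification catalog, see [modification_catalog()].
#' @param cfg A [screening_config()].
#' @return data.frame of calls (`base`, `modifications`, `delta_ppm`)
#'   sorted by absolute ppm error; zero rows when nothing fits.
#' @examples
#' lib <- starter_library()
#' sco <- lib$compounds[lib$compounds$name == "scopoletin", ]
#' infer_modification(355.1024, sco) # hexosylation (scopolin-like)
#' @export
infer_modification <- function(precursor_mz, base,
                               mods = modification_catalog(),
                               cfg = screening_config()) {
  delta <- precursor_mz - base$mh_mz
  empty <- data.frame(base = character(), modifications = character(),
                      delta_ppm = numeric(), stringsAsFactors = FALSE)
  if (delta <= 0) return(empty)
  combos <- list()
  n <- nrow(mods)
  idx_sets <- lapply(seq_len(cfg$modification_max_steps), function(k) {
    m <- utils::combn(n + k - 1L, k)        # multisets via stars-and-bars
    apply(m, 2, function(col) col - seq_len(k) + 1L, simplify = FALSE)
  })
  win <- tolerance_window(cfg$precursor_tol, precursor_mz)
  out <- list()
  for (k_sets in idx_sets) {
    for (idx in k_sets) {
      total <- sum(mods$mass[idx])
      if (abs(delta - total) <= win) {
        out[[length(out) + 1L]] <- data.frame(
          base = base$name,
          modifications = paste(mods$label[idx], collapse = "+"),
          delta_ppm = (delta - total) / precursor_mz * 1e6,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(abs(res$delta_ppm), res$modifications), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.diagnostic_set_for <- function(mh_mz, compound_class, catalog, cfg) {
  seqs <- switch(compound_class,
                 coumarin = class_loss_sequences("coumarin"),
                 cinnamic_acid = class_loss_sequences("cinnamic_acid"),
                 NULL)
  if (is.null(seqs)) return(numeric())
  rungs <- tryCatch(ladder_rungs(mh_mz, seqs, catalog),
                    error = function(e) numeric())
  rungs[rungs > 0]
}

#' Screen a single MS2 spectrum
#'
#' The per-node automatic screening pipeline: (1) match the precursor
#' against the in-house library at 10 ppm; (2) call compound classes
#' from detected neutral losses; (3) score every library candidate
#' against its own generated diagnostic-ion ladder, retaining those
#' whose score strictly exceeds the threshold; (4) when no library
#' candidate survives, explain the precursor as a class-consistent
#' library compound plus modifications (structural-unit assembly);
#' (5) assign the annotation tier. Nodes with two or more retained
#' matches are flagged for manual review. Deterministic given inputs.
#'
#' @param spec A [spectrum()].
#' @param lib A `compound_library`.
#' @param rules Class rules ([default_class_rules()]).
#' @param catalog Loss catalog.
#' @param mods Modification catalog.
#' @param cfg A [screening_config()].
#' @return An `annotation_result`.
#' @export
screen_spectrum <- function(spec, lib, rules = default_class_rules(),
                            catalog = loss_catalog(),
                            mods = modification_catalog(),
                            cfg = screening_config()) {
  stopifnot(inherits(spec, "ms2_spectrum"), inherits(lib, "compound_library"))
  if (nrow(spec$peaks) == 0L)
    return(.annotation_result(spec$node_id, spec$precursor_mz))

  losses <- detect_neutral_losses(spec, catalog, cfg$fragment_tol)
  loss_labels <- detected_loss_labels(losses)
  class_calls <- classify_class(spec, rules, catalog, cfg$fragment_tol)

  cand <- match_precursor(lib, spec$precursor_mz, cfg$precursor_tol)
  best_score <- NA_real_
  passing <- NULL
  if (nrow(cand)) {
    scores <- vapply(seq_len(nrow(cand)), function(i) {
      dset <- .diagnostic_set_for(cand$mh_mz[i], cand$class[i], catalog, cfg)
      if (length(dset) < cfg$min_diagnostic_set_size) return(NA_real_)
      diagnostic_ion_score(spec, dset, cfg$fragment_tol)
    }, 0)
    best_score <- if (all(is.na(scores))) NA_real_ else max(scores, na.rm = TRUE)
    keep <- !is.na(scores) & scores > cfg$score_threshold
    if (any(keep)) {
      passing <- cand[keep, c("name", "class", "delta_ppm"), drop = FALSE]
      passing$diagnostic_score <- scores[keep]
      passing <- passing[order(-passing$diagnostic_score,
                               abs(passing$delta_ppm)), , drop = FALSE]
      rownames(passing) <- NULL
    }
  }

  if (!is.null(passing)) {
    return(.annotation_result(
      spec$node_id, spec$precursor_mz,
      class_call = unique(c(passing$class[1], class_calls$class)),
      diagnostic_score = max(passing$diagnostic_score),
      losses_detected = loss_labels,
      library_matches = passing,
      tier = "library_confirmed"))
  }

  if (nrow(class_calls)) {
    called <- class_calls$class
    bases <- lib$compounds[lib$compounds$class %in% called &
                             lib$compounds$mh_mz < spec$precursor_mz, ,
                           drop = FALSE]
    best_mod <- NULL; best_mod_score <- -Inf
    for (i in seq_len(nrow(bases))) {
      calls <- infer_modification(spec$precursor_mz, bases[i, ], mods, cfg)
      if (!nrow(calls)) next
      dset <- .diagnostic_set_for(bases$mh_mz[i], bases$class[i], catalog, cfg)
      sc <- if (length(dset) >= cfg$min_diagnostic_set_size)
        diagnostic_ion_score(spec, dset, cfg$fragment_tol) else 0
      if (sc > cfg$score_threshold && sc > best_mod_score) {
        best_mod_score <- sc
        best_mod <- list(base = bases$name[i],
                         base_class = bases$class[i],
                         modifications = strsplit(calls$modifications[1],
                                                  "+", fixed = TRUE)[[1]],
                         delta_ppm = calls$delta_ppm[1],
                         diagnostic_score = sc)
      }
    }
    if (!is.null(best_mod)) {
      return(.annotation_result(
        spec$node_id, spec$precursor_mz,
        class_call = called,
        diagnostic_score = best_mod$diagnostic_score,
        losses_detected = loss_labels,
        modification_call = best_mod,
        tier = "class_plus_modification"))
    }
    return(.annotation_result(
      spec$node_id, spec$precursor_mz, class_call = called,
      diagnostic_score = if (is.na(best_score)) NA_real_ else best_score,
      losses_detected = loss_labels, tier = "class_only"))
  }

  .annotation_result(spec$node_id, spec$precursor_mz,
                     diagnostic_score = best_score,
                     losses_detected = loss_labels)
}

#' Screen a corpus of spectra
#'
#' Applies [screen_spectrum()] to every spectrum and summarizes tier and
#' class counts. Results are independent of corpus order (they are
#' reported sorted by node id).
#'
#' @inheritParams screen_spectrum
#' @param spectra List of [spectrum()] objects (non-empty).
#' @return List with `results` (list of `annotation_result`, sorted by
#'   node id) and `summary` (counts per tier and per class, and the
#'   fraction of nodes automatically annotated, i.e. non-unassigned).
#' @export
screen_corpus <- function(spectra, lib, rules = default_class_rules(),
                          catalog = loss_catalog(),
                          mods = modification_catalog(),
                          cfg = screening_config()) {
  if (!length(spectra)) stop("empty corpus")
  results <- lapply(spectra, screen_spectrum, lib = lib, rules = rules,
                    catalog = catalog, mods = mods, cfg = cfg)
  ids <- vapply(results, function(r) as.character(r$node_id), "")
  results <- results[order(ids)]
  tiers <- vapply(results, function(r) r$tier, "")
  classes <- unlist(lapply(results, function(r) r$class_call[1]))
  summary <- list(
    n = length(results),
    tiers = table(factor(tiers, levels = c("library_confirmed",
                                           "class_plus_modification",
                                           "class_only", "unassigned"))),
    classes = if (length(classes)) table(classes) else table(character()),
    fraction_annotated = mean(tiers != "unassigned")
  )
  list(results = results, summary = summary)
}

#' Flatten annotation results to a data.frame
#'
#' @param results List of `annotation_result` objects (or the list
#'   returned by [screen_corpus()]).
#' @return data.frame with one row per node, multi-valued fields joined
#'   with `";"`.
#' @export
annotations_to_df <- function(results) {
  if (!is.null(results$results)) results <- results$results
  rows <- lapply(results, function(r) {
    data.frame(
      node_id = as.character(r$node_id),
      precursor_mz = r$precursor_mz,
      class_call = paste(r$class_call, collapse = ";"),
      diagnostic_score = r$diagnostic_score,
      losses_detected = paste(r$losses_detected, collapse = ";"),
      library_matches = paste(r$library_matches$name, collapse = ";"),
      modification_call = if (is.null(r$modification_call)) ""
        else paste0(r$modification_call$base, "+",
                    paste(r$modification_call$modifications, collapse = "+")),
      tier = r$tier,
      needs_manual_review = r$needs_manual_review,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(node_id = character(), precursor_mz = numeric(),
                     class_call = character(), diagnostic_score = numeric(),
                     losses_detected = character(),
                     library_matches = character(),
                     modification_call = character(), tier = character(),
                     needs_manual_review = logical(), stringsAsFactors = FALSE)
  df <- df[order(df$node_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read the annotation report
#'
#' Tab-delimited, stable column order, rows sorted by node id.
#'
#' @param results List of `annotation_result` (or [screen_corpus()]
#'   output, or a data.frame from [annotations_to_df()]).
#' @param path Output path.
#' @export
write_annotations <- function(results, path) {
  df <- if (is.data.frame(results)) results else annotations_to_df(results)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c(node_id = "character"))
}
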