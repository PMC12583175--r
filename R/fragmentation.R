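#' Generate a sequential neutral-loss fragment ladder
#'
#' Starting from a precursor m/z, applies an ordered sequence of neutral
#' losses and records the fragment m/z after each cumulative loss (the
#' "rungs"). This is the in-silico counterpart of the proposed coumarin
#' fragmentation pathways: e.g. protonated isofraxidin 223.06 losing
#' CH3, CHO, CO2, CO in turn passes through 208.04, 179.03, 135.04,
#' 107.05.
#'
#' @param start_mz Precursor (or fragment) m/z to start from.
#' @param steps Character vector of loss labels, applied in order; may
#'   be empty.
#' @param catalog Loss catalog, see [loss_catalog()].
#' @return A `fragment_ladder`: list with `start_mz`, `steps`, `rungs`
#'   (full precision) and `display` (2-decimal half-up rounding).
#' @examples
#' iso <- adduct_mz(monoisotopic_mass("C11H10O5"))
#' generate_ladder(iso, c("CH3", "CHO", "CO2", "CO"))$display
#' @export
generate_ladder <- function(start_mz, steps = character(), catalog = loss_catalog()) {
  stopifnot(is.numeric(start_mz), length(start_mz) == 1L, start_mz > 0)
  steps <- as.character(steps)
  if (!length(steps)) {
    return(structure(list(start_mz = start_mz, steps = character(),
                          rungs = numeric(), display = numeric()),
                     class = "fragment_ladder"))
  }
  masses <- .catalog_mass(catalog, steps)
  rungs <- start_mz - cumsum(masses)
  if (any(rungs <= 0)) {
    i <- which(rungs <= 0)[1]
    stop("cumulative loss exceeds start m/z at step ", i, " (", steps[i], ")")
  }
  structure(list(start_mz = start_mz, steps = steps, rungs = rungs,
                 display = round_half_up(rungs, 2)),
            class = "fragment_ladder")
}

#' @export
print.fragment_ladder <- function(x, ...) {
  cat("fragment ladder from m/z", format(x$start_mz, digits = 8), "\n")
  if (length(x$steps)) {
    lab <- paste0("-", x$steps)
    cat(paste(sprintf("  %-6s -> %.4f (%.2f)", lab, x$rungs, x$display),
              collapse = "\n"), "\n")
  } else cat("  (no steps)\n")
  invisible(x)
}

#' Unique diagnostic rungs from several loss sequences
#'
#' Pools the rungs of all branching pathways from one precursor and
#' deduplicates rungs closer than 1e-9 Da (branches sharing a prefix
#' share rungs). Used to build per-candidate diagnostic-ion sets.
#'
#' @param start_mz Precursor m/z.
#' @param sequences List of loss-label vectors (see
#'   [class_loss_sequences()]).
#' @param catalog Loss catalog.
#' @return Numeric vector of unique rung m/z values, descending.
#' @export
ladder_rungs <- function(start_mz, sequences, catalog = loss_catalog()) {
  rungs <- unlist(lapply(sequences, function(s)
    generate_ladder(start_mz, s, catalog)$rungs))
  if (!length(rungs)) return(numeric())
  rungs <- sort(rungs, decreasing = TRUE)
  keep <- c(TRUE, diff(rungs) < -1e-9)
  rungs[keep]
}

#' Detect neutral losses in an observed spectrum
#'
#' A loss is detected when the precursor and a fragment, or two
#' fragments, differ by the loss mass within tolerance. Counting
#' fragment-to-fragment differences (not only precursor-to-fragment)
#' matters because coumarin ladders are sequential: the CO2 step of
#' isofraxidin shows up between 179.03 and 135.04, not from the
#' precursor. The tolerance window is evaluated at the heavier ion of
#' each pair.
#'
#' @param spec A [spectrum()].
#' @param catalog Loss catalog.
#' @param tol Fragment-level [mass_tolerance()].
#' @return data.frame of detections (`label`, `from_mz`, `to_mz`,
#'   `delta`, `from_precursor`); the unique detected labels are in
#'   `attr(, "labels")` and via [detected_loss_labels()].
#' @export
detect_neutral_losses <- function(spec, catalog = loss_catalog(),
                                  tol = fragment_tolerance()) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  pk <- spec$peaks
  if (nrow(pk) < 1L) stop("spectrum has no peaks")
  from <- c(rep(spec$precursor_mz, nrow(pk)))
  to <- pk[, "mz"]
  from_prec <- rep(TRUE, nrow(pk))
  if (nrow(pk) >= 2L) {
    idx <- utils::combn(nrow(pk), 2L)
    hi <- pmax(pk[idx[1, ], "mz"], pk[idx[2, ], "mz"])
    lo <- pmin(pk[idx[1, ], "mz"], pk[idx[2, ], "mz"])
    from <- c(from, hi)
    to <- c(to, lo)
    from_prec <- c(from_prec, rep(FALSE, ncol(idx)))
  }
  delta <- from - to
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    win <- tolerance_window(tol, from)
    hit <- delta > 0 & abs(delta - catalog$mass[i]) <= win
    if (!any(hit)) return(NULL)
    data.frame(label = catalog$label[i], from_mz = from[hit], to_mz = to[hit],
               delta = delta[hit], from_precursor = from_prec[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(label = character(), from_mz = numeric(),
                      to_mz = numeric(), delta = numeric(),
                      from_precursor = logical(), stringsAsFactors = FALSE)
  attr(out, "labels") <- unique(out$label)
  out
}

#' @rdname detect_neutral_losses
#' @param detections Result of `detect_neutral_losses()`.
#' @export
detected_loss_labels <- function(detections) attr(detections, "labels")

#' Fraction of diagnostic ions present in a spectrum
#'
#' The screening score of the workflow: the fraction of a candidate's
#' expected characteristic ions that have a matching peak. Candidates
#' are retained only when this exceeds the configured threshold
#' (default: strictly more than 60 percent).
#'
#' @param spec A [spectrum()].
#' @param diagnostic_mzs Non-empty numeric vector of expected fragment
#'   m/z values.
#' @param tol Fragment-level [mass_tolerance()].
#' @return Fraction in `[0, 1]`.
#' @export
diagnostic_ion_score <- function(spec, diagnostic_mzs,
                                 tol = fragment_tolerance()) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  if (!length(diagnostic_mzs)) stop("empty diagnostic-ion set")
  if (nrow(spec$peaks) == 0L) return(0)
  mz <- spec$peaks[, "mz"]
  hit <- vapply(diagnostic_mzs,
                function(d) any(within_tolerance(mz, d, tol)), TRUE)
  mean(hit)
}

#' Default compound-class rules
#'
#' A class is called only when all of its required diagnostic losses are
#' detected; soft features (predicates on the spectrum) adjust ranking
#' among called classes but are never required. Coumarins are gated on
#' CH3 and CO losses; cinnamic acids on H2O and CO, with the typical
#' intensity ordering `[M+H-H2O]+ > [M+H-CO]+` as a soft feature.
#'
#' @return Named list of class rules (`diagnostic_losses`,
#'   `soft_features`).
#' @export
default_class_rules <- function() {
  list(
    coumarin = list(
      class_name = "coumarin",
      diagnostic_losses = c("CH3", "CO"),
      soft_features = list()
    ),
    cinnamic_acid = list(
      class_name = "cinnamic_acid",
      diagnostic_losses = c("H2O", "CO"),
      soft_features = list(
        water_loss_dominates = function(spec, catalog, tol) {
          i_h2o <- .peak_intensity_at(spec,
            spec$precursor_mz - .catalog_mass(catalog, "H2O"), tol)
          i_co <- .peak_intensity_at(spec,
            spec$precursor_mz - .catalog_mass(catalog, "CO"), tol)
          !is.na(i_h2o) && !is.na(i_co) && i_h2o > i_co
        }
      )
    )
  )
}

.peak_intensity_at <- function(spec, mz, tol) {
  if (mz <= 0 || nrow(spec$peaks) == 0L) return(NA_real_)
  hit <- within_tolerance(spec$peaks[, "mz"], mz, tol)
  if (!any(hit)) NA_real_ else max(spec$peaks[hit, "intensity"])
}

#' Call compound classes from detected neutral losses
#'
#' @param spec A [spectrum()].
#' @param rules Class rules, see [default_class_rules()].
#' @param catalog Loss catalog.
#' @param tol Fragment-level tolerance.
#' @return data.frame of called classes ranked by evidence
#'   (`class`, `n_diagnostic`, `n_support`, `soft_score`), possibly
#'   zero rows; a spectrum may legitimately receive several calls
#'   (class overlap is real: CH3/CO/CO2 losses are shared across
#'   coumarins, flavonoids and cinnamic acids).
#' @export
classify_class <- function(spec, rules = default_class_rules(),
                           catalog = loss_catalog(),
                           tol = fragment_tolerance()) {
  if (!length(rules)) stop("no class rules given")
  if (nrow(spec$peaks) == 0L)
    return(data.frame(class = character(), n_diagnostic = integer(),
                      n_support = integer(), soft_score = numeric(),
                      stringsAsFactors = FALSE))
  detections <- detect_neutral_losses(spec, catalog, tol)
  det <- detected_loss_labels(detections)
  calls <- lapply(rules, function(r) {
    if (!all(r$diagnostic_losses %in% det)) return(NULL)
    soft <- if (length(r$soft_features))
      sum(vapply(r$soft_features,
                 function(f) isTRUE(f(spec, catalog, tol)), TRUE))
    else 0
    data.frame(class = r$class_name,
               n_diagnostic = length(r$diagnostic_losses),
               n_support = sum(detections$label %in% r$diagnostic_losses),
               soft_score = soft, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  if (is.null(out))
    return(data.frame(class = character(), n_diagnostic = integer(),
                      n_support = integer(), soft_score = numeric(),
                      stringsAsFactors = FALSE))
  # rank by soft evidence, then by how many loss pairs actually support
  # the rule's required losses (class overlap keeps all calls)
  out <- out[order(-out$soft_score, -out$n_support, -out$n_diagnostic,
                   out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discriminate C-C from C-O linked coumarin dimers
#'
#' Bicoumarins fall apart differently depending on the inter-unit bond.
#' An ether (C-O) linkage cleaves readily, so the spectrum is dominated
#' by a descending small-loss ladder from the precursor (continuous
#' CH3, CH2, CO2 losses). A C-C linkage resists cleavage, so the
#' abundant ions instead reproduce the fragment ladder of a single
#' coumarin unit. "Dominates" means the pattern's peaks carry more than
#' `dominance` of the total ion intensity.
#'
#' @param spec A [spectrum()] whose precursor is dimer-sized.
#' @param monomer_mh_mzs Numeric vector of candidate monomer `[M+H]+`
#'   values (e.g. from the coumarins of an in-house library).
#' @param catalog Loss catalog.
#' @param tol Fragment-level tolerance.
#' @param min_precursor Dimer gate on precursor m/z (default 300).
#' @param dominance Intensity fraction a pattern must carry (default 0.5).
#' @return List with `call` (`"CO_linked"`, `"CC_linked"` or
#'   `"undetermined"`), the intensity shares of both patterns, and the
#'   best-supported monomer m/z.
#' @export
classify_dimer_linkage <- function(spec, monomer_mh_mzs,
                                   catalog = loss_catalog(),
                                   tol = fragment_tolerance(),
                                   min_precursor = 300,
                                   dominance = 0.5) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  empty <- list(call = "undetermined", share_co = NA_real_,
                share_cc = NA_real_, monomer_mh = NA_real_)
  if (spec$precursor_mz < min_precursor || nrow(spec$peaks) == 0L)
    return(empty)
  total <- sum(spec$peaks[, "intensity"])
  if (total <= 0) return(empty)
  matched_share <- function(targets) {
    hit <- vapply(spec$peaks[, "mz"], function(m)
      any(within_tolerance(m, targets[targets > 0], tol)), TRUE)
    sum(spec$peaks[hit, "intensity"]) / total
  }
  co_rungs <- generate_ladder(spec$precursor_mz,
                              c("CH3", "CH2", "CO2"), catalog)$rungs
  share_co <- matched_share(co_rungs)
  share_cc <- 0; best_mono <- NA_real_
  for (mh in monomer_mh_mzs) {
    if (mh <= 0 || mh >= spec$precursor_mz) next
    rungs <- c(mh, ladder_rungs(mh, class_loss_sequences("coumarin"), catalog))
    s <- matched_share(rungs)
    if (s > share_cc) { share_cc <- s; best_mono <- mh }
  }
  call <- "undetermined"
  if (share_co > dominance && share_co > share_cc) call <- "CO_linked"
  else if (share_cc > dominance && share_cc > share_co) call <- "CC_linked"
  list(call = call, share_co = share_co, share_cc = share_cc,
       monomer_mh = best_mono)
}
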