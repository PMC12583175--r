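# Shared fixtures and independent oracles for the test suite.

# Quick spectrum builder from parallel mz/intensity vectors.
make_spec <- function(node_id, precursor, mz, intensity = rep(100, length(mz))) {
  spectrum(node_id, precursor, cbind(mz, intensity))
}

# A three-compound toy library (two coumarin isomers would collide;
# these are mass-distinct).
toy_library <- function() {
  build_library(data.frame(
    name = c("scopoletin", "isofraxidin", "caffeic acid"),
    formula = c("C10H8O4", "C11H10O5", "C9H8O4"),
    class = c("coumarin", "coumarin", "cinnamic_acid"),
    stringsAsFactors = FALSE))
}

# Brute-force oracle for the modified-cosine peak assignment: exhaustive
# recursion over candidate pairs, maximizing total sqrt-intensity score.
# Independent of the package's igraph-based assignment.
oracle_modified_cosine <- function(a, b, tol, precursor_shift = TRUE) {
  wa <- sqrt(a$peaks[, "intensity"])
  wb <- sqrt(b$peaks[, "intensity"])
  norm <- sqrt(sum(wa^2)) * sqrt(sum(wb^2))
  if (norm == 0) return(c(cosine = 0, matched_peaks = 0))
  shift <- a$precursor_mz - b$precursor_mz
  cand <- list()
  for (i in seq_len(nrow(a$peaks))) {
    for (j in seq_len(nrow(b$peaks))) {
      mza <- a$peaks[i, "mz"]; mzb <- b$peaks[j, "mz"]
      win <- tolerance_window(tol, (mza + mzb) / 2)
      ok <- abs(mza - mzb) <= win ||
        (precursor_shift && abs(shift) > 1e-9 && abs(mza - mzb - shift) <= win)
      if (ok && wa[i] * wb[j] > 0)
        cand[[length(cand) + 1L]] <- c(i, j, wa[i] * wb[j])
    }
  }
  if (!length(cand)) return(c(cosine = 0, matched_peaks = 0))
  cand <- do.call(rbind, cand)
  best <- new.env()
  best$score <- 0; best$n <- 0L
  recurse <- function(k, used_a, used_b, score, n) {
    if (score > best$score + 1e-15 ||
        (abs(score - best$score) <= 1e-15 && n > best$n)) {
      best$score <- score; best$n <- n
    }
    if (k > nrow(cand)) return()
    # upper bound prune: remaining total
    if (score + sum(cand[k:nrow(cand), 3]) < best$score - 1e-15) return()
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      recurse(k + 1L, used_a, used_b, score + cand[k, 3], n + 1L)
      used_a[i] <- FALSE; used_b[j] <- FALSE
    }
    recurse(k + 1L, used_a, used_b, score, n)
  }
  recurse(1L, logical(nrow(a$peaks)), logical(nrow(b$peaks)), 0, 0L)
  c(cosine = min(best$score / norm, 1), matched_peaks = best$n)
}

# All-pairs brute-force oracle for neutral-loss detection.
oracle_detect_losses <- function(spec, catalog, tol) {
  src <- c(spec$precursor_mz, spec$peaks[, "mz"])
  labels <- character()
  for (li in seq_len(nrow(catalog))) {
    for (i in seq_along(src)) {
      for (j in seq_len(nrow(spec$peaks))) {
        hi <- src[i]; lo <- spec$peaks[j, "mz"]
        if (hi <= lo) next
        if (i >= 2 && (i - 1) == j) next
        if (abs((hi - lo) - catalog$mass[li]) <= tolerance_window(tol, hi)) {
          labels <- c(labels, catalog$label[li])
        }
      }
    }
  }
  sort(unique(labels))
}

# Random valid spectrum for fuzzing (some peaks shared with a partner).
random_spectrum <- function(node_id, n_peaks, precursor = NULL) {
  if (is.null(precursor)) precursor <- runif(1, 150, 450)
  mz <- sort(runif(n_peaks, 50, precursor - 1))
  spectrum(node_id, precursor, cbind(mz, runif(n_peaks, 10, 1000)))
}
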