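#' Construct an MS2 spectrum
#'
#' One MS2 scan / network node: a feature identifier, precursor m/z,
#' optional retention time (seconds) and a peak list. Peaks are sorted
#' ascending by m/z and peaks closer than 1e-6 Da are merged (summed
#' intensity), so the stored list satisfies the class invariants by
#' construction. Zero-peak spectra are allowed (MGF exports contain
#' them) but flagged via `attr(x, "empty")`.
#'
#' @param node_id Integer or character feature identifier.
#' @param precursor_mz Precursor m/z (> 0).
#' @param peaks Two-column matrix-like of (mz, intensity), or `NULL`.
#' @param retention_time Seconds, or `NA`.
#' @return An `ms2_spectrum` object.
#' @export
spectrum <- function(node_id, precursor_mz, peaks = NULL,
                     retention_time = NA_real_) {
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      is.na(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number")
  if (is.null(peaks) || (is.data.frame(peaks) && nrow(peaks) == 0L) ||
      (is.matrix(peaks) && nrow(peaks) == 0L) || !length(peaks)) {
    pk <- matrix(numeric(), ncol = 2,
                 dimnames = list(NULL, c("mz", "intensity")))
  } else {
    pk <- as.matrix(peaks)
    if (ncol(pk) != 2) stop("peaks must have two columns (mz, intensity)")
    colnames(pk) <- c("mz", "intensity")
    storage.mode(pk) <- "double"
    if (anyNA(pk)) stop("NA in peak list")
    if (any(pk[, "mz"] <= 0)) stop("non-positive peak m/z")
    if (any(pk[, "intensity"] < 0)) stop("negative peak intensity")
    pk <- pk[order(pk[, "mz"]), , drop = FALSE]
    if (nrow(pk) > 1L) {
      grp <- cumsum(c(TRUE, diff(pk[, "mz"]) > 1e-6))
      if (max(grp) < nrow(pk)) {
        mz <- tapply(pk[, "mz"], grp, function(x) x[1])
        it <- tapply(pk[, "intensity"], grp, sum)
        pk <- cbind(mz = as.numeric(mz), intensity = as.numeric(it))
      }
    }
  }
  structure(list(node_id = node_id, precursor_mz = precursor_mz,
                 retention_time = retention_time, peaks = pk),
            class = "ms2_spectrum", empty = nrow(pk) == 0L)
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS2 spectrum node %s: precursor m/z %.4f, %d peak(s)\n",
              as.character(x$node_id), x$precursor_mz, nrow(x$peaks)))
  invisible(x)
}

#' Read an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks. `PEPMASS` (first token) becomes
#' the precursor m/z; `FEATURE_ID` is preferred over `SCANS` as the node
#' id (MZmine FBMN export convention); `RTINSECONDS` is kept as the
#' retention time. Entries without peaks are retained and flagged.
#'
#' @param path MGF file path.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^\\s*BEGIN IONS\\s*$", lines)
  ends <- grep("^\\s*END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pep <- getv("PEPMASS")
    if (is.na(pep))
      stop("MGF entry ", k, " is missing PEPMASS")
    precursor <- as.numeric(strsplit(trimws(pep), "\\s+")[[1]][1])
    node_id <- getv("FEATURE_ID")
    if (is.na(node_id)) node_id <- getv("SCANS")
    if (is.na(node_id)) node_id <- as.character(k)
    rt <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    peak_lines <- block[!is_kv]
    pk <- NULL
    if (length(peak_lines)) {
      parts <- strsplit(trimws(peak_lines), "\\s+")
      bad <- which(vapply(parts, length, 0L) < 2L)
      if (length(bad))
        stop("unreadable peak line ", begins[k] + which(!is_kv)[bad[1]],
             " in entry ", k)
      num <- suppressWarnings(
        matrix(as.numeric(unlist(lapply(parts, `[`, 1:2))),
               ncol = 2, byrow = TRUE))
      if (anyNA(num))
        stop("non-numeric peak values in entry ", k)
      pk <- num
    }
    out[[k]] <- spectrum(node_id, precursor, pk, rt)
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "ms2_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("FEATURE_ID=", as.character(s$node_id)), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$retention_time))
      writeLines(sprintf("RTINSECONDS=%.3f", s$retention_time), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.6f %.6f", s$peaks[, "mz"],
                         s$peaks[, "intensity"]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Construct a feature quantification table
#'
#' Features-by-samples peak-area matrix with per-sample group labels,
#' the container consumed by the differential-statistics stage.
#'
#' @param feature_id Character/integer vector of feature ids.
#' @param mz,rt Numeric vectors aligned with `feature_id` (rt seconds;
#'   `NA` allowed).
#' @param areas Matrix features x samples of non-negative areas.
#' @param groups Named character vector, sample id -> group label, one
#'   entry per column of `areas`.
#' @return A `feature_table` object.
#' @export
feature_table <- function(feature_id, mz, rt, areas, groups) {
  areas <- as.matrix(areas)
  if (!nrow(areas) || !length(feature_id)) stop("no features")
  if (nrow(areas) != length(feature_id))
    stop("areas rows do not match feature ids")
  if (length(mz) != length(feature_id) || length(rt) != length(feature_id))
    stop("mz/rt not aligned with feature ids")
  if (is.null(colnames(areas))) stop("areas must carry sample column names")
  if (anyNA(areas)) stop("NA areas; impute before construction")
  if (any(areas < 0)) stop("negative peak areas")
  missing <- setdiff(colnames(areas), names(groups))
  if (length(missing))
    stop("sample(s) without group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(areas)]
  structure(list(feature_id = as.character(feature_id), mz = mz, rt = rt,
                 samples = colnames(areas), groups = groups, areas = areas),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature table: %d features x %d samples (%d group(s): %s)\n",
              nrow(x$areas), ncol(x$areas), length(unique(x$groups)),
              paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

#' Read a feature quantification table
#'
#' Reads MZmine/Compound Discoverer-style delimited exports. The
#' delimiter (comma or tab) is sniffed from the header line. The
#' feature-id, m/z and retention-time columns are recognized by name
#' (`row ID`/`id`/`feature_id`; names containing `m/z` or `mz`; names
#' containing `rt` or `retention`); every remaining numeric column is a
#' sample, with MZmine's `" Peak area"` suffix stripped. Missing areas
#' are imputed as 0 and counted in `attr(, "load_report")`.
#'
#' @param path Delimited text file.
#' @param group_map Named character vector sample -> group; every sample
#'   column must be present in it.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, group_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(gregexpr("\t", header, fixed = TRUE)) >=
             lengths(gregexpr(",", header, fixed = TRUE))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no features in ", path)
  nm <- names(df)
  low <- tolower(nm)
  id_col <- which(low %in% c("row id", "id", "feature_id", "feature id"))[1]
  if (is.na(id_col)) id_col <- 1L
  mz_col <- which(grepl("m/z|\\bmz\\b", low))[1]
  rt_col <- which(grepl("retention|\\brt\\b", low))[1]
  sample_cols <- setdiff(seq_along(nm),
                         c(id_col, mz_col, rt_col)[!is.na(c(id_col, mz_col, rt_col))])
  if (!length(sample_cols)) stop("no sample columns in ", path)
  areas <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(areas) <- "double"
  colnames(areas) <- sub("[ .]Peak[ .]area$", "", nm[sample_cols])
  n_imputed <- sum(is.na(areas))
  areas[is.na(areas)] <- 0
  if (any(areas < 0)) stop("negative peak area in ", path)
  missing <- setdiff(colnames(areas), names(group_map))
  if (length(missing))
    stop("sample(s) absent from group_map: ", paste(missing, collapse = ", "))
  tbl <- feature_table(
    feature_id = as.character(df[[id_col]]),
    mz = if (!is.na(mz_col)) as.numeric(df[[mz_col]]) else rep(NA_real_, nrow(df)),
    rt = if (!is.na(rt_col)) as.numeric(df[[rt_col]]) else rep(NA_real_, nrow(df)),
    areas = areas, groups = group_map[colnames(areas)]
  )
  attr(tbl, "load_report") <- list(n_imputed = n_imputed, delimiter = sep)
  tbl
}

#' Write a feature table (tab-delimited)
#'
#' @param tbl A [feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "feature_table"))
  df <- data.frame(`row ID` = tbl$feature_id, `row m/z` = tbl$mz,
                   `row retention time` = tbl$rt, check.names = FALSE)
  df <- cbind(df, as.data.frame(tbl$areas, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
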