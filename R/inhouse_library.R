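#' Canonical compound-name key
#'
#' Case-folds and strips punctuation/whitespace; the deduplication key
#' when literature and public-library entries are merged.
#'
#' @param name Character vector.
#' @export
canonical_name <- function(name) {
  gsub("[^a-z0-9]", "", tolower(name))
}

.KNOWN_CLASSES <- c("coumarin", "cinnamic_acid", "flavonoid", "alkaloid",
                    "fatty_acid", "benzene_derivative", "terpenoid", "other")

.new_library <- function(df) {
  df <- df[order(df$mh_mz, canonical_name(df$name)), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(compounds = df), class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  tab <- table(x$compounds$class)
  cat(sprintf("in-house library: %d compound(s) (%s)\n",
              nrow(x$compounds),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Build the in-house compound library
#'
#' Merges literature-curated compounds with high-confidence public
#' spectral-library matches. Public entries are admitted only above the
#' match-score cutoff (default 0.9); entries sharing a canonical name
#' are merged with `source = "both"`. The `[M+H]+` m/z is always
#' recomputed from the formula, never trusted from the input. Entries
#' whose formula fails to parse are dropped with a warning and listed in
#' `attr(, "rejected")`.
#'
#' @param literature_entries data.frame with columns `name`, `formula`,
#'   `class` (optional `subclass`).
#' @param public_entries Same columns plus `score` (similarity in
#'   `[0, 1]`); may be `NULL` or empty.
#' @param min_public_score Admission cutoff on `score` (strict `>`).
#' @return A `compound_library` whose `compounds` data.frame has columns
#'   `name`, `formula`, `class`, `subclass`, `source`, `score`,
#'   `neutral_mass`, `mh_mz`, sorted by `mh_mz` (the lookup index).
#' @export
build_library <- function(literature_entries, public_entries = NULL,
                          min_public_score = 0.9) {
  tidy <- function(df, source) {
    if (is.null(df) || !NROW(df)) return(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "formula", "class") %in% names(df)))
    if (is.null(df$subclass)) df$subclass <- NA_character_
    if (is.null(df$score)) df$score <- NA_real_
    bad_class <- setdiff(unique(df$class), .KNOWN_CLASSES)
    if (length(bad_class))
      stop("unknown compound class(es): ", paste(bad_class, collapse = ", "))
    df$source <- source
    df[, c("name", "formula", "class", "subclass", "source", "score")]
  }
  lit <- tidy(literature_entries, "literature")
  pub <- tidy(public_entries, "public_match")
  if (!is.null(pub)) {
    if (anyNA(pub$score)) stop("public entries must carry a match score")
    pub <- pub[pub$score > min_public_score, , drop = FALSE]
  }
  all_df <- rbind(lit, pub)
  if (is.null(all_df) || !nrow(all_df)) {
    lib <- .new_library(data.frame(
      name = character(), formula = character(), class = character(),
      subclass = character(), source = character(), score = numeric(),
      neutral_mass = numeric(), mh_mz = numeric(), stringsAsFactors = FALSE))
    attr(lib, "rejected") <- character()
    return(lib)
  }
  mass <- rep(NA_real_, nrow(all_df))
  for (i in seq_len(nrow(all_df))) {
    m <- tryCatch(monoisotopic_mass(parse_formula(all_df$formula[i])),
                  error = function(e) NA_real_)
    mass[i] <- m
  }
  rejected <- all_df$name[is.na(mass)]
  if (length(rejected))
    warning("rejected entr(ies) with unparseable formula: ",
            paste(rejected, collapse = ", "))
  all_df <- all_df[!is.na(mass), , drop = FALSE]
  mass <- mass[!is.na(mass)]
  all_df$neutral_mass <- mass
  all_df$mh_mz <- adduct_mz(mass, "[M+H]+")
  key <- canonical_name(all_df$name)
  merged <- lapply(split(seq_len(nrow(all_df)), key), function(idx) {
    rows <- all_df[idx, , drop = FALSE]
    out <- rows[which.max(rows$source == "literature"), , drop = FALSE]
    if (length(unique(rows$source)) > 1L) out$source <- "both"
    if (any(!is.na(rows$score))) out$score <- max(rows$score, na.rm = TRUE)
    out
  })
  lib <- .new_library(do.call(rbind, merged))
  attr(lib, "rejected") <- rejected
  lib
}

#' Match a precursor m/z against the library
#'
#' Windowed lookup over the mh_mz-sorted index; returns all entries
#' within tolerance (isomers give multiple hits), sorted by absolute
#' ppm error.
#'
#' @param lib A `compound_library`.
#' @param prec_mz Precursor m/z (> 0).
#' @param tol Precursor-level [mass_tolerance()] (default 10 ppm).
#' @return data.frame of matching compounds with an extra `delta_ppm`
#'   column; zero rows when nothing matches.
#' @export
match_precursor <- function(lib, prec_mz, tol = precursor_tolerance()) {
  stopifnot(inherits(lib, "compound_library"))
  if (!is.numeric(prec_mz) || length(prec_mz) != 1L || prec_mz <= 0)
    stop("prec_mz must be a single positive number")
  df <- lib$compounds
  empty <- cbind(df[0, , drop = FALSE], delta_ppm = numeric())
  if (!nrow(df)) return(empty)
  win <- max(tolerance_window(tol, prec_mz), tolerance_window(tol, df$mh_mz))
  lo <- findInterval(prec_mz - win - 1e-9, df$mh_mz)
  hi <- findInterval(prec_mz + win + 1e-9, df$mh_mz)
  if (hi <= lo) return(empty)
  cand <- df[(lo + 1L):hi, , drop = FALSE]
  keep <- within_tolerance(prec_mz, cand$mh_mz, tol)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand$delta_ppm <- ppm_difference(prec_mz, cand$mh_mz)
  cand <- cand[order(abs(cand$delta_ppm), canonical_name(cand$name)), ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Read / write a compound library file
#'
#' Tab-delimited text with columns `name`, `formula`, `class`,
#' `subclass`, `source`, `score`. Masses are recomputed on load.
#'
#' @param path File path.
#' @param min_public_score Passed to [build_library()].
#' @return A `compound_library`.
#' @export
read_library <- function(path, min_public_score = 0.9) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  src <- if (is.null(df$source)) rep("literature", nrow(df)) else df$source
  lit <- df[src != "public_match", , drop = FALSE]
  pub <- df[src == "public_match", , drop = FALSE]
  build_library(if (nrow(lit)) lit else NULL,
                if (nrow(pub)) pub else NULL,
                min_public_score = min_public_score)
}

#' @rdname read_library
#' @param lib A `compound_library`.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "compound_library"))
  utils::write.table(
    lib$compounds[, c("name", "formula", "class", "subclass", "source", "score")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged starter library
#'
#' The compounds named in the accompanying study (scopoletin,
#' isofraxidin, scopolin, the chimsalicifoliusin dimers, the common
#' cinnamic acids, two flavonoid glycosides, ...) with formulas from
#' public chemistry references. The bicoumarin formulas
#' (chimsalicifoliusins, arteminorin A) are inferred from their printed
#' precursor masses and monomer compositions; see the package vignette.
#'
#' @return A `compound_library`.
#' @export
starter_library <- function() {
  path <- system.file("extdata", "starter_library.tsv",
                      package = "coumascreen", mustWork = TRUE)
  read_library(path)
}
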