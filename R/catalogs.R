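#' Neutral-loss catalog
#'
#' The small neutral moieties that coumarins and cinnamic acids shed
#' under positive-mode CID: CH3 (methyl radical from methoxy groups),
#' CHO, CO and CO2 (lactone/carboxyl ring contractions), C2H2, H2O and
#' CH2. Masses are always recomputed from the compositions, so the
#' label/composition/mass triple cannot drift apart.
#'
#' @param extra Optional data.frame with columns `label`, `formula` to
#'   extend the catalog (e.g. from a config file).
#' @param include_radical_h If `TRUE`, adds a 1.00783 Da "H" step. Some
#'   published coumarin spectra annotate fragments sitting ~1 Da below
#'   the plain-loss ladder (an unannotated extra hydrogen loss); this
#'   step lets a ladder reproduce them, but it is off by default and no
#'   class rule uses it.
#' @return data.frame with columns `label`, `formula`, `mass` (Da).
#' @examples
#' loss_catalog()
#' @export
loss_catalog <- function(extra = NULL, include_radical_h = FALSE) {
  base <- data.frame(
    label = c("CH3", "CHO", "CO", "CO2", "C2H2", "H2O", "CH2"),
    formula = c("CH3", "CHO", "CO", "CO2", "C2H2", "H2O", "CH2"),
    stringsAsFactors = FALSE
  )
  if (include_radical_h)
    base <- rbind(base, data.frame(label = "H", formula = "H"))
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), all(c("label", "formula") %in% names(extra)))
    base <- rbind(base, extra[, c("label", "formula")])
  }
  if (anyDuplicated(base$label))
    stop("duplicate loss labels in catalog: ",
         paste(unique(base$label[duplicated(base$label)]), collapse = ", "))
  base$mass <- vapply(base$formula,
                      function(f) monoisotopic_mass(parse_formula(f)), 0)
  rownames(base) <- NULL
  base
}

#' Read a loss-catalog override file
#'
#' Plain two-column delimited text (`label`, `formula`), one loss per
#' line; replaces the default catalog.
#'
#' @param path File path.
#' @return data.frame as from [loss_catalog()].
#' @export
read_loss_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("label", "formula") %in% names(df)))
  if (anyDuplicated(df$label)) stop("duplicate loss labels in ", path)
  df$mass <- vapply(df$formula,
                    function(f) monoisotopic_mass(parse_formula(f)), 0)
  df[, c("label", "formula", "mass")]
}

.catalog_mass <- function(catalog, labels) {
  idx <- match(labels, catalog$label)
  if (anyNA(idx))
    stop("loss label(s) not in catalog: ",
         paste(labels[is.na(idx)], collapse = ", "))
  catalog$mass[idx]
}

#' Modification catalog for structural-unit assembly
#'
#' Mass differences between an annotated structural unit and the node
#' precursor are explained as combinations of these common plant
#' phase-II / substitution modifications.
#'
#' @return data.frame with columns `label`, `formula`, `mass` (Da):
#'   hexosylation +162.05282, methylation +14.01565, hydroxylation
#'   +15.99491, methoxylation +30.01057, acetylation +42.01057.
#' @export
modification_catalog <- function() {
  df <- data.frame(
    label = c("hexosylation", "methylation", "hydroxylation",
              "methoxylation", "acetylation"),
    formula = c("C6H10O5", "CH2", "O", "CH2O", "C2H2O"),
    stringsAsFactors = FALSE
  )
  df$mass <- vapply(df$formula,
                    function(f) monoisotopic_mass(parse_formula(f)), 0)
  df
}

#' Class-specific fragmentation loss sequences
#'
#' The branching neutral-loss pathways used both to synthesize class
#' spectra and to build per-candidate diagnostic-ion sets. Coumarins
#' fragment by sequential CH3/CHO/CO/CO2/C2H2 losses from the
#' protonated molecule; cinnamic acids by H2O and CO, with additional
#' 15 Da CH3 branches when a methoxy substituent is present (ferulic /
#' sinapinic type).
#'
#' @param compound_class `"coumarin"` or `"cinnamic_acid"`.
#' @param methoxylated For cinnamic acids, add the CH3-loss branches.
#' @return List of character vectors of loss labels (each a sequential
#'   pathway from the precursor).
#' @export
class_loss_sequences <- function(compound_class = c("coumarin", "cinnamic_acid"),
                                 methoxylated = FALSE) {
  compound_class <- match.arg(compound_class)
  if (compound_class == "coumarin") {
    list(c("CH3", "CHO", "CO2", "CO"),
         c("CH3", "CO2", "CH3", "C2H2"),
         c("CO", "CO2", "C2H2"),
         c("CHO", "CO", "C2H2"))
  } else {
    seqs <- list(c("H2O", "CO"), c("CO", "CO"))
    if (methoxylated)
      seqs <- c(seqs, list("CH3", c("CH3", "H2O"), c("CH3", "H2O", "CO")))
    seqs
  }
}
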