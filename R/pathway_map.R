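.PATHWAY_ENZYMES <- c("PAL", "TAL", "C3H", "C4H", "OMT", "2GT", "3CL",
                      "4CL", "F6'H", "C2'H", "COSY", "S8H")

.PATHWAY_SYNONYMS <- c(
  "isofraxin" = "isofraxidin",
  "scoparone" = "6,7-dimethoxycoumarin",
  "aesculetin" = "esculetin",
  "4-coumaric acid" = "p-coumaric acid",
  "trans-cinnamic acid" = "cinnamic acid"
)

.pathway_canonical <- function(name) {
  key <- tolower(trimws(name))
  syn_keys <- tolower(names(.PATHWAY_SYNONYMS))
  hit <- match(key, syn_keys)
  out <- ifelse(is.na(hit), key, tolower(.PATHWAY_SYNONYMS[hit]))
  unname(out)
}

#' Load a coumarin biosynthetic pathway graph
#'
#' Reads a directed pathway definition (delimited text: `from`, `to`,
#' `enzyme`, `authenticated`). The default is the packaged
#' phenylpropanoid-to-coumarin route: phenylalanine/tyrosine through
#' the cinnamic acids (PAL/TAL/C4H/C3H/OMT) to umbelliferone,
#' esculetin, scopoletin and onward to scopolin (2GT), fraxetin (S8H)
#' and isofraxidin (OMT). Steps drawn without enzymatic authentication
#' are flagged `authenticated = FALSE`. The graph must be a DAG and
#' every enzyme label must come from the recognized legend.
#'
#' @param path Optional path to a pathway file; default uses the
#'   packaged graph.
#' @return A `pathway_graph`: list with `nodes` (character) and `edges`
#'   (data.frame `from`, `to`, `enzyme`, `authenticated`).
#' @export
coumarin_pathway <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "coumarin_pathway.tsv",
                        package = "coumascreen", mustWork = TRUE)
  edges <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "enzyme", "authenticated") %in% names(edges)))
  edges$authenticated <- as.logical(edges$authenticated)
  bad <- setdiff(edges$enzyme, .PATHWAY_ENZYMES)
  if (length(bad))
    stop("enzyme label(s) outside the legend: ", paste(bad, collapse = ", "))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = TRUE)
  if (!igraph::is_dag(g)) stop("pathway graph contains a cycle")
  structure(list(nodes = sort(unique(c(edges$from, edges$to))), edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway graph: %d compound(s), %d step(s) (%d unauthenticated)\n",
              length(x$nodes), nrow(x$edges), sum(!x$edges$authenticated)))
  invisible(x)
}

#' Report pathway coverage of a screening run
#'
#' Which biosynthetic intermediates did the annotation run observe?
#' Annotated compound names (library matches and modification bases)
#' are matched against pathway node names case-insensitively with a
#' synonym table (e.g. "isofraxin" = "isofraxidin"). Exact set
#' arithmetic: covered nodes, uncovered nodes, and pathway steps whose
#' two endpoints are both covered.
#'
#' @param annotations [screen_corpus()] output, a list of
#'   `annotation_result`, an [annotations_to_df()] data.frame, or a
#'   plain character vector of compound names.
#' @param graph A `pathway_graph` (default: packaged coumarin pathway).
#' @return List with `covered`, `uncovered` (character vectors of node
#'   names), `edges_covered` (data.frame subset of graph edges),
#'   `n_covered`, `n_nodes`.
#' @export
pathway_coverage <- function(annotations, graph = coumarin_pathway()) {
  stopifnot(inherits(graph, "pathway_graph"))
  names_seen <- if (is.character(annotations)) annotations else {
    ann <- if (is.data.frame(annotations)) annotations
    else annotations_to_df(annotations)
    c(unlist(strsplit(ann$library_matches, ";")),
      sub("\\+.*$", "", ann$modification_call[nzchar(ann$modification_call)]))
  }
  seen <- unique(.pathway_canonical(names_seen[nzchar(names_seen)]))
  node_key <- .pathway_canonical(graph$nodes)
  covered <- graph$nodes[node_key %in% seen]
  uncovered <- setdiff(graph$nodes, covered)
  ec <- graph$edges[graph$edges$from %in% covered &
                      graph$edges$to %in% covered, , drop = FALSE]
  rownames(ec) <- NULL
  list(covered = covered, uncovered = uncovered, edges_covered = ec,
       n_covered = length(covered), n_nodes = length(graph$nodes))
}

#' Write a pathway coverage report
#'
#' @param coverage Result of [pathway_coverage()].
#' @param path Output path (tab-delimited).
#' @export
write_pathway_coverage <- function(coverage, path) {
  df <- data.frame(
    compound = c(coverage$covered, coverage$uncovered),
    covered = c(rep(TRUE, length(coverage$covered)),
                rep(FALSE, length(coverage$uncovered))),
    stringsAsFactors = FALSE)
  df <- df[order(df$compound), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
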