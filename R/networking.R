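#' Modified cosine similarity between two MS2 spectra
#'
#' Cosine similarity over one-to-one matched peak pairs with
#' square-root intensity weighting. Peaks match either directly
#' (|delta m/z| within tolerance) or, when `precursor_shift = TRUE`,
#' offset by the precursor mass difference, so analogs differing by one
#' modification still align. The peak pairing is solved as a
#' maximum-weight bipartite assignment over the candidate pairs
#' (`method = "optimal"`); a greedy approximation is available for
#' speed.
#'
#' @param a,b [spectrum()] objects with at least one peak each.
#' @param tol Fragment-level [mass_tolerance()].
#' @param precursor_shift Allow precursor-difference-shifted matches.
#' @param method `"optimal"` (exact assignment) or `"greedy"`.
#' @return Named numeric vector `c(cosine, matched_peaks)`.
#' @export
modified_cosine <- function(a, b, tol = fragment_tolerance(),
                            precursor_shift = TRUE,
                            method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "ms2_spectrum"), inherits(b, "ms2_spectrum"))
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L)
    stop("modified_cosine requires non-empty peak lists")
  wa <- sqrt(a$peaks[, "intensity"])
  wb <- sqrt(b$peaks[, "intensity"])
  norm <- sqrt(sum(wa^2)) * sqrt(sum(wb^2))
  if (norm == 0) return(c(cosine = 0, matched_peaks = 0))
  shift <- a$precursor_mz - b$precursor_mz
  dm <- outer(a$peaks[, "mz"], b$peaks[, "mz"], "-")
  win <- outer(a$peaks[, "mz"], b$peaks[, "mz"],
               function(x, y) tolerance_window(tol, (x + y) / 2))
  cand <- abs(dm) <= win
  if (precursor_shift && abs(shift) > 1e-9)
    cand <- cand | (abs(dm - shift) <= win)
  idx <- which(cand, arr.ind = TRUE)
  if (!nrow(idx)) return(c(cosine = 0, matched_peaks = 0))
  w <- wa[idx[, 1]] * wb[idx[, 2]]
  pos <- w > 0
  idx <- idx[pos, , drop = FALSE]
  w <- w[pos]
  if (!length(w)) return(c(cosine = 0, matched_peaks = 0))

  one_to_one <- !anyDuplicated(idx[, 1]) && !anyDuplicated(idx[, 2])
  if (one_to_one) {
    total <- sum(w)
    n_match <- length(w)
  } else if (method == "greedy") {
    ord <- order(-w)
    used_a <- logical(nrow(a$peaks)); used_b <- logical(nrow(b$peaks))
    total <- 0; n_match <- 0L
    for (i in ord) {
      ia <- idx[i, 1]; ib <- idx[i, 2]
      if (!used_a[ia] && !used_b[ib]) {
        used_a[ia] <- TRUE; used_b[ib] <- TRUE
        total <- total + w[i]; n_match <- n_match + 1L
      }
    }
  } else {
    na <- nrow(a$peaks)
    g <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, na), rep(TRUE, nrow(b$peaks))),
      edges = as.vector(t(cbind(idx[, 1], idx[, 2] + na))))
    m <- igraph::max_bipartite_match(g, weights = w)$matching
    matched_a <- which(!is.na(m[seq_len(na)]))
    total <- 0; n_match <- 0L
    for (ia in matched_a) {
      ib <- m[ia] - na
      total <- total + wa[ia] * wb[ib]
      n_match <- n_match + 1L
    }
  }
  c(cosine = min(total / norm, 1), matched_peaks = n_match)
}

#' Build a molecular network from a spectrum corpus
#'
#' All spectrum pairs are scored with [modified_cosine()]; an edge is
#' kept when the cosine strictly exceeds `min_cosine` ("above 0.6") and
#' the matched-peak count is at least `min_matched` ("at least 5").
#' Optional top-K pruning keeps an edge only if it ranks among the K
#' best of at least one endpoint. Molecular families are the connected
#' components of the thresholded graph; unconnected nodes are singleton
#' families.
#'
#' @param spectra List of [spectrum()] objects (ids must be unique).
#' @param min_cosine Cosine threshold (strict).
#' @param min_matched Minimum matched peaks (inclusive).
#' @param tol Fragment-level tolerance.
#' @param precursor_shift Allow shifted peak matches.
#' @param max_neighbors Optional top-K neighbor pruning.
#' @return A `molecular_network`: list with `edges` (data.frame
#'   `node_a`, `node_b`, `cosine`, `matched_peaks`; `node_a < node_b`),
#'   `families` (data.frame `node_id`, `family_id`) and `node_ids`.
#' @export
build_network <- function(spectra, min_cosine = 0.6, min_matched = 5L,
                          tol = fragment_tolerance(), precursor_shift = TRUE,
                          max_neighbors = NULL) {
  if (!length(spectra)) stop("no spectra")
  ids <- vapply(spectra, function(s) as.character(s$node_id), "")
  if (anyDuplicated(ids)) stop("duplicate node ids in corpus")
  ord <- order(ids)
  spectra <- spectra[ord]; ids <- ids[ord]
  n <- length(spectra)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (nrow(spectra[[i]]$peaks) == 0L) next
      for (j in (i + 1L):n) {
        if (nrow(spectra[[j]]$peaks) == 0L) next
        s <- modified_cosine(spectra[[i]], spectra[[j]], tol, precursor_shift)
        if (s["cosine"] > min_cosine && s["matched_peaks"] >= min_matched)
          rows[[length(rows) + 1L]] <- data.frame(
            node_a = ids[i], node_b = ids[j],
            cosine = unname(s["cosine"]),
            matched_peaks = as.integer(s["matched_peaks"]),
            stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows)
  else data.frame(node_a = character(), node_b = character(),
                  cosine = numeric(), matched_peaks = integer(),
                  stringsAsFactors = FALSE)
  if (!is.null(max_neighbors) && nrow(edges)) {
    keep <- logical(nrow(edges))
    for (id in ids) {
      inc <- which(edges$node_a == id | edges$node_b == id)
      if (!length(inc)) next
      top <- inc[order(-edges$cosine[inc])][seq_len(min(max_neighbors,
                                                        length(inc)))]
      keep[top] <- TRUE
    }
    edges <- edges[keep, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  # family ids numbered by smallest member node id for determinism
  first_member <- vapply(split(names(comp), comp), min, "")
  relabel <- stats::setNames(rank(first_member, ties.method = "first"),
                             names(first_member))
  fam <- data.frame(node_id = names(comp),
                    family_id = paste0("F", relabel[as.character(comp)]),
                    stringsAsFactors = FALSE)
  fam <- fam[order(fam$node_id), , drop = FALSE]
  rownames(fam) <- NULL
  rownames(edges) <- NULL
  structure(list(edges = edges, families = fam, node_ids = ids),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("molecular network: %d node(s), %d edge(s), %d famil(ies)\n",
              length(x$node_ids), nrow(x$edges),
              length(unique(x$families$family_id))))
  invisible(x)
}

#' Propagate annotation class labels onto molecular families
#'
#' Each family carries every class present among its annotated members
#' with a member support count; mixed families (e.g. coumarin plus
#' cinnamic acid) keep both labels.
#'
#' @param network A `molecular_network` (or its `families` data.frame).
#' @param annotations [screen_corpus()] output, a list of
#'   `annotation_result`, or an [annotations_to_df()] data.frame.
#' @return data.frame `family_id`, `class`, `support`, `family_size`,
#'   one row per (family, class) pair; families with no annotated
#'   members are absent.
#' @export
propagate_class <- function(network, annotations) {
  fam <- if (inherits(network, "molecular_network")) network$families
  else network
  ann <- if (is.data.frame(annotations)) annotations
  else annotations_to_df(annotations)
  primary <- stats::setNames(
    vapply(strsplit(ann$class_call, ";"), function(x)
      if (length(x) && nzchar(x[1])) x[1] else NA_character_, ""),
    ann$node_id)
  fam$class <- primary[fam$node_id]
  sizes <- table(fam$family_id)
  with_class <- fam[!is.na(fam$class), , drop = FALSE]
  if (!nrow(with_class))
    return(data.frame(family_id = character(), class = character(),
                      support = integer(), family_size = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(support = with_class$node_id),
                          by = list(family_id = with_class$family_id,
                                    class = with_class$class),
                          FUN = length)
  agg$family_size <- as.integer(sizes[agg$family_id])
  agg <- agg[order(agg$family_id, -agg$support, agg$class), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Export a molecular network
#'
#' GraphML (loadable by Cytoscape and other viewers) with node
#' attributes `precursor_mz`, `class_call`, `tier` and edge attributes
#' `cosine`, `matched_peaks`; or a plain edge-list TSV.
#'
#' @param network A `molecular_network`.
#' @param path Output path.
#' @param spectra Optional spectrum list to attach precursor m/z.
#' @param annotations Optional annotations to attach class/tier.
#' @export
write_graphml <- function(network, path, spectra = NULL, annotations = NULL) {
  stopifnot(inherits(network, "molecular_network"))
  verts <- data.frame(name = network$node_ids, stringsAsFactors = FALSE)
  if (!is.null(spectra)) {
    prec <- stats::setNames(
      vapply(spectra, function(s) s$precursor_mz, 0),
      vapply(spectra, function(s) as.character(s$node_id), ""))
    verts$precursor_mz <- unname(prec[verts$name])
  }
  if (!is.null(annotations)) {
    ann <- if (is.data.frame(annotations)) annotations
    else annotations_to_df(annotations)
    verts$class_call <- ann$class_call[match(verts$name, ann$node_id)]
    verts$tier <- ann$tier[match(verts$name, ann$node_id)]
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "molecular_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
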