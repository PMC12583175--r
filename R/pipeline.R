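.PIPELINE_KEYS <- list(
  input = c("mgf", "library", "feature_table", "groups", "pairs"),
  screening = c("precursor_ppm", "fragment_ppm", "fragment_dalton",
                "score_threshold", "min_diagnostic_set_size",
                "modification_max_steps", "dimer_min_mz"),
  network = c("min_cosine", "min_matched", "max_neighbors"),
  diffstats = c("fc_threshold", "p_threshold", "vip_threshold",
                "n_components", "scaling"),
  version = character()
)

.default_pipeline_config <- function() {
  list(
    input = list(mgf = NULL, library = NULL, feature_table = NULL,
                 groups = NULL, pairs = NULL),
    screening = list(precursor_ppm = 10, fragment_ppm = 20,
                     fragment_dalton = 0.01, score_threshold = 0.6,
                     min_diagnostic_set_size = 3, modification_max_steps = 2,
                     dimer_min_mz = 300),
    network = list(min_cosine = 0.6, min_matched = 5, max_neighbors = NULL),
    diffstats = list(fc_threshold = 2, p_threshold = 0.05, vip_threshold = 1,
                     n_components = 2, scaling = "unit_variance"),
    version = as.character(utils::packageVersion("coumascreen"))
  )
}

#' Load and validate a pipeline configuration
#'
#' YAML (or an R list) with sections `input`, `screening`, `network`,
#' `diffstats`. Unknown keys are rejected; omitted keys take the
#' workflow defaults. The resolved configuration is logged next to the
#' outputs on every run.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return The resolved configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  base <- .default_pipeline_config()
  bad_sections <- setdiff(names(config), names(.PIPELINE_KEYS))
  if (length(bad_sections))
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  for (sec in names(config)) {
    if (sec == "version") next
    bad <- setdiff(names(config[[sec]]), .PIPELINE_KEYS[[sec]])
    if (length(bad))
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    base[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  base
}

.config_to_screening <- function(cfg) {
  screening_config(
    precursor_tol = precursor_tolerance(cfg$screening$precursor_ppm),
    fragment_tol = fragment_tolerance(cfg$screening$fragment_ppm,
                                      cfg$screening$fragment_dalton),
    score_threshold = cfg$screening$score_threshold,
    min_diagnostic_set_size = cfg$screening$min_diagnostic_set_size,
    modification_max_steps = cfg$screening$modification_max_steps,
    dimer_min_mz = cfg$screening$dimer_min_mz)
}

#' Run the full screening pipeline
#'
#' Networking, automatic screening, class propagation, differential
#' statistics (when a feature table is configured) and pathway
#' coverage, in the order of the underlying workflow, writing plain
#' delimited reports to `out_dir`:
#' `network_edges.tsv`, `network.graphml`, `annotations.tsv`,
#' `family_classes.tsv`, `pathway_coverage.tsv`,
#' `diffstats/<pair>_volcano.tsv`, `diffstats/vip.tsv`,
#' `diffstats/selection_<pair>.tsv`, plus `resolved_config.yaml`.
#' Deterministic: re-running on identical inputs reproduces every
#' report byte for byte.
#'
#' @param config Path to a YAML config or a list (see
#'   [pipeline_config()]); `input$mgf` and `input$library` are
#'   required.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the per-stage objects and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- pipeline_config(config)
  for (key in c("mgf", "library")) {
    path <- cfg$input[[key]]
    if (is.null(path)) stop("config input$", key, " is required")
    if (!file.exists(path)) stop("input file not found: ", path)
  }
  if (cfg$screening$score_threshold <= 0)
    warning("score_threshold <= 0: degenerate screening ",
            "(every class-evaluated node passes); proceeding")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  spectra <- read_mgf(cfg$input$mgf)
  lib <- read_library(cfg$input$library)
  scfg <- .config_to_screening(cfg)

  net <- build_network(spectra, min_cosine = cfg$network$min_cosine,
                       min_matched = cfg$network$min_matched,
                       tol = scfg$fragment_tol,
                       max_neighbors = cfg$network$max_neighbors)
  screened <- screen_corpus(spectra, lib, cfg = scfg)
  ann_df <- annotations_to_df(screened)
  fam <- propagate_class(net, ann_df)
  cov <- pathway_coverage(ann_df)

  p <- file.path(out_dir, "network_edges.tsv")
  write_edge_list(net, p); paths <- c(paths, p)
  p <- file.path(out_dir, "network.graphml")
  write_graphml(net, p, spectra = spectra, annotations = ann_df)
  paths <- c(paths, p)
  p <- file.path(out_dir, "annotations.tsv")
  write_annotations(ann_df, p); paths <- c(paths, p)
  p <- file.path(out_dir, "family_classes.tsv")
  utils::write.table(fam, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "pathway_coverage.tsv")
  write_pathway_coverage(cov, p); paths <- c(paths, p)

  diff_out <- NULL
  if (!is.null(cfg$input$feature_table)) {
    if (is.null(cfg$input$groups))
      stop("input$groups is required with input$feature_table")
    gm <- unlist(cfg$input$groups)
    tbl <- read_feature_table(cfg$input$feature_table, gm)
    dir.create(file.path(out_dir, "diffstats"), showWarnings = FALSE)
    pls <- plsda_vip(tbl, n_components = cfg$diffstats$n_components,
                     scaling = cfg$diffstats$scaling)
    p <- file.path(out_dir, "diffstats", "vip.tsv")
    utils::write.table(
      data.frame(feature_id = names(pls$vip), vip = unname(pls$vip)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    pairs <- cfg$input$pairs
    if (is.null(pairs)) {
      gl <- unique(gm)
      pairs <- if (length(gl) >= 2L)
        utils::combn(gl, 2, paste, collapse = ":") else character()
    }
    diff_out <- list(vip = pls$vip, pairs = list())
    for (pair in pairs) {
      ab <- strsplit(pair, ":", fixed = TRUE)[[1]]
      volc <- volcano(tbl, ab[1], ab[2],
                      fc_threshold = cfg$diffstats$fc_threshold,
                      p_threshold = cfg$diffstats$p_threshold)
      sel <- select_differential(volc, pls$vip,
                                 vip_threshold = cfg$diffstats$vip_threshold)
      tag <- paste0(ab[1], "_vs_", ab[2])
      p <- file.path(out_dir, "diffstats", paste0(tag, "_volcano.tsv"))
      utils::write.table(volc, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
      p <- file.path(out_dir, "diffstats", paste0("selection_", tag, ".tsv"))
      utils::write.table(sel$results, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
      diff_out$pairs[[tag]] <- sel
    }
  }

  p <- file.path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(cfg, p); paths <- c(paths, p)
  invisible(list(network = net, screening = screened, families = fam,
                 coverage = cov, diffstats = diff_out, paths = paths))
}
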