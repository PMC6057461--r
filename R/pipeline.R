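#' Configuration of the end-to-end transcriptome pipeline
#'
#' Collects every threshold the pipeline stages use, so a run is fully
#' described (and reproducible) from its config plus its inputs.
#'
#' @param max_missing_frac Detection-filter boundary (genes with this
#'   missing fraction or more are excluded).
#' @param min_mean Intensity-filter threshold.
#' @param control_arm Control arm label (`NULL`: taken from the design).
#' @param log2 Work on log2 fold changes.
#' @param template_levels Named levels of the gradual template.
#' @param r_min PTM correlation cutoff.
#' @param alpha Enrichment significance level.
#' @param anova_alpha,anova_top_n ANOVA screen parameters (template
#'   derivation/diagnostics).
#' @param n_perm Permutations for the component-size test.
#' @param seed Seed for the permutation stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(max_missing_frac = 0.30, min_mean = 100,
                            control_arm = NULL, log2 = TRUE,
                            template_levels = c(endoRT = 1, EBRT = 2,
                                                combined = 3),
                            r_min = 0.7, alpha = 0.05,
                            anova_alpha = 0.01, anova_top_n = 500L,
                            n_perm = 999L, seed = 1L) {
  if (r_min <= 0 || r_min >= 1) stop("'r_min' must lie in (0, 1)")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("'max_missing_frac' must lie in [0, 1]")
  structure(list(max_missing_frac = max_missing_frac, min_mean = min_mean,
                 control_arm = control_arm, log2 = log2,
                 template_levels = template_levels, r_min = r_min,
                 alpha = alpha, anova_alpha = anova_alpha,
                 anova_top_n = as.integer(anova_top_n),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_header <- function(config) {
  c(sprintf("seed: %d", config$seed),
    sprintf("max_missing_frac: %g | min_mean: %g | r_min: %g | alpha: %g | n_perm: %d",
            config$max_missing_frac, config$min_mean, config$r_min,
            config$alpha, config$n_perm),
    sprintf("template_levels: %s",
            paste(names(config$template_levels), config$template_levels,
                  sep = "=", collapse = ",")))
}

#' Run the full transcriptome pipeline
#'
#' preprocess (detection filter, intensity filter, control normalization)
#' -> gradual template -> Pavlidis Template Matching -> UpCor/DownCor
#' selection -> hypergeometric enrichment -> direct-interaction network
#' with permutation largest-component significance. Inputs may be
#' in-memory objects or file paths (expression requires both matrix and
#' annotation paths).
#'
#' @param study An `expression_study`, or `c(matrix_path, annotation_path)`.
#' @param gene_sets A `gene_set_collection`, or a GMT path.
#' @param graph An [igraph::graph], or an edge-list TSV path.
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, intermediates and the summary report are
#'   written there (created if needed); re-runs with an identical config
#'   and inputs are byte-identical.
#' @return A `pipeline_report` list: `selection`, `ptm`, `enrichment_up`,
#'   `enrichment_down`, `network_up`, `network_down`, `summary` (flat
#'   named list of headline numbers), `config`.
#' @export
run_pipeline <- function(study, gene_sets, graph, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(study)) {
    stopifnot(length(study) == 2L)
    study <- read_expression(study[1], study[2])
  }
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.character(graph)) graph <- read_edges(graph)
  stopifnot(inherits(study, "expression_study"),
            inherits(gene_sets, "gene_set_collection"),
            igraph::is_igraph(graph))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  filtered <- stage("preprocess", {
    study |> filter_detection(config$max_missing_frac) |>
      filter_intensity(config$min_mean)
  })
  fc <- stage("normalize",
              normalize_to_control(filtered, config$control_arm,
                                   log2 = config$log2))
  template <- stage("template",
                    gradual_template(study$design, config$template_levels))
  ptm_res <- stage("ptm", ptm(fc, template))
  selection <- stage("select", select_correlated(ptm_res, config$r_min))

  # universe for enrichment: transcripts surviving preprocessing that are
  # in the collection's namespace
  universe <- intersect(ptm_res$gene, gene_sets$universe)
  coll <- gene_sets
  coll$universe <- universe
  enrich <- function(sel) {
    sel_u <- intersect(sel, universe)
    if (length(sel_u) == 0L) return(NULL)
    hypergeometric_enrichment(sel_u, coll, alpha = config$alpha)
  }
  enrichment_up <- stage("enrich", enrich(selection$up_cor))
  enrichment_down <- stage("enrich", enrich(selection$down_cor))

  analyse_network <- function(sel, seed_offset) {
    if (length(sel) == 0L)
      return(list(result = NULL, fraction = NA_real_, p = NA_real_))
    sub <- induce_subgraph(graph, sel)
    res <- subnetwork_components(sub)
    frac <- network_fraction(res$largest_size, length(sel), rounded = FALSE)
    perm <- component_size_pvalue(graph, length(sel), res$largest_size,
                                  n_perm = config$n_perm,
                                  seed = config$seed + seed_offset)
    list(result = res, fraction = frac, p = perm$p, perm = perm)
  }
  network_up <- stage("network", analyse_network(selection$up_cor, 0L))
  network_down <- stage("network", analyse_network(selection$down_cor, 1L))

  summary <- list(
    n_genes_input = nrow(study$intensities),
    n_genes_filtered = nrow(filtered$intensities),
    n_genes_tested = nrow(ptm_res),
    r_min = config$r_min,
    n_up_cor = length(selection$up_cor),
    n_down_cor = length(selection$down_cor),
    top_pathway_up = if (!is.null(enrichment_up) && nrow(enrichment_up))
      enrichment_up$set_id[1] else NA_character_,
    top_pathway_up_p = if (!is.null(enrichment_up) && nrow(enrichment_up))
      enrichment_up$p[1] else NA_real_,
    largest_network_up = if (!is.null(network_up$result))
      network_up$result$largest_size else 0L,
    network_fraction_up_pct = round(network_up$fraction),
    network_p_up = network_up$p,
    largest_network_down = if (!is.null(network_down$result))
      network_down$result$largest_size else 0L,
    network_fraction_down_pct = round(network_down$fraction),
    network_p_down = network_down$p)

  report <- structure(list(selection = selection, ptm = ptm_res,
                           enrichment_up = enrichment_up,
                           enrichment_down = enrichment_down,
                           network_up = network_up,
                           network_down = network_down,
                           summary = summary, config = config),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- config_header(report$config)
  p <- function(f) file.path(out_dir, f)
  write_gene_list(report$selection$up_cor, p("upcor.txt"), header = hdr)
  write_gene_list(report$selection$down_cor, p("downcor.txt"), header = hdr)
  write_tidy(report$ptm, p("ptm.csv"), header = hdr)
  if (!is.null(report$enrichment_up))
    write_tidy(report$enrichment_up, p("enrichment_upcor.csv"), header = hdr)
  if (!is.null(report$enrichment_down))
    write_tidy(report$enrichment_down, p("enrichment_downcor.csv"),
               header = hdr)
  summ <- report$summary
  jsonlite::write_json(summ, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("pipeline_report\n")
  cat(sprintf("  transcripts: %d input -> %d after filters -> %d tested\n",
              s$n_genes_input, s$n_genes_filtered, s$n_genes_tested))
  cat(sprintf("  selection at |r| >= %.2f: %d UpCor, %d DownCor\n",
              s$r_min, s$n_up_cor, s$n_down_cor))
  if (!is.na(s$top_pathway_up_p))
    cat(sprintf("  top UpCor pathway: %s (p = %.3g)\n",
                s$top_pathway_up, s$top_pathway_up_p))
  cat(sprintf("  largest UpCor network: %d nodes (%d%% of UpCor, p = %.3g)\n",
              s$largest_network_up, s$network_fraction_up_pct,
              s$network_p_up))
  cat(sprintf("  largest DownCor network: %d nodes (%d%% of DownCor, p = %.3g)\n",
              s$largest_network_down, s$network_fraction_down_pct,
              s$network_p_down))
  invisible(x)
}
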