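#' Define a treatment-arm study design
#'
#' A study design names the treatment arms, how many replicate samples each
#' arm contributes, and the arm *category* used by the gradual template:
#' `control`, `endoRT` (endoradiotherapy only), `EBRT` (external beam only,
#' photon or carbon ion), or `combined` (EBRT plus endoradiotherapy).
#' Photon- and carbon-EBRT arms share the `EBRT` category by default so the
#' template has one "EBRT only" step; pass a different `categories` vector
#' to override.
#'
#' @param arms Character vector of arm labels, in display order.
#' @param replicates Integer vector (recycled) of samples per arm.
#' @param categories Character vector mapping each arm to one of
#'   `"control"`, `"endoRT"`, `"EBRT"`, `"combined"`.
#' @return A `study_design` list with elements `arms`, `replicates`,
#'   `categories`.
#' @examples
#' study_design()  # A431-like: 6 arms x 3 replicates
#' @export
study_design <- function(arms = c("control", "EndoRT", "photon-EBRT",
                                  "carbon-EBRT", "PERT", "CERT"),
                         replicates = 3L,
                         categories = c("control", "endoRT", "EBRT",
                                        "EBRT", "combined", "combined")) {
  if (length(arms) < 2L || anyDuplicated(arms))
    stop("'arms' must be at least two unique labels")
  replicates <- as.integer(rep_len(replicates, length(arms)))
  if (any(replicates < 1L))
    stop("every arm needs at least one replicate")
  categories <- rep_len(categories, length(arms))
  valid <- c("control", "endoRT", "EBRT", "combined")
  if (!all(categories %in% valid))
    stop("categories must be among: ", paste(valid, collapse = ", "))
  if (sum(categories == "control") != 1L)
    stop("exactly one arm must have category 'control'")
  for (cat in c("endoRT", "EBRT", "combined"))
    if (!any(categories == cat))
      stop("at least one arm must have category '", cat, "'")
  structure(list(arms = arms, replicates = replicates,
                 categories = stats::setNames(categories, arms)),
            class = "study_design")
}

#' Configuration for the synthetic expression generator
#'
#' Intensities are generated on the log2 scale and exponentiated, so they
#' are always positive. A fraction of genes follows the planted 3-step
#' gradual profile: expected arm means of `up_gradual` genes increase by a
#' factor `effect_step` per template level along
#' endoRT < EBRT < combined (and `down_gradual` mirrors this downward);
#' control and endoRT arms sit at baseline. `low_intensity_frac` genes are
#' drawn well below the detection-background threshold of 100 so the
#' intensity filter has known targets. Missing ("non-assessable") entries
#' are planted completely at random at rate `missing_rate`.
#'
#' @param n_genes Number of transcripts.
#' @param frac_up_gradual,frac_down_gradual Fractions of genes planted with
#'   the upward / downward gradual profile.
#' @param effect_step Multiplicative step between consecutive template
#'   levels (> 1).
#' @param baseline_log2_mean,baseline_log2_sd Log2-intensity distribution
#'   of ordinary genes.
#' @param low_log2_mean,low_log2_sd Log2-intensity distribution of planted
#'   low-intensity genes (kept far below 100).
#' @param noise_log2_sd Per-observation log2-normal noise SD.
#' @param missing_rate Fraction of entries flagged non-assessable.
#' @param low_intensity_frac Fraction of genes planted below the intensity
#'   filter.
#' @param seed Integer seed; generation is a pure function of
#'   (design, config).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       frac_up_gradual = 0.05,
                       frac_down_gradual = 0.05,
                       effect_step = 2,
                       baseline_log2_mean = 9,
                       baseline_log2_sd = 1,
                       low_log2_mean = 3,
                       low_log2_sd = 0.5,
                       noise_log2_sd = 0.25,
                       missing_rate = 0.02,
                       low_intensity_frac = 0.10,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L)
    stop("'n_genes' must be a positive integer")
  rates <- c(frac_up_gradual, frac_down_gradual, missing_rate,
             low_intensity_frac)
  if (any(rates < 0) || any(rates > 1))
    stop("all fractions must lie in [0, 1]")
  if (frac_up_gradual + frac_down_gradual + low_intensity_frac > 1)
    stop("gradual and low-intensity fractions must sum to <= 1")
  if (effect_step <= 1)
    stop("'effect_step' must exceed 1")
  if (noise_log2_sd < 0 || baseline_log2_sd < 0 || low_log2_sd < 0)
    stop("standard deviations must be non-negative")
  structure(list(n_genes = n_genes,
                 frac_up_gradual = frac_up_gradual,
                 frac_down_gradual = frac_down_gradual,
                 effect_step = effect_step,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 low_log2_mean = low_log2_mean,
                 low_log2_sd = low_log2_sd,
                 noise_log2_sd = noise_log2_sd,
                 missing_rate = missing_rate,
                 low_intensity_frac = low_intensity_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Template level per arm category (exponent applied on top of baseline).
# control/endoRT sit at baseline; EBRT one step up; combined two steps.
.category_exponent <- c(control = 0, endoRT = 0, EBRT = 1, combined = 2)

#' Generate a synthetic expression study with planted ground truth
#'
#' Builds a gene x sample intensity matrix emulating a BeadChip-style
#' experiment: log-normal baseline intensities, a planted fraction of
#' gradually up-/down-regulated genes across treatment categories, planted
#' low-intensity genes, multiplicative log-normal noise, and
#' missing-completely-at-random non-assessable entries (stored as `NA`).
#'
#' @param design A [study_design()].
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{study}{an `expression_study`: `intensities` (gene x sample
#'       matrix, `NA` = non-assessable), `arms` (factor per sample),
#'       `design`.}
#'     \item{truth}{named character vector per gene with labels
#'       `up_gradual`, `down_gradual`, `null`, `low_intensity`.}
#'   }
#' @examples
#' sim <- generate_expression_study(study_design(), sim_config(n_genes = 100))
#' table(sim$truth)
#' @export
generate_expression_study <- function(design, config) {
  stopifnot(inherits(design, "study_design"), inherits(config, "sim_config"))
  n_genes <- config$n_genes
  sample_arm <- rep(design$arms, times = design$replicates)
  sample_ids <- unlist(lapply(seq_along(design$arms), function(i)
    sprintf("%s_r%d", design$arms[i], seq_len(design$replicates[i]))))
  n_samples <- length(sample_ids)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))

  n_up  <- round(config$frac_up_gradual * n_genes)
  n_dn  <- round(config$frac_down_gradual * n_genes)
  n_low <- round(config$low_intensity_frac * n_genes)

  withr::with_seed(config$seed, {
    labels <- rep("null", n_genes)
    special <- sample.int(n_genes, n_up + n_dn + n_low)
    labels[special[seq_len(n_up)]] <- "up_gradual"
    if (n_dn > 0) labels[special[n_up + seq_len(n_dn)]] <- "down_gradual"
    if (n_low > 0) labels[special[n_up + n_dn + seq_len(n_low)]] <- "low_intensity"

    baseline <- stats::rnorm(n_genes, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    baseline[labels == "low_intensity"] <-
      stats::rnorm(sum(labels == "low_intensity"),
                   config$low_log2_mean, config$low_log2_sd)

    exponent <- .category_exponent[design$categories[sample_arm]]
    step_l2 <- log2(config$effect_step)
    sign_g <- ifelse(labels == "up_gradual", 1,
                     ifelse(labels == "down_gradual", -1, 0))
    # gene x sample matrix of log2 means: baseline + signed gradual offset
    log2_mean <- outer(baseline, rep(1, n_samples)) +
      outer(sign_g * step_l2, exponent)
    noise <- matrix(stats::rnorm(n_genes * n_samples, 0, config$noise_log2_sd),
                    n_genes, n_samples)
    values <- 2^(log2_mean + noise)
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n_genes * n_samples) < config$missing_rate,
                     n_genes, n_samples)
      values[miss] <- NA_real_
    }
  })
  dimnames(values) <- list(gene_ids, sample_ids)
  study <- structure(list(intensities = values,
                          arms = factor(sample_arm, levels = design$arms),
                          design = design),
                     class = "expression_study")
  names(study$arms) <- sample_ids
  list(study = study, truth = stats::setNames(labels, gene_ids))
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$intensities), "genes x",
      ncol(x$intensities), "samples\n")
  cat("arms:", paste(sprintf("%s (n=%d)", levels(x$arms),
                             tabulate(x$arms)), collapse = ", "), "\n")
  cat("non-assessable entries:", sum(is.na(x$intensities)), "\n")
  invisible(x)
}

#' Generate a synthetic protein-protein interaction graph
#'
#' Plants a connected module (a random spanning tree) of `module_size`
#' genes drawn from the `up_gradual` truth labels, then adds background
#' edges independently with probability `extra_edge_prob` over all other
#' gene pairs. The result is a simple undirected graph over all genes
#' (isolated vertices kept), standing in for a curated direct-interaction
#' database.
#'
#' @param genes Character vector: the gene universe (graph vertices).
#' @param labels Truth labels as returned by [generate_expression_study()].
#' @param extra_edge_prob Background edge probability.
#' @param module_size Number of up-regulated genes in the planted module.
#' @param seed Integer seed.
#' @return An [igraph::graph] with vertex names `genes` and a graph
#'   attribute `planted_module` listing the module genes.
#' @export
generate_ppi <- function(genes, labels, extra_edge_prob = 0.001,
                         module_size = 20L, seed = 1L) {
  stopifnot(is.character(genes), length(genes) >= 2L)
  if (extra_edge_prob < 0 || extra_edge_prob > 1)
    stop("'extra_edge_prob' must lie in [0, 1]")
  up <- names(labels)[labels == "up_gradual"]
  up <- intersect(up, genes)
  module_size <- as.integer(module_size)
  if (module_size > length(up))
    stop("'module_size' (", module_size, ") exceeds the number of ",
         "up_gradual genes (", length(up), ")")
  withr::with_seed(seed, {
    module <- sample(up, module_size)
    # random spanning tree keeps the module connected by construction
    tree <- if (module_size >= 2L) {
      parent <- vapply(2:module_size, function(i) sample.int(i - 1L, 1L),
                       integer(1))
      cbind(module[parent], module[2:module_size])
    } else matrix(character(0), ncol = 2)
    bg <- igraph::sample_gnp(length(genes), extra_edge_prob, directed = FALSE)
    bg_edges <- igraph::as_edgelist(bg, names = FALSE)
  })
  edges <- rbind(tree,
                 cbind(genes[bg_edges[, 1]], genes[bg_edges[, 2]]))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "planted_module", module)
  g
}

#' Generate a synthetic gene-set collection with one planted enriched set
#'
#' The first set (`set_01`, the planted set) is drawn predominantly from
#' `up_gradual` genes (fraction `planted_purity`); the remaining sets are
#' drawn uniformly from the universe.
#'
#' @param genes Gene universe.
#' @param labels Truth labels.
#' @param n_sets Number of sets.
#' @param set_size_range Length-2 integer bounds on set sizes.
#' @param planted_purity Fraction of the planted set drawn from
#'   `up_gradual` genes (1 = entirely).
#' @param seed Integer seed.
#' @return A `gene_set_collection`: list with `sets` (named list of gene
#'   vectors), `universe`, and `planted_set_id`.
#' @export
generate_gene_sets <- function(genes, labels, n_sets = 10L,
                               set_size_range = c(10L, 50L),
                               planted_purity = 1, seed = 1L) {
  stopifnot(length(set_size_range) == 2L, n_sets >= 1L)
  set_size_range <- as.integer(sort(set_size_range))
  if (set_size_range[2] > length(genes))
    stop("'set_size_range' exceeds the size of the universe")
  if (planted_purity < 0 || planted_purity > 1)
    stop("'planted_purity' must lie in [0, 1]")
  up <- intersect(names(labels)[labels == "up_gradual"], genes)
  withr::with_seed(seed, {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- vector("list", n_sets)
    n_from_up <- min(round(planted_purity * sizes[1]), length(up))
    planted <- sample(up, n_from_up)
    if (n_from_up < sizes[1])
      planted <- c(planted,
                   sample(setdiff(genes, planted), sizes[1] - n_from_up))
    sets[[1]] <- planted
    for (i in seq_len(n_sets)[-1]) sets[[i]] <- sample(genes, sizes[i])
  })
  names(sets) <- sprintf("set_%02d", seq_len(n_sets))
  structure(list(sets = sets, universe = genes, planted_set_id = "set_01"),
            class = "gene_set_collection")
}

#' Generate synthetic tumor-growth and biodistribution tables
#'
#' Growth: per-animal caliper series under exponential growth with an
#' arm-specific doubling time after `treatment_day` (a shared pre-treatment
#' doubling time before it) and multiplicative log-normal measurement
#' noise. Caliper width and length are reported equal, back-computed from
#' volume via (width^2 x length)/2. Biodistribution: per-animal organ
#' activities (percent injected dose per gram) with configurable organ
#' means and a common coefficient of variation.
#'
#' @param design A [study_design()] (arm labels; animals per arm come from
#'   `growth_params$n_per_arm`).
#' @param growth_params List: `v0_mm3` start volume, `days` measurement
#'   days, `treatment_day`, `pre_doubling_days`, `doubling_days` (named per
#'   arm), `noise_log2_sd`, `n_per_arm`.
#' @param biodist_params List: `organ_means` (named %ID/g means), `cv`
#'   coefficient of variation, `n_animals`.
#' @param seed Integer seed.
#' @return List with `growth` (animal_id, arm, day, width_mm, length_mm)
#'   and `biodist` (animal_id, organ, pct_id_per_g) data frames.
#' @export
generate_efficacy_tables <- function(design,
                                     growth_params = list(),
                                     biodist_params = list(),
                                     seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  gp <- utils::modifyList(list(
    v0_mm3 = 225, days = seq(0, 40, by = 2), treatment_day = 0,
    pre_doubling_days = 3,
    doubling_days = NULL, noise_log2_sd = 0.15, n_per_arm = 8L), growth_params)
  if (is.null(gp$doubling_days)) {
    # default kinetics: untreated/endoRT fast, EBRT slowed, combined slowest
    dd <- c(control = 3, endoRT = 3.5, EBRT = 6, combined = 9)
    gp$doubling_days <- stats::setNames(dd[design$categories], design$arms)
  }
  if (!all(design$arms %in% names(gp$doubling_days)))
    stop("'doubling_days' must name every arm")
  bp <- utils::modifyList(list(
    organ_means = c(tumor = 9.0, muscle = 9.0 / 107.6, spleen = 2.4,
                    liver = 0.6, kidney = 0.5, lung = 0.5),
    cv = 0.4, n_animals = 11L), biodist_params)

  withr::with_seed(seed, {
    growth <- do.call(rbind, lapply(design$arms, function(arm) {
      do.call(rbind, lapply(seq_len(gp$n_per_arm), function(a) {
        t <- gp$days
        pre <- pmin(t, gp$treatment_day)
        post <- pmax(t - gp$treatment_day, 0)
        vol <- gp$v0_mm3 * 2^(pre / gp$pre_doubling_days +
                              post / gp$doubling_days[[arm]])
        vol <- vol * 2^stats::rnorm(length(t), 0, gp$noise_log2_sd)
        side <- (2 * vol)^(1 / 3)
        data.frame(animal_id = sprintf("%s_a%02d", arm, a), arm = arm,
                   day = t, width_mm = side, length_mm = side,
                   stringsAsFactors = FALSE)
      }))
    }))
    biodist <- do.call(rbind, lapply(names(bp$organ_means), function(org) {
      m <- bp$organ_means[[org]]
      data.frame(animal_id = sprintf("bd_a%02d", seq_len(bp$n_animals)),
                 organ = org,
                 pct_id_per_g = pmax(
                   m * (1 + stats::rnorm(bp$n_animals, 0, bp$cv)), 0),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(growth) <- NULL
  rownames(biodist) <- NULL
  list(growth = growth, biodist = biodist)
}
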