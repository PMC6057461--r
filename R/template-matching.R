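#' One-way ANOVA screen across treatment arms
#'
#' Computes, per gene, the one-way fixed-effects F test of equal means
#' across treatment arms (missing entries dropped pairwise) and returns
#' the genes with `p < alpha`, ranked by ascending p and truncated to
#' `top_n`. Genes with zero within-group variance in every group (no
#' residual variance, F undefined) are excluded with a message, as are
#' genes with fewer than two groups of two observations.
#'
#' @param fc A `fold_change` object.
#' @param alpha Significance level (default 0.01).
#' @param top_n Maximum number of genes returned (default 500).
#' @return Data frame `gene`, `f`, `df1`, `df2`, `p`, sorted by p.
#' @export
anova_screen <- function(fc, alpha = 0.01, top_n = 500L) {
  stopifnot(inherits(fc, "fold_change"))
  x <- fc$values
  g <- fc$arms
  if (nlevels(droplevels(g)) < 2L) stop("need at least two arms")
  obs <- !is.na(x)
  # per-gene per-group counts, sums, sums of squares (NA-aware)
  grp <- droplevels(g)
  n_gj <- t(apply(obs, 1L, function(o) tabulate(grp[o], nlevels(grp))))
  s_gj <- t(rowsum(t(ifelse(obs, x, 0)), grp))
  q_gj <- t(rowsum(t(ifelse(obs, x^2, 0)), grp))
  n_tot <- rowSums(n_gj)
  grand <- rowSums(s_gj) / n_tot
  k_eff <- rowSums(n_gj > 0L)
  with_mean <- n_gj > 0L
  m_gj <- ifelse(with_mean, s_gj / pmax(n_gj, 1L), 0)
  ssb <- rowSums(n_gj * (m_gj - grand)^2)
  ssw <- rowSums(q_gj - n_gj * m_gj^2)
  ssw <- pmax(ssw, 0)  # guard tiny negatives from cancellation
  df1 <- k_eff - 1L
  df2 <- n_tot - k_eff
  valid <- df1 >= 1L & df2 >= 1L & ssw > 0
  n_const <- sum(df1 >= 1L & df2 >= 1L & ssw == 0)
  if (n_const > 0)
    message(n_const, " gene(s) with zero within-group variance excluded ",
            "(F undefined)")
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  res <- data.frame(gene = rownames(x), f = f, df1 = df1, df2 = df2, p = p,
                    stringsAsFactors = FALSE)[valid, , drop = FALSE]
  res <- res[res$p < alpha, , drop = FALSE]
  res <- res[order(res$p, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, top_n)
}

#' Hierarchical clustering of gene arm-mean profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of
#' per-gene arm-mean fold-change profiles, as used to derive the centroid
#' templates. Genes with an undefined arm mean (all entries of some arm
#' missing) are excluded with a message. Deterministic given the input
#' gene order.
#'
#' @param fc A `fold_change` object.
#' @param genes Genes to cluster (default: all rows of `fc`).
#' @param k Number of flat clusters to cut (default 2: one upward and one
#'   downward pattern).
#' @return List with `hclust` (the dendrogram), `clusters` (named integer
#'   vector), and `profiles` (gene x arm matrix of means).
#' @export
cluster_genes <- function(fc, genes = NULL, k = 2L) {
  stopifnot(inherits(fc, "fold_change"))
  if (is.null(genes)) genes <- rownames(fc$values)
  genes <- intersect(genes, rownames(fc$values))
  if (length(genes) < 2L) stop("need at least two genes to cluster")
  prof <- arm_mean_profiles(fc, genes)
  complete <- stats::complete.cases(prof)
  if (any(!complete))
    message(sum(!complete), " gene(s) with missing arm means excluded ",
            "from clustering")
  prof <- prof[complete, , drop = FALSE]
  if (nrow(prof) < 2L) stop("fewer than two genes with complete profiles")
  hc <- stats::hclust(stats::dist(prof, method = "euclidean"),
                      method = "average")
  k <- min(k, nrow(prof))
  list(hclust = hc, clusters = stats::cutree(hc, k = k), profiles = prof)
}

# gene x arm matrix of mean fold changes (NA-aware)
arm_mean_profiles <- function(fc, genes = NULL) {
  x <- fc$values
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  grp <- droplevels(fc$arms)
  obs <- !is.na(x)
  n <- t(apply(obs, 1L, function(o) tabulate(grp[o], nlevels(grp))))
  s <- t(rowsum(t(ifelse(obs, x, 0)), grp))
  out <- s / n  # NaN where a gene has no observation in an arm
  out[n == 0L] <- NA_real_
  colnames(out) <- levels(grp)
  out
}

#' Centroid profiles of gene clusters
#'
#' The centroid of a cluster is the arithmetic mean profile of its member
#' genes; centroids summarize the dominant expression patterns and serve
#' as templates for supervised matching.
#'
#' @param fc A `fold_change` object.
#' @param clusters Named integer vector (gene -> cluster id), e.g. from
#'   [cluster_genes()].
#' @return Data frame with one row per cluster: `cluster`, `size`, and one
#'   column per arm holding the centroid value.
#' @export
centroid_profiles <- function(fc, clusters) {
  stopifnot(inherits(fc, "fold_change"), length(clusters) > 0L)
  if (is.null(names(clusters))) stop("'clusters' must be named by gene")
  prof <- arm_mean_profiles(fc, names(clusters))
  ids <- sort(unique(clusters))
  cent <- do.call(rbind, lapply(ids, function(cl) {
    members <- names(clusters)[clusters == cl]
    if (length(members) == 0L) stop("empty cluster: ", cl)
    colMeans(prof[members, , drop = FALSE], na.rm = TRUE)
  }))
  data.frame(cluster = ids, size = as.vector(table(clusters)[as.character(ids)]),
             cent, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Build the 3-step gradual treatment-intensity template
#'
#' Assigns every non-control sample the numeric level of its arm category:
#' endoradiotherapy only < EBRT only < combined treatment
#' (defaults 1 < 2 < 3). Photon- and carbon-EBRT arms share the EBRT
#' level. Control samples are excluded from the template domain (they are
#' the normalization baseline). Downstream template correlation is
#' invariant to affine rescaling of the levels.
#'
#' @param design A `study_design` (or the `design` element of a study).
#' @param levels Named numeric vector mapping the non-control categories
#'   to template levels.
#' @return A `template_profile`: list with `sample_ids`, `values` (one per
#'   non-control sample), and `levels`.
#' @export
gradual_template <- function(design,
                             levels = c(endoRT = 1, EBRT = 2, combined = 3)) {
  stopifnot(inherits(design, "study_design"))
  needed <- names(levels)
  missing_cat <- setdiff(needed, unname(design$categories))
  if (length(missing_cat) > 0)
    stop("categories absent from the design: ",
         paste(missing_cat, collapse = ", "))
  if (length(unique(levels)) < 2L)
    stop("template needs at least two distinct levels")
  sample_arm <- rep(design$arms, times = design$replicates)
  sample_ids <- unlist(lapply(seq_along(design$arms), function(i)
    sprintf("%s_r%d", design$arms[i], seq_len(design$replicates[i]))))
  cat_per_sample <- design$categories[sample_arm]
  keep <- cat_per_sample != "control"
  structure(list(sample_ids = sample_ids[keep],
                 values = stats::setNames(unname(levels[cat_per_sample[keep]]),
                                          sample_ids[keep]),
                 levels = levels),
            class = "template_profile")
}

#' Pavlidis Template Matching against a sample-level template
#'
#' Correlates every gene's per-sample fold changes with the template over
#' the template's (non-control) samples: Pearson r on pairwise-complete
#' observations, with a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Genes constant over the template samples (r undefined) or with fewer
#' than 3 paired observations are excluded with a message.
#'
#' @param fc A `fold_change` object.
#' @param template A `template_profile` from [gradual_template()].
#' @param arm_means Correlate per-arm mean profiles against per-arm levels
#'   instead of per-sample values (default `FALSE`: sample-level PTM).
#' @return Data frame `gene`, `r`, `n_obs`, `p`.
#' @export
ptm <- function(fc, template, arm_means = FALSE) {
  stopifnot(inherits(fc, "fold_change"), inherits(template, "template_profile"))
  if (arm_means) {
    sample_arm <- as.character(fc$arms[template$sample_ids])
    lv <- tapply(template$values, sample_arm, unique)
    prof <- arm_mean_profiles(fc)[, names(lv), drop = FALSE]
    x <- prof
    tv <- as.numeric(lv)
  } else {
    missing_samples <- setdiff(template$sample_ids, colnames(fc$values))
    if (length(missing_samples) > 0)
      stop("template samples absent from the matrix: ",
           paste(missing_samples, collapse = ", "))
    x <- fc$values[, template$sample_ids, drop = FALSE]
    tv <- unname(template$values)
  }
  n_obs <- rowSums(!is.na(x))
  res <- t(apply(x, 1L, function(row) {
    ok <- !is.na(row)
    n <- sum(ok)
    if (n < 3L) return(c(NA_real_, n))
    if (stats::sd(row[ok]) == 0 || stats::sd(tv[ok]) == 0)
      return(c(NA_real_, n))
    c(stats::cor(row[ok], tv[ok]), n)
  }))
  r <- res[, 1]
  n <- res[, 2]
  dropped <- is.na(r)
  if (any(dropped))
    message(sum(dropped), " gene(s) excluded from template matching ",
            "(constant profile or fewer than 3 paired observations)")
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- data.frame(gene = rownames(x), r = r, n_obs = as.integer(n), p = p,
                    stringsAsFactors = FALSE)[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select correlating (UpCor) and anti-correlating (DownCor) genes
#'
#' UpCor collects genes with `r >= r_min`, DownCor genes with
#' `r <= -r_min`. Selections are nested across cutoffs: the r >= 0.8
#' selection is always a subset of the r >= 0.7 selection.
#'
#' @param results PTM result data frame from [ptm()].
#' @param r_min Correlation cutoff in (0, 1); the study's cutoffs are 0.7
#'   and 0.8.
#' @return A `gene_selection`: list with `up_cor`, `down_cor`, `cutoff`,
#'   `universe_size` (number of tested transcripts).
#' @export
select_correlated <- function(results, r_min = 0.7) {
  stopifnot(is.data.frame(results), all(c("gene", "r") %in% names(results)))
  if (r_min <= 0 || r_min >= 1) stop("'r_min' must lie in (0, 1)")
  structure(list(up_cor = results$gene[results$r >= r_min],
                 down_cor = results$gene[results$r <= -r_min],
                 cutoff = r_min,
                 universe_size = nrow(results)),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection at |r| >= %.2f: %d UpCor, %d DownCor (of %d tested)\n",
              x$cutoff, length(x$up_cor), length(x$down_cor),
              x$universe_size))
  invisible(x)
}
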