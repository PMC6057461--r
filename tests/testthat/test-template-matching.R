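make_fc <- function(seed = 13, n_genes = 60) {
  sim <- generate_expression_study(
    default_design(), sim_config(n_genes = n_genes, frac_up_gradual = 0.1,
                                 frac_down_gradual = 0.1,
                                 low_intensity_frac = 0, missing_rate = 0.05,
                                 seed = seed))
  list(fc = normalize_to_control(sim$study), truth = sim$truth,
       study = sim$study)
}

test_that("ANOVA screen excludes constant genes and keeps separated ones", {
  fx <- make_fc()
  fc <- fx$fc
  fc$values[1, ] <- 0                      # identical in all samples
  expect_message(res <- anova_screen(fc, alpha = 1, top_n = Inf),
                 "zero within-group variance")
  expect_false(rownames(fc$values)[1] %in% res$gene)
  # planted gradual genes separate strongly across arms
  planted <- names(fx$truth)[fx$truth != "null"]
  hits <- res$gene[res$p < 0.01]
  expect_gt(length(intersect(planted, hits)), 0.9 * length(planted))
})

test_that("ANOVA p-values match stats::oneway.test per gene", {
  fx <- make_fc(seed = 17, n_genes = 40)
  fc <- fx$fc
  res <- anova_screen(fc, alpha = 1, top_n = Inf)
  for (g in sample(res$gene, 10)) {
    y <- fc$values[g, ]
    ok <- !is.na(y)
    oracle <- stats::oneway.test(y[ok] ~ droplevels(fc$arms[ok]),
                                 var.equal = TRUE)
    expect_equal(res$p[res$gene == g], unname(oracle$p.value),
                 tolerance = 1e-10)
    expect_equal(res$f[res$gene == g], unname(oracle$statistic),
                 tolerance = 1e-10)
  }
  # ranked ascending by p and truncated
  expect_false(is.unsorted(res$p))
  expect_lte(nrow(anova_screen(fc, alpha = 1, top_n = 5)), 5L)
})

test_that("clustering merges identical profiles at height zero and honors known distances", {
  # three profiles with known pairwise Euclidean distances 3, 4, 5
  d <- default_design()
  fc <- structure(list(
    values = NULL, arms = NULL, design = d, log2 = TRUE),
    class = "fold_change")
  arms <- rep(d$arms, times = d$replicates)
  ids <- paste0("s", seq_along(arms))
  m <- matrix(0, nrow = 3, ncol = length(arms),
              dimnames = list(c("gA", "gB", "gC"), ids))
  # profiles are constant within arm so arm means equal the profile values;
  # use two arms as the two coordinates
  a1 <- arms == d$arms[1]
  a2 <- arms == d$arms[2]
  m["gB", a2] <- 3   # (0,0) vs (0,3): distance 3 over the first two arms
  m["gC", a1] <- 4   # (4,0): distances 4 and 5 to gA and gB
  fc$values <- m
  fc$arms <- stats::setNames(factor(arms, d$arms), ids)
  cl <- cluster_genes(fc, k = 2)
  hc <- cl$hclust
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("gA", "gB"))
  expect_equal(hc$height[1], 3)
  # identical profiles merge at distance 0
  fc$values <- rbind(m, gD = m["gC", ])
  cl2 <- cluster_genes(fc, k = 2)
  expect_equal(min(cl2$hclust$height), 0)
  # flat clusters are invariant to gene order (up to labels)
  fc_perm <- fc
  fc_perm$values <- fc$values[c(3, 1, 4, 2), ]
  cl3 <- cluster_genes(fc_perm, k = 2)
  split_a <- unname(split(names(cl2$clusters), cl2$clusters))
  split_b <- unname(split(names(cl3$clusters), cl3$clusters))
  expect_setequal(lapply(split_a, sort), lapply(split_b, sort))
})

test_that("centroid profiles are the arithmetic means of member genes", {
  fx <- make_fc(seed = 19, n_genes = 30)
  cl <- cluster_genes(fx$fc, k = 3)
  cent <- centroid_profiles(fx$fc, cl$clusters)
  prof <- cl$profiles
  for (i in seq_len(nrow(cent))) {
    members <- names(cl$clusters)[cl$clusters == cent$cluster[i]]
    arm_cols <- setdiff(names(cent), c("cluster", "size"))
    expect_equal(unlist(cent[i, arm_cols]),
                 colMeans(prof[members, arm_cols, drop = FALSE]),
                 tolerance = 1e-12)
    expect_identical(cent$size[i], length(members))
  }
  # singleton cluster: centroid equals the gene profile
  single <- stats::setNames(1L, rownames(fx$fc$values)[1])
  cent1 <- centroid_profiles(fx$fc, single)
  arm_cols <- setdiff(names(cent1), c("cluster", "size"))
  expect_equal(unlist(cent1[1, arm_cols]),
               arm_mean_profiles(fx$fc, names(single))[1, ],
               tolerance = 1e-12)
})

test_that("gradual template assigns category levels per sample, control excluded", {
  d <- study_design(arms = c("ctl", "endo", "beam", "both"),
                    replicates = 2,
                    categories = c("control", "endoRT", "EBRT", "combined"))
  tpl <- gradual_template(d)
  expect_identical(unname(tpl$values), c(1, 1, 2, 2, 3, 3))
  expect_false(any(grepl("^ctl", tpl$sample_ids)))
  # photon- and carbon-EBRT both sit on the EBRT level
  tpl6 <- gradual_template(default_design())
  expect_equal(unname(tpl6$values[grepl("photon-EBRT", names(tpl6$values))]),
               rep(2, 3))
  expect_equal(unname(tpl6$values[grepl("carbon-EBRT", names(tpl6$values))]),
               rep(2, 3))
  expect_error(
    gradual_template(d, levels = c(endoRT = 1, EBRT = 2, combined = 3,
                                   boost = 4)),
    "absent")
})

test_that("PTM correlation is invariant to affine rescaling of template levels", {
  fx <- make_fc(seed = 23)
  t1 <- gradual_template(fx$fc$design,
                         levels = c(endoRT = 1, EBRT = 2, combined = 3))
  t2 <- gradual_template(fx$fc$design,
                         levels = c(endoRT = 10, EBRT = 20, combined = 30))
  expect_equal(ptm(fx$fc, t1)$r, ptm(fx$fc, t2)$r, tolerance = 1e-12)
})

test_that("PTM recovers perfect correlation and matches cor.test", {
  fx <- make_fc(seed = 29)
  fc <- fx$fc
  tpl <- gradual_template(fc$design)
  # plant one gene exactly equal to the template and one equal to its negative
  fc$values["g00001", tpl$sample_ids] <- tpl$values
  fc$values["g00002", tpl$sample_ids] <- -tpl$values
  res <- ptm(fc, tpl)
  expect_equal(res$r[res$gene == "g00001"], 1)
  expect_equal(res$r[res$gene == "g00002"], -1)
  for (g in sample(res$gene, 8)) {
    y <- fc$values[g, tpl$sample_ids]
    ok <- !is.na(y)
    ct <- stats::cor.test(y[ok], tpl$values[ok])
    expect_equal(res$r[res$gene == g], unname(ct$estimate), tolerance = 1e-10)
    if (abs(res$r[res$gene == g]) < 1 - 1e-12)
      expect_equal(res$p[res$gene == g], ct$p.value, tolerance = 1e-8)
  }
})

test_that("PTM significance follows the t transform of Pearson r", {
  # r = 0.8 at n = 15 paired observations
  r <- 0.8; n <- 15
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(t_stat, 4.807, tolerance = 1e-3)
  p <- 2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE)
  expect_equal(p, 3.4e-4, tolerance = 0.02)
  expect_lt(p, 0.001)
  # and the implementation reproduces it on constructed data
  d <- default_design()
  tpl <- gradual_template(d)  # 15 non-control samples
  arms <- rep(d$arms, times = d$replicates)
  ids <- unlist(lapply(seq_along(d$arms), function(i)
    sprintf("%s_r%d", d$arms[i], seq_len(d$replicates[i]))))
  # build a profile with exactly r = 0.8 against the template via
  # orthogonal decomposition
  tv <- tpl$values
  z <- scale(as.numeric(tv))[, 1]
  e <- withr::with_seed(41,
    stats::residuals(stats::lm(stats::rnorm(length(z)) ~ z)))
  e <- e / sqrt(sum(e^2))
  y <- 0.8 * z / sqrt(sum(z^2)) + sqrt(1 - 0.8^2) * e
  m <- matrix(0, 1, length(arms), dimnames = list("gX", ids))
  m[1, tpl$sample_ids] <- y
  fc <- structure(list(values = m,
                       arms = stats::setNames(factor(arms, d$arms), ids),
                       design = d, log2 = TRUE), class = "fold_change")
  res <- ptm(fc, tpl)
  expect_equal(res$r, 0.8, tolerance = 1e-10)
  expect_equal(res$n_obs, 15L)
  expect_equal(res$p, p, tolerance = 1e-8)
})

test_that("PTM excludes constant genes and short profiles", {
  fx <- make_fc(seed = 31)
  fc <- fx$fc
  tpl <- gradual_template(fc$design)
  fc$values[1, tpl$sample_ids] <- 2           # constant over the template
  fc$values[2, tpl$sample_ids[-(1:2)]] <- NA  # only 2 paired observations
  expect_message(res <- ptm(fc, tpl), "excluded")
  expect_false(any(rownames(fc$values)[1:2] %in% res$gene))
})

test_that("selection splits by sign and nests across cutoffs", {
  results <- data.frame(gene = c("gA", "gB", "gC"),
                        r = c(0.85, 0.75, -0.9),
                        n_obs = 15L, p = 1e-3)
  s08 <- select_correlated(results, 0.8)
  expect_identical(s08$up_cor, "gA")
  expect_identical(s08$down_cor, "gC")
  s07 <- select_correlated(results, 0.7)
  expect_setequal(s07$up_cor, c("gA", "gB"))
  expect_identical(s07$down_cor, "gC")
  expect_error(select_correlated(results, 1.2), "\\(0, 1\\)")
  # nesting property on random correlation tables
  withr::with_seed(1, {
    for (i in 1:20) {
      rr <- data.frame(gene = paste0("g", 1:100),
                       r = runif(100, -1, 1), n_obs = 15L, p = 0.5)
      hi <- select_correlated(rr, 0.8)
      lo <- select_correlated(rr, 0.7)
      expect_true(all(hi$up_cor %in% lo$up_cor))
      expect_true(all(hi$down_cor %in% lo$down_cor))
      expect_length(intersect(lo$up_cor, lo$down_cor), 0L)
    }
  })
})

test_that("PTM r transforms predictably under per-gene affine maps", {
  fx <- make_fc(seed = 37)
  fc <- fx$fc
  tpl <- gradual_template(fc$design)
  base <- ptm(fc, tpl)
  fc_pos <- fc; fc_pos$values <- 3 * fc$values + 5
  expect_equal(ptm(fc_pos, tpl)$r, base$r, tolerance = 1e-12)
  fc_neg <- fc; fc_neg$values <- -2 * fc$values + 1
  expect_equal(ptm(fc_neg, tpl)$r, -base$r, tolerance = 1e-12)
})
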