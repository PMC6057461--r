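test_that("caliper volume follows (width^2 x length) / 2", {
  expect_equal(tumor_volume(10, 20), 1000)
  expect_equal(tumor_volume(7, 7), 7^3 / 2)
  withr::with_seed(3, {
    w <- runif(20, 1, 15); l <- w + runif(20, 0, 10)
    expect_equal(tumor_volume(w, l), w^2 * l / 2)
  })
  expect_error(tumor_volume(0, 5), "positive")
  expect_warning(v <- tumor_volume(20, 10), "swapped")
  expect_equal(v, 1000)  # swap restores the convention
  # monotone in both dimensions
  expect_gt(tumor_volume(6, 10), tumor_volume(5, 10))
  expect_gt(tumor_volume(5, 11), tumor_volume(5, 10))
})

test_that("growth inhibition reproduces the reported percentages", {
  expect_identical(growth_inhibition(440, 1117), 61)
  expect_identical(growth_inhibition(414, 1117), 63)
  expect_identical(growth_inhibition(500, 500), 0)
  expect_equal(growth_inhibition(440, 1117, rounded = FALSE),
               100 * (1 - 440 / 1117))
  # monotone decreasing in the treated mean
  expect_gt(growth_inhibition(400, 1117, rounded = FALSE),
            growth_inhibition(500, 1117, rounded = FALSE))
  expect_error(growth_inhibition(100, 0), "positive")
})

test_that("RBE is the iso-effective photon-to-carbon dose ratio", {
  expect_equal(rbe_iso_effect(10, 5), 2)
  expect_equal(rbe_iso_effect(40, 25), 1.6)
  expect_equal(rbe_iso_effect(12, 12), 1)
  expect_error(rbe_iso_effect(0, 5), "positive")
})

test_that("TMR and its change reproduce the reported uptake arithmetic", {
  expect_equal(tmr(9.0, 9.0 / 107.6), 107.6)
  expect_equal(tmr(3, 3), 1)
  expect_identical(tmr_change(195.1, 107.6), 81)
  expect_identical(tmr_change(5, 5), 0)
  expect_error(tmr(1, 0), "positive")
  expect_error(tmr_change(1, 0), "positive")
})

test_that("%ID/g is activity fraction per gram", {
  expect_equal(pid_per_gram(0.09, 1.0, 1.0), 9.0)
  expect_equal(pid_per_gram(0, 1, 2), 0)
  withr::with_seed(11, {
    act <- runif(10); inj <- runif(10, 0.5, 2); wt <- runif(10, 0.1, 3)
    expect_equal(pid_per_gram(act, inj, wt), 100 * (act / inj) / wt)
  })
  expect_error(pid_per_gram(1, 0, 1), "positive")
  expect_error(pid_per_gram(1, 1, 0), "positive")
})

test_that("time to progression is the first threshold crossing, else censoring", {
  side <- function(v) (2 * v)^(1 / 3)
  g <- data.frame(animal_id = "a1", day = c(0, 5, 10),
                  width_mm = side(c(100, 400, 600)),
                  length_mm = side(c(100, 400, 600)))
  ev <- time_to_progression(g, 500)
  expect_identical(ev$time, 10)
  expect_true(ev$event)
  g2 <- data.frame(animal_id = "a2", day = c(0, 5, 10),
                   width_mm = side(c(100, 300, 450)),
                   length_mm = side(c(100, 300, 450)))
  ev2 <- time_to_progression(g2, 500)
  expect_identical(ev2$time, 10)
  expect_false(ev2$event)
  expect_error(time_to_progression(g[0, ], 500), "empty")
})

test_that("noise-free exponential growth crosses at the closed-form day", {
  d <- default_design()
  tabs <- generate_efficacy_tables(
    d, growth_params = list(noise_log2_sd = 0, v0_mm3 = 100,
                            treatment_day = 0,
                            doubling_days = stats::setNames(rep(5, 6), d$arms),
                            days = seq(0, 30, 2), n_per_arm = 1L),
    seed = 1)
  ev <- time_to_progression(tabs$growth, 500)
  # V0 2^(t/5) >= 500 at t = 5 log2(5) = 11.6 -> first observation day 12
  t_exact <- 5 * log2(500 / 100)
  expected_day <- min(seq(0, 30, 2)[seq(0, 30, 2) >= t_exact])
  expect_true(all(ev$event))
  expect_true(all(ev$time == expected_day))
})

test_that("Kaplan-Meier matches the hand product-limit calculation", {
  events <- data.frame(time = 1:4, event = TRUE)
  km <- km_estimate(events)
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  # curve is non-increasing
  expect_false(is.unsorted(rev(km$curve$surv)))
  # single event among n drops S by 1/n
  ev1 <- data.frame(time = c(3, 5, 5, 5), event = c(TRUE, FALSE, FALSE, FALSE))
  km1 <- km_estimate(ev1)
  expect_equal(km1$curve$surv[km1$curve$time == 3], 1 - 1 / 4)
  # all censored: median undefined, flagged
  expect_message(km2 <- km_estimate(data.frame(time = c(2, 3),
                                               event = FALSE)),
                 "median undefined")
  expect_true(is.na(km2$median))
})

test_that("log-rank test is null for identical groups and detects separation", {
  same <- data.frame(time = rep(1:4, 2), event = TRUE,
                     group = rep(c("A", "B"), each = 4))
  lr <- logrank_test(same)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_identical(lr$df, 1L)
  sep <- data.frame(time = c(1:5, 21:25), event = TRUE,
                    group = rep(c("A", "B"), each = 5))
  expect_lt(logrank_test(sep)$p, 0.01)
  expect_error(logrank_test(data.frame(time = 1, event = TRUE, group = "A")),
               "two groups")
})

test_that("KM medians across arms follow the planted growth-rate ordering", {
  d <- default_design()
  tabs <- generate_efficacy_tables(d, growth_params = list(n_per_arm = 8L),
                                   seed = 14)
  ev <- time_to_progression(tabs$growth, 1000)
  med <- vapply(split(ev, ev$arm), function(e) km_estimate(e)$median,
                numeric(1))
  cats <- d$categories
  expect_lt(med[["control"]], min(med[names(cats)[cats == "EBRT"]]))
  expect_lt(max(med[names(cats)[cats == "EBRT"]]),
            min(med[names(cats)[cats == "combined"]]))
})

test_that("microvessel density and Ki-67 index are the documented means", {
  cnt <- data.frame(section_id = "s1", hpf_id = 1:3, vessels = c(10, 12, 14))
  expect_equal(mvd(cnt), 12)
  ki <- data.frame(section_id = "s1", hpf_id = 1, ki67_pos = 50, dapi = 200)
  expect_equal(ki67_index(ki), 0.25)
  # sections are averaged after pooling HPFs within section
  ki2 <- data.frame(section_id = c("s1", "s1", "s2"), hpf_id = c(1, 2, 1),
                    ki67_pos = c(10, 30, 10), dapi = c(100, 100, 50))
  expect_equal(ki67_index(ki2), mean(c(40 / 200, 10 / 50)))
  expect_warning(ki3 <- ki67_index(rbind(ki, data.frame(section_id = "s1",
                                                        hpf_id = 2,
                                                        ki67_pos = 0,
                                                        dapi = 0))),
                 "zero DAPI")
  expect_equal(ki3, 0.25)
  expect_error(ki67_index(data.frame(section_id = "s", hpf_id = 1,
                                     ki67_pos = 5, dapi = 4)),
               "cannot exceed")
  withr::with_seed(15, {
    v <- rpois(9, 10)
    rnd <- data.frame(section_id = rep(c("a", "b", "c"), each = 3),
                      hpf_id = rep(1:3, 3), vessels = v)
    expect_equal(mvd(rnd), mean(v))
  })
})

test_that("pooled t-test matches the textbook formula and labels significance", {
  withr::with_seed(17, {
    a <- rnorm(8, 0, 1); b <- rnorm(10, 1, 1.5)
  })
  got <- group_ttest(a, b)
  # textbook pooled-variance computation
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  df <- length(a) + length(b) - 2
  expect_equal(got$statistic, t_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * stats::pt(-abs(t_manual), df), tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  same <- c(1, 2, 3, 4)
  eq <- group_ttest(same, same)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # clear separation is highly significant
  jit <- c(0, 1e-6, -1e-6, 2e-6)
  strong <- group_ttest(0 + jit, 1 + jit)
  expect_lt(strong$p, 1e-6)
  expect_identical(strong$label, "highly significant")
  expect_error(group_ttest(rep(1, 3), rep(1, 3)), "zero variance")
  # Welch variant runs and reports fractional df
  expect_lt(group_ttest(a, b, welch = TRUE)$df,
            length(a) + length(b) - 2)
})
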