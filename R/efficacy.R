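#' Caliper tumor volume
#'
#' Ellipsoid approximation from two caliper dimensions:
#' `volume = (width^2 * length) / 2` (mm^3). By convention width is the
#' smaller dimension; if width > length the two are swapped with a
#' warning.
#'
#' @param width,length Caliper dimensions in mm (positive; vectorized).
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 20)  # 1000
#' @export
tumor_volume <- function(width, length) {
  if (any(width <= 0) || any(length <= 0))
    stop("caliper dimensions must be positive")
  swap <- width > length
  if (any(swap)) {
    warning(sum(swap), " measurement(s) with width > length swapped")
    tmp <- width[swap]
    width[swap] <- length[swap]
    length[swap] <- tmp
  }
  width^2 * length / 2
}

#' Tumor growth inhibition relative to control
#'
#' `100 * (1 - treated_mean / control_mean)` percent, reported rounded to
#' the nearest integer (full precision with `rounded = FALSE`).
#'
#' @param treated_mean,control_mean Mean tumor volumes (mm^3);
#'   `control_mean` must be positive.
#' @param rounded Round to integer percent.
#' @return Percent inhibition.
#' @examples
#' growth_inhibition(440, 1117)  # 61
#' @export
growth_inhibition <- function(treated_mean, control_mean, rounded = TRUE) {
  if (any(control_mean <= 0)) stop("'control_mean' must be positive")
  pct <- 100 * (1 - treated_mean / control_mean)
  if (rounded) round(pct) else pct
}

#' Relative biological effectiveness from iso-effective doses
#'
#' RBE is the ratio of the photon dose to the particle (carbon-ion) dose
#' producing the same biological effect; the caller asserts that the two
#' schedules were iso-effective.
#'
#' @param photon_total_dose,carbon_total_dose Total doses in Gy (> 0).
#' @return Dose ratio (photon / carbon).
#' @examples
#' rbe_iso_effect(10, 5)   # 2
#' rbe_iso_effect(40, 25)  # 1.6
#' @export
rbe_iso_effect <- function(photon_total_dose, carbon_total_dose) {
  if (any(photon_total_dose <= 0) || any(carbon_total_dose <= 0))
    stop("doses must be positive")
  photon_total_dose / carbon_total_dose
}

#' Tumor-to-muscle ratio and its relative change
#'
#' `tmr()` is the ratio of tumor to muscle uptake (%ID/g), a tumor
#' targeting selectivity index. `tmr_change()` is the percent change
#' `100 * (after - before) / before`, reported rounded to the nearest
#' integer (full precision with `rounded = FALSE`).
#'
#' @param tumor,muscle Uptake in %ID/g; `muscle` must be positive.
#' @return `tmr()`: the ratio.
#' @examples
#' round(tmr_change(195.1, 107.6))  # 81
#' @export
tmr <- function(tumor, muscle) {
  if (any(muscle <= 0)) stop("'muscle' uptake must be positive")
  tumor / muscle
}

#' @rdname tmr
#' @param after,before TMR values; `before` must be positive.
#' @param rounded Round to integer percent.
#' @return `tmr_change()`: percent change.
#' @export
tmr_change <- function(after, before, rounded = TRUE) {
  if (any(before <= 0)) stop("'before' must be positive")
  pct <- 100 * (after - before) / before
  if (rounded) round(pct) else pct
}

#' Percent injected dose per gram of organ tissue
#'
#' Fractional uptake of the injected activity in an organ divided by the
#' organ weight: `100 * (organ_activity / injected_activity) /
#' organ_weight`.
#'
#' @param organ_activity,injected_activity Activities in the same units;
#'   `injected_activity` must be positive.
#' @param organ_weight Organ weight in grams (> 0).
#' @return Uptake in %ID/g.
#' @examples
#' pid_per_gram(0.09, 1.0, 1.0)  # 9
#' @export
pid_per_gram <- function(organ_activity, injected_activity, organ_weight) {
  if (any(injected_activity <= 0)) stop("'injected_activity' must be positive")
  if (any(organ_weight <= 0)) stop("'organ_weight' must be positive")
  100 * (organ_activity / injected_activity) / organ_weight
}

#' Time to progression from caliper series
#'
#' Progression is the first study day on which the tumor volume
#' (`(width^2 * length) / 2`) reaches the threshold (500 mm^3 or
#' 1000 mm^3 in the two models, i.e. a 5-fold increase over treatment
#' start). No interpolation between measurement days: the event time is
#' the first observed crossing. Animals never crossing are censored at
#' their last observation.
#'
#' @param growth Data frame with columns `animal_id`, `day`, `width_mm`,
#'   `length_mm`, and optionally `arm` (carried through).
#' @param threshold_mm3 Progression threshold in mm^3.
#' @return Data frame `animal_id` (, `arm`), `time`, `event`
#'   (`TRUE` = progressed, `FALSE` = censored).
#' @export
time_to_progression <- function(growth, threshold_mm3 = 500) {
  need <- c("animal_id", "day", "width_mm", "length_mm")
  if (!all(need %in% names(growth)))
    stop("'growth' must have columns: ", paste(need, collapse = ", "))
  if (nrow(growth) == 0L) stop("empty measurement series")
  has_arm <- "arm" %in% names(growth)
  out <- do.call(rbind, lapply(split(growth, growth$animal_id), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    vol <- tumor_volume(d$width_mm, d$length_mm)
    hit <- which(vol >= threshold_mm3)
    data.frame(animal_id = d$animal_id[1],
               arm = if (has_arm) d$arm[1] else NA_character_,
               time = if (length(hit)) d$day[hit[1]] else max(d$day),
               event = length(hit) > 0,
               stringsAsFactors = FALSE)
  }))
  if (!has_arm) out$arm <- NULL
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate of progression-free time
#'
#' Product-limit estimator of the probability of remaining progression
#' free, with the median defined as the first time the curve drops to
#' 0.5 or below (undefined, `NA`, if it never does — flagged with a
#' message when the group is all-censored).
#'
#' @param events Data frame with columns `time` and `event` (logical or
#'   0/1), e.g. from [time_to_progression()].
#' @return List with `curve` (data frame `time`, `n_risk`, `n_event`,
#'   `surv`), `median`, and `fit` (the underlying
#'   [survival::survfit] object).
#' @export
km_estimate <- function(events) {
  stopifnot(all(c("time", "event") %in% names(events)))
  if (nrow(events) == 0L) stop("no event records")
  if (!any(events$event)) message("all records censored: median undefined")
  fit <- survival::survfit(
    survival::Surv(events$time, as.integer(events$event)) ~ 1)
  # median = first time the curve drops to 0.5 or below (not survfit's
  # interval-midpoint convention)
  below <- fit$time[fit$surv <= 0.5]
  med <- if (length(below)) min(below) else NA_real_
  list(curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, surv = fit$surv),
       median = med, fit = fit)
}

#' Log-rank test between two progression groups
#'
#' Two-sample log-rank test (ties handled by the standard aggregated
#' risk-set formulation), chi-square with 1 degree of freedom.
#'
#' @param events Data frame with columns `time`, `event`, and `group`.
#' @return List `chisq`, `df`, `p`.
#' @export
logrank_test <- function(events) {
  stopifnot(all(c("time", "event", "group") %in% names(events)))
  groups <- unique(events$group)
  if (length(groups) != 2L) stop("log-rank test needs exactly two groups")
  sd <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ group, data = events)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Microvessel density: mean CD31-positive vessels per high-power field
#'
#' @param counts Data frame with columns `section_id`, `hpf_id`,
#'   `vessels`.
#' @return Mean vessel count per HPF across all fields.
#' @export
mvd <- function(counts) {
  stopifnot(all(c("section_id", "hpf_id", "vessels") %in% names(counts)))
  if (nrow(counts) == 0L) stop("need at least one high-power field")
  if (any(counts$vessels < 0)) stop("counts must be non-negative")
  mean(counts$vessels)
}

#' Ki-67 proliferation index
#'
#' Per section, the number of Ki-67-positive cells divided by the number
#' of DAPI-positive cells summed over that section's high-power fields;
#' the index is the mean over sections. Fields with zero DAPI count are
#' excluded with a warning.
#'
#' @param counts Data frame with columns `section_id`, `hpf_id`,
#'   `ki67_pos`, `dapi`.
#' @return Proliferation index in `[0, 1]`.
#' @export
ki67_index <- function(counts) {
  stopifnot(all(c("section_id", "hpf_id", "ki67_pos", "dapi")
                %in% names(counts)))
  if (nrow(counts) == 0L) stop("need at least one high-power field")
  if (any(counts$ki67_pos > counts$dapi))
    stop("'ki67_pos' cannot exceed 'dapi'")
  zero <- counts$dapi == 0
  if (any(zero)) {
    warning(sum(zero), " HPF(s) with zero DAPI count excluded")
    counts <- counts[!zero, , drop = FALSE]
    if (nrow(counts) == 0L) stop("no usable high-power fields")
  }
  per_section <- vapply(split(counts, counts$section_id), function(d)
    sum(d$ki67_pos) / sum(d$dapi), numeric(1))
  mean(per_section)
}

#' Two-sample t-test with study-style significance labels
#'
#' Student's pooled-variance two-sample t-test by default (Welch's
#' unequal-variance form with `welch = TRUE`), two-sided. The label
#' annotates `p < 0.05` as "significant" and `p < 0.01` as "highly
#' significant".
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param welch Use the Welch form.
#' @return List `statistic`, `df`, `p`, `label`.
#' @export
group_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least two observations")
  if (stats::var(a) + stats::var(b) == 0)
    stop("zero variance in both samples: t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = !welch)
  p <- ht$p.value
  list(statistic = unname(ht$statistic), df = unname(ht$parameter), p = p,
       label = if (p < 0.01) "highly significant"
               else if (p < 0.05) "significant" else "not significant")
}
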