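#' Detection filter: drop transcripts with too many non-assessable reads
#'
#' Retains exactly the genes whose fraction of missing (non-assessable)
#' entries is strictly below `max_missing_frac`. A gene missing in 30% or
#' more of the samples is excluded at the default threshold; gene order
#' and the sample set are unchanged.
#'
#' @param study An `expression_study`.
#' @param max_missing_frac Exclusion boundary in `[0, 1]`; a gene is kept
#'   iff its missing fraction is `< max_missing_frac`.
#' @return The filtered `expression_study`.
#' @export
filter_detection <- function(study, max_missing_frac = 0.30) {
  stopifnot(inherits(study, "expression_study"))
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("'max_missing_frac' must lie in [0, 1]")
  x <- study$intensities
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty expression matrix")
  frac <- rowMeans(is.na(x))
  study$intensities <- x[frac < max_missing_frac, , drop = FALSE]
  study
}

#' Intensity filter: drop transcripts at background-noise level
#'
#' Retains genes whose arithmetic mean intensity over non-missing entries
#' is at least `min_mean` (boundary inclusive: a gene sitting exactly at
#' the background level of 100 is kept). Genes with all entries missing
#' have no defined mean and are excluded with a message.
#'
#' @param study An `expression_study`.
#' @param min_mean Minimum mean intensity.
#' @return The filtered `expression_study`.
#' @export
filter_intensity <- function(study, min_mean = 100) {
  stopifnot(inherits(study, "expression_study"))
  x <- study$intensities
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty expression matrix")
  if (any(x < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing))
    message(sum(all_missing),
            " gene(s) with all entries missing excluded (mean undefined)")
  m <- rowMeans(x, na.rm = TRUE)
  keep <- !all_missing & m >= min_mean
  study$intensities <- x[keep, , drop = FALSE]
  study
}

#' Normalize intensities to the control-arm arithmetic mean
#'
#' Divides every value of a gene by that gene's arithmetic mean over the
#' (non-missing) control-arm samples, yielding fold changes relative to
#' control; with `log2 = TRUE` (default) the log2 ratio is returned.
#' Missing entries stay missing. Genes whose control mean is zero,
#' negative, or undefined (all control entries missing) are excluded with
#' a message.
#'
#' @param study An `expression_study`.
#' @param control_arm Label of the control arm (default: the arm with
#'   category `"control"` in the design).
#' @param log2 Return log2 ratios (`TRUE`) or raw ratios.
#' @return A `fold_change` object: `values` (gene x sample matrix), `arms`,
#'   `design`, `log2` flag.
#' @export
normalize_to_control <- function(study, control_arm = NULL, log2 = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(control_arm))
    control_arm <- names(study$design$categories)[
      study$design$categories == "control"]
  if (!control_arm %in% levels(study$arms))
    stop("control arm '", control_arm, "' not present in the annotation")
  ctl <- study$arms == control_arm
  if (!any(ctl)) stop("control arm has no samples")
  x <- study$intensities
  ctl_mean <- rowMeans(x[, ctl, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(ctl_mean) | ctl_mean <= 0
  if (any(bad))
    message(sum(bad), " gene(s) with undefined or non-positive control ",
            "mean excluded from normalization")
  x <- x[!bad, , drop = FALSE]
  fc <- x / ctl_mean[!bad]
  if (log2) fc <- base::log2(fc)
  structure(list(values = fc, arms = study$arms, design = study$design,
                 log2 = log2),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat("fold_change:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", if (x$log2) "log2 ratios" else "raw ratios", ")\n")
  invisible(x)
}
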