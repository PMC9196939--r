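#' Summarize a parametric map over a region of interest
#'
#' Mean and SD (n-1 denominator) over the fitted, unmasked voxels inside
#' the ROI; voxels excluded by the map's fit mask are counted, never
#' imputed.
#'
#' @param map a [parametric_map()].
#' @param mask logical ROI array.
#' @param subject,cohort,roi identifying tags carried into the summary row.
#' @return one-row data.frame: subject, cohort, roi, param, mean, sd,
#'   n_voxels, n_excluded.
#' @export
summarize_roi <- function(map, mask, subject = NA, cohort = NA, roi = NA) {
  stopifnot(inherits(map, "parametric_map"),
            identical(dim(mask), dim(map$values)))
  sel <- mask & map$mask
  if (!any(sel))
    stop("ROI has no fitted voxels in this map")
  v <- map$values[sel]
  data.frame(subject = subject, cohort = cohort, roi = roi,
             param = map$param,
             mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
             n_voxels = length(v), n_excluded = sum(mask) - length(v))
}

# guard: t.test errors (or yields NaN) on constant data; the convention
# here is p = 1 when the degenerate difference is zero, p -> 0 (t = Inf)
# when it is constant and nonzero
.safe_t <- function(expr, zero_diff, nonzero_const_diff = FALSE) {
  guard <- function() {
    if (zero_diff)
      list(statistic = c(t = 0), parameter = c(df = NA), p.value = 1)
    else if (nonzero_const_diff)
      list(statistic = c(t = Inf), parameter = c(df = NA), p.value = 0)
  }
  if (zero_diff || nonzero_const_diff)
    return(tryCatch({
      res <- expr
      if (is.nan(res$p.value)) guard() else res
    }, error = function(e) guard()))
  expr
}

#' Two-sample t-test between cohorts
#'
#' Welch (unequal-variance) two-tailed test by default; set
#' `var_equal = TRUE` for the pooled-variance variant. Degenerate inputs
#' (zero variance in both groups with equal means) return p = 1 with a
#' flag rather than erroring.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param contrast label for the comparison row.
#' @param var_equal pooled-variance test instead of Welch.
#' @return one-row data.frame: contrast, statistic, df, p, n_a, n_b,
#'   degenerate.
#' @export
two_sample_ttest <- function(a, b, contrast = "a vs b", var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  degen <- stats::sd(a) == 0 && stats::sd(b) == 0
  tt <- .safe_t(stats::t.test(a, b, var.equal = var_equal),
                zero_diff = degen && mean(a) == mean(b),
                nonzero_const_diff = degen)
  data.frame(contrast = contrast, statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             n_a = length(a), n_b = length(b), degenerate = degen)
}

#' Paired t-test within subjects
#'
#' Two-tailed paired test on the within-subject differences (pairing by
#' position). All-zero differences return p = 1; constant nonzero
#' differences return p -> 0; both are flagged degenerate.
#'
#' @inheritParams two_sample_ttest
#' @return one-row data.frame as in [two_sample_ttest()].
#' @export
paired_ttest <- function(a, b, contrast = "a vs b (paired)") {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  degen <- stats::sd(d) == 0
  tt <- .safe_t(stats::t.test(a, b, paired = TRUE),
                zero_diff = degen && mean(d) == 0,
                nonzero_const_diff = degen)
  data.frame(contrast = contrast, statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             n_a = length(a), n_b = length(b), degenerate = degen)
}

#' Holm step-down multiple-comparison adjustment
#'
#' The step-down Bonferroni procedure: sort p-values ascending, multiply
#' the i-th smallest by (m - i + 1), enforce monotonicity, cap at 1;
#' returned in input order. Thin wrapper over
#' `stats::p.adjust(method = "holm")`.
#'
#' @param pvals numeric p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @export
holm_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "holm")
}

#' Cohort comparison table for one parameter
#'
#' Builds the standard set of contrasts from per-subject ROI means (pure
#' tumor vs pure RN, pure vs mixed for each tissue, and the paired
#' tumor-vs-RN comparison within the mixed cohort) and applies the Holm
#' adjustment across the family.
#'
#' @param summaries data.frame of [summarize_roi()] rows for one parameter.
#' @param var_equal passed to [two_sample_ttest()].
#' @return data.frame of comparisons with raw and adjusted p-values.
#' @export
compare_cohorts <- function(summaries, var_equal = FALSE) {
  stopifnot(length(unique(summaries$param)) == 1)
  grab <- function(cohort, roi)
    summaries$mean[summaries$cohort == cohort & summaries$roi == roi]
  rows <- list()
  add <- function(res) rows[[length(rows) + 1]] <<- res
  tum <- grab("tumor", "tumor"); rn <- grab("rn", "rn")
  tum_m <- grab("mixed", "tumor"); rn_m <- grab("mixed", "rn")
  if (length(tum) >= 2 && length(tum_m) >= 2)
    add(two_sample_ttest(tum, tum_m, "tumor vs tumor-in-mixed", var_equal))
  if (length(rn) >= 2 && length(rn_m) >= 2)
    add(two_sample_ttest(rn, rn_m, "rn vs rn-in-mixed", var_equal))
  if (length(tum) >= 2 && length(rn) >= 2)
    add(two_sample_ttest(tum, rn, "tumor vs rn", var_equal))
  if (length(tum_m) >= 2 && length(tum_m) == length(rn_m))
    add(paired_ttest(tum_m, rn_m, "tumor-in-mixed vs rn-in-mixed (paired)"))
  if (!length(rows)) stop("not enough cohort data for any contrast")
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p)
  out$param <- unique(summaries$param)
  out
}
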