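#' Summarize biological-replicate values
#'
#' Mean, sample SD (n-1 denominator) and n for one group of replicate-level
#' values. The SD is reported as `NA` and flagged undefined for a single
#' replicate.
#'
#' @param values Numeric vector, one value per biological replicate.
#' @param group Optional group label carried on the result.
#' @return A list of class `replicate_summary`: `group`, `values`, `mean`,
#'   `sd`, `n`, `sd_defined`.
#' @export
summarize_replicates <- function(values, group = NA_character_) {
  if (length(values) == 0L) stopf("empty replicate group")
  structure(list(group = group, values = values, mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
                 n = length(values), sd_defined = length(values) > 1L),
            class = "replicate_summary")
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-tailed t-test assuming unequal variances, with the
#' Welch-Satterthwaite fractional degrees of freedom. Degenerate input where
#' both groups have zero variance returns `p = 1` when the means are equal
#' and `p = 0` otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list of class `welch_ttest`: `t`, `df`, `p`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                          df = length(a) + length(b) - 2,
                          p = if (eq) 1 else 0),
                     class = "welch_ttest"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "welch_ttest")
}

#' @export
print.welch_ttest <- function(x, ...) {
  cat(sprintf("<welch_ttest> t = %.4f, df = %.3f, two-tailed p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Dilution factors of a serial dilution
#'
#' A 1:`fold` serial scheme maps dilution index k to a factor of `fold^k`;
#' the default two-fold scheme over four dilutions gives factors 2, 4, 8, 16.
#'
#' @param n Number of dilutions.
#' @param fold Fold per step (2 for a 1:1 dilution with diluent).
#' @return Numeric vector of dilution factors, index 1..n.
#' @export
serial_dilution_factors <- function(n = 4L, fold = 2) {
  fold^seq_len(n)
}

#' Back-calculate CFU/mL from plate counts
#'
#' Per plate, `CFU/mL = count * dilution_factor / plated_volume_ml`. The
#' pooled estimate is the count-weighted mean of the per-plate estimates
#' (inverse-variance weighting on the relative scale under Poisson
#' counting); all-zero counts give a pooled 0 flagged below detection.
#'
#' @param counts Colony counts per plate (>= 0).
#' @param dilution_factors Per-plate dilution factors (>= 1), e.g.
#'   [serial_dilution_factors()].
#' @param plated_volume_ml Volume plated per plate in mL (> 0).
#' @param resuspension_ml Optional resuspension volume (mL); when given, the
#'   total CFU in the sample is also reported.
#' @return A list: `per_plate` (data frame with `count`, `dilution_factor`,
#'   `cfu_per_ml`), `pooled_cfu_per_ml`, `below_detection`, and `total_cfu`
#'   when `resuspension_ml` is given.
#' @export
cfu_per_ml <- function(counts, dilution_factors,
                       plated_volume_ml = 0.1, resuspension_ml = NULL) {
  if (length(counts) != length(dilution_factors))
    stopf("counts and dilution_factors must have equal length")
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (any(dilution_factors < 1)) stopf("dilution factors must be >= 1")
  if (!is_scalar_num(plated_volume_ml) || plated_volume_ml <= 0)
    stopf("plated volume must be > 0")
  per <- counts * dilution_factors / plated_volume_ml
  pooled <- if (sum(counts) > 0) sum(counts * per) / sum(counts) else 0
  out <- list(per_plate = data.frame(count = counts,
                                     dilution_factor = dilution_factors,
                                     cfu_per_ml = per),
              pooled_cfu_per_ml = pooled,
              below_detection = sum(counts) == 0)
  if (!is.null(resuspension_ml))
    out$total_cfu <- pooled * resuspension_ml
  out
}

#' Cross-contamination purity report
#'
#' Fraction of producer-tagged colonies among all colonies examined, with a
#' one-sided exact (Clopper-Pearson) upper confidence bound on the
#' contamination rate. With zero producers observed the bound reduces to
#' `1 - (1 - conf)^(1/n)`, the exact form of the rule of three.
#'
#' @param n_reporter,n_producer Counts of reporter-tagged (CFP-only) and
#'   producer-tagged (mCherry) colonies.
#' @param conf One-sided confidence level (default 0.95).
#' @return A list: `n_total`, `n_producer`, `fraction`, `upper_bound`,
#'   `conf`.
#' @export
contamination_check <- function(n_reporter, n_producer, conf = 0.95) {
  n <- n_reporter + n_producer
  if (n <= 0) stopf("zero total colonies")
  upper <- if (n_producer >= n) 1
           else stats::qbeta(conf, n_producer + 1, n - n_producer)
  list(n_total = n, n_producer = n_producer, fraction = n_producer / n,
       upper_bound = upper, conf = conf)
}
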