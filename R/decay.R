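#' Smooth an intensity vector with a centered moving average
#'
#' Centered moving window of `window` samples (the field's default of 20
#' samples controls baseline noise in weak early-time profiles); near the
#' vector ends the window truncates symmetrically to the available samples,
#' so the output has the input's length, constants are preserved exactly and
#' linear trends are preserved at interior samples.
#'
#' @param y Numeric intensity vector.
#' @param window Window width in samples (>= 1); 1 is the identity.
#' @return Smoothed numeric vector, same length as `y`.
#' @export
smooth_profile <- function(y, window = 20L) {
  if (!is_scalar_num(window) || window < 1) stopf("window must be >= 1")
  n <- length(y)
  if (n == 0L) stopf("empty intensity vector")
  h <- floor(window / 2)
  if (h == 0L) return(y)
  cs <- cumsum(c(0, y))
  idx <- seq_len(n)
  hw <- pmin(h, idx - 1L, n - idx)
  (cs[idx + hw + 1L] - cs[idx - hw]) / (2 * hw + 1)
}

#' Estimate the baseline intensity from the profile tail
#'
#' Arithmetic mean of the last `n_tail` valid samples, i.e. the samples
#' furthest from the producer colony, where the reporter signal has returned
#' to its background expression level.
#'
#' @param y Numeric intensity vector, ordered by distance from the producer.
#' @param n_tail Number of trailing samples to average (default 20).
#' @param mask Optional logical validity vector; masked samples are skipped.
#' @return The baseline intensity (scalar).
#' @export
estimate_baseline <- function(y, n_tail = 20L, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(y))
  yv <- y[mask]
  if (length(yv) < n_tail)
    stopf("need at least %d valid samples for the baseline, have %d",
          n_tail, length(yv))
  mean(utils::tail(yv, n_tail))
}

#' Subtract a baseline from a decay curve
#'
#' Controls for differences in baseline reporter expression between colonies;
#' after subtraction the tail mean of the curve is approximately zero.
#'
#' @param y Numeric intensity vector.
#' @param baseline Finite scalar baseline.
#' @return `y - baseline`.
#' @export
subtract_baseline <- function(y, baseline) {
  if (!is_scalar_num(baseline)) stopf("baseline must be a finite number")
  y - baseline
}

#' Half-maximal intensity between peak and baseline
#'
#' The fluorescence value halfway between the maximum signal and the
#' baseline: `baseline + (max_signal - baseline) / 2`. When the response
#' amplitude `max_signal - baseline` does not exceed `response_floor` the
#' profile shows no response and `NA` is returned with a reason attribute,
#' rather than a spurious midpoint.
#'
#' @param max_signal Peak intensity.
#' @param baseline Baseline intensity (must not exceed `max_signal`).
#' @param response_floor Minimum amplitude counted as a real response
#'   (default 0, flagging only degenerate `max == baseline` profiles).
#' @return The half-maximal intensity, or `NA` with `attr(, "reason") =
#'   "no response"`.
#' @export
compute_yfp50 <- function(max_signal, baseline, response_floor = 0) {
  if (max_signal < baseline)
    stopf("max_signal (%g) below baseline (%g)", max_signal, baseline)
  if ((max_signal - baseline) <= response_floor)
    return(structure(NA_real_, reason = "no response"))
  baseline + (max_signal - baseline) / 2
}

# Shared crossing scan: first index pair (i, i+1) at/after `from` with
# y[i] >= level > y[i+1]; linear interpolation between the bracketing
# samples. Returns NA when the curve never falls below `level`.
first_downward_crossing <- function(d, y, level, from = 1L) {
  n <- length(y)
  if (n >= from + 1L) {
    for (i in seq.int(from, n - 1L)) {
      if (y[i] >= level && y[i + 1L] < level) {
        t <- (y[i] - level) / (y[i] - y[i + 1L])
        return(list(dist = d[i] + t * (d[i + 1L] - d[i]), i = i))
      }
    }
  }
  list(dist = NA_real_, i = NA_integer_)
}

#' Half-maximal decay distance (dist50) of an aligned profile
#'
#' The distance at which a smoothed, aligned decay profile first falls to the
#' half-maximal intensity `yfp50`, scanning outward from the profile peak
#' with linear interpolation between the bracketing samples. The first
#' crossing is used deliberately: noisy tails can re-cross, and the first
#' crossing from the peak is the conservative estimate of the spatial range.
#'
#' @param distance Sample positions (um), 0 at the alignment origin (YFP peak
#'   for the lawn assay, producer edge for the colony assay).
#' @param y Smoothed intensities, same length as `distance`.
#' @param yfp50 The half-maximal intensity computed from this profile.
#' @param mask Optional validity vector; masked samples are ignored.
#' @return A list with `dist50` (um, `NA` when undefined), `valid`, and
#'   `reason` (`"ok"`, `"no crossing"`, ...).
#' @export
compute_dist50 <- function(distance, y, yfp50, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(y))
  keep <- mask & distance >= 0 & is.finite(y)
  d <- distance[keep]; yv <- y[keep]
  if (length(yv) < 2L)
    return(list(dist50 = NA_real_, valid = FALSE, reason = "too few samples"))
  if (is.na(yfp50))
    return(list(dist50 = NA_real_, valid = FALSE, reason = "no response"))
  hit <- first_downward_crossing(d, yv, yfp50, from = which.max(yv))
  if (is.na(hit$dist))
    return(list(dist50 = NA_real_, valid = FALSE, reason = "no crossing"))
  list(dist50 = hit$dist, valid = TRUE, reason = "ok")
}

#' Inferred dist50 for non-contacting colonies
#'
#' Non-contacting reporter colonies do not reach the full induced response,
#' so their decay curves cannot define their own half-maximum. Instead the
#' half-maximal intensity measured on contacting colonies (averaged across
#' replicates, on the baseline-subtracted scale) is carried over as a
#' reference, and the distance from the producer edge of the first valid
#' downward crossing of that reference is reported.
#'
#' @param distance Sample positions (um), 0 at the producer-colony edge; the
#'   inter-colony gap must already be masked.
#' @param y Smoothed, baseline-subtracted intensities.
#' @param yfp50_reference Reference half-maximal intensity from contacting
#'   colonies (baseline-subtracted scale).
#' @param mask Validity vector with the gap masked out.
#' @return As [compute_dist50()]; `reason` is `"reference above profile"`
#'   when the reference exceeds the profile maximum and `"crossing in gap"`
#'   when the crossing falls inside the masked interval.
#' @export
infer_dist50_noncontacting <- function(distance, y, yfp50_reference,
                                       mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(y))
  keep <- mask & distance >= 0 & is.finite(y)
  d <- distance[keep]; yv <- y[keep]
  if (length(yv) < 2L)
    return(list(dist50 = NA_real_, valid = FALSE, reason = "too few samples"))
  if (is.na(yfp50_reference) || yfp50_reference > max(yv))
    return(list(dist50 = NA_real_, valid = FALSE,
                reason = "reference above profile"))
  hit <- first_downward_crossing(d, yv, yfp50_reference, from = 1L)
  if (is.na(hit$dist))
    return(list(dist50 = NA_real_, valid = FALSE, reason = "no crossing"))
  step <- stats::median(diff(d))
  if (diff(d[c(hit$i, hit$i + 1L)]) > 1.5 * step)
    return(list(dist50 = NA_real_, valid = FALSE, reason = "crossing in gap"))
  list(dist50 = hit$dist, valid = TRUE, reason = "ok")
}

#' Peak signal of a profile
#'
#' Maximum valid intensity and the distance at which it occurs; ties break
#' toward the smallest distance. Used both for the maximum-YFP summary of
#' lawn assays and for membrane-separation cross-sections.
#'
#' @param distance Sample positions (um).
#' @param y Intensities (typically smoothed).
#' @param mask Optional validity vector.
#' @return A list with `value` and `distance`.
#' @export
peak_signal <- function(distance, y, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(y))
  if (!any(mask)) stopf("fully masked profile")
  d <- distance[mask]; yv <- y[mask]
  m <- max(yv)
  at <- min(d[yv == m])
  list(value = m, distance = at)
}

#' Min-max scale a vector to [0, 1]
#'
#' Display normalization for representative images and profiles:
#' `(y - min) / (max - min)`. Invariant under affine transforms of the input.
#'
#' @param y Numeric vector with `max(y) > min(y)`.
#' @return Vector rescaled to span exactly `[0, 1]`.
#' @export
minmax_scale <- function(y) {
  rng <- range(y)
  if (diff(rng) <= 0) stopf("zero dynamic range: cannot min-max scale")
  (y - rng[1]) / diff(rng)
}

#' Average aligned decay profiles on a common distance grid
#'
#' Resamples every profile onto the intersection of their distance ranges by
#' linear interpolation of valid samples, then reports the pointwise mean,
#' sample SD (n-1 denominator) and contributing count. Distances supported by
#' fewer than `min_n` profiles are flagged.
#'
#' @param profiles List of aligned [cross_section()] objects (or lists with
#'   `distance`, `value` and optional `mask`).
#' @param channel Channel averaged when elements are cross-sections.
#' @param step Grid step in micrometres; default, the smallest median step
#'   among the profiles.
#' @param min_n Minimum number of contributing profiles per distance.
#' @return A `data.frame` with `distance`, `mean`, `sd`, `n`, `flagged`.
#' @export
average_decays <- function(profiles, channel = "YFP", step = NULL,
                           min_n = 2L) {
  if (length(profiles) == 0L) stopf("empty profile list")
  curves <- lapply(profiles, function(p) {
    if (inherits(p, "cross_section")) {
      if (!channel %in% names(p$intensity))
        stopf("profile has no channel '%s'", channel)
      list(d = p$distance[p$mask], y = p$intensity[[channel]][p$mask])
    } else {
      m <- if (is.null(p$mask)) rep(TRUE, length(p$distance)) else p$mask
      list(d = p$distance[m], y = p$value[m])
    }
  })
  lo <- max(vapply(curves, function(cv) min(cv$d), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$d), numeric(1)))
  if (hi <= lo) stopf("profiles share no common distance range")
  if (is.null(step))
    step <- min(vapply(curves, function(cv) stats::median(diff(cv$d)),
                       numeric(1)))
  grid <- seq(lo, hi, by = step)
  vals <- vapply(curves, function(cv)
    stats::approx(cv$d, cv$y, xout = grid, rule = 1)$y,
    numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- rowSums(is.finite(vals))
  mu <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1L, function(v) stats::sd(v[is.finite(v)]))
  data.frame(distance = grid, mean = mu, sd = sdv, n = n,
             flagged = n < min_n)
}

#' Full decay analysis of one aligned profile
#'
#' Runs the decay pipeline on a single aligned cross-section: smooth the
#' valid samples, estimate the baseline from the smoothed tail, compute the
#' half-maximal intensity, and locate dist50. Contacting profiles use their
#' own half-maximum; non-contacting profiles require the contacting
#' reference (baseline-subtracted scale) and use the inferred estimator.
#' A response floor of `response_floor_k` times the raw tail SD gates
#' profiles with no real response.
#'
#' @param profile An aligned [cross_section()].
#' @param channel Reporter channel (default `"YFP"`).
#' @param window Smoothing window in samples.
#' @param n_tail Tail length (samples) for the baseline and its SD.
#' @param response_floor_k Response floor in units of the raw tail SD.
#' @param contact_class `"contacting"` or `"non-contacting"`.
#' @param yfp50_reference Contacting-colony reference half-maximum on the
#'   baseline-subtracted scale; required for non-contacting profiles.
#' @param baseline_on Estimate the baseline on the `"smoothed"` (default) or
#'   `"raw"` curve.
#' @return An object of class `decay_result`: list with `distance`,
#'   `smoothed`, `mask`, `baseline`, `max_signal`, `peak_distance`, `yfp50`,
#'   `dist50`, `contact_class`, `valid`, `reason`.
#' @export
analyze_decay <- function(profile, channel = "YFP", window = 20L,
                          n_tail = 20L, response_floor_k = 3,
                          contact_class = c("contacting", "non-contacting"),
                          yfp50_reference = NULL,
                          baseline_on = c("smoothed", "raw")) {
  stopifnot(inherits(profile, "cross_section"))
  contact_class <- match.arg(contact_class)
  baseline_on <- match.arg(baseline_on)
  if (is.null(profile$origin_kind))
    stopf("profile must be aligned (see align_profile) before decay analysis")
  if (!channel %in% names(profile$intensity))
    stopf("profile has no channel '%s'", channel)
  keep <- profile$mask & profile$distance >= 0
  d <- profile$distance[keep]
  raw <- profile$intensity[[channel]][keep]
  res <- list(distance = d, smoothed = NULL, mask = rep(TRUE, length(d)),
              baseline = NA_real_, max_signal = NA_real_,
              peak_distance = NA_real_, yfp50 = NA_real_, dist50 = NA_real_,
              contact_class = contact_class, valid = FALSE, reason = "ok")
  class(res) <- "decay_result"
  if (length(d) < max(2L, n_tail)) {
    res$reason <- "too few valid samples"
    return(res)
  }
  sm <- smooth_profile(raw, window)
  res$smoothed <- sm
  base_curve <- if (baseline_on == "smoothed") sm else raw
  res$baseline <- mean(utils::tail(base_curve, n_tail))
  tail_sd <- stats::sd(utils::tail(raw, n_tail))
  pk <- peak_signal(d, sm)
  res$max_signal <- pk$value
  res$peak_distance <- pk$distance
  if (contact_class == "contacting") {
    floor <- response_floor_k * if (is.na(tail_sd)) 0 else tail_sd
    y50 <- compute_yfp50(max(res$max_signal, res$baseline), res$baseline,
                         response_floor = floor)
    res$yfp50 <- as.numeric(y50)
    if (is.na(y50)) {
      res$reason <- attr(y50, "reason")
      return(res)
    }
    cr <- compute_dist50(d, sm, res$yfp50)
  } else {
    if (is.null(yfp50_reference))
      stopf("non-contacting analysis needs yfp50_reference")
    res$yfp50 <- res$baseline + yfp50_reference
    cr <- infer_dist50_noncontacting(d, sm - res$baseline, yfp50_reference)
  }
  res$dist50 <- cr$dist50
  res$valid <- cr$valid
  res$reason <- cr$reason
  res
}

#' @export
print.decay_result <- function(x, ...) {
  cat(sprintf(paste0("<decay_result> %s: baseline %.4g, max %.4g, ",
                     "yfp50 %.4g, dist50 %s um (%s)\n"),
              x$contact_class, x$baseline, x$max_signal, x$yfp50,
              if (is.na(x$dist50)) "NA" else sprintf("%.2f", x$dist50),
              x$reason))
  invisible(x)
}

#' Plot an averaged decay curve
#'
#' Mean curve with an SD ribbon, the standard display for replicate-averaged
#' reporter decay profiles.
#'
#' @param avg A data frame from [average_decays()].
#' @param dist50 Optional vertical marks (um), e.g. per-replicate dist50.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_decay_average <- function(avg, dist50 = NULL, ...) {
  ok <- is.finite(avg$mean)
  graphics::plot(avg$distance[ok], avg$mean[ok], type = "n",
                 xlab = "distance (um)", ylab = "intensity", ...)
  sdv <- ifelse(is.finite(avg$sd), avg$sd, 0)
  graphics::polygon(c(avg$distance[ok], rev(avg$distance[ok])),
                    c(avg$mean[ok] - sdv[ok], rev(avg$mean[ok] + sdv[ok])),
                    col = grDevices::adjustcolor("goldenrod", 0.3),
                    border = NA)
  graphics::lines(avg$distance[ok], avg$mean[ok], col = "goldenrod4", lwd = 2)
  if (!is.null(dist50))
    graphics::abline(v = dist50, lty = 2, col = "grey40")
  invisible(avg)
}
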