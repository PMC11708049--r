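#' Gate specification
#'
#' One node of a hierarchical gating tree. Supported geometries: `rectangle`
#' (two channels, bounds `c(x_lo, x_hi, y_lo, y_hi)`), `threshold` (one
#' channel, bounds `c(lo, hi)`), and `ratio_band` (two channels, membership
#' when `channels[1] / channels[2]` lies in `c(lo, hi)`); `Inf`/`-Inf` bounds
#' are allowed. The tree is rooted at the implicit `"root"` gate holding all
#' events.
#'
#' @param name Gate name.
#' @param parent Parent gate name, `"root"` for a top-level gate.
#' @param type `"rectangle"`, `"threshold"` or `"ratio_band"`.
#' @param channels Character vector of the channels involved.
#' @param bounds Numeric bounds (see above).
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(name, parent = "root",
                      type = c("rectangle", "threshold", "ratio_band"),
                      channels, bounds) {
  type <- match.arg(type)
  need <- switch(type, rectangle = c(2L, 4L), threshold = c(1L, 2L),
                 ratio_band = c(2L, 2L))
  if (length(channels) != need[1] || length(bounds) != need[2])
    stopf("gate '%s' (%s): expected %d channel(s) and %d bounds",
          name, type, need[1], need[2])
  structure(list(name = name, parent = parent, type = type,
                 channels = channels, bounds = as.numeric(bounds)),
            class = "gate_spec")
}

gate_membership <- function(tbl, gate) {
  for (ch in gate$channels)
    if (!ch %in% names(tbl)) stopf("gate '%s': missing channel '%s'",
                                   gate$name, ch)
  b <- gate$bounds
  switch(gate$type,
    rectangle = {
      x <- tbl[[gate$channels[1]]]; y <- tbl[[gate$channels[2]]]
      x >= b[1] & x <= b[2] & y >= b[3] & y <= b[4]
    },
    threshold = {
      x <- tbl[[gate$channels[1]]]
      x >= b[1] & x <= b[2]
    },
    ratio_band = {
      r <- tbl[[gate$channels[1]]] / tbl[[gate$channels[2]]]
      r >= b[1] & r <= b[2]
    })
}

#' Apply a hierarchical gate tree to an event table
#'
#' Evaluates each gate on the events of its parent, so membership of a gate
#' always implies membership of its parent and counts are non-increasing
#' along any root-to-leaf path. An empty gate list leaves all events in the
#' root gate.
#'
#' @param tbl Flow-event table (columns named as in [sample_flow_events()]).
#' @param gates List of [gate_spec()] objects; parents must form a tree
#'   rooted at `"root"`.
#' @return A list of class `gate_result`: `membership` (named list of logical
#'   vectors, including `root`), `counts` (data frame gate/n), `gates`.
#' @export
apply_gates <- function(tbl, gates = list()) {
  if (inherits(gates, "gate_spec")) gates <- list(gates)
  membership <- list(root = rep(TRUE, nrow(tbl)))
  pending <- gates
  while (length(pending) > 0L) {
    placed <- FALSE
    rest <- list()
    for (g in pending) {
      if (g$name %in% names(membership))
        stopf("duplicate gate name '%s'", g$name)
      if (g$parent %in% names(membership)) {
        membership[[g$name]] <- membership[[g$parent]] & gate_membership(tbl, g)
        placed <- TRUE
      } else rest <- c(rest, list(g))
    }
    if (!placed)
      stopf("gate graph is not a tree rooted at 'root' (missing parent or cycle: %s)",
            paste(vapply(rest, `[[`, "", "name"), collapse = ", "))
    pending <- rest
  }
  counts <- data.frame(gate = names(membership),
                       n = vapply(membership, sum, integer(1)),
                       row.names = NULL)
  structure(list(membership = membership, counts = counts, gates = gates),
            class = "gate_result")
}

#' Events belonging to a gate
#'
#' @param tbl The event table passed to [apply_gates()].
#' @param gating A `gate_result`.
#' @param gate Gate name; default, the last (leaf) gate applied.
#' @return The subset of `tbl` in that gate.
#' @export
gated_events <- function(tbl, gating, gate = NULL) {
  stopifnot(inherits(gating, "gate_result"))
  if (is.null(gate)) gate <- utils::tail(names(gating$membership), 1L)
  if (!gate %in% names(gating$membership)) stopf("unknown gate '%s'", gate)
  tbl[gating$membership[[gate]], , drop = FALSE]
}

#' Split a bimodal intensity channel between its two populations
#'
#' Data-driven cut between two well-separated intensity populations: a
#' two-means clustering of the log10 intensities (initialized at the extreme
#' values, hence deterministic), returning the midpoint of the two cluster
#' centres on the original scale. Used to derive gate bounds and
#' classification cutoffs from reference samples instead of hard-coding
#' instrument-specific numbers. Meaningless on unimodal data.
#'
#' @param values Positive intensities containing two separated populations.
#' @return The cut point (original intensity scale).
#' @export
intensity_split <- function(values) {
  v <- log10(values[values > 0])
  if (length(v) < 2L) stopf("need at least 2 positive values")
  if (diff(range(v)) == 0) stopf("constant channel: no split")
  km <- stats::kmeans(v, centers = matrix(range(v), ncol = 1L))
  10^mean(km$centers)
}

#' Build the standard debris/singlet gate tree from a reference sample
#'
#' Two-stage gating: a `cells` rectangle on FSC-A/SSC-A removing low-scatter
#' debris, then a `singlets` band on the FSC-H/FSC-A ratio removing doublets
#' (whose area is about twice their height). Bounds are derived from the
#' reference table itself via [intensity_split()], so the reference must
#' contain the populations to be excluded; the band is symmetric on the log
#' scale around unity.
#'
#' @param reference A flow-event table containing debris and doublets (e.g.
#'   the t = 0 sample).
#' @return List of two [gate_spec()] objects (`cells`, `singlets`).
#' @export
auto_gate_tree <- function(reference) {
  fsc_cut <- intensity_split(reference$FSC_A)
  ssc_cut <- intensity_split(reference$SSC_A)
  ratio <- reference$FSC_H / reference$FSC_A
  r_cut <- intensity_split(ratio)   # between doublet (~0.5) and singlet (~1)
  list(gate_spec("cells", "root", "rectangle", c("FSC_A", "SSC_A"),
                 c(fsc_cut, Inf, ssc_cut, Inf)),
       gate_spec("singlets", "cells", "ratio_band", c("FSC_H", "FSC_A"),
                 c(r_cut, 1 / r_cut)))
}

#' Classify events as reporters or producers
#'
#' Reporter cells are high in constitutive CFP and low in mCherry; producers
#' the converse. Events high or low in both tags are left unclassified.
#'
#' @param tbl Flow-event table.
#' @param cfp_cutoff,mcherry_cutoff Intensity cutoffs separating the high and
#'   low populations of each tag (e.g. from [intensity_split()]).
#' @return Character vector (`"reporter"`, `"producer"`, `"unclassified"`),
#'   one per event.
#' @export
classify_populations <- function(tbl, cfp_cutoff, mcherry_cutoff) {
  hi_c <- tbl$CFP_A >= cfp_cutoff
  hi_m <- tbl$mCherry_A >= mcherry_cutoff
  out <- rep("unclassified", nrow(tbl))
  out[hi_c & !hi_m] <- "reporter"
  out[hi_m & !hi_c] <- "producer"
  out
}

#' Three-SD positivity cutoff from the t = 0 distribution
#'
#' The conservative DNA-damage-positive threshold: mean plus three sample
#' standard deviations (n-1 denominator) of the reporter intensities at the
#' start of the experiment.
#'
#' @param t0_values Reporter-channel intensities at t = 0 (length >= 2).
#' @return The cutoff intensity.
#' @export
compute_cutoff <- function(t0_values) {
  if (length(t0_values) < 2L) stopf("need at least 2 values for the cutoff")
  mean(t0_values) + 3 * stats::sd(t0_values)
}

#' Percent of events above a cutoff
#'
#' Positivity is strictly greater than the cutoff (ties count negative),
#' matching the conservative-threshold convention.
#'
#' @param values Event intensities (non-empty).
#' @param cutoff Finite threshold.
#' @return A list of class `threshold_classification`: `cutoff`, `n_total`,
#'   `n_positive`, `percent_positive`.
#' @export
percent_positive <- function(values, cutoff) {
  if (length(values) == 0L) stopf("empty intensity vector")
  if (!is_scalar_num(cutoff)) stopf("cutoff must be finite")
  npos <- sum(values > cutoff)
  structure(list(cutoff = cutoff, n_total = length(values),
                 n_positive = npos,
                 percent_positive = 100 * npos / length(values)),
            class = "threshold_classification")
}

#' @export
print.threshold_classification <- function(x, ...) {
  cat(sprintf("<threshold_classification> %d / %d above %.4g (%.3f%%)\n",
              x$n_positive, x$n_total, x$cutoff, x$percent_positive))
  invisible(x)
}

#' Percent-positive time course with a fixed t = 0 cutoff
#'
#' For each time point: gate, classify reporter cells, and report the percent
#' of reporters whose reporter-channel intensity exceeds the cutoff computed
#' once from the t = 0 reporters (mean + 3 SD). Using one cutoff for all
#' time points makes the curve comparable across times.
#'
#' @param tables Named list of flow-event tables; names are times in hours
#'   and must include `0`.
#' @param gates Gate list applied to every table; default, the debris/singlet
#'   tree built from the t = 0 table.
#' @param cfp_cutoff,mcherry_cutoff Classification cutoffs; defaults derived
#'   from the gated t = 0 table via [intensity_split()].
#' @param channel Response channel (default `"YFP_A"`).
#' @return Data frame with one row per time: `time_h`, `n_gated`,
#'   `n_reporter`, `cutoff`, `percent_positive`.
#' @export
timecourse <- function(tables, gates = NULL, cfp_cutoff = NULL,
                       mcherry_cutoff = NULL, channel = "YFP_A") {
  times <- suppressWarnings(as.numeric(names(tables)))
  if (any(is.na(times))) stopf("tables must be named by time in hours")
  if (!any(times == 0)) stopf("missing t = 0 table")
  t0 <- tables[[which(times == 0)[1L]]]
  if (is.null(gates)) gates <- auto_gate_tree(t0)
  g0 <- gated_events(t0, apply_gates(t0, gates))
  if (is.null(cfp_cutoff)) cfp_cutoff <- intensity_split(g0$CFP_A)
  if (is.null(mcherry_cutoff)) mcherry_cutoff <- intensity_split(g0$mCherry_A)
  rep0 <- g0[classify_populations(g0, cfp_cutoff, mcherry_cutoff) ==
               "reporter", , drop = FALSE]
  cutoff <- compute_cutoff(rep0[[channel]])
  ord <- order(times)
  rows <- lapply(ord, function(i) {
    tb <- tables[[i]]
    gg <- gated_events(tb, apply_gates(tb, gates))
    rp <- gg[classify_populations(gg, cfp_cutoff, mcherry_cutoff) ==
               "reporter", , drop = FALSE]
    pp <- percent_positive(rp[[channel]], cutoff)
    data.frame(time_h = times[i], n_gated = nrow(gg), n_reporter = nrow(rp),
               cutoff = cutoff, percent_positive = pp$percent_positive)
  })
  do.call(rbind, rows)
}

#' Propidium-iodide lysis fraction
#'
#' Percent of gated singlet events above a PE-A cutoff. The cutoff should be
#' set from reference histograms (unstained and heat-killed controls), not
#' from the sample itself.
#'
#' @param tbl Flow-event table with a `PE_A` column.
#' @param pe_cutoff PE-A intensity cutoff.
#' @param gates Gate list; default, the debris/singlet tree derived from
#'   `tbl` itself.
#' @return A `threshold_classification` for the gated events.
#' @export
lysis_fraction <- function(tbl, pe_cutoff, gates = NULL) {
  if (!"PE_A" %in% names(tbl)) stopf("missing PE_A channel")
  if (is.null(gates)) gates <- auto_gate_tree(tbl)
  gg <- gated_events(tbl, apply_gates(tbl, gates))
  percent_positive(gg$PE_A, pe_cutoff)
}
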