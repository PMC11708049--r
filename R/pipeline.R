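# End-to-end assay pipelines over the synthetic generators. Each run_*()
# function simulates the study conditions of one assay, pushes the data
# through the measurement modules, and returns tidy result tables; with an
# `outdir` the tables are also written as CSV.

params_hash <- function(...) {
  v <- unlist(list(...))
  paste0("p", format(sum(cumsum(as.numeric(utils::head(
    strtoi(charToRaw(paste(names(v), v, collapse = ";")), 16L), 64L)))) %%
    1e9, scientific = FALSE))
}

write_if <- function(df, outdir, name) {
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  invisible(df)
}

# Measure one lawn colony: render, extract the radial section, align at the
# smoothed YFP peak, run the decay analysis.
lawn_colony_result <- function(gt, step, window, n_tail, response_floor_k) {
  img <- render_scene(gt)
  pc <- gt$producer_colonies[1L, ]
  w <- gt$image_shape[2] * gt$pixel_size
  prof <- extract_cross_section(img, c(pc$x, pc$y),
                                c(w - gt$pixel_size, pc$y), step = step)
  sm <- smooth_profile(prof$intensity$YFP, window)
  pk <- peak_signal(prof$distance, sm, prof$mask)
  aligned <- align_profile(prof, pk$distance, "yfp-peak")
  list(result = analyze_decay(aligned, window = window, n_tail = n_tail,
                              response_floor_k = response_floor_k),
       profile = aligned)
}

#' Run the reporter-lawn decay assay on simulated plates
#'
#' Simulates producer colonies on a lawn of reporter cells (one scene per
#' technical-replicate colony), measures the YFP decay away from each colony
#' and reports per-colony decay results plus replicate-averaged curves. The
#' default conditions mirror the saturated lawn co-culture: a 250 um
#' producer colony, a 100 um gradient decay length and 10 colonies per
#' biological replicate.
#'
#' @param n_colonies Technical-replicate colonies per biological replicate.
#' @param n_replicates Biological replicates.
#' @param decay_length Ground-truth gradient decay length (um).
#' @param lambda_cv Log-normal coefficient of variation of the per-colony
#'   decay length (0 for identical colonies).
#' @param pixel_size,image_shape,colony_radius,amplitude,gain,baseline,
#'   cfp_level,mcherry_level,noise_sd Scene parameters passed to
#'   [scene_ground_truth()].
#' @param step Profile sampling step (um); defaults to one pixel.
#' @param window,n_tail,response_floor_k Decay-analysis parameters.
#' @param seed Master seed; every scene gets a derived child seed.
#' @param outdir Optional directory for `lawn_results.csv`.
#' @return List with `results` (one row per colony), `replicate_means`,
#'   `averaged` (mean +/- SD decay curve) and `params_hash`.
#' @export
run_lawn_assay <- function(n_colonies = 10L, n_replicates = 1L,
                           decay_length = 100, lambda_cv = 0,
                           pixel_size = 5, image_shape = c(600L, 600L),
                           colony_radius = 250, amplitude = 1000, gain = 10,
                           baseline = 500, cfp_level = 3000,
                           mcherry_level = 20000, noise_sd = 50,
                           step = pixel_size, window = 20L, n_tail = 20L,
                           response_floor_k = 3, seed = 1L, outdir = NULL) {
  ntot <- n_colonies * n_replicates
  seeds <- derive_seeds(seed, ntot + 1L)
  lambdas <- with_seed(seeds[ntot + 1L],
                       decay_length * exp(stats::rnorm(ntot, 0, lambda_cv)))
  hash <- params_hash(n_colonies = n_colonies, n_replicates = n_replicates,
                      decay_length = decay_length, lambda_cv = lambda_cv,
                      noise_sd = noise_sd, window = window, seed = seed)
  cx <- image_shape[2] * pixel_size / 2
  cy <- image_shape[1] * pixel_size / 2
  rows <- list(); profs <- list()
  k <- 0L
  for (r in seq_len(n_replicates)) {
    for (ci in seq_len(n_colonies)) {
      k <- k + 1L
      gt <- scene_ground_truth(
        pixel_size = pixel_size, image_shape = image_shape,
        producer_colonies = data.frame(x = cx, y = cy, r = colony_radius),
        reporter_regions = "lawn", toxin_amplitude = amplitude,
        decay_length = lambdas[k], yfp_baseline = baseline, yfp_gain = gain,
        cfp_level = cfp_level, mcherry_level = mcherry_level,
        noise_sd = noise_sd, seed = seeds[k])
      m <- lawn_colony_result(gt, step, window, n_tail, response_floor_k)
      res <- m$result
      profs[[k]] <- m$profile
      rows[[k]] <- data.frame(
        scene_id = sprintf("lawn_r%d_c%d", r, ci), replicate = r,
        colony = ci, lambda_true = lambdas[k], baseline = res$baseline,
        max_signal = res$max_signal, yfp50 = res$yfp50,
        dist50_um = res$dist50, valid = res$valid, reason = res$reason,
        params_hash = hash, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  ok <- results$valid
  if (!any(ok))
    stopf("no valid colonies; reasons: %s",
          paste(unique(results$reason), collapse = ", "))
  rep_means <- stats::aggregate(dist50_um ~ replicate,
                                data = results[ok, , drop = FALSE], FUN = mean)
  averaged <- tryCatch(average_decays(profs[ok], channel = "YFP"),
                       error = function(e) NULL)
  write_if(results, outdir, "lawn_results.csv")
  list(results = results, replicate_means = rep_means, averaged = averaged,
       params_hash = hash)
}

# Measure one colony pair: render at the requested gap, extract the section
# through both centres, align at the detected mCherry edge, mask the gap.
pair_profile <- function(gt, gap, colony_radius, window) {
  img <- render_colony_pair(gt, gap, reporter_radius = colony_radius)
  pc <- gt$producer_colonies[1L, ]
  far_x <- pc$x + pc$r + gap + 2 * colony_radius - gt$pixel_size
  prof <- extract_cross_section(img, c(pc$x, pc$y), c(far_x, pc$y),
                                step = gt$pixel_size)
  edge <- detect_producer_edge(prof)
  aligned <- align_profile(prof, edge, "mcherry-edge")
  if (gap > 0) aligned <- mask_gap(aligned, 0, gap)
  aligned
}

#' Run the contacting / non-contacting colony-pair assay
#'
#' Simulates producer-reporter colony pairs at gap 0 (contacting) and at a
#' non-contacting gap, from one common toxin-field parameterization, and
#' compares the two dist50 estimators: contacting pairs use their own
#' half-maximum; non-contacting pairs use the contacting half-maximal
#' intensity averaged across all replicates as a reference. Per-replicate
#' mean dist50 values feed a two-tailed Welch test of the
#' contact-equivalence hypothesis.
#'
#' @param n_replicates Biological replicates per group.
#' @param pairs_per_replicate Colony pairs per replicate.
#' @param gap Edge-to-edge gap (um) of the non-contacting group (>= 10 um by
#'   the non-contacting definition).
#' @param decay_length Ground-truth decay length (um); a length-2 vector
#'   applies separate values to the contacting and non-contacting groups
#'   (e.g. for a power check).
#' @param lambda_cv Per-colony log-normal decay-length CV; the default 8%
#'   supplies the colony-to-colony biological variability of a plate.
#' @param colony_radius Radius (um) of both colonies.
#' @param pixel_size,amplitude,gain,baseline,cfp_level,mcherry_level,noise_sd
#'   Scene parameters.
#' @param window,n_tail,response_floor_k Decay-analysis parameters.
#' @param seed Master seed.
#' @param outdir Optional directory for `colony_results.csv`.
#' @return List with `results` (per pair), `replicate_means`,
#'   `group_summary`, `reference_yfp50` (baseline-subtracted contacting
#'   half-maximum) and `ttest` (`NULL`, with a warning, if a group has fewer
#'   than 2 replicates with valid pairs).
#' @export
run_colony_assay <- function(n_replicates = 3L, pairs_per_replicate = 10L,
                             gap = 50, decay_length = 100, lambda_cv = 0.08,
                             colony_radius = 200, pixel_size = 4,
                             amplitude = 1000, gain = 10, baseline = 500,
                             cfp_level = 3000, mcherry_level = 20000,
                             noise_sd = 50, window = 20L, n_tail = 20L,
                             response_floor_k = 3, seed = 1L, outdir = NULL) {
  if (gap < 10)
    warning("non-contacting colonies are defined by a gap of at least 10 um")
  dl <- rep(decay_length, length.out = 2L)
  groups <- data.frame(group = c("contacting", "non-contacting"),
                       gap = c(0, gap), lambda = dl,
                       stringsAsFactors = FALSE)
  npair <- n_replicates * pairs_per_replicate
  seeds <- derive_seeds(seed, 2L * npair + 2L)
  hash <- params_hash(n_replicates = n_replicates,
                      pairs = pairs_per_replicate, gap = gap,
                      dl1 = dl[1], dl2 = dl[2], lambda_cv = lambda_cv,
                      noise_sd = noise_sd, seed = seed)
  margin <- 10 * pixel_size
  cy <- colony_radius + margin
  rows <- 2L * ceiling(cy / pixel_size)
  profiles <- list(contacting = list(), `non-contacting` = list())
  meta <- list(contacting = list(), `non-contacting` = list())
  k <- 0L
  for (gi in 1:2) {
    lam_seed <- seeds[2L * npair + gi]
    lambdas <- with_seed(lam_seed,
                         groups$lambda[gi] * exp(stats::rnorm(npair, 0, lambda_cv)))
    j <- 0L
    for (r in seq_len(n_replicates)) {
      for (pi in seq_len(pairs_per_replicate)) {
        k <- k + 1L; j <- j + 1L
        sd_seed <- seeds[k]
        gt <- local({
          gp <- groups$gap[gi]
          cols <- ceiling((2 * margin + 3 * colony_radius + gp +
                             colony_radius) / pixel_size) + 1L
          scene_ground_truth(
            pixel_size = pixel_size, image_shape = c(rows, cols),
            producer_colonies = data.frame(x = colony_radius + margin,
                                           y = cy, r = colony_radius),
            toxin_amplitude = amplitude, decay_length = lambdas[j],
            yfp_baseline = baseline, yfp_gain = gain,
            cfp_level = cfp_level, mcherry_level = mcherry_level,
            noise_sd = noise_sd, seed = sd_seed)
        })
        prof <- pair_profile(gt, groups$gap[gi], colony_radius, window)
        idx <- length(profiles[[gi]]) + 1L
        profiles[[gi]][[idx]] <- prof
        meta[[gi]][[idx]] <- data.frame(
          scene_id = sprintf("pair_%s_r%d_p%d", groups$group[gi], r, pi),
          group = groups$group[gi], replicate = r, pair = pi,
          gap_um = groups$gap[gi], lambda_true = lambdas[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  analyze_group <- function(gi, ref = NULL) {
    contact <- if (gi == 1L) "contacting" else "non-contacting"
    mapply(function(prof, md) {
      res <- analyze_decay(prof, window = window, n_tail = n_tail,
                           response_floor_k = response_floor_k,
                           contact_class = contact, yfp50_reference = ref)
      cbind(md, data.frame(baseline = res$baseline,
                           max_signal = res$max_signal, yfp50 = res$yfp50,
                           dist50_um = res$dist50, valid = res$valid,
                           reason = res$reason, params_hash = hash,
                           stringsAsFactors = FALSE))
    }, profiles[[gi]], meta[[gi]], SIMPLIFY = FALSE)
  }
  res_c <- do.call(rbind, analyze_group(1L))
  okc <- res_c$valid
  reference <- mean(res_c$yfp50[okc] - res_c$baseline[okc])
  res_n <- do.call(rbind, analyze_group(2L, ref = reference))
  results <- rbind(res_c, res_n)
  ok <- results$valid
  rep_means <- stats::aggregate(dist50_um ~ group + replicate,
                                data = results[ok, , drop = FALSE],
                                FUN = mean)
  grp <- split(rep_means$dist50_um, rep_means$group)
  summ <- lapply(names(grp), function(g) {
    s <- summarize_replicates(grp[[g]], g)
    data.frame(group = g, mean_dist50_um = s$mean, sd = s$sd,
               n_replicates = s$n)
  })
  group_summary <- do.call(rbind, summ)
  tt <- NULL
  if (all(c("contacting", "non-contacting") %in% names(grp)) &&
      all(vapply(grp, length, integer(1)) >= 2L)) {
    tt <- welch_ttest(grp[["contacting"]], grp[["non-contacting"]])
  } else {
    warning("a group has fewer than 2 replicates with valid pairs; ",
            "equivalence test skipped")
  }
  write_if(results, outdir, "colony_results.csv")
  list(results = results, replicate_means = rep_means,
       group_summary = group_summary, reference_yfp50 = reference,
       ttest = tt, params_hash = hash)
}

#' Run a simulated percent-positive flow time course
#'
#' Simulates co-culture flow samples over time for a producer (`pks_plus`)
#' and a control (`pks_minus`) series, in which the ground-truth responder
#' fraction rises as `plateau * (1 - exp(-t / rise_time_h))` for the
#' producer series and stays zero for the control. Gates and the 3-SD
#' positivity cutoff are fixed from the t = 0 sample and reused at all
#' times; the ground-truth responder percentage among the same gated
#' reporter events is reported alongside for validation.
#'
#' @param times Sampling times in hours; must include 0.
#' @param n_events Events per sample.
#' @param responder_plateau Saturating responder fraction of the producer
#'   series (the co-culture plateaus with 30-50% of reporter cells positive;
#'   default 0.4).
#' @param rise_time_h Exponential rise time of the responder fraction.
#' @param spec A template [flow_population_spec()]; its responder fraction
#'   and seed are overridden per sample.
#' @param seed Master seed.
#' @param outdir Optional directory for `flow_timecourse.csv`.
#' @return Data frame with `series`, `time_h`, `n_gated`, `n_reporter`,
#'   `cutoff`, `percent_positive`, `true_percent`.
#' @export
run_flow_timecourse <- function(times = c(0, 3, 8, 24, 48),
                                n_events = 20000L, responder_plateau = 0.4,
                                rise_time_h = 6,
                                spec = flow_population_spec(),
                                seed = 1L, outdir = NULL) {
  if (length(times) < 2L) stopf("need at least 2 time points including t = 0")
  if (!any(times == 0)) stopf("missing t = 0")
  series <- c(pks_plus = responder_plateau, pks_minus = 0)
  seeds <- derive_seeds(seed, 2L * length(times))
  out <- list(); k <- 0L
  for (s in names(series)) {
    tables <- list()
    for (i in seq_along(times)) {
      k <- k + 1L
      sp <- spec
      sp$n_events <- as.integer(n_events)
      sp$responder_fraction <-
        series[[s]] * (1 - exp(-times[i] / rise_time_h))
      sp$seed <- seeds[k]
      tables[[as.character(times[i])]] <- sample_flow_events(sp)
    }
    t0 <- tables[[as.character(0)]]
    gates <- auto_gate_tree(t0)
    tc <- timecourse(tables, gates = gates)
    g0 <- gated_events(t0, apply_gates(t0, gates))
    cfp_cut <- intensity_split(g0$CFP_A)
    mch_cut <- intensity_split(g0$mCherry_A)
    truth <- vapply(as.character(tc$time_h), function(tm) {
      tb <- tables[[tm]]
      gg <- gated_events(tb, apply_gates(tb, gates))
      rp <- gg[classify_populations(gg, cfp_cut, mch_cut) == "reporter", ,
               drop = FALSE]
      100 * mean(rp$label == "reporter-responder")
    }, numeric(1))
    out[[s]] <- cbind(data.frame(series = s, stringsAsFactors = FALSE),
                      tc, true_percent = unname(truth))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  write_if(res, outdir, "flow_timecourse.csv")
  res
}

#' Run a simulated propidium-iodide lysis assay
#'
#' Simulates stained producer and control cultures in triplicate plus a
#' heat-killed positive control, sets the PE cutoff from the pooled
#' unstained-like and heat-killed histograms, and reports the percent of
#' gated singlets above it per culture, with a Welch test between the two
#' strains.
#'
#' @param lysed_fractions Named ground-truth lysed fractions, one per strain.
#' @param n_events Events per sample.
#' @param n_replicates Cultures per strain.
#' @param spec Template [flow_population_spec()].
#' @param seed Master seed.
#' @param outdir Optional directory for `lysis_results.csv`.
#' @return List with `results` (per culture), `pe_cutoff`, `heatkill_percent`
#'   and `ttest`.
#' @export
run_lysis_assay <- function(lysed_fractions = c(pks_plus = 0.012,
                                                pks_minus = 0.008),
                            n_events = 50000L, n_replicates = 3L,
                            spec = flow_population_spec(responder_fraction = 0),
                            seed = 1L, outdir = NULL) {
  ns <- length(lysed_fractions)
  seeds <- derive_seeds(seed, ns * n_replicates + 2L)
  make <- function(frac, sd) {
    sp <- spec
    sp$n_events <- as.integer(n_events)
    sp$lysed_fraction <- frac
    # keep the exclusive-label budget feasible (heat-kill sets frac = 1)
    room <- 1 - frac
    excl <- sp$debris_fraction + sp$doublet_fraction
    if (excl > room && excl > 0) {
      sp$debris_fraction <- sp$debris_fraction * room / excl
      sp$doublet_fraction <- sp$doublet_fraction * room / excl
    }
    sp$seed <- sd
    sample_flow_events(sp)
  }
  unstained <- make(0, seeds[ns * n_replicates + 1L])
  heatkill <- make(1, seeds[ns * n_replicates + 2L])
  pe_cutoff <- intensity_split(c(unstained$PE_A, heatkill$PE_A))
  gates <- auto_gate_tree(unstained)
  rows <- list(); k <- 0L
  for (s in names(lysed_fractions)) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      tb <- make(lysed_fractions[[s]], seeds[k])
      pp <- lysis_fraction(tb, pe_cutoff, gates = gates)
      rows[[k]] <- data.frame(strain = s, replicate = r,
                              n_gated = pp$n_total,
                              percent_pi_positive = pp$percent_positive,
                              true_lysed_fraction = lysed_fractions[[s]],
                              stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  hk <- lysis_fraction(heatkill, pe_cutoff, gates = gates)
  grp <- split(results$percent_pi_positive, results$strain)
  tt <- if (length(grp) == 2L) welch_ttest(grp[[1L]], grp[[2L]]) else NULL
  write_if(results, outdir, "lysis_results.csv")
  list(results = results, pe_cutoff = pe_cutoff,
       heatkill_percent = hk$percent_positive, ttest = tt)
}

#' Run the colony cross-contamination control
#'
#' Simulates the serial-dilution viable count of cells picked from the edge
#' of a non-contacting reporter colony (Poisson plate counts under the 1:1
#' four-dilution scheme), back-calculates CFU/mL, and reports the purity of
#' the screened colonies with an exact upper bound on the producer
#' contamination rate.
#'
#' @param true_cfu_per_ml Ground-truth viable density of the picked sample.
#' @param n_dilutions Number of 1:1 dilution steps.
#' @param plated_volume_ml Volume plated per dilution (mL).
#' @param n_colonies_screened Colonies examined for fluorescent tags.
#' @param n_producer Producer-tagged colonies observed among them.
#' @param seed RNG seed for the Poisson plate counts.
#' @return List with `counts`, `cfu` (from [cfu_per_ml()]) and `purity`
#'   (from [contamination_check()]).
#' @export
run_contamination_check <- function(true_cfu_per_ml = 150000,
                                    n_dilutions = 4L,
                                    plated_volume_ml = 0.1,
                                    n_colonies_screened = 7500L,
                                    n_producer = 0L, seed = 1L) {
  factors <- serial_dilution_factors(n_dilutions)
  counts <- with_seed(seed,
    stats::rpois(n_dilutions, true_cfu_per_ml * plated_volume_ml / factors))
  cfu <- cfu_per_ml(counts, factors, plated_volume_ml)
  purity <- contamination_check(n_colonies_screened - n_producer, n_producer)
  list(counts = counts, cfu = cfu, purity = purity)
}
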