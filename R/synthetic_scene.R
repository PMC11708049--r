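#' Ground truth for a synthetic plate scene
#'
#' Full parameterization of a simulated co-culture plate: producer-colony
#' geometry, the toxin gradient (amplitude and decay length), reporter-channel
#' gains and background levels, camera noise, and an RNG seed. All distances
#' are in micrometres; intensities are in 16-bit camera units.
#'
#' The toxin field around a producer colony of radius R is
#' `T(r) = A` for `r <= R` and `T(r) = A * exp(-(r - R) / lambda)` beyond the
#' colony edge, i.e. secretion with first-order loss collapsed to a radial
#' exponential. The rendered reporter (YFP) channel is
#' `yfp_baseline + yfp_gain * T` on reporter material.
#'
#' @param pixel_size Pixel edge length in micrometres (> 0). Mandatory
#'   calibration: all geometry below is specified in micrometres.
#' @param image_shape Integer `c(rows, cols)` of the rendered rasters.
#' @param producer_colonies Data frame with columns `x`, `y`, `r`
#'   (centre coordinates and radius, micrometres), one row per producer colony.
#' @param reporter_regions Either the string `"lawn"` (reporter cells
#'   everywhere outside producer footprints) or a data frame with `x`, `y`,
#'   `r` giving discrete reporter colonies.
#' @param toxin_amplitude Toxin level `A` inside a producer footprint
#'   (arbitrary units).
#' @param decay_length Gradient decay length `lambda` in micrometres (> 0).
#' @param yfp_baseline Reporter-channel background intensity `b`.
#' @param yfp_gain Reporter intensity per unit toxin `g`.
#' @param cfp_level Constitutive CFP intensity on reporter material.
#' @param mcherry_level Constitutive mCherry intensity on producer footprints.
#' @param noise_sd Standard deviation of the additive Gaussian camera noise
#'   (>= 0); rendered intensities are clipped at zero and quantized to 16 bit.
#' @param seed Integer seed making every render bit-reproducible.
#'
#' @return An object of class `scene_ground_truth`.
#' @seealso [simulate_toxin_field()], [render_scene()], [render_colony_pair()]
#' @export
scene_ground_truth <- function(pixel_size = 5,
                               image_shape = c(600L, 600L),
                               producer_colonies = data.frame(x = 1500, y = 1500, r = 250),
                               reporter_regions = "lawn",
                               toxin_amplitude = 1000,
                               decay_length = 100,
                               yfp_baseline = 500,
                               yfp_gain = 10,
                               cfp_level = 3000,
                               mcherry_level = 20000,
                               noise_sd = 50,
                               seed = 1L) {
  gt <- structure(
    list(pixel_size = pixel_size, image_shape = as.integer(image_shape),
         producer_colonies = producer_colonies,
         reporter_regions = reporter_regions,
         toxin_amplitude = toxin_amplitude, decay_length = decay_length,
         yfp_baseline = yfp_baseline, yfp_gain = yfp_gain,
         cfp_level = cfp_level, mcherry_level = mcherry_level,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "scene_ground_truth")
  validate_scene_ground_truth(gt)
  gt
}

validate_scene_ground_truth <- function(gt) {
  if (!is_scalar_num(gt$pixel_size) || gt$pixel_size <= 0)
    stopf("pixel_size must be a positive number")
  if (length(gt$image_shape) != 2L || any(gt$image_shape < 1L))
    stopf("image_shape must be two positive integers (rows, cols)")
  if (!is_scalar_num(gt$decay_length) || gt$decay_length <= 0)
    stopf("decay_length must be > 0")
  if (!is_scalar_num(gt$noise_sd) || gt$noise_sd < 0)
    stopf("noise_sd must be >= 0")
  pc <- gt$producer_colonies
  if (!is.data.frame(pc) || !all(c("x", "y", "r") %in% names(pc)))
    stopf("producer_colonies must be a data frame with columns x, y, r")
  if (nrow(pc) > 0 && any(pc$r <= 0)) stopf("colony radii must be > 0")
  w <- gt$image_shape[2] * gt$pixel_size
  h <- gt$image_shape[1] * gt$pixel_size
  inside <- function(df) {
    all(df$x - df$r >= 0 & df$x + df$r <= w &
        df$y - df$r >= 0 & df$y + df$r <= h)
  }
  if (nrow(pc) > 0 && !inside(pc))
    stopf("producer colony footprints must lie fully inside the image")
  rr <- gt$reporter_regions
  if (is.data.frame(rr)) {
    if (!all(c("x", "y", "r") %in% names(rr)))
      stopf("reporter_regions must be 'lawn' or a data frame with x, y, r")
    if (nrow(rr) > 0 && (any(rr$r <= 0) || !inside(rr)))
      stopf("reporter colony footprints must lie fully inside the image")
  } else if (!identical(rr, "lawn")) {
    stopf("reporter_regions must be 'lawn' or a data frame with x, y, r")
  }
  invisible(gt)
}

# Matrix of Euclidean distances (um) from every pixel centre to (cx, cy).
pixel_distance <- function(image_shape, pixel_size, cx, cy) {
  yc <- (seq_len(image_shape[1]) - 0.5) * pixel_size
  xc <- (seq_len(image_shape[2]) - 0.5) * pixel_size
  sqrt(outer((yc - cy)^2, (xc - cx)^2, "+"))
}

disc_mask <- function(image_shape, pixel_size, discs) {
  m <- matrix(FALSE, image_shape[1], image_shape[2])
  for (i in seq_len(nrow(discs))) {
    m <- m | (pixel_distance(image_shape, pixel_size,
                             discs$x[i], discs$y[i]) <= discs$r[i])
  }
  m
}

#' Simulate the toxin concentration field of a scene
#'
#' Evaluates the radial toxin model at every pixel centre: the field equals
#' `toxin_amplitude` inside each producer footprint and decays as
#' `A * exp(-(r - R) / lambda)` with distance from the colony edge.
#' Contributions from multiple colonies combine by `max` by default, which
#' keeps the single-colony closed form exact near each colony; `"sum"` is
#' available as an alternative superposition rule.
#'
#' @param gt A [scene_ground_truth()] object.
#' @param combine How fields of multiple colonies combine: `"max"` (default)
#'   or `"sum"`.
#' @return A numeric matrix (rows x cols) of toxin levels; non-negative,
#'   equal to the amplitude on each colony boundary, and non-increasing with
#'   distance from the nearest colony (under `"max"`).
#' @export
simulate_toxin_field <- function(gt, combine = c("max", "sum")) {
  validate_scene_ground_truth(gt)
  combine <- match.arg(combine)
  pc <- gt$producer_colonies
  if (nrow(pc) == 0L) stopf("scene has no source: no producer colonies")
  A <- gt$toxin_amplitude
  lam <- gt$decay_length
  field <- matrix(0, gt$image_shape[1], gt$image_shape[2])
  for (i in seq_len(nrow(pc))) {
    r <- pixel_distance(gt$image_shape, gt$pixel_size, pc$x[i], pc$y[i])
    ti <- ifelse(r <= pc$r[i], A, A * exp(-(r - pc$r[i]) / lam))
    field <- if (combine == "max") pmax(field, ti) else field + ti
  }
  field
}

#' Render the multichannel image set of a synthetic scene
#'
#' Produces registered CFP, YFP and mCherry rasters from a ground-truth
#' parameterization. On reporter material the YFP channel is
#' `yfp_baseline + yfp_gain * T(pixel)` with `T` the toxin field and CFP is
#' the constitutive `cfp_level`; mCherry is `mcherry_level` on producer
#' footprints only. Zero-mean Gaussian noise (`noise_sd`) is added everywhere,
#' then intensities are clipped at zero and quantized to the 16-bit range.
#' Rendering is bit-reproducible for a fixed `seed`.
#'
#' @inheritParams simulate_toxin_field
#' @return An [image_set()] with channels `CFP`, `YFP`, `mCherry`; scene
#'   parameters are carried in `metadata`.
#' @export
render_scene <- function(gt, combine = c("max", "sum")) {
  validate_scene_ground_truth(gt)
  combine <- match.arg(combine)
  shp <- gt$image_shape
  producer <- if (nrow(gt$producer_colonies) > 0)
    disc_mask(shp, gt$pixel_size, gt$producer_colonies)
  else matrix(FALSE, shp[1], shp[2])
  if (identical(gt$reporter_regions, "lawn")) {
    reporter <- !producer
  } else {
    reporter <- disc_mask(shp, gt$pixel_size, gt$reporter_regions)
    if (any(reporter & producer))
      stopf("reporter and producer footprints overlap")
  }
  field <- simulate_toxin_field(gt, combine = combine)
  yfp <- ifelse(reporter, gt$yfp_baseline + gt$yfp_gain * field, 0)
  cfp <- ifelse(reporter, gt$cfp_level, 0)
  mch <- ifelse(producer, gt$mcherry_level, 0)
  chans <- with_seed(gt$seed, {
    noisy <- function(m) {
      if (gt$noise_sd > 0) m <- m + stats::rnorm(length(m), 0, gt$noise_sd)
      quantize16(matrix(m, shp[1], shp[2]))
    }
    list(CFP = noisy(cfp), YFP = noisy(yfp), mCherry = noisy(mch))
  })
  image_set(chans, gt$pixel_size,
            metadata = list(ground_truth = gt, combine = combine))
}

#' Render a producer/reporter colony pair at a controlled gap
#'
#' Places one producer colony (from `gt`) and one reporter colony on the same
#' plate with a nearest-edge distance of `gap` micrometres along the +x axis;
#' `gap = 0` encodes contacting (tangent) colonies. The reporter colony's YFP
#' follows the same toxin-response law as a lawn, restricted to the reporter
#' footprint.
#'
#' @inheritParams simulate_toxin_field
#' @param gap Edge-to-edge separation in micrometres (>= 0).
#' @param reporter_radius Radius of the reporter colony (um); defaults to the
#'   producer radius.
#' @return An [image_set()]; `metadata$gap` records the gap and
#'   `metadata$reporter_centre` the placed colony centre.
#' @export
render_colony_pair <- function(gt, gap, reporter_radius = NULL) {
  validate_scene_ground_truth(gt)
  if (!is_scalar_num(gap) || gap < 0) stopf("gap must be >= 0")
  pc <- gt$producer_colonies
  if (nrow(pc) < 1L) stopf("scene has no source: no producer colonies")
  pc <- pc[1L, , drop = FALSE]
  rr <- if (is.null(reporter_radius)) pc$r else reporter_radius
  centre <- c(pc$x + pc$r + gap + rr, pc$y)
  w <- gt$image_shape[2] * gt$pixel_size
  h <- gt$image_shape[1] * gt$pixel_size
  if (centre[1] + rr > w || centre[2] + rr > h || centre[2] - rr < 0)
    stopf("gap of %g um places the reporter colony outside the image", gap)
  gt$producer_colonies <- pc
  gt$reporter_regions <- data.frame(x = centre[1], y = centre[2], r = rr)
  img <- render_scene(gt)
  img$metadata$gap <- gap
  img$metadata$reporter_centre <- centre
  img$metadata$reporter_radius <- rr
  img
}

#' Write a rendered scene as per-channel 16-bit TIFF files
#'
#' Writes `<scene>_CFP.tif`, `<scene>_YFP.tif` and `<scene>_mCherry.tif`
#' (16-bit grayscale, uncompressed) plus, when the image set carries ground
#' truth, a YAML sidecar `<scene>_ground_truth.yaml` recording every
#' generator parameter.
#'
#' @param img An [image_set()].
#' @param dir Output directory (created if missing).
#' @param scene Scene identifier used as the filename stem.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_image_set <- function(img, dir, scene = "scene") {
  stopifnot(inherits(img, "image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in names(img$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", scene, ch))
    tiff::writeTIFF(img$channels[[ch]] / 65535, p, bits.per.sample = 16L,
                    compression = "none")
    paths[ch] <- p
  }
  gt <- img$metadata$ground_truth
  if (!is.null(gt)) {
    sp <- file.path(dir, sprintf("%s_ground_truth.yaml", scene))
    rec <- unclass(gt)
    rec$producer_colonies <- as.list(as.data.frame(rec$producer_colonies))
    if (is.data.frame(rec$reporter_regions))
      rec$reporter_regions <- as.list(as.data.frame(rec$reporter_regions))
    yaml::write_yaml(c(rec, list(pixel_size_um = gt$pixel_size)), sp)
    paths["ground_truth"] <- sp
  }
  invisible(paths)
}

#' Specification of a synthetic flow-cytometry event mixture
#'
#' Parameterizes a log-normal mixture of flow events emulating a
#' producer/reporter co-culture: responder and non-responder reporters,
#' producers, low-scatter debris, FSC-A-doubled doublets, and a
#' propidium-iodide-positive (lysed) subpopulation. All channel locations and
#' spreads are on the log10 scale; event values are `10^N(mean, sd)`.
#'
#' @param n_events Number of events to draw (>= 0).
#' @param responder_fraction Fraction of reporter cells carrying the DNA-damage
#'   response (YFP shift), in `[0, 1]`.
#' @param channel_means,channel_sds Named numeric vectors of log10 locations /
#'   spreads for `FSC_A`, `FSC_H`, `SSC_A`, `CFP_A`, `YFP_A`, `mCherry_A`,
#'   `PE_A`.
#' @param yfp_shift Log10 offset added to responders' YFP-A; the default 0.36
#'   is six fluorescence SDs, a well-separated induced population.
#' @param debris_fraction,doublet_fraction,lysed_fraction Proportions of the
#'   event stream that are sub-cellular debris, FSC doublets, or PI-positive
#'   lysed cells; mutually exclusive labels, together <= 1.
#' @param producer_to_reporter_ratio Producer:reporter cell ratio; the
#'   co-culture design mixes producers and reporters 10:1.
#' @param cfp_shift,mcherry_shift,pe_shift Log10 offsets marking reporters
#'   (constitutive CFP), producers (constitutive mCherry) and lysed cells
#'   (PI/PE-A).
#' @param debris_shift Log10 offset applied to debris scatter channels
#'   (negative: debris is small and dim).
#' @param fsc_ratio_sd Log10 SD of the per-event FSC-A/FSC-H mismatch for
#'   singlets; doublets additionally double FSC-A.
#' @param seed Integer seed; sampling is bit-reproducible.
#' @return An object of class `flow_population_spec`.
#' @export
flow_population_spec <- function(n_events = 10000L,
                                 responder_fraction = 0.4,
                                 channel_means = c(FSC_A = 4.0, FSC_H = 4.0,
                                                   SSC_A = 3.5, CFP_A = 2.0,
                                                   YFP_A = 2.0, mCherry_A = 2.0,
                                                   PE_A = 1.5),
                                 channel_sds = c(FSC_A = 0.10, FSC_H = 0.10,
                                                 SSC_A = 0.12, CFP_A = 0.06,
                                                 YFP_A = 0.06, mCherry_A = 0.06,
                                                 PE_A = 0.06),
                                 yfp_shift = 0.36,
                                 debris_fraction = 0.05,
                                 doublet_fraction = 0.03,
                                 lysed_fraction = 0,
                                 producer_to_reporter_ratio = 10,
                                 cfp_shift = 1.5,
                                 mcherry_shift = 1.5,
                                 pe_shift = 1.5,
                                 debris_shift = -1.5,
                                 fsc_ratio_sd = 0.02,
                                 seed = 1L) {
  spec <- structure(
    list(n_events = as.integer(n_events),
         responder_fraction = responder_fraction,
         channel_means = channel_means, channel_sds = channel_sds,
         yfp_shift = yfp_shift,
         debris_fraction = debris_fraction,
         doublet_fraction = doublet_fraction,
         lysed_fraction = lysed_fraction,
         producer_to_reporter_ratio = producer_to_reporter_ratio,
         cfp_shift = cfp_shift, mcherry_shift = mcherry_shift,
         pe_shift = pe_shift, debris_shift = debris_shift,
         fsc_ratio_sd = fsc_ratio_sd, seed = as.integer(seed)),
    class = "flow_population_spec")
  validate_flow_population_spec(spec)
  spec
}

validate_flow_population_spec <- function(spec) {
  fr <- c(spec$responder_fraction, spec$debris_fraction,
          spec$doublet_fraction, spec$lysed_fraction)
  if (any(fr < 0 | fr > 1)) stopf("all fractions must lie in [0, 1]")
  excl <- spec$debris_fraction + spec$doublet_fraction + spec$lysed_fraction
  if (excl > 1) stopf("debris + doublet + lysed fractions exceed 1")
  if (spec$n_events < 0L) stopf("n_events must be >= 0")
  if (spec$producer_to_reporter_ratio < 0)
    stopf("producer_to_reporter_ratio must be >= 0")
  need <- c("FSC_A", "FSC_H", "SSC_A", "CFP_A", "YFP_A", "mCherry_A", "PE_A")
  if (!all(need %in% names(spec$channel_means)) ||
      !all(need %in% names(spec$channel_sds)))
    stopf("channel_means and channel_sds must name all of: %s",
          paste(need, collapse = ", "))
  invisible(spec)
}

flow_event_columns <- c("event_id", "FSC_A", "FSC_H", "SSC_A",
                        "CFP_A", "YFP_A", "mCherry_A", "PE_A", "label")

#' Sample a synthetic flow-event table with ground-truth labels
#'
#' Draws `n_events` events from the mixture described by a
#' [flow_population_spec()]. Every event carries a ground-truth `label` in
#' `{reporter-responder, reporter-nonresponder, producer, debris, doublet,
#' lysed}`. Responders receive the log-scale YFP shift; doublets have
#' FSC-A approximately twice FSC-H relative to singlets; debris is shifted
#' down on the scatter channels; lysed cells are bright in PE-A.
#'
#' @param spec A [flow_population_spec()].
#' @return A `data.frame` (class `flow_events`) with columns `event_id`,
#'   `FSC_A`, `FSC_H`, `SSC_A`, `CFP_A`, `YFP_A`, `mCherry_A`, `PE_A`,
#'   `label`; exactly `n_events` rows.
#' @export
sample_flow_events <- function(spec) {
  validate_flow_population_spec(spec)
  n <- spec$n_events
  if (n == 0L) {
    tbl <- data.frame(event_id = integer(0), FSC_A = numeric(0),
                      FSC_H = numeric(0), SSC_A = numeric(0),
                      CFP_A = numeric(0), YFP_A = numeric(0),
                      mCherry_A = numeric(0), PE_A = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
    class(tbl) <- c("flow_events", "data.frame")
    return(tbl)
  }
  p_excl <- c(debris = spec$debris_fraction,
              doublet = spec$doublet_fraction,
              lysed = spec$lysed_fraction)
  p_cell <- 1 - sum(p_excl)
  pr <- spec$producer_to_reporter_ratio
  p_prod <- p_cell * pr / (1 + pr)
  p_rep <- p_cell / (1 + pr)
  probs <- c(p_excl,
             producer = p_prod,
             `reporter-responder` = p_rep * spec$responder_fraction,
             `reporter-nonresponder` = p_rep * (1 - spec$responder_fraction))
  mu <- spec$channel_means
  sdv <- spec$channel_sds
  with_seed(spec$seed, {
    counts <- stats::rmultinom(1L, n, probs)[, 1L]
    label <- sample(rep(names(counts), counts))
    is_debris <- label == "debris"
    is_doublet <- label == "doublet"
    is_lysed <- label == "lysed"
    is_resp <- label == "reporter-responder"
    is_rep <- is_resp | label == "reporter-nonresponder"
    is_prod <- label == "producer"
    # Doublets and lysed cells still belong to one strain for the
    # constitutive tags; draw that strain at the co-culture ratio.
    hidden_rep <- (is_doublet | is_lysed) &
      (stats::runif(n) < 1 / (1 + pr))
    rep_tag <- is_rep | hidden_rep
    prod_tag <- is_prod | ((is_doublet | is_lysed) & !hidden_rep)
    log_fsc_h <- stats::rnorm(n, mu["FSC_H"], sdv["FSC_H"]) +
      spec$debris_shift * is_debris
    log_fsc_a <- log_fsc_h + stats::rnorm(n, 0, spec$fsc_ratio_sd) +
      log10(2) * is_doublet
    log_ssc <- stats::rnorm(n, mu["SSC_A"], sdv["SSC_A"]) +
      spec$debris_shift * is_debris
    log_cfp <- stats::rnorm(n, mu["CFP_A"], sdv["CFP_A"]) +
      spec$cfp_shift * rep_tag
    log_yfp <- stats::rnorm(n, mu["YFP_A"], sdv["YFP_A"]) +
      spec$yfp_shift * is_resp
    log_mch <- stats::rnorm(n, mu["mCherry_A"], sdv["mCherry_A"]) +
      spec$mcherry_shift * prod_tag
    log_pe <- stats::rnorm(n, mu["PE_A"], sdv["PE_A"]) +
      spec$pe_shift * is_lysed
    tbl <- data.frame(event_id = seq_len(n),
                      FSC_A = 10^log_fsc_a, FSC_H = 10^log_fsc_h,
                      SSC_A = 10^log_ssc, CFP_A = 10^log_cfp,
                      YFP_A = 10^log_yfp, mCherry_A = 10^log_mch,
                      PE_A = 10^log_pe, label = label,
                      stringsAsFactors = FALSE)
    class(tbl) <- c("flow_events", "data.frame")
    tbl
  })
}

#' Read and write flow-event tables as CSV
#'
#' The canonical on-disk event format is a CSV with header
#' `event_id, FSC_A, FSC_H, SSC_A, CFP_A, YFP_A, mCherry_A, PE_A, label`;
#' the `label` column is optional (absent for real, unlabelled data).
#'
#' @param tbl A flow-event `data.frame`.
#' @param path File path.
#' @return `read_flow_events` returns the table (class `flow_events`);
#'   `write_flow_events` returns `path` invisibly.
#' @export
write_flow_events <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_events
#' @export
read_flow_events <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tbl) <- c("flow_events", "data.frame")
  tbl
}
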