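test_that("toxin field matches the radial exponential closed form", {
  gt <- tiny_lawn_gt(decay_length = 100)
  field <- simulate_toxin_field(gt)
  pc <- gt$producer_colonies
  # evaluate at chosen pixel centres along the +x axis from the centre
  r_of <- function(col) abs((col - 0.5) * gt$pixel_size - pc$x)
  row <- gt$image_shape[1] / 2  # y = 497.5, ~centre
  y_um <- (row - 0.5) * gt$pixel_size
  closed_form <- function(col) {
    r <- sqrt(r_of(col)^2 + (y_um - pc$y)^2)
    if (r <= pc$r) 1000 else 1000 * exp(-(r - pc$r) / 100)
  }
  for (col in c(100L, 120L, 150L, 199L)) {
    expect_equal(field[row, col], closed_form(col), tolerance = 1e-12)
  }
  # r - R = lambda ln 2 halves the amplitude; r - R = 250 gives A e^-2.5
  expect_equal(1000 * exp(-(100 * log(2)) / 100), 500)
  expect_equal(1000 * exp(-250 / 100), 82.08499862, tolerance = 1e-8)
  # field is non-negative everywhere and maximal inside the colony
  expect_true(all(field >= 0))
  expect_equal(max(field), 1000)
})

test_that("toxin field declines monotonically with distance from the colony", {
  gt <- tiny_lawn_gt()
  field <- simulate_toxin_field(gt)
  row <- gt$image_shape[1] / 2
  profile <- field[row, 100:200]
  expect_true(all(diff(profile) <= 1e-12))
})

test_that("a scene without producer colonies is rejected", {
  gt <- tiny_lawn_gt()
  gt$producer_colonies <- gt$producer_colonies[0, ]
  expect_error(simulate_toxin_field(gt), "no source")
})

test_that("noise-free render reproduces baseline, gain and decay law", {
  # degenerate gain: YFP exactly the baseline over the lawn
  gt0 <- tiny_lawn_gt(gain = 0, baseline = 700)
  img0 <- render_scene(gt0)
  lawn <- img0$channels$mCherry < 10000  # outside producer footprint
  expect_true(all(img0$channels$YFP[lawn] == 700))
  # rendered pixels follow b + g A exp(-d / lambda) along a radial ray
  gt <- tiny_lawn_gt(baseline = 500, gain = 10)
  img <- render_scene(gt)
  row <- gt$image_shape[1] / 2
  y_um <- (row - 0.5) * gt$pixel_size
  for (col in c(130L, 160L, 190L)) {
    r <- sqrt(((col - 0.5) * 5 - 500)^2 + (y_um - 500)^2)
    expect_equal(img$channels$YFP[row, col],
                 round(500 + 10 * 1000 * exp(-(r - 100) / 100)),
                 tolerance = 1e-12)
  }
  # producer channel confined to the producer footprint
  expect_true(all(img$channels$mCherry[lawn] == 0))
  # doubling the gain doubles YFP - b pointwise (noise-free scaling),
  # up to the 16-bit quantization of each render
  gt2 <- tiny_lawn_gt(baseline = 500, gain = 20)
  img2 <- render_scene(gt2)
  lawn_in <- img$channels$CFP > 0
  expect_equal(img2$channels$YFP[lawn_in] - 500,
               2 * (img$channels$YFP[lawn_in] - 500),
               tolerance = 1.1 / 500)
})

test_that("rendering is bit-reproducible for a fixed seed", {
  gt <- tiny_lawn_gt(noise_sd = 50, seed = 42L)
  expect_identical(render_scene(gt), render_scene(gt))
  gt2 <- tiny_lawn_gt(noise_sd = 50, seed = 43L)
  expect_false(identical(render_scene(gt)$channels$YFP,
                         render_scene(gt2)$channels$YFP))
})

test_that("colony pairs sit at the requested edge gap", {
  gt <- tiny_lawn_gt(pixel_size = 5, image_shape = c(150L, 400L),
                     radius = 150)
  gt$producer_colonies <- data.frame(x = 250, y = 375, r = 150)
  for (gap in c(0, 150)) {
    img <- render_colony_pair(gt, gap, reporter_radius = 150)
    prod_mask <- img$channels$mCherry > 10000
    rep_mask <- img$channels$CFP > 1500
    # brute-force nearest-edge distance between the two footprint masks
    pw <- which(prod_mask, arr.ind = TRUE) * 5 - 2.5
    rw <- which(rep_mask, arr.ind = TRUE) * 5 - 2.5
    dmin <- sqrt(min(outer(rw[, 1], pw[, 1], "-")^2 +
                     outer(rw[, 2], pw[, 2], "-")^2))
    # nearest pixel-centre distance exceeds the gap by up to ~1 px per side
    expect_gte(dmin, gap)
    expect_lte(dmin, gap + 2.5 * sqrt(2) * 5)
  }
  expect_error(render_colony_pair(gt, 5000), "outside the image")
})

test_that("a flat-gain colony pair has uniform reporter YFP", {
  gt <- tiny_lawn_gt(pixel_size = 5, image_shape = c(150L, 400L),
                     radius = 150, gain = 0, baseline = 600)
  gt$producer_colonies <- data.frame(x = 250, y = 375, r = 150)
  img <- render_colony_pair(gt, 100, reporter_radius = 150)
  rep_mask <- img$channels$CFP > 1500
  expect_true(all(img$channels$YFP[rep_mask] == 600))
})

test_that("flow event tables honour labels, counts and reproducibility", {
  spec <- flow_population_spec(n_events = 5000L, responder_fraction = 0,
                               seed = 7L)
  tbl <- sample_flow_events(spec)
  expect_equal(nrow(tbl), 5000L)
  expect_false(any(tbl$label == "reporter-responder"))
  expect_true(all(table(tbl$label) >= 0))
  expect_equal(sum(table(tbl$label)), 5000L)
  # empty table keeps the full column schema
  empty <- sample_flow_events(flow_population_spec(n_events = 0L))
  expect_equal(names(empty), c("event_id", "FSC_A", "FSC_H", "SSC_A",
                               "CFP_A", "YFP_A", "mCherry_A", "PE_A",
                               "label"))
  expect_equal(nrow(empty), 0L)
  # bit-reproducible
  expect_identical(sample_flow_events(spec), sample_flow_events(spec))
  # doublets carry FSC_A ~ 2x FSC_H; singlet cells ~ 1x
  spec2 <- flow_population_spec(n_events = 20000L, doublet_fraction = 0.2,
                                seed = 8L)
  tb2 <- sample_flow_events(spec2)
  dr <- tb2$FSC_A / tb2$FSC_H
  expect_equal(median(dr[tb2$label == "doublet"]), 2, tolerance = 0.05)
  expect_equal(median(dr[tb2$label == "producer"]), 1, tolerance = 0.05)
})

test_that("invalid generator parameters are rejected", {
  expect_error(flow_population_spec(responder_fraction = 1.5), "fractions")
  expect_error(flow_population_spec(debris_fraction = 0.6,
                                    doublet_fraction = 0.6), "exceed")
  expect_error(scene_ground_truth(decay_length = -5), "decay_length")
  expect_error(scene_ground_truth(pixel_size = 0), "pixel_size")
  expect_error(
    scene_ground_truth(producer_colonies = data.frame(x = 10, y = 10,
                                                      r = 500)),
    "inside the image")
})

test_that("image sets round-trip through 16-bit TIFF files", {
  gt <- tiny_lawn_gt(noise_sd = 30, seed = 5L)
  img <- render_scene(gt)
  dir <- withr::local_tempdir()
  paths <- write_image_set(img, dir, scene = "s1")
  expect_true(file.exists(paths[["ground_truth"]]))
  back <- read_image_set(paths[c("CFP", "YFP", "mCherry")], pixel_size = 5)
  expect_identical(back$channels$YFP, img$channels$YFP)
  expect_identical(back$channels$CFP, img$channels$CFP)
  expect_identical(back$channels$mCherry, img$channels$mCherry)
})
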