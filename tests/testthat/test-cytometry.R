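test_that("gate membership nests and counts are monotone along the tree", {
  spec <- flow_population_spec(n_events = 20000L, debris_fraction = 0.1,
                               doublet_fraction = 0.05, seed = 11L)
  tbl <- sample_flow_events(spec)
  gates <- auto_gate_tree(tbl)
  g <- apply_gates(tbl, gates)
  # empty gate list: everything in root
  expect_equal(apply_gates(tbl)$counts$n, nrow(tbl))
  # child membership implies parent membership; counts non-increasing
  expect_true(all(g$membership$singlets <= g$membership$cells))
  expect_true(all(diff(g$counts$n) <= 0))
  # debris and doublet exclusion agrees exactly with the labels
  expect_identical(g$membership$cells, tbl$label != "debris")
  expect_identical(g$membership$singlets,
                   !(tbl$label %in% c("debris", "doublet")))
})

test_that("malformed gate trees and missing channels are rejected", {
  tbl <- sample_flow_events(flow_population_spec(n_events = 100L))
  expect_error(apply_gates(tbl, list(
    gate_spec("a", parent = "nowhere", type = "threshold",
              channels = "FSC_A", bounds = c(0, Inf)))), "tree")
  expect_error(apply_gates(tbl, list(
    gate_spec("a", type = "threshold", channels = "NOPE",
              bounds = c(0, Inf)))), "missing channel")
  expect_error(gate_spec("r", type = "rectangle", channels = "FSC_A",
                         bounds = 1:4), "2 channel")
})

test_that("reporter/producer classification follows the two-colour rule", {
  tbl <- data.frame(CFP_A = c(1000, 10, 1000, 10),
                    mCherry_A = c(10, 1000, 1000, 10))
  cls <- classify_populations(tbl, 100, 100)
  expect_equal(cls, c("reporter", "producer", "unclassified",
                      "unclassified"))
  # the 10:1 co-culture ratio is recovered within binomial error
  spec <- flow_population_spec(n_events = 50000L, seed = 21L)
  mix <- sample_flow_events(spec)
  gates <- auto_gate_tree(mix)
  gg <- gated_events(mix, apply_gates(mix, gates))
  cls2 <- classify_populations(gg, intensity_split(gg$CFP_A),
                               intensity_split(gg$mCherry_A))
  # classification agrees with the ground-truth strain labels
  expect_identical(cls2 == "reporter",
                   gg$label %in% c("reporter-responder",
                                   "reporter-nonresponder"))
  expect_identical(cls2 == "producer", gg$label == "producer")
  # and the recovered ratio sits at the 10:1 mixing proportion
  n_rep <- sum(cls2 == "reporter"); n_pro <- sum(cls2 == "producer")
  p_hat <- n_rep / (n_rep + n_pro)
  se <- sqrt(p_hat * (1 - p_hat) / (n_rep + n_pro))
  expect_lt(abs(p_hat - 1 / 11), 4 * se)
})

test_that("the 3-SD cutoff matches a two-pass oracle and the normal tail", {
  expect_equal(compute_cutoff(rep(100, 10)), 100)
  x <- withr::with_seed(5L, rnorm(5000, 100, 10))
  expect_equal(compute_cutoff(x), mean(x) + 3 * two_pass_sd(x),
               tolerance = 1e-12)
  expect_error(compute_cutoff(1), "at least 2")
  # a 3-SD cutoff keeps ~0.135% of a normal sample positive
  big <- withr::with_seed(6L, rnorm(1e6))
  pp <- percent_positive(big, compute_cutoff(big))
  expect_equal(pp$percent_positive, 100 * pnorm(-3), tolerance = 0.15)
})

test_that("percent positive counts strict exceedances", {
  expect_equal(percent_positive(c(1, 2, 3), 5)$percent_positive, 0)
  expect_equal(percent_positive(c(1, 1, 3, 3), 2)$percent_positive, 50)
  # ties are negative
  expect_equal(percent_positive(c(1, 2), 2)$percent_positive, 50 * 0)
  expect_error(percent_positive(numeric(0), 1), "empty")
})

test_that("timecourse reuses the t0 cutoff and tracks the truth", {
  spec <- flow_population_spec(n_events = 20000L, seed = 31L)
  run <- run_flow_timecourse(times = c(0, 3, 8, 24, 48), n_events = 20000L,
                             spec = spec, seed = 31L)
  plus <- run[run$series == "pks_plus", ]
  minus <- run[run$series == "pks_minus", ]
  # one cutoff per series, fixed from t0
  expect_equal(length(unique(plus$cutoff)), 1L)
  # recovered percent matches the ground-truth labels within 1 point
  expect_true(all(abs(run$percent_positive - run$true_percent) < 1))
  # control series stays below 1% positive at every time
  expect_true(all(minus$percent_positive < 1))
  # producer series approaches the 40% plateau
  expect_gt(plus$percent_positive[plus$time_h == 48], 35)
  # deterministic rerun
  run2 <- run_flow_timecourse(times = c(0, 3, 8, 24, 48),
                              n_events = 20000L, spec = spec, seed = 31L)
  expect_identical(run, run2)
  expect_error(timecourse(list(`3` = sample_flow_events(spec))), "t = 0")
})

test_that("lysis fractions recover the generator's ground truth", {
  spec <- flow_population_spec(n_events = 100000L, responder_fraction = 0,
                               lysed_fraction = 0.015, seed = 41L)
  tbl <- sample_flow_events(spec)
  clean <- sample_flow_events(flow_population_spec(
    n_events = 20000L, responder_fraction = 0, lysed_fraction = 0,
    seed = 42L))
  hot <- sample_flow_events(flow_population_spec(
    n_events = 20000L, responder_fraction = 0, lysed_fraction = 1,
    debris_fraction = 0, doublet_fraction = 0, seed = 43L))
  cutoff <- intensity_split(c(clean$PE_A, hot$PE_A))
  gates <- auto_gate_tree(tbl)
  est <- lysis_fraction(tbl, cutoff, gates = gates)
  # oracle: ground-truth lysed labels among the same gated events
  gg <- gated_events(tbl, apply_gates(tbl, gates))
  expect_equal(est$percent_positive, 100 * mean(gg$label == "lysed"),
               tolerance = 0.05 / 1.5)
  # the generator itself delivered ~1.5% lysed events
  expect_equal(100 * mean(tbl$label == "lysed"), 1.5, tolerance = 0.15 / 1.5)
  # negative and positive controls
  expect_equal(lysis_fraction(clean, cutoff,
                              gates = gates)$percent_positive, 0)
  expect_gt(lysis_fraction(hot, cutoff, gates = gates)$percent_positive, 99)
  expect_error(lysis_fraction(clean[, -8], cutoff), "PE_A")
})
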