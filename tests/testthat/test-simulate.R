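test_that("near-deterministic and pure-guess routes behave as expected", {
  des <- experiment_design("cue_delay", cue_delays_ms = 0,
                           trials_per_cell = 400, subjects = 1,
                           report_conditions = "SR", seed = 3)
  # everything routed through attention with tiny stage noise
  sc <- generative_scenario("C", model_c_params(1, 0, decay_law(5, 5, 400),
                                                sigma_attention = 1,
                                                sigma_stm = 1),
                            subject_sd_sigma = 0, subject_sd_weight = 0)
  tr <- simulate_trials(des, sc)
  expect_true(all(abs(tr$error_deg) < 6))
  expect_true(all(tr$hidden_route == "attention"))
  # omega1 = 0: uniform guessing, mean |error| near 90
  sc0 <- generative_scenario("C", model_c_params(0, 0.5, decay_law(5, 5, 400),
                                                 1, 1),
                             subject_sd_sigma = 0, subject_sd_weight = 0)
  tr0 <- simulate_trials(des, sc0)
  expect_true(all(tr0$hidden_route == "guess"))
  expect_equal(mean(abs(tr0$error_deg)), 90, tolerance = 4 * 52 / sqrt(400))
})

test_that("hidden route frequencies match the routing weights", {
  des <- experiment_design("cue_delay", cue_delays_ms = 0,
                           trials_per_cell = 5000, subjects = 1,
                           report_conditions = "SR", seed = 7)
  p <- model_c_params(0.8, 0.5, decay_law(10, 25, 400), 6, 4)
  sc <- generative_scenario("C", p, subject_sd_sigma = 0,
                            subject_sd_weight = 0)
  tr <- simulate_trials(des, sc)
  w <- c(sm = 0.4, attention = 0.4, guess = 0.2)
  for (r in names(w)) {
    se <- sqrt(w[[r]] * (1 - w[[r]]) / 5000)
    expect_lt(abs(mean(tr$hidden_route == r) - w[[r]]), 3 * se)
  }
})

test_that("SM-routed trials spread more at long delays, per the decay law", {
  des <- experiment_design("cue_delay", cue_delays_ms = c(0, 1600),
                           trials_per_cell = 4000, subjects = 1,
                           report_conditions = "SR", seed = 9)
  p <- model_c_params(1, 1, decay_law(8, 26, 400), 6, 4)
  sc <- generative_scenario("C", p, subject_sd_sigma = 0,
                            subject_sd_weight = 0)
  tr <- simulate_trials(des, sc)
  sd0 <- sd(tr$error_deg[tr$cue_delay_ms == 0])
  sd16 <- sd(tr$error_deg[tr$cue_delay_ms == 1600])
  expect_gt(sd16, sd0)
  expect_equal(sd0, sqrt(8^2 + 4^2), tolerance = 0.05 * sd0)
  exp16 <- sqrt(decay_sd(p$sm_decay, 1600)^2 + 16)
  expect_equal(sd16, exp16, tolerance = 0.05 * exp16)
})

test_that("cell histograms converge to the reduced mixture density", {
  # a single seed fails the 1% threshold by chance 1% of the time; require
  # the property at the majority of three independent seeds
  pvals <- vapply(13:15, function(s) {
    des <- experiment_design("cue_delay", cue_delays_ms = 400,
                             trials_per_cell = 1e4, subjects = 1,
                             report_conditions = "SR", seed = s)
    p <- model_d_demo_params()
    sc <- generative_scenario("D", p, subject_sd_sigma = 0,
                              subject_sd_weight = 0)
    tr <- simulate_trials(des, sc)
    spec <- attr(tr, "cell_specs")$spec[[1]]
    breaks <- seq(-180, 180, by = 10)
    counts <- table(cut(tr$error_deg, breaks, include.lowest = TRUE))
    probs <- diff(pmixture(breaks, spec))
    suppressWarnings(stats::chisq.test(as.numeric(counts),
                                       p = probs / sum(probs)))$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 2)
})

test_that("the trial table is deterministic given the seed", {
  des <- experiment_design("set_size", trials_per_cell = 30, subjects = 2,
                           seed = 21)
  sc <- default_model_c_scenario()
  t1 <- simulate_trials(des, sc)
  t2 <- simulate_trials(des, sc)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_trials(experiment_design("set_size", trials_per_cell = 30,
                                          subjects = 2, seed = 22), sc)
  expect_false(identical(t1$error_deg, t3$error_deg))
})

test_that("the packaged dataset has the advertised bookkeeping", {
  tr <- emulate_study_dataset(seed = 2, trials_per_cell = 20, subjects = 5)
  # 5 subjects x 2 conditions x (4 set sizes + 6 delays) x 20 trials
  expect_equal(nrow(tr), 5 * 2 * (4 + 6) * 20)
  expect_setequal(unique(tr$experiment), c("set_size", "cue_delay"))
  expect_setequal(unique(tr$report_condition), c("SR", "FR1"))
  expect_equal(sort(unique(tr$cue_delay_ms[tr$experiment == "cue_delay"])),
               c(0, 100, 200, 400, 800, 1600))
  expect_true(all(tr$error_deg > -180 & tr$error_deg <= 180))
  specs <- attr(tr, "cell_specs")
  expect_equal(nrow(specs), 5 * 2 * (4 + 6))
})

test_that("invalid designs are rejected before sampling", {
  expect_error(experiment_design("cue_delay", trials_per_cell = 0),
               class = "memmixr_domain_error")
  expect_error(experiment_design("cue_delay", cue_delays_ms = -5),
               class = "memmixr_domain_error")
  # invalid cell parameters surface as a domain error, not bad samples
  expect_error(
    simulate_trials(
      experiment_design("cue_delay", trials_per_cell = 5, subjects = 1),
      generative_scenario("C", model_c_params(0.5, 0.5,
                                              decay_law(5, 5, 400), 6, 4),
                          set_size_effects = list(`3` = list(sigma_scale = -1)),
                          subject_sd_sigma = 0, subject_sd_weight = 0)
    ),
    class = "memmixr_domain_error"
  )
})

test_that("trial tables round-trip through CSV", {
  tr <- emulate_study_dataset(seed = 3, trials_per_cell = 5, subjects = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- load_trials(path)
  expect_equal(nrow(back), nrow(tr))
  expect_false("hidden_route" %in% names(back))
  expect_equal(back$error_deg, tr$error_deg, tolerance = 1e-12)
})
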