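test_that("Gaussian convolution adds means and variances, multiplies weights", {
  g <- convolve_gaussians(gaussian_component(0, 3), gaussian_component(0, 4))
  expect_equal(g$mu, 0); expect_equal(g$sigma, 5)
  g2 <- convolve_gaussians(gaussian_component(2, 1, 0.5),
                           gaussian_component(-2, 1, 0.5))
  expect_equal(g2$mu, 0); expect_equal(g2$sigma, sqrt(2))
  expect_equal(g2$weight, 0.25)
  # Monte-Carlo oracle: X + Y has the returned Gaussian's distribution
  withr::with_seed(7, {
    xy <- rnorm(1e5, 1, 6) + rnorm(1e5, -3, 8)
  })
  conv <- convolve_gaussians(gaussian_component(1, 6),
                             gaussian_component(-3, 8))
  ks <- stats::ks.test(xy, "pnorm", conv$mu, conv$sigma)
  expect_gt(ks$p.value, 0.01)
})

test_that("decay laws are nondecreasing and anchored at sigma0", {
  for (form in c("exponential_approach", "linear_saturating", "constant")) {
    law <- decay_law(5, 20, 400, form = form)
    t <- c(0, 100, 200, 400, 800, 1600)
    s <- decay_sd(law, t)
    expect_equal(s[1], 5)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s <= 20 + 1e-12))
  }
  expect_equal(decay_sd(decay_law(5, 20, 400), 400), 20 - 15 * exp(-1))
  expect_error(decay_law(5, 2, 400), class = "memmixr_domain_error")
  expect_error(decay_sd(decay_law(5), -1), class = "memmixr_domain_error")
})

test_that("single-store reductions give one Gaussian + uniform", {
  sp <- reduce_model_ab(gaussian_component(0, 6), omega = 0.7,
                        stm = gaussian_component(0, 8))
  expect_equal(nrow(sp$components), 1)
  expect_equal(sp$components$sigma, 10)
  expect_equal(sp$components$weight, 0.7)
  expect_equal(sp$uniform_weight, 0.3)
  # guessing only
  sp0 <- reduce_model_ab(gaussian_component(0, 6), omega = 0)
  expect_equal(nrow(sp0$components), 0)
  expect_equal(sp0$uniform_weight, 1)
  # degenerate second stage recovers the single-stage model
  spa <- reduce_model_ab(gaussian_component(0, 6), omega = 1,
                         stm = gaussian_component(0, 1e-9))
  expect_equal(spa$components$sigma, 6, tolerance = 1e-9)
  expect_equal(spa$uniform_weight, 0)
})

test_that("SM/attention/STM reduction has the stated weights and delay signature", {
  p <- model_c_params(omega1 = 0.8, omega2 = 0.5,
                      sm_decay = decay_law(5, 20, 400),
                      sigma_attention = 6, sigma_stm = 4)
  sp <- reduce_model_c(p, 0)
  w <- setNames(sp$components$weight, sp$components$label)
  expect_equal(unname(w["sm"]), 0.4)
  expect_equal(unname(w["attention"]), 0.4)
  expect_equal(sp$uniform_weight, 0.2)
  # weight closure holds exactly for any omega pair
  for (s in 1:20) {
    o <- withr::with_seed(s, runif(2))
    pc <- model_c_params(o[1], o[2], decay_law(5, 20, 400), 6, 4)
    spc <- reduce_model_c(pc, 100)
    expect_identical(sum(spc$components$weight) + spc$uniform_weight, 1)
  }
  # omega2 = 1 collapses to a single memory Gaussian
  p1 <- model_c_params(0.8, 1, decay_law(5, 20, 400), 6, 4)
  expect_equal(nrow(reduce_model_c(p1, 0)$components), 1)
  # only the SM-routed SD grows with delay
  s0 <- reduce_model_c(p, 0)$components
  s16 <- reduce_model_c(p, 1600)$components
  sm0 <- s0$sigma[s0$label == "sm"]; sm16 <- s16$sigma[s16$label == "sm"]
  at0 <- s0$sigma[s0$label == "attention"]
  at16 <- s16$sigma[s16$label == "attention"]
  expect_gt(sm16, sm0)
  expect_identical(at0, at16)
})

test_that("parallel-routes reduction has the stated weights and both SDs decay", {
  p <- model_d_demo_params()
  sp <- reduce_model_d(p, 0)
  expect_equal(sum(sp$components$weight), 0.8)
  expect_equal(sp$uniform_weight, 0.2, tolerance = 1e-12)
  s0 <- reduce_model_d(p, 0)$components$sigma
  s16 <- reduce_model_d(p, 1600)$components$sigma
  expect_true(all(s16 > s0))
  # identical routes merge into one Gaussian of the summed weight
  pid <- model_d_params(0.5, 0.3, sm_decay1 = decay_law(8, 8, 400),
                        sigma_stm1 = 5)
  spid <- reduce_model_d(pid, 0)
  expect_equal(nrow(spid$components), 1)
  expect_equal(spid$components$weight, 0.8)
  expect_equal(spid$uniform_weight, 0.2, tolerance = 1e-12)
})

test_that("sequential-stage sampling matches the reduced mixture when clipping is negligible", {
  # two-store chain: SM then STM
  withr::with_seed(11, {
    pB <- list(omega = 0.75, mu_sm = 0, sm_decay = decay_law(10, 25, 400),
               mu_stm = 0, sigma_stm = 8)
    e <- {
      n <- 1e5
      route <- runif(n) < pB$omega
      out <- runif(n, -180, 180)
      out[route] <- rnorm(sum(route), 0, decay_sd(pB$sm_decay, 400)) +
        rnorm(sum(route), 0, 8)
      wrap_error(out)
    }
    red <- reduce_model_ab(gaussian_component(0, decay_sd(pB$sm_decay, 400)),
                           pB$omega, stm = gaussian_component(0, 8))
    ks <- suppressWarnings(stats::ks.test(e, function(q) pmixture(q, red)))
    expect_gt(ks$p.value, 0.01)
  })
  # SM/attention/STM at a moderate delay (all stage SDs <= 30)
  withr::with_seed(12, {
    p <- model_c_params(0.8, 0.5, decay_law(12, 28, 400), 6, 4)
    e <- oracle_sample_c(p, 800, 1e5)
    red <- reduce_model_c(p, 800)
    ks <- suppressWarnings(stats::ks.test(e, function(q) pmixture(q, red)))
    expect_gt(ks$p.value, 0.01)
  })
  # clipping grows with stage SD: discrepancy is measurable near 90 degrees
  withr::with_seed(13, {
    ks_stat <- function(sd_sm) {
      p <- model_c_params(1, 1, decay_law(sd_sm, sd_sm, 400), 6, 4)
      e <- oracle_sample_c(p, 0, 2e4)
      suppressWarnings(stats::ks.test(e, function(q)
        pmixture(q, reduce_model_c(p, 0)))$statistic)
    }
    expect_gt(ks_stat(90), ks_stat(20))
  })
})
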