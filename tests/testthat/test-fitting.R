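test_that("negative log-likelihood matches closed forms and a brute-force loop", {
  u <- mixture_spec(numeric(0), numeric(0), numeric(0), uniform_weight = 1)
  e <- withr::with_seed(1, runif(57, -180, 180))
  expect_equal(neg_log_likelihood(e, u), 57 * log(360))

  half <- mixture_spec(5, 12, 0.5)
  z <- pnorm(180, 5, 12) - pnorm(-180, 5, 12)
  expect_equal(neg_log_likelihood(5, half),
               -log(0.5 * dnorm(5, 5, 12) / z + 0.5 / 360))

  spec <- random_spec(3, seed = 77)
  e <- rmixture(100, spec, seed = 78)
  loop <- 0
  for (i in seq_along(e)) loop <- loop - log(dmixture(e[i], spec))
  expect_equal(neg_log_likelihood(e, spec), loop, tolerance = 1e-10)

  expect_error(neg_log_likelihood(numeric(0), u),
               class = "memmixr_domain_error")
  g_only <- mixture_spec(0, 1, 1)
  expect_warning(v <- neg_log_likelihood(150, g_only, "plain"),
                 "zero density")
  expect_true(is.finite(v))
})

test_that("BIC uses k ln N - 2 ln L with the stated parameter count", {
  e <- rmixture(20, mixture_spec(0, 15, 0.8), seed = 5)
  # the 20-trial fixture is deliberately below the recommended N, which warns
  f <- suppressWarnings(
    fit_mixture(e, fit_options(n_components = 1, n_starts = 4, seed = 2)))
  expect_equal(f$n_free_params, 3)  # mu, sigma, weight; uniform derived
  # independent arithmetic on the 20-trial fixture
  expect_equal(BIC(f), 3 * log(20) - 2 * f$log_likelihood, tolerance = 1e-9)
  expect_equal(f$bic, BIC(f), tolerance = 1e-9)

  f2 <- suppressWarnings(fit_mixture(e, fit_options(n_components = 2,
                                                    fix_means_at_zero = TRUE,
                                                    n_starts = 4, seed = 2)))
  expect_equal(f2$n_free_params, 4)
  expect_equal(as.numeric(logLik(f2)), f2$log_likelihood)
})

test_that("maximum-likelihood fitting recovers a one-Gaussian + uniform truth", {
  truth <- mixture_spec(0, 12, 0.7)
  e <- rmixture(5000, truth, seed = 31)
  f <- fit_mixture(e, fit_options(n_components = 1, n_starts = 8, seed = 3))
  expect_true(f$converged)
  expect_equal(f$spec$components$weight, 0.7, tolerance = 0.03)
  expect_equal(f$spec$components$sigma, 12, tolerance = 1 / 12)
  expect_equal(f$spec$components$mu, 0, tolerance = 1)
  # ML dominance: NLL at truth >= NLL at optimum on the same sample
  expect_gte(neg_log_likelihood(e, truth), -f$log_likelihood - 1e-6)
})

test_that("fitted objective is at least as good as every start", {
  e <- rmixture(400, mixture_spec(c(0, 0), c(8, 30), c(0.4, 0.4)), seed = 41)
  opts <- fit_options(n_components = 2, n_starts = 6, seed = 9,
                      fix_means_at_zero = TRUE)
  f <- suppressWarnings(fit_mixture(e, opts))
  obj <- memmixr:::fit_objective(e, opts)
  for (theta0 in memmixr:::make_starts(opts)) {
    expect_lte(f$objective_value, obj(theta0) + 1e-9)
  }
})

test_that("degenerate spike data pin sigma at the bound and are flagged", {
  e <- rep(1e-9, 80)
  f <- suppressWarnings(fit_mixture(e, fit_options(n_components = 1,
                                                   n_starts = 4, seed = 1)))
  expect_true(f$boundary)
  expect_lt(f$spec$components$sigma, 1)
  expect_gt(f$spec$components$weight, 0.95)
})

test_that("fits are deterministic given seed and data", {
  e <- rmixture(500, mixture_spec(0, 20, 0.6), seed = 55)
  o <- fit_options(n_components = 1, n_starts = 5, seed = 17)
  f1 <- fit_mixture(e, o)
  f2 <- fit_mixture(e, o)
  expect_identical(fit_to_json(f1), fit_to_json(f2))
})

test_that("adding a component never worsens in-sample NLL from an embedded start", {
  e <- rmixture(1000, mixture_spec(0, 15, 0.7), seed = 66)
  f1 <- fit_mixture(e, fit_options(n_components = 1, n_starts = 5, seed = 4))
  f2 <- suppressWarnings(fit_mixture(
    e, fit_options(n_components = 2, n_starts = 5, seed = 4,
                   fix_means_at_zero = FALSE),
    extra_starts = list(f1$spec)
  ))
  expect_lte(-f2$log_likelihood, -f1$log_likelihood + 1e-6)
})

test_that("CDF least-squares fitting agrees with ML on clean data", {
  truth <- mixture_spec(0, 15, 0.65)
  # a 'perfect' sample placed at the mixture quantiles: objective near zero
  # and the generating parameters recovered
  qs <- qmixture((seq_len(400) - 0.5) / 400, truth)
  fq <- fit_cdf_least_squares(qs, fit_options(n_components = 1, n_starts = 6,
                                              seed = 2))
  expect_lt(fq$objective_value, 0.01)
  expect_equal(fq$spec$components$sigma, 15, tolerance = 0.5)
  expect_equal(fq$spec$components$weight, 0.65, tolerance = 0.02)
  # on a finite random sample the two objectives give consistent estimates
  e <- rmixture(4000, truth, seed = 71)
  oml <- fit_options(n_components = 1, n_starts = 6, seed = 2)
  fml <- fit_mixture(e, oml)
  fls <- fit_cdf_least_squares(e, oml)
  expect_equal(fls$spec$components$sigma, fml$spec$components$sigma,
               tolerance = 0.05)
  expect_equal(fls$spec$components$weight, fml$spec$components$weight,
               tolerance = 0.05)
  # log-likelihood is still reported for comparability
  expect_true(is.finite(fls$log_likelihood))
  # degenerate duplicated data flagged as in the ML route
  fdeg <- suppressWarnings(fit_cdf_least_squares(
    rep(2, 50), fit_options(n_components = 1, n_starts = 4, seed = 1)))
  expect_true(fdeg$boundary)
})

test_that("BIC comparison finds no Gaussian structure in uniform data", {
  e <- withr::with_seed(81, runif(2000, -179.999, 180))
  cmp <- suppressWarnings(compare_models(
    e, fit_options(n_starts = 5, fix_means_at_zero = TRUE, seed = 3), 1:2))
  expect_equal(cmp$winner, 1)
  w <- cmp$fits[["1"]]$spec
  intake <- if (nrow(w$components) == 0) 0 else sum(w$components$weight)
  expect_lt(intake, 0.05)
  # ordering contract
  expect_lte(cmp$fits[[as.character(cmp$winner)]]$bic,
             cmp$fits[[as.character(cmp$runner_up)]]$bic)
  expect_equal(nrow(tidy(cmp)), 2)
  expect_equal(glance(cmp)$winner, 1)
})

test_that("tidiers expose components and model summaries", {
  e <- rmixture(800, mixture_spec(0, 10, 0.8), seed = 91)
  f <- fit_mixture(e, fit_options(n_components = 1, n_starts = 4, seed = 1))
  td <- tidy(f)
  expect_named(td, c("component", "mu", "sigma", "precision", "weight"))
  expect_equal(td$component[nrow(td)], "uniform")
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(f)
  expect_equal(gl$n_obs, 800)
  expect_equal(gl$n_components, 1)
})
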