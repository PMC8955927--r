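# shared fixtures: all synthetic, built in code at test time

# a random valid mixture spec with n components (weights Dirichlet-uniform,
# SDs log-uniform, means within +-30 degrees)
random_spec <- function(n, seed) {
  withr::with_seed(seed, {
    w <- rgamma(n + 1, 1)
    w <- w / sum(w)
    mixture_spec(mu = runif(n, -30, 30),
                 sigma = exp(runif(n, log(2), log(60))),
                 weight = w[seq_len(n)],
                 uniform_weight = w[n + 1])
  })
}

# independent sequential-stage sampling oracle: draws each stage's Gaussian
# noise separately, sums, wraps; route chosen by weight. Mirrors the block
# diagrams directly rather than the reduced mixture.
oracle_sample_c <- function(p, t, n) {
  route <- sample(c("sm", "attention", "guess"), n, replace = TRUE,
                  prob = c(p$omega1 * p$omega2, p$omega1 * (1 - p$omega2),
                           1 - p$omega1))
  e <- numeric(n)
  i <- route == "sm"
  e[i] <- rnorm(sum(i), p$mu_sm, decay_sd(p$sm_decay, t)) +
    rnorm(sum(i), p$mu_stm, p$sigma_stm)
  i <- route == "attention"
  e[i] <- rnorm(sum(i), p$mu_attention, p$sigma_attention) +
    rnorm(sum(i), p$mu_stm, p$sigma_stm)
  i <- route == "guess"
  e[i] <- runif(sum(i), -180, 180)
  wrap_error(e)
}

oracle_sample_d <- function(p, t, n) {
  route <- sample(c("r1", "r2", "guess"), n, replace = TRUE,
                  prob = c(p$omega1, p$omega2, 1 - p$omega1 - p$omega2))
  e <- numeric(n)
  i <- route == "r1"
  e[i] <- rnorm(sum(i), p$mu_sm1, decay_sd(p$sm_decay1, t)) +
    rnorm(sum(i), p$mu_stm1, p$sigma_stm1)
  i <- route == "r2"
  e[i] <- rnorm(sum(i), p$mu_sm2, decay_sd(p$sm_decay2, t)) +
    rnorm(sum(i), p$mu_stm2, p$sigma_stm2)
  i <- route == "guess"
  e[i] <- runif(sum(i), -180, 180)
  wrap_error(e)
}

# parallel-routes scenario with both routes decaying appreciably; the wider
# selective route needs larger cells to fit, hence the 800-trial default in
# the demonstrations
model_d_demo_params <- function() {
  model_d_params(omega1 = 0.45, omega2 = 0.35,
                 sm_decay1 = decay_law(6, 18, 400), sigma_stm1 = 4,
                 sm_decay2 = decay_law(12, 32, 400), sigma_stm2 = 6)
}

# bounded-SD options used for per-cell trend fitting (SDs above 60 degrees
# are not distinguishable from guessing on this domain)
trend_fit_options <- function(seed = 5, n_starts = 10) {
  fit_options(n_components = 2, n_starts = n_starts,
              fix_means_at_zero = TRUE, seed = seed,
              sigma_bounds = c(0.5, 60))
}
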