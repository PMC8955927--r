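#' Fitting options for mixture estimation
#'
#' @param n_components Number of Gaussian components, 1..5.
#' @param objective `"max_likelihood"` (default) or `"cdf_least_squares"`
#'   (minimises the squared distance between the empirical CDF at the sorted
#'   errors and the mixture CDF; the log-likelihood is still reported at the
#'   optimum for comparability).
#' @param clip_mode Passed to [dmixture()]; the default truncated-renormalized
#'   mode gives a valid unit-mass likelihood on the support, which BIC
#'   comparison requires.
#' @param fix_means_at_zero If `TRUE`, all component means are pinned at 0
#'   (2 free parameters per component instead of 3).
#' @param n_starts Number of stratified random multi-start initialisations
#'   (mixture likelihoods are multimodal). Default 20.
#' @param seed Integer seed governing the starts; fits are deterministic
#'   given seed + data.
#' @param sigma_bounds Lower/upper SD bounds in degrees. The 0.5 degree floor
#'   prevents spike components on repeated values.
#' @param max_iterations Maximum objective evaluations per start for the
#'   Nelder-Mead simplex; default `400 * n_parameters`.
#' @param convergence_tolerance Relative convergence tolerance.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(n_components = 2,
                        objective = c("max_likelihood", "cdf_least_squares"),
                        clip_mode = "truncated_renormalized",
                        fix_means_at_zero = FALSE,
                        n_starts = 20, seed = 1L,
                        sigma_bounds = c(0.5, 180),
                        max_iterations = NULL,
                        convergence_tolerance = 1e-8) {
  objective <- match.arg(objective)
  clip_mode <- check_clip_mode(clip_mode)
  if (n_components < 1 || n_components > 5) {
    abort("`n_components` must be 1..5.", class = "memmixr_domain_error")
  }
  if (n_starts < 1) abort("`n_starts` must be >= 1.", class = "memmixr_domain_error")
  if (length(sigma_bounds) != 2 || sigma_bounds[1] < 0.5 - 1e-12 ||
      sigma_bounds[2] > 180 || sigma_bounds[1] >= sigma_bounds[2]) {
    abort("`sigma_bounds` must be ordered within [0.5, 180].",
          class = "memmixr_domain_error")
  }
  structure(list(n_components = as.integer(n_components), objective = objective,
                 clip_mode = clip_mode,
                 fix_means_at_zero = isTRUE(fix_means_at_zero),
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 sigma_bounds = as.numeric(sigma_bounds),
                 max_iterations = max_iterations,
                 convergence_tolerance = convergence_tolerance),
            class = "fit_options")
}

#' Negative log-likelihood of errors under a mixture
#'
#' @param errors Numeric vector of error angles in `(-180, 180]`; nonempty.
#' @param spec A [mixture_spec()].
#' @param clip_mode Passed to [dmixture()].
#' @return `-sum(log(pdf))` in nats. With a positive uniform weight every
#'   trial has positive density and the value is finite; in `"plain"` mode
#'   densities are floored at `1e-300` before the log so a zero-density
#'   outlier yields a large finite value and a warning rather than `NaN`.
#' @export
neg_log_likelihood <- function(errors, spec, clip_mode = "truncated_renormalized") {
  if (length(errors) == 0) {
    abort("`errors` must be nonempty.", class = "memmixr_domain_error")
  }
  d <- dmixture(errors, spec, clip_mode)
  if (any(d <= 0)) {
    warn("zero density encountered (uniform_weight = 0 with outlying errors); flooring.")
    d <- pmax(d, 1e-300)
  }
  -sum(log(d))
}

# ---- internal: fast objective on raw parameter vectors -----------------------

# density without tibble/validation overhead, for the optimizer inner loop
mix_nll_raw <- function(errors, mu, sigma, w, uw, truncated) {
  dens <- rep(uw / 360, length(errors))
  for (i in seq_along(mu)) {
    d <- dnorm(errors, mu[i], sigma[i])
    if (truncated) {
      d <- d / (pnorm(180, mu[i], sigma[i]) - pnorm(-180, mu[i], sigma[i]))
    }
    dens <- dens + w[i] * d
  }
  -sum(log(pmax(dens, 1e-300)))
}

mix_cdf_raw <- function(q, mu, sigma, w, uw, truncated) {
  p <- uw * (q + 180) / 360
  for (i in seq_along(mu)) {
    pi_ <- pnorm(q, mu[i], sigma[i])
    if (truncated) {
      lo <- pnorm(-180, mu[i], sigma[i])
      pi_ <- (pi_ - lo) / (pnorm(180, mu[i], sigma[i]) - lo)
    }
    p <- p + w[i] * pi_
  }
  p
}

# theta layout: [mu_1..n if free] [logit-sigma_1..n] [weight-logits z_1..n]
# sigma = lo + (hi - lo) * plogis(s); weights softmax against uniform logit 0.
theta_unpack <- function(theta, n, fix_means, sigma_bounds) {
  i <- 0L
  if (fix_means) mu <- rep(0, n) else { mu <- theta[seq_len(n)]; i <- n }
  s <- theta[i + seq_len(n)]
  z <- theta[i + n + seq_len(n)]
  sigma <- sigma_bounds[1] + diff(sigma_bounds) * plogis(s)
  m <- max(c(z, 0))
  ez <- exp(z - m); e0 <- exp(-m)
  tot <- e0 + sum(ez)
  list(mu = mu, sigma = sigma, w = ez / tot, uw = e0 / tot)
}

theta_pack <- function(mu, sigma, w, uw, fix_means, sigma_bounds) {
  s <- qlogis(pmin(pmax((sigma - sigma_bounds[1]) / diff(sigma_bounds),
                        1e-8), 1 - 1e-8))
  z <- log(pmax(w, 1e-12) / max(uw, 1e-12))
  if (fix_means) c(s, z) else c(mu, s, z)
}

fit_objective <- function(errors, opts) {
  n <- opts$n_components
  fix <- opts$fix_means_at_zero
  sb <- opts$sigma_bounds
  truncated <- opts$clip_mode == "truncated_renormalized"
  if (opts$objective == "max_likelihood") {
    function(theta) {
      p <- theta_unpack(theta, n, fix, sb)
      mix_nll_raw(errors, p$mu, p$sigma, p$w, p$uw, truncated)
    }
  } else {
    xs <- sort(errors)
    emp <- seq_along(xs) / length(xs)
    function(theta) {
      p <- theta_unpack(theta, n, fix, sb)
      sum((emp - mix_cdf_raw(xs, p$mu, p$sigma, p$w, p$uw, truncated))^2)
    }
  }
}

# stratified random starts: SDs log-uniform in [2, 90] (clipped to bounds),
# weights Dirichlet-uniform over the n + 1 simplex, means N(0, 10) when free
make_starts <- function(opts) {
  n <- opts$n_components
  lo <- max(2, opts$sigma_bounds[1] + 0.01)
  hi <- min(90, opts$sigma_bounds[2] - 0.01)
  withr::with_seed(opts$seed, {
    lapply(seq_len(opts$n_starts), function(k) {
      sigma <- sort(exp(runif(n, log(lo), log(hi))))
      g <- rgamma(n + 1, shape = 1)
      w <- g / sum(g)
      mu <- rnorm(n, 0, 10)
      theta_pack(mu, sigma, w[seq_len(n)], w[n + 1],
                 opts$fix_means_at_zero, opts$sigma_bounds)
    })
  })
}

#' Fit an n-Gaussian + uniform mixture to report errors
#'
#' Maximum-likelihood (or CDF least-squares) estimation by multi-start
#' Nelder-Mead simplex search in an unconstrained parameterisation:
#' component SDs are mapped through a logistic transform onto
#' `sigma_bounds`, the `n + 1` mixture weights (including the uniform) live
#' on the simplex via a softmax with the uniform's logit fixed at 0, and
#' means are free (or pinned at 0). The best of `n_starts` seeded
#' initialisations is retained, so results are deterministic given the seed.
#'
#' @param errors Numeric vector of error angles in `(-180, 180]`.
#' @param opts A [fit_options()].
#' @param extra_starts Optional list of [mixture_spec()]s used as additional
#'   warm starts (e.g. a smaller fit embedded with a near-zero-weight extra
#'   component, which guarantees the larger model cannot fit worse in
#'   sample).
#' @return An object of class `mixture_fit`: the fitted [mixture_spec()]
#'   (components sorted by SD), `log_likelihood` (nats), `n_obs`,
#'   `n_free_params`, `bic`, `converged`, `boundary` (any SD pinned at a
#'   bound — e.g. degenerate spike data), `n_starts_used`,
#'   `best_start_index`, and the options used.
#' @examples
#' spec <- mixture_spec(0, 12, 0.7)
#' e <- rmixture(1000, spec, seed = 42)
#' fit <- fit_mixture(e, fit_options(n_components = 1, n_starts = 5, seed = 1))
#' glance(fit)
#' @export
fit_mixture <- function(errors, opts = fit_options(), extra_starts = NULL) {
  stopifnot(inherits(opts, "fit_options"))
  if (length(errors) == 0) {
    abort("`errors` must be nonempty.", class = "memmixr_domain_error")
  }
  if (any(!is.finite(errors)) || any(errors <= -180 | errors > 180)) {
    abort("`errors` must lie in (-180, 180].", class = "memmixr_domain_error")
  }
  n <- opts$n_components
  k <- (if (opts$fix_means_at_zero) 2L else 3L) * n
  if (length(errors) < 10 * k) {
    warn(sprintf("only %d trials for %d free parameters; fit may be unstable.",
                 length(errors), k))
  }
  obj <- fit_objective(errors, opts)
  starts <- make_starts(opts)
  if (!is.null(extra_starts)) {
    starts <- c(starts, lapply(extra_starts, function(sp) {
      cmp <- sp$components
      pad <- n - nrow(cmp)  # pad with tiny-weight mid-scale components
      mu <- c(cmp$mu, rep(0, pad))
      sigma <- pmin(pmax(c(cmp$sigma, rep(30, pad)),
                         opts$sigma_bounds[1] + 1e-6),
                    opts$sigma_bounds[2] - 1e-6)
      w <- c(cmp$weight, rep(1e-8, pad))
      theta_pack(mu, sigma, w / (sum(w) + sp$uniform_weight),
                 sp$uniform_weight / (sum(w) + sp$uniform_weight),
                 opts$fix_means_at_zero, opts$sigma_bounds)
    }))
  }
  maxit <- opts$max_iterations %||% (400L * length(starts[[1]]))
  best <- NULL
  best_val <- Inf
  best_idx <- NA_integer_
  any_conv <- FALSE
  for (i in seq_along(starts)) {
    res <- optim(starts[[i]], obj, method = "Nelder-Mead",
                 control = list(maxit = maxit,
                                reltol = opts$convergence_tolerance))
    if (res$convergence == 0) any_conv <- TRUE
    if (res$value < best_val) {
      best_val <- res$value
      best <- res
      best_idx <- i
    }
  }
  p <- theta_unpack(best$par, n, opts$fix_means_at_zero, opts$sigma_bounds)
  spec <- mixture_spec(p$mu, p$sigma, p$w, p$uw)
  ll <- -neg_log_likelihood(errors, spec, opts$clip_mode)
  N <- length(errors)
  # degenerate when an SD is pinned at a bound or the data are a point mass
  boundary <- any(p$sigma - opts$sigma_bounds[1] < 0.05) ||
    any(opts$sigma_bounds[2] - p$sigma < 0.05) ||
    length(unique(errors)) == 1L
  structure(list(
    spec = spec,
    log_likelihood = ll,
    n_obs = N,
    n_free_params = k,
    bic = k * log(N) - 2 * ll,
    converged = best$convergence == 0 && any_conv,
    boundary = boundary,
    objective = opts$objective,
    objective_value = best_val,
    n_starts_used = length(starts),
    best_start_index = best_idx,
    options = opts,
    errors = errors
  ), class = "mixture_fit")
}

#' Fit by least squares on the cumulative distribution
#'
#' Convenience wrapper around [fit_mixture()] with
#' `objective = "cdf_least_squares"`: minimises the summed squared
#' difference between the empirical CDF at the sorted errors and the mixture
#' CDF, with the same constraints and component ordering as the ML fit.
#'
#' @inheritParams fit_mixture
#' @return A `mixture_fit` (its `bic` and `log_likelihood` are evaluated at
#'   the least-squares optimum).
#' @export
fit_cdf_least_squares <- function(errors, opts = fit_options()) {
  opts$objective <- "cdf_least_squares"
  fit_mixture(errors, opts)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-Gaussian + uniform mixture fit (%s, %s)\n",
              n_components(x$spec), x$objective,
              if (x$converged) "converged" else "NOT converged"))
  print(x$spec)
  cat(sprintf("logLik %.3f | BIC %.3f | N = %d | k = %d\n",
              x$log_likelihood, x$bic, x$n_obs, x$n_free_params))
  if (x$boundary) cat("note: an SD is pinned at a bound (degenerate fit)\n")
  invisible(x)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_free_params,
            nobs = object$n_obs, class = "logLik")
}

#' Bayesian information criterion of a mixture fit
#'
#' `BIC = k ln N - 2 ln L`, where `k` counts 3 free parameters per Gaussian
#' (mean, SD, weight; the uniform weight is derived) or 2 when means are
#' fixed at zero. Smaller is better.
#'
#' @param object A `mixture_fit`.
#' @param ... Unused.
#' @export
BIC.mixture_fit <- function(object, ...) {
  if (object$n_obs == 0) abort("N = 0.", class = "memmixr_domain_error")
  object$n_free_params * log(object$n_obs) - 2 * object$log_likelihood
}

#' @rdname tidy_memmixr
#' @export
tidy.mixture_fit <- function(x, ...) {
  cmp <- x$spec$components
  dplyr::bind_rows(
    tibble::tibble(component = cmp$label, mu = cmp$mu, sigma = cmp$sigma,
                   precision = 1 / cmp$sigma, weight = cmp$weight),
    tibble::tibble(component = "uniform", mu = NA_real_, sigma = NA_real_,
                   precision = NA_real_, weight = x$spec$uniform_weight)
  )
}

#' Tidiers for mixture fits and model comparisons
#'
#' `tidy()` returns one row per mixture component (plus the uniform guessing
#' component); `glance()` returns a one-row model summary.
#'
#' @param x A `mixture_fit` or `model_comparison`.
#' @param ... Unused.
#' @name tidy_memmixr
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    n_components = n_components(x$spec),
    log_likelihood = x$log_likelihood,
    bic = x$bic,
    n_obs = x$n_obs,
    n_free_params = x$n_free_params,
    converged = x$converged,
    boundary = x$boundary
  )
}

#' Serialise a fit to JSON
#'
#' Deterministic given the fit (no timestamps or environment state), so two
#' fits from identical seeds and data serialise byte-identically.
#'
#' @param fit A `mixture_fit`.
#' @return A JSON string.
#' @export
fit_to_json <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  jsonlite::toJSON(
    list(
      spec = list(components = fit$spec$components[, c("mu", "sigma", "weight")],
                  uniform_weight = fit$spec$uniform_weight,
                  support = fit$spec$support),
      log_likelihood = fit$log_likelihood,
      bic = fit$bic,
      n_obs = fit$n_obs,
      n_free_params = fit$n_free_params,
      converged = fit$converged,
      boundary = fit$boundary,
      objective = fit$objective,
      n_starts_used = fit$n_starts_used,
      best_start_index = fit$best_start_index
    ),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
}

#' Compare mixtures with 1..5 components by BIC
#'
#' Fits each candidate number of Gaussian components with a shared seed
#' policy (`seed + n` per candidate) and ranks by BIC. Ties are broken
#' toward the smaller number of components (parsimony). Candidates whose fit
#' fails are excluded with a warning.
#'
#' @inheritParams fit_mixture
#' @param n_list Integer vector of candidate component counts (subset of
#'   1..5).
#' @return An object of class `model_comparison`: `fits` (named list of
#'   `mixture_fit`s), `table` (tibble of n, BIC, delta-BIC), `winner` and
#'   `runner_up` component counts.
#' @export
compare_models <- function(errors, opts = fit_options(), n_list = 1:5) {
  stopifnot(inherits(opts, "fit_options"))
  n_list <- sort(unique(as.integer(n_list)))
  if (any(n_list < 1 | n_list > 5)) {
    abort("`n_list` must be within 1..5.", class = "memmixr_domain_error")
  }
  fits <- list()
  for (n in n_list) {
    o <- opts
    o$n_components <- n
    o$seed <- opts$seed + n
    f <- tryCatch(suppressWarnings(fit_mixture(errors, o)),
                  error = function(e) {
                    warn(sprintf("fit with n = %d failed: %s", n,
                                 conditionMessage(e)))
                    NULL
                  })
    if (!is.null(f)) fits[[as.character(n)]] <- f
  }
  if (length(fits) == 0) {
    abort("all candidate fits failed.", class = "memmixr_fit_error")
  }
  tab <- dplyr::bind_rows(lapply(fits, glance)) |>
    dplyr::mutate(delta_bic = .data$bic - min(.data$bic)) |>
    dplyr::arrange(.data$n_components)
  ord <- order(tab$bic, tab$n_components)  # parsimony on ties
  winner <- tab$n_components[ord[1]]
  runner_up <- if (length(ord) > 1) tab$n_components[ord[2]] else NA_integer_
  structure(list(fits = fits, table = tab, winner = winner,
                 runner_up = runner_up),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("BIC model comparison: winner n = %d, runner-up n = %s\n",
              x$winner, ifelse(is.na(x$runner_up), "-", x$runner_up)))
  print(x$table)
  invisible(x)
}

#' @rdname tidy_memmixr
#' @export
tidy.model_comparison <- function(x, ...) x$table

#' @rdname tidy_memmixr
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(winner = x$winner, runner_up = x$runner_up,
                 delta_bic_runner_up =
                   if (is.na(x$runner_up)) NA_real_ else
                     x$table$delta_bic[x$table$n_components == x$runner_up])
}
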