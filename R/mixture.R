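#' Construct an n-Gaussian + uniform mixture on the error domain
#'
#' A `mixture_spec` describes the distribution of signed report errors as a
#' mixture of up to five Gaussian components plus a uniform "guessing"
#' component on the fixed support `(-180, 180]` degrees. Components are
#' canonicalised: zero-weight components are dropped, exact duplicates
#' (identical mean and SD) are merged, and components are sorted by SD
#' ascending so that the most precise component is always first (this resolves
#' mixture label switching; the smallest-SD component is conventionally
#' called Sigma1).
#'
#' @param mu Numeric vector of component means (accuracy), degrees.
#' @param sigma Numeric vector of component SDs, degrees; `1/sigma` is the
#'   precision. All must be positive.
#' @param weight Numeric vector of component weights in `[0, 1]`.
#' @param uniform_weight Weight of the uniform guessing component; defaults to
#'   `1 - sum(weight)`. Weights must sum to 1 within `1e-9`.
#' @param label Optional character vector naming each component (e.g. the
#'   generative route it reduces from). Defaults to `g1..gn` after sorting.
#' @return An object of class `mixture_spec`: a list with a `components`
#'   tibble (`label`, `mu`, `sigma`, `weight`), `uniform_weight`, and the
#'   fixed `support`.
#' @examples
#' mixture_spec(mu = c(0, 0), sigma = c(8, 30), weight = c(0.4, 0.4))
#' @export
mixture_spec <- function(mu, sigma, weight, uniform_weight = NULL,
                         label = NULL) {
  mu <- as.numeric(mu); sigma <- as.numeric(sigma); weight <- as.numeric(weight)
  n <- length(mu)
  if (length(sigma) != n || length(weight) != n) {
    abort("`mu`, `sigma`, `weight` must have equal length.",
          class = "memmixr_domain_error")
  }
  if (is.null(uniform_weight)) uniform_weight <- 1 - sum(weight)
  if (anyNA(c(mu, sigma, weight, uniform_weight))) {
    abort("mixture parameters must be non-missing.", class = "memmixr_domain_error")
  }
  # drop numerically-zero components before validating counts
  keep <- weight > 1e-12
  mu <- mu[keep]; sigma <- sigma[keep]; weight <- weight[keep]
  if (!is.null(label)) label <- label[keep]
  n <- length(mu)
  if (n > 0 && any(sigma <= 0)) {
    abort("all component sigmas must be > 0.", class = "memmixr_domain_error")
  }
  if (any(weight < 0) || uniform_weight < -1e-9) {
    abort("weights must be nonnegative.", class = "memmixr_domain_error")
  }
  uniform_weight <- max(uniform_weight, 0)
  if (abs(sum(weight) + uniform_weight - 1) > 1e-9) {
    abort("component weights + uniform_weight must sum to 1.",
          class = "memmixr_domain_error")
  }
  # merge exact duplicates (identical mean and SD)
  if (n > 1) {
    key <- paste(signif(mu, 15), signif(sigma, 15))
    if (anyDuplicated(key)) {
      agg <- tapply(weight, key, sum)
      first <- !duplicated(key)
      w_new <- as.numeric(agg[key[first]])
      mu <- mu[first]; sigma <- sigma[first]; weight <- w_new
      if (!is.null(label)) label <- label[first]
      n <- length(mu)
    }
  }
  if (n > 5) {
    abort("at most 5 Gaussian components are supported.",
          class = "memmixr_domain_error")
  }
  ord <- order(sigma)
  mu <- mu[ord]; sigma <- sigma[ord]; weight <- weight[ord]
  label <- if (is.null(label)) paste0("g", seq_len(n)) else as.character(label[ord])
  structure(
    list(
      components = tibble::tibble(label = label, mu = mu, sigma = sigma,
                                  weight = weight),
      uniform_weight = uniform_weight,
      support = c(-180, 180)
    ),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("n-Gaussian + uniform mixture on (-180, 180] degrees\n")
  print(x$components)
  cat(sprintf("uniform (guess) weight: %.4f\n", x$uniform_weight))
  invisible(x)
}

n_components <- function(spec) nrow(spec$components)

check_clip_mode <- function(clip_mode) {
  match.arg(clip_mode, c("truncated_renormalized", "plain"))
}

#' Mixture density of report errors
#'
#' Density (per degree) of a [mixture_spec()] at given error angles. Under
#' `clip_mode = "truncated_renormalized"` (the default) each Gaussian is
#' divided by its mass on `[-180, 180]`, so the mixture integrates to exactly
#' 1 on the support and is a valid likelihood; `"plain"` uses unnormalised
#' Gaussian tails, matching the common approximation in which clipping at the
#' ends of the error range is ignored.
#'
#' @param x Numeric vector of error angles in `(-180, 180]`.
#' @param spec A [mixture_spec()].
#' @param clip_mode `"truncated_renormalized"` or `"plain"`.
#' @return Numeric vector of densities (per degree).
#' @export
dmixture <- function(x, spec, clip_mode = "truncated_renormalized") {
  clip_mode <- check_clip_mode(clip_mode)
  stopifnot(inherits(spec, "mixture_spec"))
  if (any(!is.finite(x)) || any(x <= -180 | x > 180)) {
    abort("`x` must lie in (-180, 180].", class = "memmixr_domain_error")
  }
  cmp <- spec$components
  dens <- rep(spec$uniform_weight / 360, length(x))
  for (i in seq_len(nrow(cmp))) {
    d <- dnorm(x, cmp$mu[i], cmp$sigma[i])
    if (clip_mode == "truncated_renormalized") {
      z <- pnorm(180, cmp$mu[i], cmp$sigma[i]) - pnorm(-180, cmp$mu[i], cmp$sigma[i])
      d <- d / z
    }
    dens <- dens + cmp$weight[i] * d
  }
  dens
}

#' Mixture cumulative distribution of report errors
#'
#' @inheritParams dmixture
#' @param q Numeric vector of error angles in `(-180, 180]` (values at the
#'   support ends are permitted).
#' @return Numeric vector of probabilities. Under the truncated-renormalized
#'   mode `pmixture(-180) == 0` and `pmixture(180) == 1`.
#' @export
pmixture <- function(q, spec, clip_mode = "truncated_renormalized") {
  clip_mode <- check_clip_mode(clip_mode)
  stopifnot(inherits(spec, "mixture_spec"))
  if (any(!is.finite(q)) || any(q < -180 | q > 180)) {
    abort("`q` must lie in [-180, 180].", class = "memmixr_domain_error")
  }
  cmp <- spec$components
  p <- spec$uniform_weight * (q + 180) / 360
  for (i in seq_len(nrow(cmp))) {
    pi_ <- pnorm(q, cmp$mu[i], cmp$sigma[i])
    if (clip_mode == "truncated_renormalized") {
      lo <- pnorm(-180, cmp$mu[i], cmp$sigma[i])
      z <- pnorm(180, cmp$mu[i], cmp$sigma[i]) - lo
      pi_ <- (pi_ - lo) / z
    }
    p <- p + cmp$weight[i] * pi_
  }
  p
}

#' Mixture quantile function
#'
#' Inverse of [pmixture()] under the truncated-renormalized mode, computed by
#' monotone root finding.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param spec A [mixture_spec()].
#' @return Numeric vector of error angles in `[-180, 180]`.
#' @export
qmixture <- function(p, spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].", class = "memmixr_domain_error")
  }
  vapply(p, function(pi_) {
    if (pi_ <= 0) return(-180)
    if (pi_ >= 1) return(180)
    stats::uniroot(function(q) pmixture(q, spec) - pi_,
                   lower = -180, upper = 180, tol = 1e-10)$root
  }, numeric(1))
}

#' Sample report errors from a mixture
#'
#' Draws from the truncated-renormalized mixture density: a component is
#' chosen by weight, Gaussian components are sampled by inverse-CDF
#' truncation to the support, and the uniform component is sampled on
#' `(-180, 180]`.
#'
#' @param n Number of draws.
#' @param spec A [mixture_spec()].
#' @param seed Optional integer seed (the draw is made in a local RNG scope).
#' @return Numeric vector of `n` error angles in `(-180, 180]`.
#' @export
rmixture <- function(n, spec, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  draw <- function() {
    cmp <- spec$components
    w <- c(cmp$weight, spec$uniform_weight)
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    out <- numeric(n)
    for (i in seq_len(nrow(cmp))) {
      sel <- idx == i
      if (!any(sel)) next
      lo <- pnorm(-180, cmp$mu[i], cmp$sigma[i])
      hi <- pnorm(180, cmp$mu[i], cmp$sigma[i])
      out[sel] <- qnorm(runif(sum(sel), lo, hi), cmp$mu[i], cmp$sigma[i])
    }
    sel <- idx == nrow(cmp) + 1
    if (any(sel)) out[sel] <- runif(sum(sel), -180, 180)
    wrap_error(out)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Serialise a mixture to JSON
#'
#' @param spec A [mixture_spec()].
#' @return A JSON string with keys `components` (array of
#'   `{mu, sigma, weight}`), `uniform_weight` and `support`.
#' @export
mixture_to_json <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  jsonlite::toJSON(
    list(
      components = spec$components[, c("mu", "sigma", "weight")],
      uniform_weight = spec$uniform_weight,
      support = spec$support
    ),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
}

#' Deserialise a mixture from JSON
#'
#' @param json A JSON string produced by [mixture_to_json()].
#' @return A [mixture_spec()].
#' @export
mixture_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cmp <- obj$components
  if (is.null(cmp) || length(cmp) == 0) {
    mixture_spec(numeric(0), numeric(0), numeric(0),
                 uniform_weight = obj$uniform_weight)
  } else {
    mixture_spec(cmp$mu, cmp$sigma, cmp$weight,
                 uniform_weight = obj$uniform_weight)
  }
}
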