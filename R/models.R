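#' Sensory-memory decay law
#'
#' The sensory-memory (SM) stage holds a high-capacity but rapidly decaying
#' trace: its report-error SD grows with the cue delay over durations up to a
#' second or so while the other stages (attention, STM) are time-stable. The
#' decay law gives `sigma_SM(t)` as a nondecreasing function of cue delay
#' equal to `sigma0` at `t = 0`. The default saturating-exponential form is
#' `sigma(t) = sigma_inf - (sigma_inf - sigma0) * exp(-t / tau)`.
#'
#' @param sigma0 SD at zero delay, degrees (> 0).
#' @param sigma_inf Asymptotic SD, degrees (>= `sigma0`). Ignored for
#'   `form = "constant"`.
#' @param tau Time constant, milliseconds (> 0).
#' @param form One of `"exponential_approach"` (default),
#'   `"linear_saturating"` (linear rise reaching `sigma_inf` at `t = tau`),
#'   or `"constant"`.
#' @return An object of class `decay_law`.
#' @export
decay_law <- function(sigma0, sigma_inf = sigma0, tau = 400,
                      form = c("exponential_approach", "linear_saturating",
                               "constant")) {
  form <- match.arg(form)
  if (sigma0 <= 0 || tau <= 0 || sigma_inf < sigma0) {
    abort("need sigma0 > 0, tau > 0, sigma_inf >= sigma0.",
          class = "memmixr_domain_error")
  }
  structure(list(form = form, sigma0 = sigma0, sigma_inf = sigma_inf,
                 tau = tau), class = "decay_law")
}

#' Evaluate a decay law
#'
#' @param law A [decay_law()].
#' @param t Cue delay(s), milliseconds (>= 0).
#' @return SD in degrees, nondecreasing in `t`, equal to `sigma0` at `t = 0`.
#' @export
decay_sd <- function(law, t) {
  stopifnot(inherits(law, "decay_law"))
  if (any(t < 0)) abort("`t` must be >= 0.", class = "memmixr_domain_error")
  switch(law$form,
    constant = rep(law$sigma0, length(t)),
    linear_saturating =
      pmin(law$sigma0 + (law$sigma_inf - law$sigma0) * t / law$tau,
           law$sigma_inf),
    exponential_approach =
      law$sigma_inf - (law$sigma_inf - law$sigma0) * exp(-t / law$tau)
  )
}

#' Gaussian stage component
#'
#' A single Gaussian processing stage (or reduced memory route): mean `mu`
#' (accuracy), SD `sigma` (its reciprocal is the precision) and a mixture
#' `weight`.
#'
#' @param mu Mean, degrees.
#' @param sigma SD, degrees (> 0).
#' @param weight Mixture weight in `[0, 1]`.
#' @return A one-row tibble with columns `mu`, `sigma`, `weight`.
#' @export
gaussian_component <- function(mu, sigma, weight = 1) {
  if (sigma <= 0) abort("`sigma` must be > 0.", class = "memmixr_domain_error")
  if (weight < 0 || weight > 1) {
    abort("`weight` must be in [0, 1].", class = "memmixr_domain_error")
  }
  tibble::tibble(mu = mu, sigma = sigma, weight = weight)
}

#' Convolve two Gaussian stages
#'
#' The error contributed by two sequential Gaussian stages is their
#' convolution, which is again Gaussian with the means and variances summed;
#' weights multiply (the probability of routing through both stages).
#'
#' @param g1,g2 Components from [gaussian_component()] (or any one-row data
#'   frame with `mu`, `sigma`, `weight`).
#' @return A [gaussian_component()].
#' @export
convolve_gaussians <- function(g1, g2) {
  gaussian_component(
    mu = g1$mu + g2$mu,
    sigma = sqrt(g1$sigma^2 + g2$sigma^2),
    weight = g1$weight * g2$weight
  )
}

#' Block-diagram parameters: SM -> attention -> STM with guessing
#'
#' Parameters of the four-process memory model in which encoded items either
#' remain in pre-attentive sensory memory (probability `omega2`, SD decaying
#' with cue delay) or are routed through attention (time-stable SD), both
#' feeding short-term memory; with probability `1 - omega1` no stored
#' information is available and the report is a uniform guess. Its reduction
#' is a two-Gaussian + uniform mixture in which exactly one component SD
#' depends on the cue delay.
#'
#' @param omega1 Non-guess rate in `[0, 1]` (the intake).
#' @param omega2 Fraction of non-guess trials routed through SM, in `[0, 1]`.
#' @param sm_decay A [decay_law()] giving `sigma_SM(t)` (its `sigma0` is the
#'   SM SD at zero delay).
#' @param sigma_attention,sigma_stm Stage SDs, degrees (> 0).
#' @param mu_sm,mu_attention,mu_stm Stage means, degrees.
#' @return An object of class `model_c_params`.
#' @export
model_c_params <- function(omega1, omega2, sm_decay, sigma_attention,
                           sigma_stm, mu_sm = 0, mu_attention = 0,
                           mu_stm = 0) {
  stopifnot(inherits(sm_decay, "decay_law"))
  if (omega1 < 0 || omega1 > 1 || omega2 < 0 || omega2 > 1) {
    abort("omega1, omega2 must be in [0, 1].", class = "memmixr_domain_error")
  }
  if (sigma_attention <= 0 || sigma_stm <= 0) {
    abort("stage sigmas must be > 0.", class = "memmixr_domain_error")
  }
  structure(list(omega1 = omega1, omega2 = omega2, sm_decay = sm_decay,
                 sigma_attention = sigma_attention, sigma_stm = sigma_stm,
                 mu_sm = mu_sm, mu_attention = mu_attention,
                 mu_stm = mu_stm),
            class = "model_c_params")
}

#' Block-diagram parameters: parallel selective/nonselective memory routes
#'
#' Parameters of the model that splits SM and STM into two parallel routes
#' (nonselective and selective transfer) with weights `omega1` and `omega2`
#' and a uniform guess weight `1 - omega1 - omega2`. Both routes contain an
#' SM stage, so on reduction both Gaussian component SDs depend on the cue
#' delay when decay is active.
#'
#' @param omega1,omega2 Route weights with `omega1 + omega2 <= 1`.
#' @param sm_decay1,sm_decay2 [decay_law()]s for the SM stage of each route
#'   (`sm_decay2` defaults to `sm_decay1`, i.e. shared decay).
#' @param sigma_stm1,sigma_stm2 STM SDs per route, degrees (> 0).
#' @param mu_sm1,mu_stm1,mu_sm2,mu_stm2 Stage means, degrees.
#' @return An object of class `model_d_params`.
#' @export
model_d_params <- function(omega1, omega2, sm_decay1, sigma_stm1,
                           sm_decay2 = sm_decay1, sigma_stm2 = sigma_stm1,
                           mu_sm1 = 0, mu_stm1 = 0, mu_sm2 = 0,
                           mu_stm2 = 0) {
  stopifnot(inherits(sm_decay1, "decay_law"), inherits(sm_decay2, "decay_law"))
  if (omega1 < 0 || omega2 < 0 || omega1 + omega2 > 1 + 1e-12) {
    abort("need omega1, omega2 >= 0 and omega1 + omega2 <= 1.",
          class = "memmixr_domain_error")
  }
  if (sigma_stm1 <= 0 || sigma_stm2 <= 0) {
    abort("STM sigmas must be > 0.", class = "memmixr_domain_error")
  }
  structure(list(omega1 = omega1, omega2 = omega2,
                 sm_decay1 = sm_decay1, sm_decay2 = sm_decay2,
                 sigma_stm1 = sigma_stm1, sigma_stm2 = sigma_stm2,
                 mu_sm1 = mu_sm1, mu_stm1 = mu_stm1,
                 mu_sm2 = mu_sm2, mu_stm2 = mu_stm2),
            class = "model_d_params")
}

#' Reduce single-memory block diagrams to mixture form
#'
#' A single memory stage (optionally preceded by an SM stage, i.e. the
#' classic two-store SM -> STM chain) plus uniform guessing reduces to a
#' one-Gaussian + uniform mixture; with both stages present the Gaussian is
#' their convolution.
#'
#' @param memory A [gaussian_component()] for the (first) memory stage; its
#'   `weight` field is ignored in favour of `omega`.
#' @param omega Non-guess rate in `[0, 1]`.
#' @param stm Optional second-stage [gaussian_component()] to convolve with
#'   `memory`.
#' @return A [mixture_spec()] with at most one Gaussian component.
#' @export
reduce_model_ab <- function(memory, omega, stm = NULL) {
  if (omega < 0 || omega > 1) {
    abort("`omega` must be in [0, 1].", class = "memmixr_domain_error")
  }
  g <- gaussian_component(memory$mu, memory$sigma, 1)
  if (!is.null(stm)) g <- convolve_gaussians(g, gaussian_component(stm$mu, stm$sigma, 1))
  mixture_spec(mu = g$mu, sigma = g$sigma, weight = omega,
               uniform_weight = 1 - omega, label = "memory")
}

#' Reduce the SM/attention/STM block diagram at a cue delay
#'
#' At cue delay `t` the model reduces to a two-Gaussian + uniform mixture:
#' an SM-routed component `G(mu_SM + mu_STM, sqrt(sigma_SM(t)^2 +
#' sigma_STM^2))` with weight `omega1 * omega2`, an attention-routed
#' component `G(mu_Att + mu_STM, sqrt(sigma_Att^2 + sigma_STM^2))` with
#' weight `omega1 * (1 - omega2)`, and uniform weight `1 - omega1`. Only the
#' SM-routed component's SD depends on `t` — the signature that
#' distinguishes this architecture from the parallel-routes one.
#'
#' @param p A [model_c_params()].
#' @param t Cue delay, milliseconds.
#' @return A [mixture_spec()]; component labels record the route
#'   (`"sm"`, `"attention"`).
#' @export
reduce_model_c <- function(p, t = 0) {
  stopifnot(inherits(p, "model_c_params"))
  sig_sm <- decay_sd(p$sm_decay, t)
  mixture_spec(
    mu = c(p$mu_sm + p$mu_stm, p$mu_attention + p$mu_stm),
    sigma = c(sqrt(sig_sm^2 + p$sigma_stm^2),
              sqrt(p$sigma_attention^2 + p$sigma_stm^2)),
    weight = c(p$omega1 * p$omega2, p$omega1 * (1 - p$omega2)),
    uniform_weight = 1 - p$omega1,
    label = c("sm", "attention")
  )
}

#' Reduce the parallel-routes block diagram at a cue delay
#'
#' At cue delay `t` the model reduces to a two-Gaussian + uniform mixture
#' with component weights `omega1` and `omega2` and uniform weight
#' `1 - omega1 - omega2`; each route's SD is `sqrt(sigma_SMk(t)^2 +
#' sigma_STMk^2)`, so with active decay both component SDs grow with `t`.
#'
#' @param p A [model_d_params()].
#' @param t Cue delay, milliseconds.
#' @return A [mixture_spec()]; labels record the route
#'   (`"route1"`, `"route2"`).
#' @export
reduce_model_d <- function(p, t = 0) {
  stopifnot(inherits(p, "model_d_params"))
  mixture_spec(
    mu = c(p$mu_sm1 + p$mu_stm1, p$mu_sm2 + p$mu_stm2),
    sigma = c(sqrt(decay_sd(p$sm_decay1, t)^2 + p$sigma_stm1^2),
              sqrt(decay_sd(p$sm_decay2, t)^2 + p$sigma_stm2^2)),
    weight = c(p$omega1, p$omega2),
    uniform_weight = 1 - p$omega1 - p$omega2,
    label = c("route1", "route2")
  )
}
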