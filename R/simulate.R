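#' Experimental design for synthetic trial generation
#'
#' Describes a continuous-report design of the kind the analysis targets:
#' either a set-size experiment (1-4 moving disks, report cued immediately)
#' or a cue-delay experiment (set size fixed at three; cue delays 0, 100,
#' 200, 400, 800 or 1600 ms), with a single-report (SR) and/or
#' first-full-report (FR1) condition per trial.
#'
#' @param experiment `"cue_delay"` or `"set_size"`.
#' @param set_sizes Integer vector of set sizes; defaults to `1:4` for the
#'   set-size experiment and `3` for the cue-delay experiment.
#' @param cue_delays_ms Numeric vector of cue delays in ms; defaults to
#'   `c(0, 100, 200, 400, 800, 1600)` for the cue-delay experiment and `0`
#'   for the set-size experiment.
#' @param trials_per_cell Trials per subject x condition x cell. Default 300.
#' @param subjects Number of subjects. Default 5.
#' @param report_conditions Subset of `c("SR", "FR1")`.
#' @param seed Integer seed for the whole simulated table.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(experiment = c("cue_delay", "set_size"),
                              set_sizes = NULL, cue_delays_ms = NULL,
                              trials_per_cell = 300, subjects = 5,
                              report_conditions = c("SR", "FR1"),
                              seed = 1L) {
  experiment <- match.arg(experiment)
  if (is.null(set_sizes)) {
    set_sizes <- if (experiment == "set_size") 1:4 else 3L
  }
  if (is.null(cue_delays_ms)) {
    cue_delays_ms <- if (experiment == "cue_delay")
      c(0, 100, 200, 400, 800, 1600) else 0
  }
  if (trials_per_cell < 1 || subjects < 1 || any(cue_delays_ms < 0) ||
      any(set_sizes < 1)) {
    abort("invalid design: need trials_per_cell >= 1, subjects >= 1, nonnegative delays, set sizes >= 1.",
          class = "memmixr_domain_error")
  }
  report_conditions <- match.arg(report_conditions, c("SR", "FR1"),
                                 several.ok = TRUE)
  structure(list(experiment = experiment, set_sizes = as.integer(set_sizes),
                 cue_delays_ms = as.numeric(cue_delays_ms),
                 trials_per_cell = as.integer(trials_per_cell),
                 subjects = as.integer(subjects),
                 report_conditions = report_conditions,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Generative scenario: which memory architecture produces the errors
#'
#' Bundles a block-diagram model with optional set-size effects and
#' between-subject heterogeneity. `params` is a [model_c_params()] or
#' [model_d_params()] (or, for the single-store architectures `"A"`/`"B"`, a
#' plain list; see Details), either one object shared by all report
#' conditions or a named list keyed by condition (e.g. SR and FR1 with
#' different routing weights).
#'
#' @details For `model = "A"` supply `list(omega, mu, sigma)`; for
#'   `model = "B"` supply `list(omega, mu_sm, sm_decay, mu_stm, sigma_stm)`
#'   with `sm_decay` a [decay_law()].
#'
#'   Set-size effects are an explicit per-set-size map (a named list keyed by
#'   set size) rather than a parametric law, since each set size is fitted
#'   independently; each entry may give `omega1`, `omega2` overrides and a
#'   `sigma_scale` multiplier applied to every stage SD.
#'
#'   Subject heterogeneity is multiplicative log-normal jitter on all stage
#'   SDs (`subject_sd_sigma`, SD of log, default 0.1) and additive jitter on
#'   the logit of the routing weights (`subject_sd_weight`, default 0.2),
#'   enabling repeated-measures analyses across synthetic observers.
#'
#' @param model `"A"`, `"B"`, `"C"` or `"D"`.
#' @param params Model parameters (possibly per report condition).
#' @param set_size_effects Optional named list keyed by set size.
#' @param subject_sd_sigma,subject_sd_weight Heterogeneity SDs (0 disables).
#' @return An object of class `generative_scenario`.
#' @export
generative_scenario <- function(model = c("C", "D", "A", "B"), params,
                                set_size_effects = NULL,
                                subject_sd_sigma = 0.1,
                                subject_sd_weight = 0.2) {
  model <- match.arg(model)
  structure(list(model = model, params = params,
                 set_size_effects = set_size_effects,
                 subject_sd_sigma = subject_sd_sigma,
                 subject_sd_weight = subject_sd_weight),
            class = "generative_scenario")
}

# jitter helpers ---------------------------------------------------------------

scale_decay <- function(law, mult) {
  decay_law(law$sigma0 * mult, law$sigma_inf * mult, law$tau, law$form)
}

jitter_omega <- function(omega, jit) {
  if (omega <= 0 || omega >= 1) return(omega)  # degenerate weights stay put
  plogis(qlogis(omega) + jit)
}

# apply set-size overrides + subject multipliers to one parameter object
adjust_params <- function(model, p, eff, sig_mult, w_jit1, w_jit2) {
  sc <- (eff$sigma_scale %||% 1) * sig_mult
  if (model == "C") {
    model_c_params(
      omega1 = jitter_omega(eff$omega1 %||% p$omega1, w_jit1),
      omega2 = jitter_omega(eff$omega2 %||% p$omega2, w_jit2),
      sm_decay = scale_decay(p$sm_decay, sc),
      sigma_attention = p$sigma_attention * sc,
      sigma_stm = p$sigma_stm * sc,
      mu_sm = p$mu_sm, mu_attention = p$mu_attention, mu_stm = p$mu_stm
    )
  } else if (model == "D") {
    w1 <- jitter_omega(eff$omega1 %||% p$omega1, w_jit1)
    w2 <- jitter_omega(eff$omega2 %||% p$omega2, w_jit2)
    if (w1 + w2 > 1) { s <- (1 - 1e-6) / (w1 + w2); w1 <- w1 * s; w2 <- w2 * s }
    model_d_params(
      omega1 = w1, omega2 = w2,
      sm_decay1 = scale_decay(p$sm_decay1, sc), sigma_stm1 = p$sigma_stm1 * sc,
      sm_decay2 = scale_decay(p$sm_decay2, sc), sigma_stm2 = p$sigma_stm2 * sc,
      mu_sm1 = p$mu_sm1, mu_stm1 = p$mu_stm1,
      mu_sm2 = p$mu_sm2, mu_stm2 = p$mu_stm2
    )
  } else if (model == "B") {
    list(omega = jitter_omega(eff$omega1 %||% p$omega, w_jit1),
         mu_sm = p$mu_sm, sm_decay = scale_decay(p$sm_decay, sc),
         mu_stm = p$mu_stm, sigma_stm = p$sigma_stm * sc)
  } else {
    list(omega = jitter_omega(eff$omega1 %||% p$omega, w_jit1),
         mu = p$mu, sigma = p$sigma * sc)
  }
}

# reduced mixture of one adjusted cell (the generator's ground truth)
cell_mixture <- function(model, p, t) {
  switch(model,
    A = reduce_model_ab(gaussian_component(p$mu, p$sigma), p$omega),
    B = reduce_model_ab(gaussian_component(p$mu_sm, decay_sd(p$sm_decay, t)),
                        p$omega,
                        stm = gaussian_component(p$mu_stm, p$sigma_stm)),
    C = reduce_model_c(p, t),
    D = reduce_model_d(p, t)
  )
}

# sequential-stage sampling of one cell: route choice, per-stage Gaussian
# noises summed, then wrapped onto (-180, 180]
sample_cell <- function(model, p, t, n) {
  if (model == "C") {
    w <- c(sm = p$omega1 * p$omega2, attention = p$omega1 * (1 - p$omega2),
           guess = 1 - p$omega1)
  } else if (model == "D") {
    w <- c(route1 = p$omega1, route2 = p$omega2,
           guess = 1 - p$omega1 - p$omega2)
  } else {
    w <- c(memory = p$omega, guess = 1 - p$omega)
  }
  route <- sample(names(w), n, replace = TRUE, prob = w)
  err <- numeric(n)
  for (r in unique(route)) {
    sel <- route == r
    m <- sum(sel)
    err[sel] <- switch(r,
      guess = runif(m, -180, 180),
      memory = if (model == "A") rnorm(m, p$mu, p$sigma) else
        rnorm(m, p$mu_sm, decay_sd(p$sm_decay, t)) +
          rnorm(m, p$mu_stm, p$sigma_stm),
      sm = rnorm(m, p$mu_sm, decay_sd(p$sm_decay, t)) +
        rnorm(m, p$mu_stm, p$sigma_stm),
      attention = rnorm(m, p$mu_attention, p$sigma_attention) +
        rnorm(m, p$mu_stm, p$sigma_stm),
      route1 = rnorm(m, p$mu_sm1, decay_sd(p$sm_decay1, t)) +
        rnorm(m, p$mu_stm1, p$sigma_stm1),
      route2 = rnorm(m, p$mu_sm2, decay_sd(p$sm_decay2, t)) +
        rnorm(m, p$mu_stm2, p$sigma_stm2)
    )
  }
  tibble::tibble(error_deg = wrap_error(err), hidden_route = route)
}

#' Simulate per-trial report errors
#'
#' For every design cell (subject x report condition x set size x cue delay)
#' the generative route is chosen by the model's routing weights, stage
#' noises are sampled sequentially (e.g. SM at `sigma_SM(t)`, then STM),
#' summed and wrapped onto `(-180, 180]`; the guessing route samples
#' uniformly. Fully reproducible from the design seed. The chosen route is
#' retained per trial as hidden ground truth.
#'
#' @param design An [experiment_design()].
#' @param scenario A [generative_scenario()].
#' @return A tibble of trials with columns `subject_id`, `experiment`,
#'   `report_condition`, `set_size`, `cue_delay_ms`, `error_deg`,
#'   `hidden_route`. The attribute `"cell_specs"` holds a tibble of the
#'   subject-adjusted reduced [mixture_spec()] per cell (list column
#'   `spec`), the generator's ground truth for parameter-recovery checks.
#' @export
simulate_trials <- function(design, scenario) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(scenario, "generative_scenario"))
  # validate every cell reduces to a valid mixture before any sampling
  base_params <- function(cond) {
    p <- scenario$params
    if (!is.null(names(p)) && cond %in% names(p)) p[[cond]] else p
  }
  withr::with_seed(design$seed, {
    subj <- sprintf("S%d", seq_len(design$subjects))
    sig_mult <- exp(rnorm(design$subjects, 0, scenario$subject_sd_sigma))
    w_jit1 <- rnorm(design$subjects, 0, scenario$subject_sd_weight)
    w_jit2 <- rnorm(design$subjects, 0, scenario$subject_sd_weight)
    cells <- tidyr::expand_grid(
      subject_id = subj,
      report_condition = design$report_conditions,
      set_size = design$set_sizes,
      cue_delay_ms = design$cue_delays_ms
    )
    adj <- purrr::pmap(cells, function(subject_id, report_condition,
                                       set_size, cue_delay_ms) {
      i <- match(subject_id, subj)
      eff <- (scenario$set_size_effects %||% list())[[as.character(set_size)]] %||% list()
      adjust_params(scenario$model, base_params(report_condition), eff,
                    sig_mult[i], w_jit1[i], w_jit2[i])
    })
    specs <- purrr::map2(adj, cells$cue_delay_ms,
                         ~ cell_mixture(scenario$model, .x, .y))
    trials <- purrr::map2(adj, seq_len(nrow(cells)), function(p, i) {
      sample_cell(scenario$model, p, cells$cue_delay_ms[i],
                  design$trials_per_cell)
    })
    out <- cells |>
      dplyr::mutate(experiment = design$experiment, data = trials) |>
      tidyr::unnest("data") |>
      dplyr::select("subject_id", "experiment", "report_condition",
                    "set_size", "cue_delay_ms", "error_deg", "hidden_route")
    attr(out, "cell_specs") <- dplyr::mutate(cells, spec = specs)
    out
  })
}

#' Packaged default synthetic dataset
#'
#' A ready-made stand-in for the (non-deposited) behavioral data: 5 synthetic
#' subjects run through both experiments (set size 1-4 at zero delay; set
#' size 3 at delays 0-1600 ms) in the SR and FR1 conditions, generated from
#' the SM/attention/STM architecture. Parameters are chosen so the fitted
#' summaries show the qualitative signatures the analysis targets: the
#' smaller component SD (Sigma1) is flat in cue delay for both conditions,
#' the larger (Sigma2, the SM route) rises steeply with delay for SR and only
#' mildly for FR1, and intake declines with set size.
#'
#' @param seed Integer seed.
#' @param trials_per_cell Trials per subject x condition x cell.
#' @param subjects Number of synthetic subjects.
#' @return A tibble of trials (both experiments bound together), with the
#'   per-experiment `"cell_specs"` attributes merged.
#' @export
emulate_study_dataset <- function(seed = 1L, trials_per_cell = 300,
                                  subjects = 5) {
  scen <- default_model_c_scenario()
  d1 <- experiment_design("set_size", trials_per_cell = trials_per_cell,
                          subjects = subjects, seed = seed)
  d2 <- experiment_design("cue_delay", trials_per_cell = trials_per_cell,
                          subjects = subjects, seed = seed + 1L)
  t1 <- simulate_trials(d1, scen)
  t2 <- simulate_trials(d2, scen)
  out <- dplyr::bind_rows(t1, t2)
  attr(out, "cell_specs") <- dplyr::bind_rows(
    dplyr::mutate(attr(t1, "cell_specs"), experiment = "set_size"),
    dplyr::mutate(attr(t2, "cell_specs"), experiment = "cue_delay")
  )
  out
}

#' Default SM/attention/STM generative scenario
#'
#' The scenario behind [emulate_study_dataset()]: SR routes half of
#' non-guess trials through decaying SM (`sigma_SM` 13 -> 30 degrees,
#' tau = 400 ms) while FR1 — where the observer reports the best-remembered,
#' already-transferred item — routes only a quarter through SM with a milder
#' decay ceiling; attention and STM SDs are 6 and 4 degrees (time-stable);
#' intake `omega1` falls from 0.95 to 0.65 across set sizes 1-4.
#'
#' @return A [generative_scenario()].
#' @export
default_model_c_scenario <- function() {
  generative_scenario(
    model = "C",
    params = list(
      SR = model_c_params(omega1 = 0.80, omega2 = 0.50,
                          sm_decay = decay_law(13, 30, 400),
                          sigma_attention = 6, sigma_stm = 4),
      FR1 = model_c_params(omega1 = 0.85, omega2 = 0.25,
                           sm_decay = decay_law(13, 20, 400),
                           sigma_attention = 6, sigma_stm = 4)
    ),
    set_size_effects = list(
      `1` = list(omega1 = 0.95, sigma_scale = 0.8),
      `2` = list(omega1 = 0.85, sigma_scale = 0.9),
      `3` = list(),
      `4` = list(omega1 = 0.65, sigma_scale = 1.1)
    )
  )
}

#' Write a trial table to CSV
#'
#' @param trials A trial tibble from [simulate_trials()] or
#'   [emulate_study_dataset()].
#' @param path Output CSV path.
#' @param include_hidden_route Keep the generator's hidden route label
#'   (excluded by default, as an analysis would not have it).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, include_hidden_route = FALSE) {
  out <- trials
  if (!include_hidden_route) out$hidden_route <- NULL
  readr::write_csv(out, path)
  invisible(path)
}
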