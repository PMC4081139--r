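# Model registry: the CLI resolves models by name; a plugin model registers
# its constructor (a function returning a predq_model) under a unique name.
the_registry <- new.env(parent = emptyenv())

#' Register or resolve a model by name
#'
#' @param name Model name.
#' @param constructor Zero-argument function returning a `predq_model`.
#' @return `register_model` returns `name` invisibly; `resolve_model` the
#'   constructed `predq_model`.
#' @export
register_model <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = the_registry)
  invisible(name)
}

#' @rdname register_model
#' @export
resolve_model <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) {
    rlang::abort(paste0("unknown model '", name, "'; registered: ",
                        paste(ls(the_registry), collapse = ", ")),
                 class = "predq_parse_error")
  }
  get(name, envir = the_registry)()
}

.onLoad <- function(libname, pkgname) {
  register_model("autoregulation", function() autoregulation_model())
}

#' The autoregulation demonstration study
#'
#' `autoreg_calibration()` builds the package's standard demonstration of a
#' sloppy calibration: the [autoregulation_model()] started high at
#' `y(0) = 100` with input `sin(t)`, true parameters `theta = (10, 0.3)`,
#' observed at times 1..10 with 10% Gaussian noise, under a log-uniform prior
#' between `1e-2` and `1e4` for both parameters. With the slow decay rate
#' `theta2 = 0.3` the trajectory stays far above `theta1 = 10` the whole
#' time (quasi-steady level near `10/theta2`, modulated by the input), so the
#' Hill term is saturated: the data barely constrain `theta1` while pinning
#' `theta2` — the prototypical sloppy posterior. (Decay rates of 1 or more
#' would instead collapse the trajectory toward zero, since decay would then
#' dominate production at every input phase.)
#'
#' `autoreg_scenarios()` returns the three standard prediction scenarios for
#' the fitted model: `low_start` (`y(0) = 1`), `high_start` (`y(0) = 1e4`)
#' and `strong_input` (`y(0) = 1` with a 7-fold input amplitude).
#'
#' @param seed Integer seed for the simulated dataset.
#' @param noise_fraction Measurement-noise SD as a fraction of signal.
#' @param times Observation times.
#' @return `autoreg_calibration()`: a `predq_problem` with attribute
#'   `theta_true`; `autoreg_scenarios()`: a named list of `predq_scenario`s.
#' @export
#' @examples
#' prob <- autoreg_calibration(seed = 1)
#' chi_squared(prob, attr(prob, "theta_true"))
autoreg_calibration <- function(seed, noise_fraction = 0.1, times = 1:10) {
  model <- autoregulation_model(y0 = 100, input = sin)
  theta_true <- c(theta1 = 10, theta2 = 0.3)
  scenario <- prediction_scenario(horizon = max(times))
  data <- generate_dataset(model, theta_true, scenario, times = times,
                           noise_fraction = noise_fraction, seed = seed)
  prob <- inference_problem(model, data,
                            prior_spec(c(1e-2, 1e-2), c(1e4, 1e4)),
                            scenario)
  attr(prob, "theta_true") <- theta_true
  prob
}

#' @rdname autoreg_calibration
#' @param horizon,grid_size Prediction horizon and uniform-grid size.
#' @export
autoreg_scenarios <- function(horizon = 10, grid_size = 201L) {
  list(
    low_start = prediction_scenario(initial_state = 1, horizon = horizon,
                                    grid_size = grid_size),
    high_start = prediction_scenario(initial_state = 1e4, horizon = horizon,
                                     grid_size = grid_size),
    strong_input = prediction_scenario(initial_state = 1, input_scale = 7,
                                       horizon = horizon, grid_size = grid_size)
  )
}

#' Run the full demonstration analysis
#'
#' Generates the demonstration dataset, samples the posterior with DE-MCz
#' (15000 iterations, 5000 burn-in, thinning 30, 3 chains — 999 exported
#' draws), and computes the Q distribution and envelope for each of the three
#' standard prediction scenarios, with the true parameter vector as the
#' reference (as is natural for simulated data).
#'
#' @param seed Integer seed driving data generation and sampling.
#' @param sampler Optional [sampler_config()] overriding the defaults (its
#'   seed is still taken from `seed`).
#' @param alpha,b Uncertainty-quantifier settings.
#' @return A list with `problem`, `theta_true`, `sample`, `diagnostics`,
#'   `qresults` (named list of `predq_qresult`), `envelopes` (named list of
#'   `predq_envelope`), and `q_alpha` (named numeric vector).
#' @export
autoreg_demo <- function(seed, sampler = NULL, alpha = 0.95, b = 2) {
  prob <- autoreg_calibration(seed = seed)
  theta_true <- attr(prob, "theta_true")
  cfg <- sampler %||% sampler_config(seed = seed)
  cfg$seed <- as.integer(seed)
  sample <- run_demcz(prob, cfg)
  scns <- autoreg_scenarios()
  draws <- draws_matrix(sample)
  bundles <- lapply(names(scns), function(nm) {
    pd <- predict_draws(prob$model, draws, scns[[nm]])
    list(q = q_from_pd(prob$model, pd, scns[[nm]], theta_ref = theta_true,
                       b = b, alpha = alpha, reference = "theta",
                       scenario_id = nm),
         env = envelope_from_pd(prob$model, pd, scns[[nm]], alpha = alpha,
                                theta_ref = theta_true, scenario_id = nm))
  })
  qresults <- lapply(bundles, `[[`, "q")
  envelopes <- lapply(bundles, `[[`, "env")
  names(qresults) <- names(envelopes) <- names(scns)
  list(problem = prob, theta_true = theta_true, sample = sample,
       diagnostics = convergence_diagnostics(sample),
       qresults = qresults, envelopes = envelopes,
       q_alpha = vapply(qresults, attr, numeric(1), "q_alpha"))
}
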