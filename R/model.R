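#' Define a dynamical model
#'
#' A dynamical model is a parameterised ODE system
#' \deqn{\dot x(t) = f(x(t), \theta, u(t)), \quad y(t) = g(x(t), \theta),
#'       \quad x(0) = h(\theta),}
#' with state \eqn{x}, strictly positive parameters \eqn{\theta} (length `p`),
#' external input \eqn{u(t)} and positive-valued output \eqn{y} (length `m`).
#' The output positivity is required downstream by the log-ratio geometry of
#' the uncertainty quantifier Q.
#'
#' Construction runs a probe evaluation at `probe_theta` to check that the
#' dimensions of `rate`, `output_map` and `init_map` are mutually consistent
#' and that the probe output is strictly positive.
#'
#' @param name Model identifier (used by the CLI model registry).
#' @param state_dim,param_dim,output_dim Positive integers: dimensions of the
#'   state vector, parameter vector and output vector.
#' @param rate Function `(state, theta, u)` returning the state derivative
#'   (numeric vector of length `state_dim`). `u` is the scalar/vector value of
#'   the input at the current time.
#' @param output_map Function `(state, theta)` returning the output vector
#'   (length `output_dim`, strictly positive on the model's domain).
#' @param init_map Function `(theta)` returning the initial state.
#' @param input Function `(t)` returning the external input at time `t`.
#'   Defaults to the zero input.
#' @param param_names Character vector of length `param_dim`.
#' @param output_names Character vector of length `output_dim`; defaults to
#'   `y1, y2, ...` (a scalar output is named `y`).
#' @param probe_theta Parameter vector used for the construction-time probe;
#'   defaults to all ones.
#'
#' @return An object of class `predq_model`.
#' @seealso [autoregulation_model()], [simulate_model()], [prediction_scenario()]
#' @export
dynamical_model <- function(name, state_dim, param_dim, output_dim,
                            rate, output_map, init_map,
                            input = NULL, param_names = NULL,
                            output_names = NULL,
                            probe_theta = rep(1, param_dim)) {
  stopifnot(is.character(name), length(name) == 1L)
  state_dim <- as.integer(state_dim)
  param_dim <- as.integer(param_dim)
  output_dim <- as.integer(output_dim)
  if (state_dim < 1L || param_dim < 1L || output_dim < 1L) {
    rlang::abort("state_dim, param_dim and output_dim must be positive integers",
                 class = "predq_config_error")
  }
  if (is.null(input)) input <- function(t) 0
  if (is.null(param_names)) param_names <- paste0("theta", seq_len(param_dim))
  if (is.null(output_names)) {
    output_names <- if (output_dim == 1L) "y" else paste0("y", seq_len(output_dim))
  }
  stopifnot(length(param_names) == param_dim,
            length(output_names) == output_dim)

  # probe evaluation: dimensional consistency and output positivity
  x0 <- init_map(probe_theta)
  if (length(x0) != state_dim) {
    rlang::abort("init_map(probe_theta) does not have length state_dim",
                 class = "predq_config_error")
  }
  dx <- rate(x0, probe_theta, input(0))
  if (length(dx) != state_dim || !all(is.finite(dx))) {
    rlang::abort("rate(x0, probe_theta, u(0)) must return a finite vector of length state_dim",
                 class = "predq_config_error")
  }
  y0 <- output_map(x0, probe_theta)
  if (length(y0) != output_dim) {
    rlang::abort("output_map(x0, probe_theta) does not have length output_dim",
                 class = "predq_config_error")
  }
  if (!all(is.finite(y0)) || any(y0 <= 0)) {
    rlang::abort("output_map must be strictly positive at the probe point",
                 class = "predq_config_error")
  }

  structure(
    list(name = name, state_dim = state_dim, param_dim = param_dim,
         output_dim = output_dim, rate = rate, output_map = output_map,
         init_map = init_map, input = input, param_names = param_names,
         output_names = output_names),
    class = "predq_model"
  )
}

#' @export
print.predq_model <- function(x, ...) {
  cat("<predq_model> ", x$name, "\n",
      "  states: ", x$state_dim,
      "  parameters: ", x$param_dim, " (", paste(x$param_names, collapse = ", "), ")",
      "  outputs: ", x$output_dim, "\n", sep = "")
  invisible(x)
}

#' Self-regulating gene transcription model
#'
#' A minimal model of transcriptional autoregulation: protein concentration
#' \eqn{y(t)} is produced by a Hill-type positive feedback, degraded linearly,
#' and modulated multiplicatively by an external signal,
#' \deqn{\dot y = \frac{10\,y^2}{\theta_1 + y^2} - \theta_2\, y + y\,u(t),}
#' with input \eqn{u(t) = \sin(t)} by default. \eqn{\theta_1} tunes the
#' half-saturation of the positive feedback and \eqn{\theta_2} the decay rate.
#' The output is the concentration \eqn{y} itself (`m = 1`, `p = 2`).
#'
#' For \eqn{u \equiv 0} and \eqn{\theta = (10, 1)} the nonzero steady states
#' are \eqn{y = 5 \pm \sqrt{15}}; the origin is always a fixed point.
#'
#' @param y0 Default initial concentration (the calibration experiments in
#'   this package start high, at `y0 = 100`). Prediction scenarios override it.
#' @param input Input function of time; defaults to `sin`.
#' @return A `predq_model` with parameters `theta1`, `theta2`.
#' @export
#' @examples
#' m <- autoregulation_model()
#' simulate_model(m, c(10, 2), prediction_scenario(horizon = 10))
autoregulation_model <- function(y0 = 100, input = sin) {
  force(y0)
  dynamical_model(
    name = "autoregulation",
    state_dim = 1L, param_dim = 2L, output_dim = 1L,
    rate = function(x, theta, u) 10 * x^2 / (theta[1] + x^2) - theta[2] * x + x * u,
    output_map = function(x, theta) x,
    init_map = function(theta) y0,
    input = input,
    param_names = c("theta1", "theta2"),
    probe_theta = c(10, 1)
  )
}

#' Describe a prediction scenario
#'
#' A scenario is the experimental condition under which a prediction is made:
#' an optional initial-state override, an optional replacement or rescaling of
#' the input signal, optional multiplicative parameter perturbations, and the
#' evaluation horizon/grid. Scenarios are applied identically to every
#' posterior draw and to the reference parameter vector.
#'
#' @param initial_state Optional full state vector (a single number for scalar
#'   models) replacing the model's `init_map`.
#' @param input Optional replacement input function of time.
#' @param input_scale Optional scalar multiplying the model's input (e.g. `7`
#'   for a 7-fold amplitude increase). Ignored when `input` is given.
#' @param param_factors Optional named (by parameter) or full-length numeric
#'   vector of strictly positive multiplicative factors applied to the
#'   parameters before integration.
#' @param horizon Prediction horizon `T` (> 0). When `NULL`, callers default it
#'   to the last observation time of the fitted data.
#' @param grid_size Number of uniform evaluation points on `[0, T]` (>= 2).
#' @return An object of class `predq_scenario`.
#' @export
prediction_scenario <- function(initial_state = NULL, input = NULL,
                                input_scale = NULL, param_factors = NULL,
                                horizon = NULL, grid_size = 201L) {
  if (!is.null(param_factors)) {
    if (!is.numeric(param_factors) || any(param_factors <= 0)) {
      rlang::abort("param_factors must be strictly positive",
                   class = "predq_config_error")
    }
  }
  if (!is.null(horizon) && horizon <= 0) {
    rlang::abort("horizon must be strictly positive", class = "predq_config_error")
  }
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) {
    rlang::abort("grid_size must be at least 2", class = "predq_config_error")
  }
  if (!is.null(input_scale)) stopifnot(is.numeric(input_scale), length(input_scale) == 1L)
  structure(
    list(initial_state = initial_state, input = input, input_scale = input_scale,
         param_factors = param_factors, horizon = horizon, grid_size = grid_size),
    class = "predq_scenario"
  )
}

#' Fold a scenario into a model
#'
#' Returns a derived [dynamical_model()] in which the scenario's overrides are
#' materialised: parameter perturbation factors are fixed multipliers inside
#' `rate`/`output_map`/`init_map`, a replacement (or rescaled) input is
#' substituted, and an overridden initial state replaces `init_map`. The
#' original model is untouched; simulating the derived model equals simulating
#' the original under the scenario.
#'
#' @param model A `predq_model`.
#' @param scenario A `predq_scenario`.
#' @return A `predq_model`.
#' @export
apply_scenario <- function(model, scenario) {
  stopifnot(inherits(model, "predq_model"), inherits(scenario, "predq_scenario"))
  factors <- resolve_param_factors(model, scenario$param_factors)

  rate0 <- model$rate; out0 <- model$output_map; init0 <- model$init_map
  rate <- rate0; output_map <- out0; init_map <- init0
  if (!is.null(factors)) {
    rate <- function(x, theta, u) rate0(x, factors * theta, u)
    output_map <- function(x, theta) out0(x, factors * theta)
    init_map <- function(theta) init0(factors * theta)
  }
  input <- model$input
  if (!is.null(scenario$input)) {
    input <- scenario$input
  } else if (!is.null(scenario$input_scale)) {
    base_input <- model$input; s <- scenario$input_scale
    input <- function(t) s * base_input(t)
  }
  if (!is.null(scenario$initial_state)) {
    x0 <- scenario$initial_state
    if (length(x0) != model$state_dim) {
      rlang::abort("initial_state override must have length state_dim",
                   class = "predq_config_error")
    }
    init_map <- function(theta) x0
  }

  dynamical_model(
    name = model$name, state_dim = model$state_dim, param_dim = model$param_dim,
    output_dim = model$output_dim, rate = rate, output_map = output_map,
    init_map = init_map, input = input, param_names = model$param_names,
    output_names = model$output_names,
    probe_theta = rep(1, model$param_dim)
  )
}

# expand named/short factor vectors to full length; NULL when identity
resolve_param_factors <- function(model, param_factors) {
  if (is.null(param_factors)) return(NULL)
  p <- model$param_dim
  if (!is.null(names(param_factors)) && any(names(param_factors) != "")) {
    bad <- setdiff(names(param_factors), model$param_names)
    if (length(bad)) {
      rlang::abort(paste0("unknown parameter(s) in param_factors: ",
                          paste(bad, collapse = ", ")),
                   class = "predq_config_error")
    }
    full <- rep(1, p)
    full[match(names(param_factors), model$param_names)] <- param_factors
  } else if (length(param_factors) == p) {
    full <- as.numeric(param_factors)
  } else {
    rlang::abort("param_factors must be named or of length param_dim",
                 class = "predq_config_error")
  }
  if (all(full == 1)) return(NULL)
  full
}

# --- integration core -------------------------------------------------------
#
# Plain-matrix simulation path shared by the user-facing simulate_model() and
# the hot loops (chi-squared inside MCMC, per-draw prediction sets). Returns
# list(times, outputs [n_times x m], states, ok, positivity_ok, message).
sim_core <- function(model, theta, scenario = NULL, times = NULL,
                     rtol = 1e-8, atol = 1e-10) {
  if (!is.null(scenario)) model <- apply_scenario(model, scenario)
  if (is.null(times)) {
    horizon <- scenario$horizon
    if (is.null(horizon)) {
      rlang::abort("either an explicit time grid or a scenario horizon is required",
                   class = "predq_config_error")
    }
    times <- seq(0, horizon, length.out = scenario$grid_size)
  }
  if (times[1] != 0) times <- c(0, times)
  if (is.unsorted(times, strictly = TRUE)) {
    rlang::abort("time grid must be strictly increasing from 0",
                 class = "predq_config_error")
  }

  rate <- model$rate; input <- model$input
  deriv <- function(t, x, parms) list(rate(x, parms, input(t)))
  x0 <- model$init_map(theta)

  sol <- tryCatch(
    suppressWarnings(
      deSolve::lsoda(y = x0, times = times, func = deriv, parms = theta,
                     rtol = rtol, atol = atol, maxsteps = 20000)
    ),
    error = function(e) e
  )
  fail <- function(msg, t_fail) {
    list(times = times, outputs = NULL, states = NULL, ok = FALSE,
         positivity_ok = NA, message = msg, theta = theta, failure_time = t_fail)
  }
  if (inherits(sol, "error")) return(fail(conditionMessage(sol), NA_real_))
  if (nrow(sol) < length(times) || !all(is.finite(sol[, -1, drop = FALSE]))) {
    n_ok <- sum(stats::complete.cases(sol))
    t_fail <- if (n_ok >= 1) sol[n_ok, 1] else times[1]
    return(fail("integration did not reach the end of the grid with finite state",
                t_fail))
  }

  states <- sol[, -1, drop = FALSE]
  outputs <- t(apply(states, 1L, function(x) model$output_map(x, theta)))
  if (model$output_dim == 1L) outputs <- matrix(outputs, ncol = 1L)
  colnames(outputs) <- model$output_names
  if (!all(is.finite(outputs))) return(fail("non-finite model output", NA_real_))
  list(times = times, outputs = outputs, states = states, ok = TRUE,
       positivity_ok = all(outputs > 0), message = NULL,
       theta = theta, failure_time = NA_real_)
}

sim_or_abort <- function(model, theta, scenario = NULL, times = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  sim <- sim_core(model, theta, scenario, times, rtol, atol)
  if (!sim$ok) {
    rlang::abort(
      paste0("integration failure: ", sim$message,
             " (theta = ", paste(signif(theta, 6), collapse = ", "),
             if (!is.na(sim$failure_time)) paste0(", near t = ", signif(sim$failure_time, 6)),
             ")"),
      class = "predq_integration_failure", theta = theta,
      failure_time = sim$failure_time
    )
  }
  sim
}

#' Simulate a model under a scenario
#'
#' Numerically integrates the ODE system for one parameter vector under a
#' prediction scenario, using a stiffness-switching adaptive solver
#' ([deSolve::lsoda()]) with tight default tolerances (`rtol = 1e-8`,
#' `atol = 1e-10`) so that integration error is negligible relative to the
#' uncertainty measures computed downstream.
#'
#' @param model A `predq_model`.
#' @param theta Strictly positive parameter vector of length `param_dim`.
#' @param scenario A `predq_scenario`; its overrides are applied before
#'   integration. May be omitted when `times` is supplied.
#' @param times Optional explicit, strictly increasing time grid starting at 0;
#'   overrides the scenario's uniform grid.
#' @param keep_states Retain the state matrix as an attribute?
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `predq_trajectory` with columns `time`,
#'   `component` and `value` (long format, one row per grid point and output
#'   component), and attributes `times`, `outputs` (matrix), `positivity_ok`.
#'   Solver failure aborts with class `predq_integration_failure`; a
#'   trajectory containing non-positive outputs carries `positivity_ok = FALSE`
#'   and raises a warning.
#' @export
simulate_model <- function(model, theta, scenario = NULL, times = NULL,
                           keep_states = FALSE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "predq_model"))
  theta <- as.numeric(theta)
  if (length(theta) != model$param_dim || any(!is.finite(theta)) || any(theta <= 0)) {
    rlang::abort("theta must be strictly positive and of length param_dim",
                 class = "predq_config_error")
  }
  sim <- sim_or_abort(model, theta, scenario, times, rtol, atol)
  if (!isTRUE(sim$positivity_ok)) {
    rlang::warn("simulated outputs are not strictly positive everywhere",
                class = "predq_positivity_warning")
  }
  as_trajectory(sim$times, sim$outputs, model$output_names,
                positivity_ok = sim$positivity_ok,
                states = if (keep_states) sim$states else NULL)
}

as_trajectory <- function(times, outputs, output_names,
                          positivity_ok = all(outputs > 0), states = NULL) {
  colnames(outputs) <- output_names
  tb <- tibble::tibble(
    time = rep(times, times = length(output_names)),
    component = rep(output_names, each = length(times)),
    value = as.vector(outputs)
  )
  structure(tb, class = c("predq_trajectory", class(tb)),
            times = times, outputs = outputs,
            positivity_ok = positivity_ok, states = states)
}

# matrix view of a trajectory (n_times x m), with times attribute
traj_matrix <- function(traj) {
  out <- attr(traj, "outputs")
  if (is.null(out)) {
    wide <- tidyr::pivot_wider(traj, names_from = "component", values_from = "value")
    out <- as.matrix(wide[, -1, drop = FALSE])
    attr(out, "times") <- wide$time
  } else {
    attr(out, "times") <- attr(traj, "times")
  }
  out
}
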