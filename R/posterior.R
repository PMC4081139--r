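#' Generate a synthetic calibration dataset
#'
#' Simulates the model at `theta_true` under the calibration scenario and adds
#' independent Gaussian measurement noise with standard deviation equal to
#' `noise_fraction` times the noiseless output value at each observation —
#' the 10%-of-signal noise model used throughout the package's simulated
#' experiments. The recorded `sigma` column carries that same SD (computed
#' from the noiseless value, which keeps the generative model internally
#' consistent); negative observed values arising from the noise are kept.
#'
#' @param model A `predq_model`.
#' @param theta_true True parameter vector used to generate the data.
#' @param scenario Calibration scenario (initial state, input) under which the
#'   data are observed.
#' @param times Observation times (strictly positive, within the horizon).
#' @param noise_fraction Noise SD as a fraction of the signal; default `0.1`.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A tibble of class `predq_data` with columns `time`, `component`
#'   (output index, 1-based), `value` and `sigma`.
#' @export
#' @examples
#' m <- autoregulation_model()
#' d <- generate_dataset(m, c(10, 2), prediction_scenario(horizon = 10),
#'                       times = 1:10, seed = 1)
generate_dataset <- function(model, theta_true, scenario, times,
                             noise_fraction = 0.1, seed) {
  stopifnot(inherits(model, "predq_model"), noise_fraction >= 0)
  if (missing(seed)) rlang::abort("seed is required", class = "predq_config_error")
  times <- sort(unique(as.numeric(times)))
  if (any(times <= 0)) {
    rlang::abort("observation times must be strictly positive",
                 class = "predq_config_error")
  }
  sim <- sim_or_abort(model, theta_true, scenario, times = c(0, times))
  keep <- match(times, sim$times)
  y <- sim$outputs[keep, , drop = FALSE]
  if (any(y <= 0)) {
    rlang::abort("model output is non-positive at an observation time; cannot form relative noise",
                 class = "predq_generation_error")
  }
  m <- model$output_dim
  d <- tibble::tibble(
    time = rep(times, times = m),
    component = rep(seq_len(m), each = length(times)),
    value = as.vector(y),
    sigma = noise_fraction * as.vector(y)
  )
  if (noise_fraction > 0) {
    d$value <- with_local_seed(seed, d$value + stats::rnorm(nrow(d), 0, d$sigma))
  }
  new_predq_data(d)
}

new_predq_data <- function(d) {
  structure(d, class = c("predq_data", setdiff(class(d), "predq_data")))
}

validate_dataset <- function(d, line_offset = 0) {
  need <- c("time", "component", "value", "sigma")
  if (!all(need %in% names(d))) {
    rlang::abort("dataset must have columns time, component, value, sigma",
                 class = "predq_parse_error")
  }
  bad <- which(!(d$sigma > 0))
  if (length(bad)) {
    rlang::abort(paste0("sigma must be strictly positive (row ", bad[1] + line_offset, ")"),
                 class = "predq_parse_error")
  }
  if (any(d$component < 1 | d$component != round(d$component))) {
    rlang::abort("component indices must be positive integers",
                 class = "predq_parse_error")
  }
  d
}

# run code under a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specify a prior over positive parameters
#'
#' The default prior is log-uniform: uniform for the logarithm of each
#' parameter between positive bounds, i.e. density proportional to
#' \eqn{\prod_j 1/\theta_j} on the natural scale. Because all sampling and
#' optimisation happen in log-coordinates, the log-uniform prior contributes a
#' constant (taken as zero) inside its support and \eqn{-\infty} outside.
#' `kind = "uniform"` instead makes the prior flat on the natural scale
#' (useful for linear-Gaussian benchmark problems with a Normal posterior);
#' in log-coordinates it then carries the Jacobian term \eqn{\sum_j \log\theta_j}.
#'
#' @param lower,upper Strictly positive bound vectors, `0 < lower < upper`,
#'   recycled to a common length.
#' @param kind `"log-uniform"` (default) or `"uniform"`.
#' @return An object of class `predq_prior`.
#' @export
prior_spec <- function(lower, upper, kind = c("log-uniform", "uniform")) {
  kind <- match.arg(kind)
  p <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), p); upper <- rep_len(as.numeric(upper), p)
  if (any(lower <= 0) || any(upper <= lower)) {
    rlang::abort("prior bounds must satisfy 0 < lower < upper",
                 class = "predq_config_error")
  }
  structure(list(lower = lower, upper = upper, kind = kind, param_dim = p),
            class = "predq_prior")
}

#' Log prior density in sampling (log) coordinates
#'
#' Returns the log prior density of `theta` under the convention that the
#' sampling coordinates are \eqn{\log\theta}: zero inside the support for the
#' log-uniform prior, \eqn{\sum_j \log\theta_j} for the natural-scale uniform
#' prior, and `-Inf` when any component falls outside its bounds.
#'
#' @param prior A [prior_spec()].
#' @param theta Parameter vector on the natural scale (strictly positive).
#' @return A scalar, possibly `-Inf`.
#' @export
log_prior <- function(prior, theta) {
  stopifnot(inherits(prior, "predq_prior"))
  theta <- as.numeric(theta)
  if (length(theta) != prior$param_dim) {
    rlang::abort("theta length does not match prior", class = "predq_config_error")
  }
  if (any(theta <= 0)) {
    rlang::abort("theta must be strictly positive", class = "predq_domain_error")
  }
  if (any(theta < prior$lower | theta > prior$upper)) return(-Inf)
  if (prior$kind == "uniform") sum(log(theta)) else 0
}

#' Bundle model, data and prior into an inference problem
#'
#' @param model A `predq_model`.
#' @param data A `predq_data` tibble (columns `time`, `component`, `value`,
#'   `sigma`) observed under `scenario`.
#' @param prior A [prior_spec()] of length `param_dim`.
#' @param scenario The calibration scenario under which the data were
#'   observed; its horizon defaults to the last observation time.
#' @return An object of class `predq_problem`.
#' @export
inference_problem <- function(model, data, prior,
                              scenario = prediction_scenario()) {
  stopifnot(inherits(model, "predq_model"), inherits(prior, "predq_prior"))
  data <- validate_dataset(tibble::as_tibble(data))
  if (prior$param_dim != model$param_dim) {
    rlang::abort("prior dimension does not match model param_dim",
                 class = "predq_config_error")
  }
  if (any(data$component > model$output_dim)) {
    rlang::abort("data component indices exceed model output_dim",
                 class = "predq_config_error")
  }
  if (is.null(scenario$horizon)) scenario$horizon <- max(data$time)
  structure(list(model = model, data = new_predq_data(data), prior = prior,
                 scenario = scenario),
            class = "predq_problem")
}

# simulate the calibration scenario on a grid containing all observation
# times exactly; returns fitted values aligned with the data records
fitted_at_data <- function(problem, theta) {
  d <- problem$data
  times <- sort(unique(d$time))
  sim <- sim_or_abort(problem$model, theta, problem$scenario, times = c(0, times))
  idx_t <- match(d$time, sim$times)
  sim$outputs[cbind(idx_t, d$component)]
}

#' Chi-squared fitting error
#'
#' The weighted residual sum of squares
#' \deqn{\chi^2(\theta) = \sum_i \frac{(y_i(\theta) - y_{d,i})^2}{\sigma_i^2},}
#' summed over every data record. Observation times are inserted into the
#' solver grid so no interpolation error enters the sum.
#'
#' @param problem A [inference_problem()].
#' @param theta Parameter vector on the natural scale.
#' @return Non-negative scalar. Integration failure aborts with class
#'   `predq_integration_failure`.
#' @export
chi_squared <- function(problem, theta) {
  stopifnot(inherits(problem, "predq_problem"))
  yhat <- fitted_at_data(problem, theta)
  sum(((yhat - problem$data$value) / problem$data$sigma)^2)
}

#' Log posterior density (up to a constant)
#'
#' Returns \eqn{-\chi^2(\theta)/2 + \log p(\theta)} in sampling (log)
#' coordinates; the data-dependent additive constant is omitted since it
#' cancels in Metropolis ratios. Outside the prior support the function
#' short-circuits to `-Inf` without integrating the ODE; integration failures
#' inside the support also yield `-Inf` (with a warning), so the sampler
#' simply rejects such candidates.
#'
#' @inheritParams chi_squared
#' @return A scalar, possibly `-Inf`.
#' @export
log_posterior <- function(problem, theta) {
  lp <- log_prior(problem$prior, theta)
  if (!is.finite(lp)) return(-Inf)
  chi2 <- tryCatch(chi_squared(problem, theta), predq_integration_failure = function(e) {
    rlang::warn(paste0("integration failure treated as log-posterior -Inf: ",
                       conditionMessage(e)),
                class = "predq_integration_warning")
    NA_real_
  })
  if (is.na(chi2)) return(-Inf)
  -chi2 / 2 + lp
}

#' Penalized maximum likelihood estimate
#'
#' Maximises the log posterior over the prior box, working in log-parameter
#' coordinates with `L-BFGS-B`. Multiple deterministic starts are used (the
#' box centre plus points along its diagonal); when a posterior `sample` is
#' supplied its best draw is an additional start, which guarantees the result
#' is at least as good as every draw.
#'
#' @inheritParams chi_squared
#' @param sample Optional `predq_sample` (see [run_demcz()]); its best draw
#'   seeds one optimisation start.
#' @param n_starts Number of deterministic starts along the prior-box diagonal.
#' @return The maximising parameter vector (natural scale) with attribute
#'   `log_posterior`.
#' @export
find_pml <- function(problem, sample = NULL, n_starts = 5) {
  stopifnot(inherits(problem, "predq_problem"))
  prior <- problem$prior
  llo <- log(prior$lower); lup <- log(prior$upper)
  obj <- function(lth) {
    v <- log_posterior(problem, exp(lth))
    if (!is.finite(v)) 1e300 else -v
  }
  fracs <- seq(0.2, 0.8, length.out = max(1, n_starts))
  fracs[which.min(abs(fracs - 0.5))] <- 0.5
  starts <- lapply(fracs, function(f) llo + f * (lup - llo))
  if (!is.null(sample)) {
    dm <- draws_matrix(sample)
    lp <- apply(dm, 1L, function(th) log_posterior(problem, th))
    starts <- c(starts, list(log(dm[which.max(lp), ])))
  }
  fits <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = llo, upper = lup,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  fits <- fits[vapply(fits, function(f) f$value < 1e300, logical(1))]
  if (!length(fits)) {
    rlang::abort(paste0("all ", length(starts), " optimisation starts failed"),
                 class = "predq_optim_failure")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- exp(best$par)
  names(theta) <- problem$model$param_names
  structure(theta, log_posterior = -best$value)
}
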