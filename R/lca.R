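#' Output sensitivities with respect to log-parameters
#'
#' Central finite differences of the model output with respect to
#' \eqn{\log\theta_j}: each parameter is perturbed to
#' \eqn{\theta_j e^{\pm h}} and the difference quotient
#' \eqn{(y^+ - y^-) / (2h)} is formed, so the chain rule
#' \eqn{\partial y/\partial\log\theta_j = \theta_j\,\partial y/\partial\theta_j}
#' holds automatically. With `of = "log-output"` the differences are taken on
#' \eqn{\log y}, giving the dimensionless logarithmic gains used by the
#' log-scale prediction band.
#'
#' @param model A `predq_model`.
#' @param theta Parameter vector (natural scale).
#' @param scenario A `predq_scenario` applied before integration.
#' @param times Evaluation grid (including 0; prepended if absent).
#' @param h Step in natural-log units (default `1e-4`).
#' @param of `"output"` (default) or `"log-output"`.
#' @return A tibble with columns `time`, `component`, `parameter`,
#'   `sensitivity`, plus attribute `array` (`n_times x m x p`).
#' @export
output_sensitivities <- function(model, theta, scenario, times,
                                 h = 1e-4, of = c("output", "log-output")) {
  of <- match.arg(of)
  arr <- sens_array(model, theta, scenario, times, h = h, log_output = of == "log-output")
  times_out <- attr(arr, "times")
  tb <- tidyr::expand_grid(parameter = model$param_names,
                           component = model$output_names,
                           time = times_out)
  tb <- tb[, c("time", "component", "parameter")]
  tb$sensitivity <- as.vector(arr)
  structure(tibble::as_tibble(tb), array = arr)
}

# n_times x m x p sensitivity array by central differences in log theta
sens_array <- function(model, theta, scenario, times, h = 1e-4,
                       log_output = FALSE) {
  if (times[1] != 0) times <- c(0, times)
  derived <- if (is.null(scenario)) model else apply_scenario(model, scenario)
  p <- model$param_dim; m <- model$output_dim
  arr <- array(NA_real_, dim = c(length(times), m, p))
  for (j in seq_len(p)) {
    up <- theta; up[j] <- up[j] * exp(h)
    dn <- theta; dn[j] <- dn[j] * exp(-h)
    y_up <- sim_or_abort(derived, up, times = times)$outputs
    y_dn <- sim_or_abort(derived, dn, times = times)$outputs
    if (log_output) {
      y_up <- log(pmax(y_up, 1e-12)); y_dn <- log(pmax(y_dn, 1e-12))
    }
    g <- (y_up - y_dn) / (2 * h)
    if (!all(is.finite(g))) {
      bad <- which(!is.finite(g), arr.ind = TRUE)[1, ]
      rlang::abort(paste0("non-finite sensitivity for parameter ",
                          model$param_names[j], ", component ", bad[2],
                          ", t = ", signif(times[bad[1]], 6)),
                   class = "predq_sensitivity_failure")
    }
    arr[, , j] <- g
  }
  attr(arr, "times") <- times
  arr
}

#' Linearized parameter covariance (Gauss-Newton)
#'
#' Approximates the posterior covariance of the log-parameters from a local
#' quadratic expansion of the log-posterior at `theta_center`: the information
#' matrix is the Gauss-Newton form \eqn{F = J^\top \Sigma^{-1} J}, where `J`
#' stacks the output sensitivities (w.r.t. log-parameters) at the data's
#' times and components and \eqn{\Sigma} is the diagonal matrix of the data's
#' noise variances. The flat (log-uniform) prior contributes nothing inside
#' its support. The covariance is the Moore-Penrose pseudo-inverse of `F`;
#' rank deficiency is not an error — it is precisely structural sloppiness —
#' and is reported via the `rank` and `regularized` attributes.
#'
#' @param problem A [inference_problem()].
#' @param theta_center Expansion point (natural scale), typically the
#'   penalized maximum likelihood estimate or the true parameters in a
#'   simulation study.
#' @param h Finite-difference step in log units.
#' @return A `p x p` covariance matrix in log-parameter coordinates with
#'   attributes `theta_center`, `rank`, `regularized`.
#' @export
parameter_covariance_lca <- function(problem, theta_center, h = 1e-4) {
  stopifnot(inherits(problem, "predq_problem"))
  if (!is.finite(log_prior(problem$prior, theta_center))) {
    rlang::abort("theta_center must lie inside the prior support",
                 class = "predq_config_error")
  }
  d <- problem$data
  times <- sort(unique(d$time))
  arr <- sens_array(problem$model, theta_center, problem$scenario,
                    times = c(0, times), h = h)
  idx_t <- match(d$time, attr(arr, "times"))
  p <- problem$model$param_dim
  J <- vapply(seq_len(p), function(j) {
    Sj <- matrix(arr[, , j], nrow = dim(arr)[1])
    Sj[cbind(idx_t, d$component)]
  }, numeric(nrow(d)))
  J <- matrix(J, nrow = nrow(d), ncol = p)
  Jw <- J / d$sigma
  F_ <- crossprod(Jw)
  sv <- svd(F_)
  tol <- max(dim(F_)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  C <- MASS::ginv(F_)
  C <- (C + t(C)) / 2
  dimnames(C) <- list(problem$model$param_names, problem$model$param_names)
  structure(C, theta_center = theta_center, rank = rank,
            regularized = rank < p)
}

#' Linearized prediction-uncertainty band
#'
#' First-order propagation of the log-parameter covariance onto a predicted
#' trajectory: at every grid time and component, the prediction variance is
#' \eqn{v(t) = s(t)^\top C\, s(t)} with `s(t)` the scenario-specific
#' sensitivity vector, and the band is the central prediction \eqn{\pm
#' z_{(1+\alpha)/2}\sqrt{v(t)}}. By default propagation happens on the
#' log-output scale and the band is exponentiated, which keeps it strictly
#' positive and geometrically comparable with the Q quantifier;
#' `scale = "natural"` propagates on the output scale directly (exact for
#' models linear in the parameters).
#'
#' @param model A `predq_model`.
#' @param theta_center Central parameter vector (natural scale).
#' @param covariance Log-parameter covariance matrix (PSD), e.g. from
#'   [parameter_covariance_lca()].
#' @param scenario A `predq_scenario` with a horizon.
#' @param alpha Band level (default 0.95).
#' @param scale `"log"` (default) or `"natural"`.
#' @param h Finite-difference step.
#' @return A tibble of class `predq_lca` with columns `time`, `component`,
#'   `center`, `lower`, `upper`; attributes `alpha`, `scale`, `covariance`,
#'   `rank`, `regularized`.
#' @export
lca_prediction_band <- function(model, theta_center, covariance, scenario,
                                alpha = 0.95, scale = c("log", "natural"),
                                h = 1e-4) {
  scale <- match.arg(scale)
  if (is.null(scenario$horizon)) {
    rlang::abort("scenario horizon is required", class = "predq_config_error")
  }
  times <- seq(0, scenario$horizon, length.out = scenario$grid_size)
  derived <- apply_scenario(model, scenario)
  center <- sim_or_abort(derived, theta_center, times = times)$outputs
  arr <- sens_array(model, theta_center, scenario, times,
                    h = h, log_output = scale == "log")
  z <- stats::qnorm((1 + alpha) / 2)
  m <- model$output_dim
  res <- purrr::map_dfr(seq_len(m), function(i) {
    S <- matrix(arr[, i, ], nrow = length(times))
    v <- rowSums((S %*% covariance) * S)
    v[v < 0] <- 0
    half <- z * sqrt(v)
    if (scale == "log") {
      lower <- center[, i] * exp(-half); upper <- center[, i] * exp(half)
    } else {
      lower <- center[, i] - half; upper <- center[, i] + half
    }
    tibble::tibble(time = times, component = model$output_names[i],
                   center = center[, i], lower = lower, upper = upper)
  })
  structure(res, class = c("predq_lca", class(res)),
            alpha = alpha, scale = scale, covariance = covariance,
            rank = attr(covariance, "rank"),
            regularized = attr(covariance, "regularized"))
}
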