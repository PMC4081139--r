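#' The prediction-deviation quantifier Q for one trajectory pair
#'
#' For a predicted output \eqn{y_p(t)} and a reference \eqn{y_{ref}(t)} on the
#' interval \eqn{[0, T]}, the per-component deviation is
#' \deqn{Q_i = \frac{1}{T}\int_0^T \left(\log_b
#'   \frac{y_{p,i}(t)}{y_{ref,i}(t)}\right)^2 dt,}
#' evaluated by the trapezoid rule on the shared grid, and
#' \eqn{Q = \frac{1}{m}\sum_i Q_i}. Q is dimensionless, symmetric in
#' over-/under-prediction and in which trajectory is called the reference. A
#' ratio that stays strictly inside \eqn{(1/b, b)} at all times gives
#' \eqn{Q < 1}; a sustained ratio of exactly \eqn{b} gives \eqn{Q = 1}.
#' With the default `b = 2`, predictions deviating less than two-fold are
#' "tight".
#'
#' Values are clipped at a floor of `1e-12` inside the logarithm only (solver
#' undershoot protection); clipped points are counted in the result.
#'
#' @param pred,ref Trajectories ([simulate_model()] output, or any tibble with
#'   `time`/`component`/`value`) on the identical grid.
#' @param b Logarithm base characterising the deviation magnitude of interest.
#' @param at Optional vector of times: restrict Q to those grid points and use
#'   a plain mean of squared log-ratios there instead of the integral (for
#'   predictions where only a few time points are of biological interest).
#' @return A list with `q` (scalar), `q_components` (length-m named vector)
#'   and `n_clipped`.
#' @export
#' @examples
#' m <- autoregulation_model()
#' sc <- prediction_scenario(horizon = 10)
#' q_deviation(simulate_model(m, c(10, 2.2), sc), simulate_model(m, c(10, 2), sc))
q_deviation <- function(pred, ref, b = 2, at = NULL) {
  mp <- traj_matrix(pred); mr <- traj_matrix(ref)
  tp <- attr(mp, "times"); tr <- attr(mr, "times")
  if (length(tp) != length(tr) || any(tp != tr) || !all(dim(mp) == dim(mr))) {
    rlang::abort("pred and ref must share an identical time grid and components",
                 class = "predq_contract_error")
  }
  qc <- q_core(mp, mr, tp, b = b, at = at)
  list(q = mean(qc$q_components), q_components = qc$q_components,
       n_clipped = qc$n_clipped)
}

# matrix-level Q: pred/ref are n_times x m matrices on grid `times`
q_core <- function(mp, mr, times, b = 2, at = NULL) {
  floor_ <- 1e-12
  n_clipped <- sum(mp < floor_) + sum(mr < floor_)
  lr <- (log(pmax(mp, floor_)) - log(pmax(mr, floor_))) / log(b)
  sq <- lr^2
  if (!is.null(at)) {
    idx <- match(at, times)
    if (anyNA(idx)) {
      rlang::abort("`at` times must all lie on the trajectory grid",
                   class = "predq_contract_error")
    }
    qi <- colMeans(sq[idx, , drop = FALSE])
  } else {
    qi <- apply(sq, 2L, trapz, x = times) / (times[length(times)] - times[1])
  }
  names(qi) <- colnames(mp)
  list(q_components = qi, n_clipped = n_clipped)
}

trapz <- function(y, x) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Empirical lower alpha-quantile by the discard rule
#'
#' Sorts the values ascending, discards the `floor((1 - alpha) * n)` largest,
#' and returns the maximum of the remainder. This integer order-statistic rule
#' makes `Q_alpha` always one of the observed values; at `alpha = 1` it is the
#' maximum.
#'
#' @param q_values Non-empty numeric vector.
#' @param alpha Probability in `[0, 1]`.
#' @return Scalar quantile.
#' @export
#' @examples
#' q_quantile(1:1000, 0.95) # 950
q_quantile <- function(q_values, alpha = 0.95) {
  if (!length(q_values)) {
    rlang::abort("q_values must be non-empty", class = "predq_contract_error")
  }
  if (alpha < 0 || alpha > 1) {
    rlang::abort("alpha must lie in [0, 1]", class = "predq_contract_error")
  }
  s <- sort(q_values)
  k <- floor((1 - alpha) * length(s))
  s[length(s) - k]
}

# Simulate every draw of a sample under one scenario on a shared grid.
# Duplicated draws (common in thinned MCMC output) are integrated once.
# Returns list(times, preds = n_draws x n_times x m array, failed = logical).
predict_draws <- function(model, draws, scenario, times = NULL) {
  if (is.null(times)) {
    if (is.null(scenario$horizon)) {
      rlang::abort("scenario horizon is required", class = "predq_config_error")
    }
    times <- seq(0, scenario$horizon, length.out = scenario$grid_size)
  }
  derived <- apply_scenario(model, scenario)
  key <- apply(draws, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  uniq <- draws[first, , drop = FALSE]

  m <- model$output_dim
  preds_u <- array(NA_real_, dim = c(nrow(uniq), length(times), m))
  failed_u <- logical(nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    sim <- sim_core(derived, uniq[i, ], times = times)
    if (sim$ok) preds_u[i, , ] <- sim$outputs else failed_u[i] <- TRUE
  }
  list(times = times, preds = preds_u[idx, , , drop = FALSE], failed = failed_u[idx])
}

#' Posterior distribution of Q for one prediction scenario
#'
#' Simulates the scenario for every posterior draw and for the reference
#' parameter vector on one shared grid, computes [q_deviation()] per draw, and
#' summarises with the empirical [q_quantile()] at level `alpha`. Draws whose
#' integration fails are excluded and counted; more than 5% exclusions raises
#' a reliability warning.
#'
#' The reference trajectory is the simulation at `theta_ref` — typically the
#' penalized maximum likelihood estimate ([find_pml()]) or, in simulation
#' studies where it is known, the true parameter vector. Alternatively
#' `reference = "mean-log"` uses the pointwise geometric mean of the sampled
#' predictions themselves ([mean_log_reference()]), which needs no point
#' estimate at all.
#'
#' @param model A `predq_model`.
#' @param sample A `predq_sample` (or matrix of draws).
#' @param scenario A `predq_scenario` with a horizon.
#' @param theta_ref Reference parameter vector (ignored for
#'   `reference = "mean-log"`).
#' @param b Log base (default 2).
#' @param alpha Quantile level (default 0.95).
#' @param reference `"theta"` (default) or `"mean-log"`.
#' @param scenario_id Optional label stored in the result.
#' @return A tibble of class `predq_qresult` with columns `.draw`, `q` and one
#'   `q_<component>` column per output; attributes `q_alpha`, `alpha`, `b`,
#'   `reference_kind`, `scenario_id`, `n_draws`, `n_failed`.
#' @export
q_distribution <- function(model, sample, scenario, theta_ref = NULL,
                           b = 2, alpha = 0.95,
                           reference = c("theta", "mean-log"),
                           scenario_id = NULL) {
  reference <- match.arg(reference)
  draws <- if (is.matrix(sample)) sample else draws_matrix(sample)
  pd <- predict_draws(model, draws, scenario)
  q_from_pd(model, pd, scenario, theta_ref, b, alpha, reference, scenario_id)
}

q_from_pd <- function(model, pd, scenario, theta_ref, b, alpha,
                      reference, scenario_id) {
  ok <- which(!pd$failed)
  n_failed <- sum(pd$failed)
  n_total <- length(pd$failed)
  if (!length(ok)) {
    rlang::abort("every draw failed to integrate under this scenario",
                 class = "predq_integration_failure")
  }
  if (n_failed / n_total > 0.05) {
    rlang::warn(paste0(n_failed, " of ", n_total,
                       " draws (>5%) excluded for integration failure; ",
                       "Q_alpha may be unreliable"),
                class = "predq_reliability_warning")
  }

  if (reference == "theta") {
    if (is.null(theta_ref)) {
      rlang::abort("theta_ref is required unless reference = \"mean-log\"",
                   class = "predq_config_error")
    }
    ref_m <- sim_or_abort(apply_scenario(model, scenario), theta_ref,
                          times = pd$times)$outputs
  } else {
    logs <- log(pmax(pd$preds[ok, , , drop = FALSE], 1e-12))
    ref_m <- apply(logs, c(2L, 3L), mean)
    ref_m <- exp(matrix(ref_m, nrow = length(pd$times), ncol = model$output_dim))
  }

  m <- model$output_dim
  qi <- matrix(NA_real_, nrow = n_total, ncol = m)
  for (i in ok) {
    pm <- matrix(pd$preds[i, , ], ncol = m)
    qi[i, ] <- q_core(pm, ref_m, pd$times, b = b)$q_components
  }
  q <- rowMeans(qi)

  tb <- tibble::tibble(.draw = seq_len(n_total), q = q)
  qin <- as.data.frame(qi)
  names(qin) <- paste0("q_", model$output_names)
  tb <- dplyr::bind_cols(tb, tibble::as_tibble(qin))
  structure(tb, class = c("predq_qresult", class(tb)),
            q_alpha = q_quantile(q[ok], alpha), alpha = alpha, b = b,
            reference_kind = reference, scenario_id = scenario_id,
            n_draws = length(ok), n_failed = n_failed)
}

#' @export
print.predq_qresult <- function(x, ...) {
  cat("<predq_qresult> scenario ",
      if (is.null(attr(x, "scenario_id"))) "<unnamed>" else attr(x, "scenario_id"),
      ": Q_", attr(x, "alpha"), " = ", signif(attr(x, "q_alpha"), 4),
      " (b = ", attr(x, "b"), ", ", attr(x, "n_draws"), " draws, ",
      attr(x, "n_failed"), " failed)\n", sep = "")
  NextMethod()
}

#' Per-time-point prediction envelope
#'
#' For each grid time and output component, the `floor((1 - alpha)/2 * n)`
#' largest and equally many smallest predicted values among the `n`
#' successfully simulated draws are discarded; the band records the minimum
#' and maximum of the remainder — a per-time-point credible band matching the
#' 2.5/97.5 percentile summary at `alpha = 0.95`. The reference trajectory
#' (simulated at `theta_ref`) is stored alongside; it is not guaranteed to lie
#' inside the band pointwise.
#'
#' @inheritParams q_distribution
#' @param alpha Level of the band.
#' @return A tibble of class `predq_envelope` with columns `time`,
#'   `component`, `lower`, `upper`, `reference`; attributes `alpha`,
#'   `n_draws`, `n_failed`.
#' @export
compute_envelope <- function(model, sample, scenario, alpha = 0.95,
                             theta_ref = NULL, scenario_id = NULL) {
  draws <- if (is.matrix(sample)) sample else draws_matrix(sample)
  pd <- predict_draws(model, draws, scenario)
  envelope_from_pd(model, pd, scenario, alpha, theta_ref, scenario_id)
}

envelope_from_pd <- function(model, pd, scenario, alpha, theta_ref,
                             scenario_id) {
  ok <- which(!pd$failed)
  n_failed <- sum(pd$failed)
  if (!length(ok)) {
    rlang::abort("every draw failed to integrate under this scenario",
                 class = "predq_integration_failure")
  }
  if (n_failed / length(pd$failed) > 0.05) {
    rlang::warn(paste0(n_failed, " of ", nrow(draws),
                       " draws (>5%) excluded for integration failure"),
                class = "predq_reliability_warning")
  }
  n <- length(ok)
  k <- floor((1 - alpha) / 2 * n)
  m <- model$output_dim

  ref_m <- if (!is.null(theta_ref)) {
    sim_or_abort(apply_scenario(model, scenario), theta_ref, times = pd$times)$outputs
  } else matrix(NA_real_, nrow = length(pd$times), ncol = m)

  res <- purrr::map_dfr(seq_len(m), function(j) {
    vals <- matrix(pd$preds[ok, , j], nrow = n)
    band <- apply(vals, 2L, function(v) {
      s <- sort(v)
      c(s[k + 1L], s[n - k])
    })
    tibble::tibble(time = pd$times, component = model$output_names[j],
                   lower = band[1L, ], upper = band[2L, ],
                   reference = ref_m[, j])
  })
  structure(res, class = c("predq_envelope", class(res)),
            alpha = alpha, n_draws = n, n_failed = n_failed,
            scenario_id = scenario_id)
}

#' Geometric-mean reference trajectory
#'
#' The pointwise exponential of the mean of log-trajectories — the reference
#' used by the mean-log variant of Q, which replaces the penalized maximum
#' likelihood prediction when a point estimate is unreliable (e.g. very noisy
#' data). Invariant to the logarithm base.
#'
#' @param predictions List of trajectories on one shared grid.
#' @return A `predq_trajectory`.
#' @export
mean_log_reference <- function(predictions) {
  stopifnot(length(predictions) >= 1L)
  mats <- lapply(predictions, traj_matrix)
  times <- attr(mats[[1L]], "times")
  for (mt in mats) {
    if (length(attr(mt, "times")) != length(times) || any(attr(mt, "times") != times)) {
      rlang::abort("all trajectories must share one grid",
                   class = "predq_contract_error")
    }
  }
  if (any(vapply(mats, function(mt) any(mt <= 0), logical(1)))) {
    rlang::abort("trajectories must be strictly positive",
                 class = "predq_contract_error")
  }
  logs <- Reduce(`+`, lapply(mats, log)) / length(mats)
  out <- matrix(exp(logs), nrow = length(times))
  as_trajectory(times, out, colnames(mats[[1L]]))
}

#' Mean and variance of a qualitative prediction
#'
#' A qualitative prediction maps each posterior draw's trajectory to a value
#' in `[0, 1]`: a crisp yes (1) / no (0), or a graded degree of agreement with
#' the stated outcome. The mean measures the extent to which the model
#' predicts the statement; the (population) variance measures the prediction's
#' uncertainty. For crisp outcomes the mean is the yes-fraction `f` and the
#' variance is exactly `f * (1 - f)`.
#'
#' @param sample_outcomes Numeric vector with values in `[0, 1]`.
#' @return A tibble with columns `mean` and `variance`.
#' @export
qualitative_uncertainty <- function(sample_outcomes) {
  x <- as.numeric(sample_outcomes)
  if (!length(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    rlang::abort("outcomes must lie in [0, 1]", class = "predq_contract_error")
  }
  tibble::tibble(mean = mean(x), variance = mean(x^2) - mean(x)^2)
}

#' Parameter-perturbation scan of prediction uncertainty
#'
#' Systematically perturbs each parameter in turn, multiplying and dividing it
#' by `factor` (default 100), and computes the Q_alpha prediction uncertainty
#' of the perturbed system for every perturbation — `2 p` prediction sets in
#' all. The perturbation is applied identically to every posterior draw and to
#' the reference vector (the scenario defines the prediction; the reference
#' must live in the same scenario). A prediction is flagged `"uncertain"` when
#' `Q_alpha >= 1` and `"tight"` otherwise.
#'
#' @inheritParams q_distribution
#' @param theta_ref Reference parameter vector.
#' @param factor Strictly positive perturbation factor.
#' @param scenario Base scenario on which the perturbations are layered
#'   (horizon/grid/input/initial state).
#' @return A tibble of class `predq_scan` with one row per perturbation:
#'   `parameter`, `direction` (`"up"`/`"down"`), `factor`, `q_alpha`,
#'   `n_failed`, `flag`.
#' @export
perturbation_scan <- function(model, sample, theta_ref, scenario,
                              factor = 100, alpha = 0.95, b = 2) {
  if (factor <= 0) rlang::abort("factor must be > 0", class = "predq_config_error")
  grid <- tidyr::expand_grid(parameter = model$param_names,
                             direction = c("up", "down"))
  res <- purrr::pmap_dfr(grid, function(parameter, direction) {
    f <- if (direction == "up") factor else 1 / factor
    sc <- scenario
    pf <- stats::setNames(f, parameter)
    sc$param_factors <- combine_factors(model, scenario$param_factors, pf)
    row <- tryCatch({
      qr <- q_distribution(model, sample, sc, theta_ref = theta_ref,
                           b = b, alpha = alpha,
                           scenario_id = paste0(parameter, ":", direction))
      tibble::tibble(parameter = parameter, direction = direction, factor = f,
                     q_alpha = attr(qr, "q_alpha"),
                     n_failed = attr(qr, "n_failed"))
    }, error = function(e) {
      tibble::tibble(parameter = parameter, direction = direction, factor = f,
                     q_alpha = NA_real_, n_failed = NA_integer_)
    })
    row
  })
  res$flag <- dplyr::if_else(is.na(res$q_alpha), NA_character_,
                             dplyr::if_else(res$q_alpha >= 1, "uncertain", "tight"))
  structure(res, class = c("predq_scan", class(res)),
            alpha = alpha, b = b, factor = factor)
}

combine_factors <- function(model, base, extra) {
  full <- resolve_param_factors(model, base)
  if (is.null(full)) full <- rep(1, model$param_dim)
  add <- resolve_param_factors(model, extra)
  if (!is.null(add)) full <- full * add
  full
}
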