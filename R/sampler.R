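#' Configure the DE-MCz sampler
#'
#' Differential-evolution MCMC with a common archive (DE-MCz) proposes moves
#' as scaled differences of states drawn from an archive of past samples, run
#' as several parallel chains in log-parameter coordinates. The tuning
#' constants follow standard DE-MCz practice: jump scale
#' \eqn{\gamma = 2.38/\sqrt{2p}}, occasional full-size (\eqn{\gamma = 1})
#' mode-jumping proposals, occasional snooker updates along the line to an
#' archive point, and a small normal jitter that keeps proposals off exact
#' lattice differences.
#'
#' @param n_chains Number of parallel chains (>= 3).
#' @param n_iterations Total iterations per chain.
#' @param burn_in Iterations discarded before export (`burn_in < n_iterations`).
#' @param thin Thinning stride K: every Kth post-burn-in state is exported.
#' @param gamma_scale Jump scale; `NULL` means `2.38/sqrt(2 p)` (set per
#'   problem at run time).
#' @param jitter_sd SD of the per-coordinate normal jitter (log-space).
#' @param snooker_prob Probability of a snooker update.
#' @param full_gamma_prob Probability of a `gamma = 1` proposal.
#' @param archive_update_stride Iterations between archive appends.
#' @param seed Integer seed; mandatory, every random choice flows from it.
#' @return An object of class `predq_sampler_config`.
#' @export
sampler_config <- function(n_chains = 3L, n_iterations = 15000L,
                           burn_in = 5000L, thin = 30L,
                           gamma_scale = NULL, jitter_sd = 1e-4,
                           snooker_prob = 0.1, full_gamma_prob = 0.1,
                           archive_update_stride = 10L, seed) {
  if (missing(seed)) rlang::abort("seed is required", class = "predq_config_error")
  n_chains <- as.integer(n_chains); n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (n_chains < 3L) rlang::abort("n_chains must be >= 3", class = "predq_config_error")
  if (burn_in >= n_iterations) {
    rlang::abort("burn_in must be smaller than n_iterations", class = "predq_config_error")
  }
  if (thin < 1L) rlang::abort("thin must be >= 1", class = "predq_config_error")
  for (pr in c(snooker_prob, full_gamma_prob)) {
    if (pr < 0 || pr > 1) rlang::abort("probabilities must lie in [0,1]",
                                       class = "predq_config_error")
  }
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 burn_in = burn_in, thin = thin, gamma_scale = gamma_scale,
                 jitter_sd = jitter_sd, snooker_prob = snooker_prob,
                 full_gamma_prob = full_gamma_prob,
                 archive_update_stride = as.integer(archive_update_stride),
                 seed = as.integer(seed)),
            class = "predq_sampler_config")
}

#' Generate one DE-MCz proposal
#'
#' The plain parallel-direction update is
#' \deqn{\theta^* = \theta_k + \gamma (z_{r1} - z_{r2}) + e,}
#' with \eqn{z_{r1} \neq z_{r2}} drawn without replacement from the archive of
#' past states and \eqn{e} a small per-coordinate normal jitter; it is
#' symmetric, so its Hastings correction is zero. With probability
#' `full_gamma_prob` the jump uses \eqn{\gamma = 1} (mode jumping). With
#' probability `snooker_prob` a snooker update is made along the line from an
#' archive anchor `z` through the current state, using the difference of two
#' further archive states projected on that line; the snooker proposal is not
#' symmetric and the returned `log_correction`
#' \eqn{(p-1)\,\log(\|\theta^*-z\| / \|\theta_k-z\|)} must be added to the
#' Metropolis log-ratio.
#'
#' All coordinates here are sampling (log-parameter) coordinates.
#'
#' @param current Numeric vector, the chain's current position.
#' @param archive Matrix of past positions (rows); needs >= 3 distinct rows.
#' @param config A [sampler_config()].
#' @return List with `candidate` (numeric vector), `log_correction` (scalar)
#'   and `kind` (`"de"`, `"de_gamma1"` or `"snooker"`). Consumes the R RNG
#'   stream of the caller.
#' @export
demcz_propose <- function(current, archive, config) {
  d <- length(current)
  if (is.null(dim(archive))) archive <- matrix(archive, ncol = d)
  if (nrow(archive) < 3L) {
    rlang::abort("archive needs at least 3 rows to form proposals",
                 class = "predq_init_error")
  }
  gamma_de <- if (is.null(config$gamma_scale)) 2.38 / sqrt(2 * d) else config$gamma_scale
  u <- stats::runif(1)
  if (u < config$snooker_prob) {
    idx <- sample.int(nrow(archive), 3L)
    z <- archive[idx[1L], ]
    dir <- current - z
    nrm2 <- sum(dir^2)
    if (nrm2 > 0) {
      proj <- function(v) sum(v * dir) / nrm2 * dir
      gamma_s <- 2.38 / sqrt(2)
      cand <- current + gamma_s * (proj(archive[idx[2L], ]) - proj(archive[idx[3L], ]))
      if (config$jitter_sd > 0) cand <- cand + stats::rnorm(d, 0, config$jitter_sd)
      num <- sqrt(sum((cand - z)^2)); den <- sqrt(nrm2)
      logc <- if (num > 0 && den > 0) (d - 1) * (log(num) - log(den)) else 0
      return(list(candidate = cand, log_correction = logc, kind = "snooker"))
    }
    # degenerate direction: fall through to a plain DE move
  }
  gamma <- if (stats::runif(1) < config$full_gamma_prob) 1 else gamma_de
  idx <- sample.int(nrow(archive), 2L)
  cand <- current + gamma * (archive[idx[1L], ] - archive[idx[2L], ])
  if (config$jitter_sd > 0) cand <- cand + stats::rnorm(d, 0, config$jitter_sd)
  list(candidate = cand, log_correction = 0,
       kind = if (gamma == 1) "de_gamma1" else "de")
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, r)` where
#' `log r = log_post_candidate - log_post_current + log_correction`.
#' A candidate at least as good as the current state is always accepted;
#' a `-Inf` candidate never is.
#'
#' @param log_post_candidate,log_post_current Log posterior values.
#' @param log_correction Hastings term for asymmetric (snooker) proposals.
#' @return `TRUE` to accept. Consumes the caller's RNG stream.
#' @export
metropolis_accept <- function(log_post_candidate, log_post_current,
                              log_correction = 0) {
  if (!is.finite(log_post_current)) {
    rlang::abort("current state must have finite log posterior",
                 class = "predq_init_error")
  }
  if (log_post_candidate == -Inf) return(FALSE)
  logr <- log_post_candidate - log_post_current + log_correction
  if (logr >= 0) return(TRUE)
  log(stats::runif(1)) < logr
}

#' Low-level DE-MCz sampler for an arbitrary log density
#'
#' Runs DE-MCz on a user-supplied log-density over a box. This is the engine
#' behind [run_demcz()]; it is exported because sampling a closed-form density
#' (e.g. a Gaussian benchmark) is useful for validation work.
#'
#' Chains are initialised uniformly in the box, as is the initial archive
#' (`max(10, 5 d)` rows); the archive grows by the current chain states every
#' `archive_update_stride` iterations. Iteration order is
#' chain-by-chain within each sweep, driven by a single RNG stream seeded from
#' `config$seed`, so runs are exactly reproducible.
#'
#' @param log_density Function of a numeric vector returning a scalar
#'   (may be `-Inf`).
#' @param lower,upper Box bounds in sampling coordinates (finite).
#' @param config A [sampler_config()].
#' @return List with `draws` (3-d array: iteration x chain x dim, all
#'   post-burn-in thinned states), `chains` (list of full per-chain matrices),
#'   `acceptance_rate`, `n_fail` (candidates with non-finite density inside
#'   the box is not tracked here; `-Inf` densities are simply rejected).
#' @export
demcz_sample <- function(log_density, lower, upper, config) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  nC <- config$n_chains; nI <- config$n_iterations
  with_local_seed(config$seed, {
    runif_box <- function() lower + stats::runif(d) * (upper - lower)
    n0 <- max(10L, 5L * d)
    archive <- matrix(0, nrow = n0 + nC * (nI %/% config$archive_update_stride + 1L),
                      ncol = d)
    for (i in seq_len(n0)) archive[i, ] <- runif_box()
    n_arch <- n0

    states <- matrix(0, nrow = nC, ncol = d)
    lp <- numeric(nC)
    for (c in seq_len(nC)) {
      for (try in 1:100) {
        states[c, ] <- runif_box()
        lp[c] <- log_density(states[c, ])
        if (is.finite(lp[c])) break
      }
      if (!is.finite(lp[c])) {
        rlang::abort("could not initialise a chain at finite log density",
                     class = "predq_init_error")
      }
    }

    keep_iters <- seq.int(config$burn_in + config$thin, nI, by = config$thin)
    n_keep <- length(keep_iters)
    draws <- array(NA_real_, dim = c(n_keep, nC, d))
    trace <- array(NA_real_, dim = c(nI, nC, d))
    n_acc <- 0L; n_prop <- 0L
    recent_acc <- 0L; stall_window <- 500L

    for (it in seq_len(nI)) {
      for (c in seq_len(nC)) {
        prop <- demcz_propose(states[c, ], archive[seq_len(n_arch), , drop = FALSE],
                              config)
        cand <- prop$candidate
        lp_cand <- if (any(cand < lower | cand > upper)) -Inf else log_density(cand)
        n_prop <- n_prop + 1L
        if (metropolis_accept(lp_cand, lp[c], prop$log_correction)) {
          states[c, ] <- cand; lp[c] <- lp_cand
          n_acc <- n_acc + 1L; recent_acc <- recent_acc + 1L
        }
        trace[it, c, ] <- states[c, ]
      }
      if (it %% config$archive_update_stride == 0L) {
        archive[n_arch + seq_len(nC), ] <- states
        n_arch <- n_arch + nC
      }
      if (it %% stall_window == 0L) {
        if (recent_acc == 0L) {
          rlang::warn(paste0("sampler stalled: no acceptances in iterations ",
                             it - stall_window + 1L, "-", it,
                             "; current log posteriors: ",
                             paste(signif(lp, 6), collapse = ", ")),
                      class = "predq_sampler_stall")
        }
        recent_acc <- 0L
      }
      k <- match(it, keep_iters)
      if (!is.na(k)) draws[k, , ] <- states
    }

    list(draws = draws, trace = trace,
         acceptance_rate = n_acc / n_prop,
         keep_iters = keep_iters)
  })
}

#' Sample the posterior of an ODE inference problem with DE-MCz
#'
#' Runs the adaptive DE-MCz sampler on [log_posterior()] in log-parameter
#' coordinates (where the log-uniform prior is flat and proposals are
#' scale-free), discards the burn-in, exports every `thin`-th state of every
#' chain, and returns the draws exponentiated back to the natural scale.
#' Candidates outside the prior box or whose ODE integration fails are
#' rejected (log posterior `-Inf`) and never crash a chain.
#'
#' The exported draw count is
#' `n_chains * floor((n_iterations - burn_in) / thin)`.
#'
#' @param problem A [inference_problem()].
#' @param config A [sampler_config()]; prior bounds must be finite (they are,
#'   by construction of [prior_spec()]).
#' @return A tibble of class `predq_sample` with columns `.chain`,
#'   `.iteration` and one column per parameter (natural scale), plus
#'   provenance attributes (`seed`, `config`, `acceptance_rate`,
#'   `n_integration_failures`, `param_names`).
#' @export
#' @seealso [convergence_diagnostics()], [write_sample()], [tidy.predq_sample()]
run_demcz <- function(problem, config) {
  stopifnot(inherits(problem, "predq_problem"),
            inherits(config, "predq_sampler_config"))
  prior <- problem$prior
  n_fail <- 0L
  log_density <- function(lth) {
    theta <- exp(lth)
    chi2 <- tryCatch(chi_squared(problem, theta),
                     predq_integration_failure = function(e) NA_real_)
    if (is.na(chi2)) { n_fail <<- n_fail + 1L; return(-Inf) }
    lp <- if (prior$kind == "uniform") sum(lth) else 0
    -chi2 / 2 + lp
  }
  res <- demcz_sample(log_density, log(prior$lower), log(prior$upper), config)

  nms <- problem$model$param_names
  n_keep <- dim(res$draws)[1]; nC <- dim(res$draws)[2]
  flat <- do.call(rbind, lapply(seq_len(nC), function(c) {
    matrix(res$draws[, c, ], nrow = n_keep)
  }))
  colnames(flat) <- nms
  tb <- tibble::as_tibble(exp(as.data.frame(flat)))
  tb <- tibble::add_column(tb,
    .chain = rep(seq_len(nC), each = n_keep),
    .iteration = rep(res$keep_iters, times = nC),
    .before = 1L)
  new_predq_sample(tb, param_names = nms, seed = config$seed, config = config,
                   acceptance_rate = res$acceptance_rate,
                   n_integration_failures = n_fail)
}

new_predq_sample <- function(tb, param_names, seed = NA_integer_, config = NULL,
                             acceptance_rate = NA_real_,
                             n_integration_failures = NA_integer_) {
  dm <- as.matrix(tb[, param_names, drop = FALSE])
  if (any(!is.finite(dm)) || any(dm <= 0)) {
    rlang::abort("posterior draws must be finite and strictly positive",
                 class = "predq_parse_error")
  }
  structure(tb, class = c("predq_sample", setdiff(class(tb), "predq_sample")),
            param_names = param_names, seed = seed, config = config,
            acceptance_rate = acceptance_rate,
            n_integration_failures = n_integration_failures)
}

#' Extract the draws-by-parameters matrix of a posterior sample
#'
#' @param sample A `predq_sample` (or any data frame whose parameter columns
#'   are everything except `.chain`/`.iteration`).
#' @return Numeric matrix, one row per draw, natural scale.
#' @export
draws_matrix <- function(sample) {
  nms <- attr(sample, "param_names")
  if (is.null(nms)) nms <- setdiff(names(sample), c(".chain", ".iteration"))
  as.matrix(as.data.frame(sample)[, nms, drop = FALSE])
}

#' Convergence diagnostics for a posterior sample
#'
#' Computes, per parameter and on the log scale, the split-\eqn{\hat R}
#' statistic (each chain halved, between/within variance ratio) and an
#' effective sample size from Geyer's initial-positive-sequence estimate of
#' the autocorrelation time. \eqn{\hat R > 1.05} is flagged. Chains with zero
#' variance are reported as indeterminate (`NA`), not as converged.
#'
#' @param sample A `predq_sample` with `.chain` and `.iteration` columns and
#'   at least 2 chains x 4 draws.
#' @return A tibble with columns `parameter`, `rhat`, `ess`, `flagged`, and
#'   attribute `acceptance_rate` carried over from the sample.
#' @export
convergence_diagnostics <- function(sample) {
  nms <- attr(sample, "param_names")
  if (is.null(nms)) nms <- setdiff(names(sample), c(".chain", ".iteration"))
  chains <- split(as.data.frame(sample)[, nms, drop = FALSE], sample$.chain)
  if (length(chains) < 2L || any(vapply(chains, nrow, 1L) < 4L)) {
    rlang::abort("need >= 2 chains with >= 4 draws each",
                 class = "predq_config_error")
  }
  res <- purrr::map_dfr(nms, function(par) {
    mats <- lapply(chains, function(ch) log(ch[[par]]))
    halves <- unlist(lapply(mats, function(v) {
      h <- length(v) %/% 2L
      list(v[seq_len(h)], v[h + seq_len(h)])
    }), recursive = FALSE)
    n <- min(lengths(halves)); halves <- lapply(halves, function(v) v[seq_len(n)])
    means <- vapply(halves, mean, 1); vars <- vapply(halves, stats::var, 1)
    W <- mean(vars)
    if (W == 0 || !is.finite(W)) {
      return(tibble::tibble(parameter = par, rhat = NA_real_, ess = NA_real_,
                            flagged = NA))
    }
    B <- n * stats::var(means)
    var_plus <- (n - 1) / n * W + B / n
    rhat <- sqrt(var_plus / W)
    ess <- sum(vapply(mats, ess_geyer, 1))
    tibble::tibble(parameter = par, rhat = rhat, ess = ess,
                   flagged = rhat > 1.05)
  })
  structure(res, acceptance_rate = attr(sample, "acceptance_rate"))
}

# Geyer initial-positive-sequence ESS for one chain (vector)
ess_geyer <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0) return(NA_real_)
  ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[, 1, 1]
  # sum of adjacent pairs rho(2k)+rho(2k+1) while positive
  s <- 0; k <- 1L
  while (k + 1L <= length(ac)) {
    pair <- ac[k + 1L] + if (k + 2L <= length(ac)) ac[k + 2L] else 0
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  n / (1 + 2 * s)
}

#' @export
print.predq_sample <- function(x, ...) {
  cat("<predq_sample> ", nrow(x), " draws x ",
      length(attr(x, "param_names")), " parameters (",
      paste(attr(x, "param_names"), collapse = ", "), ")\n",
      "  seed ", attr(x, "seed"),
      ", acceptance rate ", signif(attr(x, "acceptance_rate"), 3), "\n",
      sep = "")
  NextMethod()
}
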