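test_that("DE proposal arithmetic follows the difference-update rule", {
  cfg <- sampler_config(jitter_sd = 0, snooker_prob = 0, full_gamma_prob = 0,
                        seed = 1)
  archive <- rbind(c(1, 0), c(0, 1), c(5, 5))
  # gamma = 2.38/sqrt(2 p) = 1.19 for p = 2; force z_r1 = row 1, z_r2 = row 2
  found <- FALSE
  set.seed(4)
  for (i in 1:200) {
    prop <- demcz_propose(c(0, 0), archive, cfg)
    diff <- prop$candidate
    if (isTRUE(all.equal(diff, 1.19 * (archive[1, ] - archive[2, ])))) {
      found <- TRUE; break
    }
  }
  expect_true(found)
  expect_identical(prop$log_correction, 0)

  # with gamma = 1 and no jitter the jump is exactly an archive difference
  cfg1 <- sampler_config(jitter_sd = 0, snooker_prob = 0, full_gamma_prob = 1,
                         seed = 1)
  diffs <- apply(expand.grid(1:3, 1:3), 1, function(ij) {
    if (ij[1] == ij[2]) return(c(NA, NA))
    archive[ij[1], ] - archive[ij[2], ]
  })
  for (i in 1:20) {
    prop <- demcz_propose(c(0, 0), archive, cfg1)
    jump <- prop$candidate - c(0, 0)
    match_any <- any(apply(diffs, 2, function(d) isTRUE(all.equal(d, jump))))
    expect_true(match_any)
    # z_r1 = z_r2 never occurs: the jump is never the zero vector
    expect_gt(sum(jump^2), 0)
  }

  expect_error(demcz_propose(c(0, 0), archive[1:2, ], cfg),
               class = "predq_init_error")
})

test_that("Metropolis acceptance has probability min(1, r)", {
  # candidate at least as good -> always accepted
  for (i in 1:20) expect_true(metropolis_accept(-1, -1.5))
  for (i in 1:20) expect_true(metropolis_accept(-2, -2))
  expect_false(metropolis_accept(-Inf, -1))
  expect_error(metropolis_accept(-1, -Inf), class = "predq_init_error")
  # log-ratio -1 -> acceptance rate e^-1 over many trials
  n <- 1e5
  set.seed(8)
  acc <- sum(replicate(n, metropolis_accept(-1, 0)))
  p <- exp(-1)
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("sampler draw-count and support contracts hold", {
  prob <- decay_problem(seed = 2)
  cfg <- sampler_config(n_iterations = 400, burn_in = 100, thin = 7, seed = 5)
  s <- run_demcz(prob, cfg)
  expect_identical(nrow(s), 3L * ((400L - 100L) %/% 7L))
  dm <- draws_matrix(s)
  expect_true(all(dm >= prob$prior$lower & dm <= prob$prior$upper))
  expect_true(all(is.finite(dm)) && all(dm > 0))
  # reproducibility: same config -> identical draws
  s2 <- run_demcz(prob, cfg)
  expect_identical(draws_matrix(s2), dm)
})

test_that("DE-MCz reproduces the conjugate Normal(1, 1/14) posterior", {
  prob <- conjugate_problem()
  cfg <- sampler_config(n_iterations = 4000, burn_in = 1000, thin = 9, seed = 31)
  s <- run_demcz(prob, cfg)
  dm <- draws_matrix(s)[, 1]
  diag <- convergence_diagnostics(s)
  ess <- max(diag$ess, 50)
  se_mean <- sd(dm) / sqrt(ess)
  expect_lt(abs(mean(dm) - 1), 3 * se_mean)
  se_sd <- sd(dm) / sqrt(2 * ess)
  expect_lt(abs(sd(dm) - 1 / sqrt(14)), 3 * se_sd)
})

test_that("DE-MCz matches a correlated 2-D Gaussian target", {
  rho <- 0.8
  Sig <- matrix(c(1, rho, rho, 1), 2)
  P <- solve(Sig)
  logd <- function(x) -0.5 * drop(t(x) %*% P %*% x)
  cfg <- sampler_config(n_iterations = 6000, burn_in = 1000, thin = 5, seed = 9)
  res <- demcz_sample(logd, lower = c(-10, -10), upper = c(10, 10), cfg)
  flat <- rbind(res$draws[, 1, ], res$draws[, 2, ], res$draws[, 3, ])
  expect_gte(nrow(flat), 1000)
  C <- cov(flat)
  expect_equal(C[1, 1], 1, tolerance = 0.2)
  expect_equal(C[2, 2], 1, tolerance = 0.2)
  expect_equal(cor(flat)[1, 2], rho, tolerance = 0.1)
})

test_that("acceptance is shift-invariant (detailed-balance smoke test)", {
  logd <- function(x) -0.5 * sum(x^2)
  cfg <- sampler_config(n_iterations = 500, burn_in = 100, thin = 2, seed = 17)
  r1 <- demcz_sample(logd, c(-5, -5), c(5, 5), cfg)
  r2 <- demcz_sample(function(x) logd(x) + 1000, c(-5, -5), c(5, 5), cfg)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$acceptance_rate, r2$acceptance_rate)
})

test_that("thinning preserves marginal means within Monte-Carlo error", {
  logd <- function(x) -0.5 * sum((x - 1)^2)
  cfg_thin <- sampler_config(n_iterations = 4000, burn_in = 1000, thin = 10,
                             seed = 23)
  cfg_all <- sampler_config(n_iterations = 4000, burn_in = 1000, thin = 1,
                            seed = 23)
  m_thin <- mean(demcz_sample(logd, -6, 8, cfg_thin)$draws)
  m_all <- mean(demcz_sample(logd, -6, 8, cfg_all)$draws)
  expect_equal(m_thin, m_all, tolerance = 0.2)
  expect_equal(m_thin, 1, tolerance = 0.2)
})

test_that("split R-hat separates mixed from unmixed chains", {
  make_sample <- function(offset) {
    set.seed(41)
    n <- 200
    tb <- tibble::tibble(
      .chain = rep(1:3, each = n),
      .iteration = rep(seq_len(n), 3),
      theta1 = exp(c(rnorm(n), rnorm(n), rnorm(n) + offset))
    )
    predq:::new_predq_sample(tb, param_names = "theta1")
  }
  good <- convergence_diagnostics(make_sample(0))
  expect_lt(abs(good$rhat - 1), 0.05)
  bad <- convergence_diagnostics(make_sample(8))
  expect_gt(bad$rhat, 1.05)
  expect_true(bad$flagged)

  # degenerate zero-variance chains are indeterminate, not converged
  tb <- tibble::tibble(.chain = rep(1:2, each = 8), .iteration = rep(1:8, 2),
                       theta1 = rep(1, 16))
  dg <- convergence_diagnostics(predq:::new_predq_sample(tb, param_names = "theta1"))
  expect_true(is.na(dg$rhat))
  expect_true(is.na(dg$flagged))
})
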