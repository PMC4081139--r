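test_that("Q matches closed forms on constructed trajectory pairs", {
  tg <- seq(0, 1, length.out = 201)
  ref <- make_traj(tg, rep(1, length(tg)))

  # identical trajectories -> Q = 0
  expect_identical(q_deviation(ref, ref)$q, 0)

  # constant ratio b at every time -> Q exactly 1 per component
  pred_b <- make_traj(tg, rep(2, length(tg)))
  expect_equal(q_deviation(pred_b, ref, b = 2)$q, 1, tolerance = 1e-12)

  # ratio 2^t on [0, 1] with b = 2 -> integral of t^2 = 1/3
  pred_t <- make_traj(tg, 2^tg)
  expect_equal(q_deviation(pred_t, ref, b = 2)$q, 1 / 3, tolerance = 1e-4)

  # grid mismatch is a contract error
  ref2 <- make_traj(seq(0, 1, length.out = 101), rep(1, 101))
  expect_error(q_deviation(pred_t, ref2), class = "predq_contract_error")
})

test_that("Q averages components and restricts to listed time points", {
  tg <- seq(0, 1, length.out = 101)
  two <- function(v1, v2) {
    predq:::as_trajectory(tg, cbind(v1, v2), c("y1", "y2"))
  }
  ref <- two(rep(1, 101), rep(1, 101))
  # component Q_i = (0, 1) -> Q = 0.5
  pred <- two(rep(1, 101), rep(2, 101))
  qd <- q_deviation(pred, ref, b = 2)
  expect_equal(unname(qd$q_components), c(0, 1), tolerance = 1e-12)
  expect_equal(qd$q, 0.5, tolerance = 1e-12)
  # summation variant: plain mean of squared log-ratios at listed points
  pred3 <- make_traj(tg, 2^tg)
  ref3 <- make_traj(tg, rep(1, 101))
  at <- c(0.5, 1)
  expect_equal(q_deviation(pred3, ref3, b = 2, at = at)$q,
               mean(c(0.5, 1)^2), tolerance = 1e-12)
})

test_that("Q obeys the base-change law and ratio-inversion symmetry", {
  set.seed(10)
  tg <- seq(0, 2, length.out = 151)
  for (i in 1:5) {
    a <- make_traj(tg, exp(cumsum(rnorm(151, 0, 0.05))) + 0.5)
    b_ <- make_traj(tg, exp(cumsum(rnorm(151, 0, 0.05))) + 0.5)
    q2 <- q_deviation(a, b_, b = 2)$q
    q10 <- q_deviation(a, b_, b = 10)$q
    expect_equal(q2, (log(10) / log(2))^2 * q10, tolerance = 1e-10)
    expect_equal(q_deviation(b_, a, b = 2)$q, q2, tolerance = 1e-12)
  }
})

test_that("trapezoid quadrature of Q converges at second order", {
  qs <- sapply(c(51, 101, 201), function(n) {
    tg <- seq(0, 1, length.out = n)
    q_deviation(make_traj(tg, 2^tg), make_traj(tg, rep(1, n)), b = 2)$q
  })
  err <- abs(qs - 1 / 3)
  expect_lt(err[2], err[1] / 3.5)
  expect_lt(err[3], err[2] / 3.5)
})

test_that("the discard-rule quantile reproduces explicit order statistics", {
  expect_identical(q_quantile(sample(1:1000), 0.95), 950L)
  expect_identical(q_quantile(1:10, 1), 10L)
  expect_identical(q_quantile(42, 0.5), 42)
  expect_error(q_quantile(numeric(0), 0.5), class = "predq_contract_error")
  # nondecreasing in alpha on any fixed value set
  set.seed(3)
  v <- rexp(137)
  qs <- sapply(seq(0.5, 1, by = 0.05), q_quantile, q_values = v)
  expect_true(all(diff(qs) >= 0))
})

test_that("envelopes trim the stated fractions per time point", {
  # synthetic 'sample' of constant trajectories valued 1..1000
  m <- decay_model()
  tg <- c(0, 1)
  const_model <- dynamical_model(
    "const", 1, 1, 1,
    rate = function(x, theta, u) 0,
    output_map = function(x, theta) x,
    init_map = function(theta) theta[1],
    param_names = "theta1")
  draws <- matrix(1:1000, ncol = 1, dimnames = list(NULL, "theta1"))
  sc <- prediction_scenario(horizon = 1, grid_size = 2)
  env <- compute_envelope(const_model, draws, sc, alpha = 0.95)
  expect_true(all(env$lower == 26))
  expect_true(all(env$upper == 975))
  env_all <- compute_envelope(const_model, draws, sc, alpha = 1)
  expect_true(all(env_all$lower == 1) && all(env_all$upper == 1000))
  # identical draws -> zero-width band at the common trajectory
  same <- matrix(rep(7, 50), ncol = 1, dimnames = list(NULL, "theta1"))
  env0 <- compute_envelope(const_model, same, sc, alpha = 0.95)
  expect_true(all(env0$lower == 7) && all(env0$upper == 7))
  # nesting: wider alpha never narrows the band
  set.seed(12)
  rnd <- matrix(rexp(200) + 0.1, ncol = 1, dimnames = list(NULL, "theta1"))
  e80 <- compute_envelope(const_model, rnd, sc, alpha = 0.80)
  e95 <- compute_envelope(const_model, rnd, sc, alpha = 0.95)
  expect_true(all(e95$lower <= e80$lower) && all(e95$upper >= e80$upper))
})

test_that("q_distribution handles identical draws, exclusions and counts", {
  m <- autoregulation_model()
  sc <- prediction_scenario(initial_state = 5, horizon = 3, grid_size = 41)
  th <- c(10, 0.5)
  draws <- matrix(rep(th, each = 20), ncol = 2,
                  dimnames = list(NULL, c("theta1", "theta2")))
  qr <- q_distribution(m, draws, sc, theta_ref = th, scenario_id = "self")
  expect_true(all(qr$q < 1e-10))
  expect_identical(attr(qr, "n_failed"), 0L)
  expect_equal(attr(qr, "q_alpha"), 0, tolerance = 1e-10)
})

test_that("failed draws are excluded, counted and warned about", {
  blow <- dynamical_model(
    "blowup2", 1, 1, 1,
    rate = function(x, theta, u) (theta[1] - 1) * x^2,
    output_map = function(x, theta) x,
    init_map = function(theta) 1,
    param_names = "k")
  # k = 1 is benign (constant), k = 6 blows up in finite time
  draws <- matrix(c(rep(1, 8), rep(6, 2)), ncol = 1, dimnames = list(NULL, "k"))
  sc <- prediction_scenario(horizon = 5, grid_size = 21)
  expect_warning(
    qr <- q_distribution(blow, draws, sc, theta_ref = 1),
    class = "predq_reliability_warning")
  expect_identical(attr(qr, "n_failed"), 2L)
  expect_identical(attr(qr, "n_draws"), 8L)
  expect_identical(sum(is.na(qr$q)), 2L)
})

test_that("mean-log reference is the pointwise geometric mean", {
  tg <- seq(0, 1, length.out = 11)
  a <- make_traj(tg, rep(2, 11)); b_ <- make_traj(tg, rep(8, 11))
  ref <- mean_log_reference(list(a, b_))
  expect_equal(attr(ref, "outputs")[, 1], rep(4, 11), tolerance = 1e-12)
  # identical inputs -> identity
  ref2 <- mean_log_reference(list(a, a))
  expect_equal(attr(ref2, "outputs"), attr(a, "outputs"), tolerance = 1e-12)
  # invariant to the log base used internally: check sqrt(a b) pointwise
  set.seed(2)
  v1 <- rexp(11) + 0.1; v2 <- rexp(11) + 0.1
  ref3 <- mean_log_reference(list(make_traj(tg, v1), make_traj(tg, v2)))
  expect_equal(attr(ref3, "outputs")[, 1], sqrt(v1 * v2), tolerance = 1e-12)
})

test_that("qualitative uncertainty reduces to f(1-f) for crisp outcomes", {
  expect_equal(qualitative_uncertainty(rep(1, 10)),
               tibble::tibble(mean = 1, variance = 0))
  out <- qualitative_uncertainty(c(rep(1, 500), rep(0, 500)))
  expect_equal(out$mean, 0.5)
  expect_equal(out$variance, 0.25)
  out2 <- qualitative_uncertainty(c(0, 0, 1, 1))
  expect_equal(out2$variance, 0.25)
  # graded outcomes: population variance
  g <- c(0.2, 0.4, 0.9)
  expect_equal(qualitative_uncertainty(g)$variance, mean(g^2) - mean(g)^2)
  expect_error(qualitative_uncertainty(c(0.5, 1.2)),
               class = "predq_contract_error")
})

test_that("perturbation scan emits 2p classified rows", {
  m <- autoregulation_model()
  th <- c(10, 0.5)
  set.seed(6)
  draws <- cbind(theta1 = th[1] * exp(rnorm(30, 0, 0.1)),
                 theta2 = th[2] * exp(rnorm(30, 0, 0.1)))
  sc <- prediction_scenario(initial_state = 20, horizon = 3, grid_size = 31)
  scan <- perturbation_scan(m, draws, theta_ref = th, scenario = sc,
                            factor = 100)
  expect_identical(nrow(scan), 4L)
  expect_setequal(scan$parameter, c("theta1", "theta2"))
  expect_true(all(scan$flag[!is.na(scan$q_alpha)] ==
                    ifelse(scan$q_alpha[!is.na(scan$q_alpha)] >= 1,
                           "uncertain", "tight")))

  # factor = 1: every row equals the unperturbed Q_alpha
  base <- q_distribution(m, draws, sc, theta_ref = th)
  scan1 <- perturbation_scan(m, draws, theta_ref = th, scenario = sc,
                             factor = 1)
  expect_true(all(abs(scan1$q_alpha - attr(base, "q_alpha")) < 1e-12))
})
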