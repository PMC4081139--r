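test_that("chi-squared matches hand-computed sums and the zero-residual case", {
  m <- decay_model()
  sc <- prediction_scenario(horizon = 2)
  prior <- prior_spec(1e-2, 1e2)

  # noiseless data at theta_true evaluated at theta_true -> ~0
  d0 <- generate_dataset(m, 1, sc, times = c(0.5, 1, 2), noise_fraction = 0,
                         seed = 1)
  d0$sigma <- 1
  p0 <- inference_problem(m, d0, prior, sc)
  expect_lt(chi_squared(p0, 1), 1e-12)

  # residuals 1 and 2 with sigma = 1 -> 5; residual 3 with sigma = 3 -> 1
  mk <- function(resid, sigma) {
    d <- d0
    d$value <- d$value[] # copy
    d <- d[seq_along(resid), ]
    d$value <- exp(-d$time) + resid
    d$sigma <- sigma
    inference_problem(m, d, prior, sc)
  }
  expect_equal(chi_squared(mk(c(1, 2), 1), 1), 5, tolerance = 1e-8)
  expect_equal(chi_squared(mk(3, 3), 1), 1, tolerance = 1e-8)
})

test_that("chi-squared is invariant to common rescaling of residuals and sigmas", {
  prob <- decay_problem(seed = 7)
  base <- chi_squared(prob, 1.3)
  d2 <- prob$data
  # scale residuals and sigma together by 10: (10 r / 10 s)^2 = (r/s)^2
  fit <- predq:::fitted_at_data(prob, 1.3)
  d2$value <- fit + 10 * (d2$value - fit)
  d2$sigma <- 10 * d2$sigma
  prob2 <- inference_problem(prob$model, d2, prob$prior, prob$scenario)
  expect_equal(chi_squared(prob2, 1.3), base, tolerance = 1e-10)
})

test_that("log prior follows the log-uniform convention", {
  prior <- prior_spec(c(0.1, 0.1), c(100, 100))
  # uniform in log space: any two in-support points have equal density
  expect_identical(log_prior(prior, c(1, 1)) - log_prior(prior, c(50, 0.2)), 0)
  # outside support -> -Inf
  expect_identical(log_prior(prior, c(1000, 1)), -Inf)
  # non-positive component -> domain error
  expect_error(log_prior(prior, c(-1, 1)), class = "predq_domain_error")
  # natural-scale density ratio prod(1/theta): p(1,1)/p(10,10) = 100.
  # In log coordinates the log-uniform density is flat, so the natural-scale
  # ratio is the Jacobian ratio prod(theta'_j/theta_j).
  nat_log_density <- function(theta) log_prior(prior, theta) - sum(log(theta))
  expect_equal(exp(nat_log_density(c(1, 1)) - nat_log_density(c(10, 10))), 100)
})

test_that("log posterior composes chi-squared and prior with c omitted", {
  prob <- decay_problem(seed = 3)
  th <- 1.1; th2 <- 0.8
  expect_equal(log_posterior(prob, th) - log_posterior(prob, th2),
               -(chi_squared(prob, th) - chi_squared(prob, th2)) / 2,
               tolerance = 1e-10)
  # outside support: -Inf without simulating
  expect_identical(log_posterior(prob, 1e5), -Inf)
  # zero residuals in support -> 0 under the c-omitted convention
  d0 <- generate_dataset(prob$model, 1, prob$scenario, times = c(1, 2),
                        noise_fraction = 0, seed = 1)
  d0$sigma <- 1
  p0 <- inference_problem(prob$model, d0, prob$prior, prob$scenario)
  expect_equal(log_posterior(p0, 1), 0, tolerance = 1e-10)
})

test_that("Metropolis ratios are invariant to the omitted constant", {
  prob <- decay_problem(seed = 5)
  la <- log_posterior(prob, 0.9); lb <- log_posterior(prob, 1.2)
  shift <- 123.456
  set.seed(1); a1 <- replicate(200, metropolis_accept(lb, la))
  set.seed(1); a2 <- replicate(200, metropolis_accept(lb + shift, la + shift))
  expect_identical(a1, a2)
})

test_that("generate_dataset honours the noise contract", {
  m <- decay_model()
  sc <- prediction_scenario(horizon = 2)
  # zero noise reproduces the trajectory exactly
  d0 <- generate_dataset(m, 1, sc, times = c(0.5, 1, 2), noise_fraction = 0,
                         seed = 9)
  expect_equal(d0$value, exp(-c(0.5, 1, 2)), tolerance = 1e-6)
  # determinism: same seed -> identical dataset; sigma = 0.1 * noiseless value
  d1 <- generate_dataset(m, 1, sc, times = c(0.5, 1, 2), seed = 11)
  d2 <- generate_dataset(m, 1, sc, times = c(0.5, 1, 2), seed = 11)
  expect_identical(d1$value, d2$value)
  expect_equal(d1$sigma, 0.1 * exp(-c(0.5, 1, 2)), tolerance = 1e-6)
})

test_that("empirical noise SD matches the 10%-of-signal specification", {
  # Monte-Carlo check at one time point over many replicate draws
  m <- decay_model()
  sc <- prediction_scenario(horizon = 1)
  y_true <- exp(-1)
  n <- 1e5
  vals <- predq:::with_local_seed(202, y_true + stats::rnorm(n, 0, 0.1 * y_true))
  expect_equal(sd(vals), 0.1 * y_true, tolerance = 0.01)
  # and the generator's single-draw noise comes from exactly that law
  d <- generate_dataset(m, 1, sc, times = 1, seed = 77)
  z <- (d$value - y_true) / (0.1 * y_true)
  expect_lt(abs(z), 5)
})

test_that("penalized maximum likelihood recovers truth and the WLS oracle", {
  # noiseless data: the truth attains the global minimum chi^2 = 0
  m <- decay_model()
  sc <- prediction_scenario(horizon = 2)
  d0 <- generate_dataset(m, 1, sc, times = c(0.5, 1, 2), noise_fraction = 0,
                         seed = 1)
  d0$sigma <- 1
  p0 <- inference_problem(m, d0, prior_spec(1e-2, 1e2), sc)
  pml <- find_pml(p0)
  expect_lt(chi_squared(p0, pml), 1e-6)

  # linear ramp y = theta t: PML equals the weighted least-squares solution
  t_obs <- c(1, 2, 3); y_obs <- c(1.2, 1.9, 3.3); sig <- c(0.1, 0.2, 0.3)
  d <- tibble::tibble(time = t_obs, component = 1L, value = y_obs, sigma = sig)
  # log-uniform prior: in sampling coordinates the objective is exactly
  # -chi^2/2, so the penalized maximum coincides with weighted least squares
  prob <- inference_problem(ramp_model(), d, prior_spec(1e-3, 1e3),
                            prediction_scenario(horizon = 3))
  wls <- sum(t_obs * y_obs / sig^2) / sum(t_obs^2 / sig^2)
  expect_equal(as.numeric(find_pml(prob)), wls, tolerance = 1e-5)
})

test_that("find_pml never falls below the best supplied draw", {
  prob <- decay_problem(seed = 13)
  draws <- matrix(c(0.5, 0.9, 1.0, 1.1, 2.0), ncol = 1,
                  dimnames = list(NULL, "theta1"))
  sample <- predq:::new_predq_sample(
    tibble::as_tibble(as.data.frame(draws)), param_names = "theta1")
  pml <- find_pml(prob, sample = sample)
  best <- max(apply(draws, 1, function(th) log_posterior(prob, th)))
  expect_gte(attr(pml, "log_posterior"), best)
})

test_that("the high-start calibration yields a sloppy posterior", {
  # theta2 (decay) is pinned by the data while theta1 (half-saturation) is
  # nearly unconstrained: the 95% credible interval of theta1 is far wider in
  # log10 units than that of theta2
  demo <- get_demo(1)
  td <- tidy(demo$sample)
  w <- log10(td$conf.high) - log10(td$conf.low)
  ratio <- w[td$parameter == "theta1"] / w[td$parameter == "theta2"]
  expect_gt(ratio, 3)
})
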