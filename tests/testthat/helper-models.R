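# Small test models and fixtures, built in code.

# pure exponential decay: y' = -theta1 * y, y(0) = 1, output y
decay_model <- function(y0 = 1) {
  dynamical_model(
    name = "decay", state_dim = 1L, param_dim = 1L, output_dim = 1L,
    rate = function(x, theta, u) -theta[1] * x,
    output_map = function(x, theta) x,
    init_map = function(theta) y0,
    param_names = "theta1"
  )
}

# linear ramp: y' = theta1, y(0) ~ 0, so y(t) = theta1 * t (+1e-9).
# Output is linear in theta, giving the conjugate Gaussian posterior oracle.
ramp_model <- function() {
  dynamical_model(
    name = "ramp", state_dim = 1L, param_dim = 1L, output_dim = 1L,
    rate = function(x, theta, u) theta[1],
    output_map = function(x, theta) x,
    init_map = function(theta) 1e-9,
    param_names = "theta1"
  )
}

# conjugate linear-Gaussian problem: noiseless data y = t at t = 1,2,3 with
# sigma = 1 and a natural-scale uniform prior; the posterior of theta is
# Normal(1, 1/14) truncated to the (wide) support.
conjugate_problem <- function() {
  d <- tibble::tibble(time = c(1, 2, 3), component = 1L,
                      value = c(1, 2, 3), sigma = 1)
  inference_problem(ramp_model(), d,
                    prior_spec(1e-3, 1e3, kind = "uniform"),
                    prediction_scenario(horizon = 3))
}

# hand-built trajectory on a grid (single component)
make_traj <- function(times, values, name = "y") {
  predq:::as_trajectory(times, matrix(values, ncol = 1), name)
}

# decay-model calibration data for coverage/recovery runs
decay_problem <- function(seed, theta_true = 1, times = c(0.5, 1, 1.5, 2, 3),
                          noise_fraction = 0.1) {
  m <- decay_model()
  sc <- prediction_scenario(horizon = max(times))
  d <- generate_dataset(m, theta_true, sc, times = times,
                        noise_fraction = noise_fraction, seed = seed)
  inference_problem(m, d, prior_spec(1e-2, 1e2), sc)
}
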