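# Independent oracles used across the test files.

# Fine-step RK4 integration of the Gompertz ODE dC/dt = a C ln(K/C),
# independent of the closed-form one-step solution in the package.
gompertz_ode_oracle <- function(C0, a, K, t, n_steps = 20000) {
  h <- t / n_steps
  f <- function(C) a * C * log(K / C)
  C <- C0
  for (i in seq_len(n_steps)) {
    k1 <- f(C)
    k2 <- f(C + h / 2 * k1)
    k3 <- f(C + h / 2 * k2)
    k4 <- f(C + h * k3)
    C <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  C
}

# Brute-force two-group log-rank statistic from explicit risk tables.
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1, 2), c(length(time_a), length(time_b)))
  ts <- sort(unique(time[event == 1]))
  O_a <- E_a <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == 1)
    if (n_a == 0 || n_a == n) next  # single group at risk: skip
    O_a <- O_a + d_a
    E_a <- E_a + d * n_a / n
    if (n > 1)
      V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (O_a - E_a)^2 / V
}

# Default truth and the five-arm observations used by calibration tests.
make_noiseless_obs <- function(params = model_params(), day = 18) {
  arms <- default_arms()
  lapply(names(arms), function(g)
    group_observation(g, arms[[g]],
                      simulate_tumor(params, arms[[g]], day)$C[day + 1],
                      day = day))
}

# Initialization at 1.5x truth, clipped into the fit bounds.
init_at_1p5 <- function(truth = model_params(),
                        free = c("a", "K", "gamma", "mu", "sigma")) {
  p <- unclass(truth)
  b <- idoRT:::default_param_bounds()
  for (nm in free)
    p[nm] <- min(max(1.5 * p[nm], b[[nm]][1]), b[[nm]][2])
  class(p) <- "model_params"
  p
}
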