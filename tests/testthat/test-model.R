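test_that("gompertz_step matches its examples and the ODE oracle", {
  # fixed point at carrying capacity; zero growth rate
  expect_equal(gompertz_step(50, a = 0.2, K = 50, dt = 1), 50)
  expect_equal(gompertz_step(7.3, a = 0, K = 100, dt = 5), 7.3)
  # closed form vs independent RK4 integration
  expect_equal(gompertz_step(1, a = 0.1, K = 100, dt = 1),
               gompertz_ode_oracle(1, 0.1, 100, 1), tolerance = 1e-8)
  expect_equal(round(gompertz_step(1, a = 0.1, K = 100, dt = 1), 3), 1.550)
  # oracle agreement over a (C, a, K) grid, rel. error < 1e-6
  for (C in c(0.01, 1, 25, 120)) for (a in c(0.05, 0.2, 0.6))
    for (K in c(150, 400)) {
      closed <- gompertz_step(C, a, K, dt = 1)
      ode <- gompertz_ode_oracle(C, a, K, 1)
      expect_lt(abs(closed - ode) / ode, 1e-6)
    }
  expect_error(gompertz_step(-1, 0.1, 100), "must be > 0")
  expect_error(gompertz_step(1, 0.1, 0), "must be > 0")
})

test_that("gompertz_step is monotone in C and stays within (0, K]", {
  C <- seq(0.1, 199, length.out = 50)
  out <- gompertz_step(C, a = 0.3, K = 200)
  expect_true(all(diff(out) > 0))
  expect_true(all(out > 0 & out <= 200))
})

test_that("lq_survival matches hand-evaluated values", {
  expect_equal(lq_survival(0, 0.2, 0.02), 1.0)
  expect_equal(lq_survival(8, 0.2, 0.02), exp(-1.6 - 1.28))
  expect_equal(round(lq_survival(8, 0.2, 0.02), 4), 0.0561)
  expect_equal(round(lq_survival(8, 0.3, 0.03), 4), 0.0133)
  # strictly decreasing in dose when alpha > 0
  expect_true(all(diff(lq_survival(0:10, 0.2, 0.02)) < 0))
  expect_error(lq_survival(-1, 0.2, 0.02), ">= 0")
})

test_that("daily_update follows the stated sub-step order", {
  # no growth, no RT, no immune pressure
  p <- model_params(a = 0, mu = 0)
  s <- daily_update(list(day = 0, C = 10, I = 0), p)
  expect_equal(s$C, 10)
  expect_equal(s$I, 0)
  expect_equal(s$day, 1)

  # immune decay then kill, 1-MT active
  p <- model_params(a = 0, gamma = 0.5, mu = 0.05, sigma = 1)
  s <- daily_update(list(day = 3, C = 10, I = 2), p, mt_active = TRUE)
  expect_equal(s$I, 1)
  expect_equal(s$C, 10 * exp(-0.1))

  # RT day: growth, LQ kill + recruitment, decay, unpotentiated kill;
  # cross-checked against composed gompertz_step / lq_survival calls
  p <- model_params(a = 0, alpha = 0.2, beta = 0.02, gamma = 0.5,
                    mu = 0.01, sigma = 0)
  s <- daily_update(list(day = 0, C = 10, I = 0), p, dose = 8)
  S <- lq_survival(8, 0.2, 0.02)
  expect_equal(s$I, 10 * (1 - S))
  expect_equal(s$C, 10 * S * exp(-0.01 * 10 * (1 - S)))
  expect_equal(round(s$C, 4), 0.5105, tolerance = 1e-3)
})

test_that("simulate_tumor reproduces closed-form growth and commuting kills", {
  # empty simulation
  p <- model_params(C0 = 0.01)
  tr <- simulate_tumor(p, treatment_schedule(), horizon = 0)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$C, 0.01)
  expect_equal(tr$I, 0)

  # control: closed-form Gompertz at day 18
  p <- model_params(a = 0.1, K = 200, C0 = 0.01, mu = 0)
  tr <- simulate_tumor(p, treatment_schedule(), horizon = 18)
  expect_equal(tr$C[19], 200 * (0.01 / 200)^exp(-0.1 * 18), tolerance = 1e-12)
  expect_equal(round(tr$C[19], 2), 38.91, tolerance = 0.02)

  # with a = 0 and mu = 0: final size is C0 * S^2, independent of interval
  S <- lq_survival(8, 0.2, 0.02)
  finals <- sapply(c(2, 5, 9), function(D) {
    p0 <- model_params(a = 0, K = 200, C0 = 10, mu = 0)
    sched <- treatment_schedule(rt_days = c(7, 7 + D), rt_dose = 8)
    simulate_tumor(p0, sched, horizon = 20)$C[21]
  })
  expect_equal(finals, rep(10 * S^2, 3), tolerance = 1e-12)
  expect_equal(round(finals[1], 4), 0.0315, tolerance = 1e-3)

  # schedule day beyond horizon errors
  expect_error(simulate_tumor(p, treatment_schedule(rt_days = 25), 18),
               "beyond the horizon")
})

test_that("without RT the immune level stays zero and growth is pure Gompertz", {
  p <- model_params()
  tr <- simulate_tumor(p, treatment_schedule(mt_days = 7:16), horizon = 40)
  expect_true(all(tr$I == 0))
  pure <- 200 * (0.01 / 200)^exp(-0.1 * tr$day)
  expect_equal(tr$C, pure, tolerance = 1e-10)
})

test_that("increasing sigma never increases the final tumor size", {
  sched <- default_arms()$mt_rt2_long
  sizes <- sapply(c(0, 0.3, 1, 3, 10), function(s) {
    p <- model_params(sigma = s)
    simulate_tumor(p, sched, horizon = 18)$C[19]
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("state stays nonnegative and finite over a 100-day horizon", {
  set.seed(7)
  for (i in 1:20) {
    p <- model_params(a = runif(1, 0, 0.5), K = runif(1, 50, 500),
                      C0 = runif(1, 0.001, 1), alpha = runif(1, 0, 0.5),
                      beta = runif(1, 0, 0.05), gamma = runif(1, 0, 0.99),
                      mu = runif(1, 0, 1), sigma = runif(1, 0, 5))
    sched <- treatment_schedule(rt_days = sort(sample(1:90, 3)),
                                rt_dose = 8, mt_days = 7:16)
    tr <- simulate_tumor(p, sched, horizon = 100)
    expect_true(all(is.finite(tr$C)) && all(is.finite(tr$I)))
    expect_true(all(tr$C >= 0) && all(tr$I >= 0))
  }
})

test_that("parameter validation enforces the stated bounds", {
  expect_error(model_params(gamma = 1), "\\[0, 1\\)")
  expect_error(model_params(C0 = 300, K = 200), "below the carrying capacity")
  expect_error(model_params(a = -0.1), ">= 0")
  expect_error(model_params(K = 0), "> 0")
  expect_error(treatment_schedule(rt_days = c(7, 7)), "unique")
  expect_error(treatment_schedule(rt_days = 7, rt_dose = 0), "> 0")
})
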