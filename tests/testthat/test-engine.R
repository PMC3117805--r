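test_that("pleural waveform matches the two forcing modes", {
  expect_equal(pleural_pressure(c(0, 1.3, 100), "fixed"), rep(-5, 3))
  tg <- seq(0, 7, by = 0.001)
  p <- pleural_pressure(tg, "sinusoid")
  expect_equal(min(p), -6, tolerance = 1e-6)
  expect_equal(max(p), -2, tolerance = 1e-6)
  expect_equal(pleural_pressure(1.234, "sinusoid"),
               pleural_pressure(1.234 + 7, "sinusoid"), tolerance = 1e-12)
})

test_that("Cash-Karp integrator reproduces closed-form solutions", {
  # exponential decay
  out <- integrate_cash_karp(function(t, y) -y, 1, c(0, 1),
                             rtol = 1e-8, atol = 1e-10)
  yT <- out$y[nrow(out$y), 1]
  expect_equal(yT, exp(-1), tolerance = 1e-7)

  # harmonic oscillator: energy drift stays near the tolerance over
  # 100 periods
  f <- function(t, y) c(y[2], -y[1])
  out <- integrate_cash_karp(f, c(1, 0), c(0, 100 * 2 * pi),
                             rtol = 1e-8, atol = 1e-10, hmax = 0.5)
  E <- out$y[, 1]^2 + out$y[, 2]^2
  expect_lt(max(abs(E - 1)), 1e-4)

  # tightening the tolerance reduces the global error
  err <- vapply(c(1e-4, 1e-8), function(rt) {
    o <- integrate_cash_karp(function(t, y) -y, 1, c(0, 1),
                             rtol = rt, atol = rt)
    abs(o$y[nrow(o$y), 1] - exp(-1))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("simulations are deterministic and conserve blood volume", {
  a <- run_scenario("control", duration = 8)
  b <- run_scenario("control", duration = 8)
  expect_identical(a$trajectory, b$trajectory)
  tv <- rowSums(a$trajectory[, 2:18])
  expect_lt((max(tv) - min(tv)) / a$params$total_blood_volume, 1e-6)
})

test_that("control scenario reaches a periodic steady state", {
  sim <- cached_sim("control")
  expect_true(sim$converged)
  bs <- sim$beat_stats
  n <- nrow(bs)
  expect_lt(max(abs(diff(bs$SV[(n - 3):n])) / bs$SV[(n - 3):(n - 1)]),
            0.005)
  # series circulation: both ventricles eject the same volume per beat
  s <- sim$summary
  expect_lt(abs(s$LVSV - s$RVSV) / s$LVSV, 0.01)
})

test_that("steady state is insensitive to initial-condition perturbations", {
  p <- default_parameters()
  base <- cached_sim("control")$summary
  set.seed(3)
  init <- initial_state(p)
  init[1:17] <- init[1:17] * runif(17, 0.9, 1.1)
  init["V_SV"] <- init["V_SV"] +
    (p$total_blood_volume - sum(init[1:17]))
  sim <- run_scenario("control", duration = 70, init = init,
                      keep = "window")
  expect_lt(abs(sim$summary$CO - base$CO) / base$CO, 0.005)
  expect_lt(abs(sim$summary$MSAP - base$MSAP) / base$MSAP, 0.005)
})

test_that("halving the tolerance barely moves the steady state", {
  co <- vapply(c(1e-6, 5e-7), function(rt) {
    run_scenario("control", duration = 50, rtol = rt,
                 keep = "window")$summary$CO
  }, numeric(1))
  expect_lt(abs(co[2] - co[1]) / co[1], 0.002)
})

test_that("result object methods expose the fitted quantities", {
  sim <- cached_sim("control")
  expect_s3_class(sim, "lvdd_sim")
  expect_output(print(sim), "scenario control")
  expect_identical(summary(sim), sim$summary)
  cf <- coef(sim)
  expect_equal(unname(cf["E_LV_ES"]), 3.5)
  expect_equal(unname(cf["lambda_SPT"]), 0.05)
  pdf(NULL)
  expect_silent(plot(sim))
  expect_silent(plot(sim, what = "pv"))
  dev.off()
})
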