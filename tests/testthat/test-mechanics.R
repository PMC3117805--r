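test_that("end-systolic law is linear with zero at V_d", {
  w <- list(E_ES = 3.5, V_d = 1, P_0 = 2, lambda = 0.025, V_0 = 1)
  expect_equal(end_systolic_pressure(w$V_d, w), 0)
  expect_equal(end_systolic_pressure(100, w), 346.5)
  expect_equal(end_systolic_pressure(100, w, alpha = 1.2),
               1.2 * end_systolic_pressure(100, w))
  expect_error(end_systolic_pressure(100, w, alpha = 0.5))
})

test_that("end-diastolic law is exponential with zero at V_0", {
  w <- list(E_ES = 3.5, V_d = 1, P_0 = 2, lambda = 0.025, V_0 = 1)
  expect_equal(end_diastolic_pressure(w$V_0, w), 0)
  expect_equal(end_diastolic_pressure(100, w), 2 * (exp(2.475) - 1),
               tolerance = 1e-10)
  # doubling the stiffness raises the whole curve above V_0
  w2 <- w; w2$lambda <- 0.05
  V <- seq(2, 200, by = 1)
  expect_true(all(end_diastolic_pressure(V, w2) >
                  end_diastolic_pressure(V, w)))
  # overflow guard
  expect_true(is.finite(end_diastolic_pressure(1e6, w)))
})

test_that("instantaneous wall pressure blends the two laws", {
  expect_equal(free_wall_pressure(1, 120, 8), 120)
  expect_equal(free_wall_pressure(0, 120, 8), 8)
  expect_equal(free_wall_pressure(0.5, 120, 8), 64)
  expect_error(free_wall_pressure(1.2, 120, 8))
})

test_that("pericardial pressure follows the exponential constraint", {
  peri <- list(P_0 = 0.5, lambda = 0.005, V_0 = 200)
  expect_equal(pericardial_pressure(200, -5, peri), -5)
  expect_equal(pericardial_pressure(400, -5, peri),
               0.5 * (exp(1) - 1) - 5, tolerance = 1e-10)
  V <- seq(100, 700, by = 10)
  expect_true(all(diff(pericardial_pressure(V, -5, peri)) > 0))
})

test_that("atrial pressure uses the weighted wall form plus pericardium", {
  la <- default_parameters()$walls$LA
  expect_equal(atrial_pressure(40, 0, la, -3), -3)
  expect_equal(atrial_pressure(50, 1, la, -3), 2.5 * 43 - 3)
  V <- seq(20, 90, by = 1)
  expect_true(all(diff(atrial_pressure(V, 0.3, la, -3)) > 0))
})

test_that("instantaneous elastance is the local dP/dV of the wall law", {
  w <- list(E_ES = 3.5, V_d = 1, P_0 = 2, lambda = 0.025, V_0 = 1)
  expect_equal(instantaneous_elastance(1, 80, w, alpha = 1.3), 1.3 * 3.5)
  expect_equal(instantaneous_elastance(0, w$V_0, w), w$lambda * w$P_0)
  # matches a centered finite difference of the wall pressure
  for (e in c(0.2, 0.7)) for (V in c(60, 120)) {
    h <- 1e-4
    num <- (free_wall_pressure(e, end_systolic_pressure(V + h, w),
                               end_diastolic_pressure(V + h, w)) -
            free_wall_pressure(e, end_systolic_pressure(V - h, w),
                               end_diastolic_pressure(V - h, w))) / (2 * h)
    expect_equal(instantaneous_elastance(e, V, w), num, tolerance = 1e-6)
  }
})

test_that("septal volume vanishes when the free-wall pressures balance", {
  p <- default_parameters()
  V_LV <- 50
  PL <- end_diastolic_pressure(V_LV, p$walls$LVF)
  # invert the RV passive law so both relaxed walls see the same pressure
  V_RV <- p$walls$RVF$V_0 +
    log1p(PL / p$walls$RVF$P_0) / p$walls$RVF$lambda
  s <- solve_septal_volume(V_LV, V_RV, 0, 0, 0.37, p)
  expect_lt(abs(s$V_SPT), 1e-8)
  expect_lt(abs(s$P_SPT), 1e-8)
})

test_that("septal solve agrees with a bisection oracle on random states", {
  p <- default_parameters()
  set.seed(42)
  n <- 200
  for (i in seq_len(n)) {
    VL <- runif(1, 30, 160); VR <- runif(1, 30, 160)
    e <- runif(3); al <- runif(1, 1, 1.5)
    got <- solve_septal_volume(VL, VR, e[1], e[2], e[3], p,
                               alpha = al)$V_SPT
    want <- septal_bisect_oracle(VL, VR, e[1], e[2], e[3], p, alpha = al)
    expect_lt(abs(got - want), 1e-6)
  }
})

test_that("septal solve is independent of its starting value", {
  p <- default_parameters()
  set.seed(7)
  for (i in 1:50) {
    VL <- runif(1, 40, 150); VR <- runif(1, 40, 150); e <- runif(3)
    cold <- solve_septal_volume(VL, VR, e[1], e[2], e[3], p,
                                V_SPT_init = 0)$V_SPT
    warm <- solve_septal_volume(VL, VR, e[1], e[2], e[3], p,
                                V_SPT_init = 40)$V_SPT
    expect_lt(abs(cold - warm), 1e-9)
  }
})

test_that("fixed-point iteration converges in about a dozen iterations", {
  sim <- cached_sim("control")
  tr <- sim$trajectory
  idx <- seq(1, nrow(tr), length.out = 40)
  p <- sim$params
  iters <- vapply(idx, function(i) {
    solve_septal_volume(tr$V_LV[i], tr$V_RV[i], tr$e_LVF[i], tr$e_RVF[i],
                        tr$e_SPT[i], p, alpha = tr$alpha[i],
                        V_SPT_init = 0)$iterations
  }, numeric(1))
  expect_gte(median(iters), 5)
  expect_lte(median(iters), 25)
})

test_that("trajectory pressures satisfy the chamber identities", {
  sim <- cached_sim("control")
  tr <- sim$trajectory
  # trans-septal pressure is exactly the chamber pressure difference
  expect_equal(tr$P_SPT, tr$P_LV - tr$P_RV, tolerance = 1e-12)
  # pericardial pressure re-derived from the recorded volumes
  pp <- pericardial_pressure(tr$V_LV + tr$V_RV + tr$V_LA + tr$V_RA +
                               sim$params$pericardium$V_fluid,
                             tr$P_PL, sim$params$pericardium)
  expect_equal(tr$P_PERI, pp, tolerance = 1e-10)
})
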