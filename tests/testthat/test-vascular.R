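test_that("compartment pressure is linear in volume", {
  comp <- list(C = 2.4, V_un = 51)
  expect_equal(compartment_pressure(51, comp, -5), -5)
  expect_equal(compartment_pressure(51 + 240, comp, 0), 100)
  V <- seq(0, 500, by = 10)
  expect_equal(diff(compartment_pressure(V, comp)),
               rep(10 / 2.4, length(V) - 1))
})

test_that("diode valve law is unidirectional and continuous", {
  mv <- list(R_open = 0.007)
  expect_equal(valve_flow(5, 12, mv), 0)
  expect_equal(valve_flow(12, 5, mv), 1000)
  dp <- seq(-0.01, 0.01, by = 1e-4)
  q <- valve_flow(dp, 0, mv)
  expect_true(all(abs(diff(q)) < 1e-4 / 0.007 + 1e-12))
  expect_equal(valve_flow(0, 0, mv), 0)
})

test_that("inertial flow derivative balances pressure and friction", {
  expect_equal(inertial_flow_derivative(200, 10, 7, 0.015, 0.0055), 0)
  expect_equal(inertial_flow_derivative(0, 1, 0, 0.015, 0.0055), 1 / 0.0055)
  expect_gt(inertial_flow_derivative(10, 5, 0, 0.015, 0.0055), 0)
  expect_lt(inertial_flow_derivative(1000, 5, 0, 0.015, 0.0055), 0)
})

random_state <- function() {
  s <- initial_state(default_parameters())
  s[1:17] <- s[1:17] * runif(17, 0.6, 1.4)
  s[18:20] <- rnorm(3, 0, 50)
  s[21:25] <- c(runif(1, 60, 130), runif(4, 0.2, 0.8))
  s
}

test_that("closed-loop derivatives conserve blood volume exactly", {
  p <- default_parameters()
  set.seed(11)
  for (i in 1:200) {
    d <- model_derivatives(random_state(), p, phase = runif(1, 0, 1),
                           period = 1.05)
    expect_lt(abs(sum(d$deriv[1:17])), 1e-10)
  }
})

test_that("right-hand side is a pure function of its inputs", {
  p <- default_parameters()
  s <- initial_state(p)
  a <- model_derivatives(s, p, phase = 0.3, period = 1.05)
  b <- model_derivatives(s, p, phase = 0.3, period = 1.05)
  expect_identical(a$deriv, b$deriv)
  expect_identical(a$aux, b$aux)
})

test_that("chamber volumes are frozen while all valves are closed", {
  p <- default_parameters()
  s <- initial_state(p)
  # isovolumic state: ventricles contracting against high arterial pressure,
  # atria near their zero-pressure volumes
  s["V_LA"] <- 40; s["V_RA"] <- 30
  d <- model_derivatives(s, p, phase = 0.06, period = 1.05)
  expect_equal(unname(d$aux["Q_M"]), 0)
  expect_equal(unname(d$aux["Q_AO"]), 0)
  expect_equal(unname(d$aux["Q_TC"]), 0)
  expect_equal(unname(d$aux["Q_PAV"]), 0)
  expect_equal(unname(d$deriv["V_LV"]), 0)
  expect_equal(unname(d$deriv["V_RV"]), 0)
})

test_that("thoracic compartments reference pleural pressure", {
  p <- default_parameters()
  s <- initial_state(p)
  # sinusoid pleural pressure: -6 mmHg at t = 0, -2 mmHg at t = 3.5 s
  a <- model_derivatives(s, p, t = 0, phase = 0.3, period = 1.05,
                         pleural = "sinusoid")
  b <- model_derivatives(s, p, t = 3.5, phase = 0.3, period = 1.05,
                         pleural = "sinusoid")
  expect_equal(unname(b$aux["P_VC"] - a$aux["P_VC"]), 4, tolerance = 1e-9)
  expect_equal(unname(b$aux["P_PA"] - a$aux["P_PA"]), 4, tolerance = 1e-9)
  expect_equal(unname(b$aux["P_SA"]), unname(a$aux["P_SA"]))
  expect_equal(unname(b$aux["P_SC"]), unname(a$aux["P_SC"]))
})

test_that("the pulmonary shunt diverts flow around the capillaries", {
  sim <- cached_sim("control")
  tr <- sim$trajectory
  expect_true(all(tr$Q_PS > 0))
  expect_lt(mean(tr$Q_PC), mean(tr$Q_PAr))
})
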