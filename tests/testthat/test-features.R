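test_that("valve events are located at flow-pulse edges", {
  fx <- make_fixture_trace(period = 1, n_beats = 2)
  ev <- detect_valve_events(fx)
  ao <- ev[ev$valve == "aortic" & ev$event == "open", "time"]
  ac <- ev[ev$valve == "aortic" & ev$event == "close", "time"]
  expect_equal(ao, c(0.06, 1.06), tolerance = 0.002)
  expect_equal(ac, c(0.34, 1.34), tolerance = 0.002)
  # zero-flow trace yields no events
  z <- fx
  z$trajectory$Q_AO <- 0
  evz <- detect_valve_events(z)
  expect_false("aortic" %in% evz$valve)
})

test_that("ventricular indices recover the fixture geometry", {
  fx <- make_fixture_trace(EDV = 120, ESV = 50, period = 1, n_beats = 4)
  vi <- ventricular_indices(fx, n_beats = 3)
  expect_equal(vi$LV$EDV, 120, tolerance = 1e-6)
  expect_equal(vi$LV$ESV, 50, tolerance = 1e-6)
  expect_equal(vi$LV$SV, 70, tolerance = 1e-6)
  expect_equal(vi$LV$EF, 70 / 120, tolerance = 1e-6)
  expect_equal(vi$HR, 60, tolerance = 1e-6)
  expect_equal(vi$CO, 70 * 60 / 1000, tolerance = 1e-6)
  expect_equal(vi$LV$ET, 0.28, tolerance = 0.005)
})

test_that("inflow pattern recovers E, A, E/A and the analytic DT", {
  fx <- make_fixture_trace(E = 80, A = 60, DT = 0.2, n_beats = 4)
  ip <- inflow_pattern(fx, "mitral", n_beats = 3)
  expect_equal(ip$E, 80, tolerance = 0.02 * 80)
  expect_equal(ip$A, 60, tolerance = 0.02 * 60)
  expect_equal(ip$EA, 80 / 60, tolerance = 0.01 * (80 / 60))
  # the descending limb is a straight line of slope -E/DT, so the
  # least-squares extrapolation recovers DT exactly
  expect_equal(ip$DT, 0.2, tolerance = 0.004)
  expect_equal(ip$PFR, 80, tolerance = 0.02 * 80)
  expect_gt(ip$RFF, ip$AFF)
  expect_equal(ip$RFF + ip$AFF, 1, tolerance = 1e-6)
})

test_that("venous D/S ratio integrates the flow windows", {
  fx <- make_fixture_trace(S_vol = 30, D_vol = 30, n_beats = 4)
  ds <- venous_ds_ratio(fx, "central", n_beats = 3)
  expect_equal(ds$DS, 1, tolerance = 0.02)
  fx2 <- make_fixture_trace(S_vol = 20, D_vol = 40, n_beats = 4)
  ds2 <- venous_ds_ratio(fx2, "central", n_beats = 3)
  expect_equal(ds2$DS, 2, tolerance = 0.05)
  expect_equal(ds2$S, 20, tolerance = 1)
  expect_equal(ds2$D, 40, tolerance = 2)
})

test_that("respiratory variation summarizes per-beat peaks", {
  fx <- make_fixture_trace(n_beats = 4, period = 1.75,
                           beat_scale = c(1, 0.9, 0.8, 0.9))
  expect_equal(respiratory_variation(fx, "Q_VC"), 20, tolerance = 0.1)
  fx0 <- make_fixture_trace(n_beats = 4, period = 1.75)
  expect_equal(respiratory_variation(fx0, "Q_VC"), 0, tolerance = 1e-6)
})

test_that("P-V loop area follows the shoelace formula", {
  # rectangular loop: V in [50, 120], P in [10, 100] -> area 6300
  rect <- data.frame(
    time = seq(0, 1, length.out = 401),
    V_LV = c(seq(120, 50, length.out = 100), rep(50, 100),
             seq(50, 120, length.out = 100), rep(120, 101)),
    P_LV = c(rep(100, 100), seq(100, 10, length.out = 100),
             rep(10, 100), seq(10, 100, length.out = 101)))
  beats <- data.frame(onset = 0, period = 1)
  loops <- pv_loop(rect, "LV", beats)
  expect_equal(loops[[1]]$area, 6300, tolerance = 0.02 * 6300)

  # simulated loop: closed, with width equal to the stroke volume
  sim <- cached_sim("control")
  lp <- pv_loop(sim)[[1]]
  expect_equal(max(lp$V) - min(lp$V), sim$summary$LVSV, tolerance = 1)
  expect_lt(abs(lp$V[1] - lp$V[length(lp$V)]), 2)
})

test_that("extractors are pure functions of the trajectory", {
  fx <- make_fixture_trace(n_beats = 3)
  expect_identical(inflow_pattern(fx, "mitral"), inflow_pattern(fx, "mitral"))
  expect_identical(venous_ds_ratio(fx, "central"),
                   venous_ds_ratio(fx, "central"))
})

test_that("fixture generation is deterministic", {
  expect_identical(make_fixture_trace(n_beats = 2),
                   make_fixture_trace(n_beats = 2))
})
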