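test_that("default parameter set carries the printed constants", {
  p <- default_parameters()
  expect_equal(p$valves["mitral", "R_open"], 0.007)
  expect_equal(p$valves["tricuspid", "R_open"], 0.0028)
  expect_equal(p$valves["aortic", "R_open"], 0.005)
  expect_equal(p$valves["pulmonic", "R_open"], 0.002)
  expect_equal(p$walls$LVF$E_ES, 3.5)
  expect_equal(p$walls$SPT$E_ES, 40)
  expect_equal(p$walls$RVF$E_ES, 0.34)
  expect_equal(p$walls$LVF$lambda, 0.025)
  expect_equal(p$walls$SPT$lambda, 0.05)
  expect_equal(p$walls$RVF$lambda, 0.01)
  expect_equal(p$walls$SPT$P_0, 1.11)
  expect_equal(p$walls$LA$E_ES, 2.5)
  expect_equal(p$walls$LA$lambda, 0.1)
  comp <- p$compartments
  expect_equal(comp$C[comp$name == "AOp"], 2.4)
  expect_equal(comp$C[comp$name == "PV"], 7.3)
  expect_equal(comp$L_out[comp$name == "AOp"], 0.0055)
  expect_equal(comp$R_out[comp$name == "SA"], 0.35)
  expect_equal(p$shunts$R_PS, 4.0)
  expect_equal(p$shunts$R_COR, 35)
  expect_equal(p$pericardium$P_0, 0.5)
  expect_equal(p$pericardium$lambda, 0.005)
  expect_equal(p$total_blood_volume, 5000)
  expect_length(validate_parameters(p), 0)
})

test_that("validation reports violations by name without raising", {
  p <- default_parameters()
  p$walls$LVF$lambda <- 0
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "LVF.*lambda")

  p <- default_parameters()
  p$compartments$C[p$compartments$name == "PC"] <- -1
  v <- validate_parameters(p)
  expect_length(v, 1)
  expect_match(v, "PC.*compliance")
})

test_that("scenario transforms install the printed disease values", {
  p <- default_parameters()

  r <- apply_scenario(p, scenario_config("R"))
  expect_equal(r$walls$LVF$lambda, 0.05)
  expect_equal(r$walls$SPT$lambda, 0.1)
  expect_equal(r$activations, p$activations)

  ir <- apply_scenario(p, scenario_config("IR"))
  for (wl in c("LVF", "SPT")) {
    a <- ir$activations[[wl]]
    expect_equal(a$A[6], 0.37)
    expect_equal(a$A[7], 0.249)
    expect_equal(a$B[7], 0.35)
    pk <- activation_value(seq(0, 1.2, by = 1e-3), a)
    expect_lt(abs(max(pk) - 1), 1e-3)
  }
  expect_equal(ir$activations$RVF, p$activations$RVF)
  expect_equal(ir$walls, p$walls)

  ns <- apply_scenario(p, scenario_config("R_NSPT"))
  expect_equal(ns$walls$LVF$lambda, 0.05)
  expect_equal(ns$walls$SPT$lambda, 0.05)

  cx <- apply_scenario(p, scenario_config("control", "increased"))
  expect_equal(cx$walls$LVF$E_ES, 5.6)
  expect_equal(cx$walls$SPT$E_ES, 64)
  expect_equal(cx$walls$RVF$E_ES, 0.34)

  expect_error(apply_scenario(p, structure(list(dd_type = "bogus",
                                                contractility = "normal",
                                                pleural = "fixed"),
                                           class = "scenario_config")),
               "unknown scenario")
})

test_that("scenario application is idempotent and composes", {
  p <- default_parameters()
  pn <- scenario_config("PN")
  once <- apply_scenario(p, pn)
  twice <- apply_scenario(once, pn)
  expect_equal(twice, once)

  # PN equals IR followed by R, field by field
  via <- apply_scenario(apply_scenario(p, scenario_config("IR")),
                        scenario_config("R"))
  expect_equal(via$walls, once$walls)
  expect_equal(via$activations, once$activations)

  # disease type and contractility commute
  a <- apply_scenario(p, scenario_config("PN", "increased"))
  b <- apply_scenario(apply_scenario(p, scenario_config("PN")),
                      scenario_config("control", "increased"))
  expect_equal(a$walls, b$walls)
  expect_equal(a$activations, b$activations)
})

test_that("parameters survive a YAML round trip exactly", {
  p <- default_parameters()
  path <- tempfile(fileext = ".yaml")
  write_parameters(p, path)
  q <- read_parameters(path)
  expect_equal(q$walls, p$walls, tolerance = 0)
  expect_equal(q$activations$LVF$A, p$activations$LVF$A, tolerance = 0)
  expect_equal(q$activations$LVF$scale, p$activations$LVF$scale,
               tolerance = 0)
  expect_equal(q$compartments$C, p$compartments$C, tolerance = 0)
  expect_equal(q$compartments$V_un, p$compartments$V_un, tolerance = 0)
  expect_equal(q$compartments$L_out, p$compartments$L_out, tolerance = 0)
  expect_equal(q$valves$R_open, p$valves$R_open, tolerance = 0)
  expect_equal(unlist(q$neural), unlist(p$neural), tolerance = 0)
  expect_equal(q$total_blood_volume, p$total_blood_volume)
  expect_length(validate_parameters(q), 0)
  unlink(path)
})

test_that("default initial state carries the configured blood volume", {
  p <- default_parameters()
  s <- initial_state(p)
  expect_equal(sum(s[1:17]), p$total_blood_volume)
  expect_true(all(s[1:17] > 0))
})
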