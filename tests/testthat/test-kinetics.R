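test_that("microbial rate laws are bilinear with correct coupling", {
  p <- kinetic_params()
  # DO = 0 shuts the aerobic laws off exactly
  r0 <- microbial_rates(list(ethanol = 46.07, acetate = 10, do = 0,
                             so4 = 291), p)
  expect_identical(r0[["do"]], 0)
  # below-gate: only the anaerobic laws act, HS production is 1:1 molar
  # with sulfate loss
  expect_equal(-r0[["so4"]] / 96.06, r0[["hs"]] / 33.073, tolerance = 1e-12)
  # aerobic ethanol consumption: molar bilinear arithmetic oracle
  ctx <- list(ethanol = 46.068, acetate = 0, do = 9.17, so4 = 291)
  r <- microbial_rates(ctx, p)
  expect_equal(r[["ethanol"]],
               -(0.24 * 1.0 * (9.17 / 31.998)) * 46.068, tolerance = 1e-12)
  # oxygen demand: 1 O2 per ethanol through the ethanol->acetate route
  expect_equal(r[["do"]] / 31.998, r[["ethanol"]] / 46.068, tolerance = 1e-12)
  # hard gate: DO above threshold kills the anaerobic laws exactly
  expect_identical(r[["so4"]], 0)
  expect_identical(r[["hs"]], 0)
  # zero concentrations give zero rates
  rz <- microbial_rates(list(ethanol = 0, acetate = 0, do = 0, so4 = 0), p)
  expect_true(all(rz == 0))
})

test_that("the DO gate is a hard switch by default and logistic on request", {
  p <- kinetic_params()
  expect_identical(do_gate_factor(9.17, p), 0)
  expect_identical(do_gate_factor(2.0, p), 1)
  expect_identical(do_gate_factor(0.5, p), 1)
  ps <- kinetic_params(gate_sharpness = 0.2)
  g <- do_gate_factor(seq(0, 9, by = 0.1), ps)
  expect_true(all(diff(g) <= 0))            # smooth monotone ramp
  expect_equal(do_gate_factor(2, ps), 0.5)
  expect_gt(do_gate_factor(1, ps), 0.99)
})

test_that("calcite law is zero at saturation and matches its coefficient form", {
  st <- solve_speciation(c(Ca = 2e-3, CO3 = 2e-3, Na = 2e-3, Cl = 2e-3),
                         mode = "fixed_ph", pH = 8.4)
  expect_gte(saturation_index(st, "calcite"), 0)
  p <- kinetic_params(calcite_mass = 10, calcite_area = 0.05,
                      calcite_coeffs = c(5e3, 3e2, 1e-8))
  expect_identical(calcite_rate(st, p), 0)   # never precipitates via the law
  # undersaturated acid water dissolves; rate equals hand evaluation
  st2 <- solve_speciation(c(Ca = 1e-5, CO3 = 1e-5, Na = 2e-5),
                          mode = "fixed_ph", pH = 5.5)
  om <- 10^saturation_index(st2, "calcite")
  k6 <- 5e3 * st2$conc[["H"]] * 1.008 + 3e2 * st2$conc[["H2CO3"]] * 44.009 +
    1e-8 * 1000
  expect_equal(calcite_rate(st2, p),
               k6 * 0.05 * 10 * (1 - om)^(2 / 3) / 100.087, tolerance = 1e-12)
  expect_gt(calcite_rate(st2, p), 0)
  # the published negative coefficient triple clips to an inert surface
  expect_identical(calcite_rate(st2, kinetic_params(calcite_mass = 10)), 0)
})

test_that("sulfate-only decay reproduces the closed-form exponential", {
  tt <- setNames(numeric(14), default_thermo_db()$components$name)
  tt["SO4"] <- 291 / 96060
  tt["Na"] <- 2 * tt[["SO4"]]
  cl <- cell_state(tt)
  p <- kinetic_params()     # gate open since DO = 0
  out <- integrate_cell(cl, dt = 67500, p)
  expect_equal(out$totals[["SO4"]] * 96060, 291 * exp(-5e-6 * 67500),
               tolerance = 1e-6)
  expect_equal(291 * exp(-5e-6 * 67500), 207.6, tolerance = 1e-3)
  # HS produced equals sulfate consumed, in moles
  expect_equal(out$totals[["HS"]], tt[["SO4"]] - out$totals[["SO4"]],
               tolerance = 1e-10)
  # closed form holds for other k5 and t on the sulfate-only system
  for (k5 in c(1e-6, 2e-5)) {
    p2 <- kinetic_params(k5 = k5)
    o2 <- integrate_cell(cell_state(tt), dt = 30000, p2)
    expect_equal(o2$totals[["SO4"]], tt[["SO4"]] * exp(-k5 * 30000),
                 tolerance = 1e-6)
  }
})

test_that("a cell with all rates zero is unchanged", {
  tt <- influent_totals_fixture()
  # remove the supersaturated copper so no equilibrium transfer happens
  tt[["Cu"]] <- 0
  cl <- cell_state(tt)
  out <- integrate_cell(cl, dt = 5000, dead_kinetics())
  expect_equal(out$totals[names(tt)], tt, tolerance = 1e-10)
  expect_true(all(out$minerals == 0))
  expect_error(integrate_cell(cl, dt = 0, dead_kinetics()), "dt")
})

test_that("elemental inventories are conserved across integrate_cell", {
  tt <- influent_totals_fixture()
  cl <- cell_state(tt)
  p <- kinetic_params()
  for (i in 1:6) {
    before <- cell_element_totals(cl$totals, cl$minerals)
    cl <- integrate_cell(cl, dt = 5625, p)
    after <- cell_element_totals(cl$totals, cl$minerals)
    for (el in c("S", "Ca", "Zn", "Cu", "Cd", "Si")) {
      expect_lt(abs(after[[el]] - before[[el]]) / max(before[[el]], 1e-12),
                1e-8)
    }
    # carbon enters TIC from ethanol/acetate: total C conserved
    expect_lt(abs(after[["C"]] - before[["C"]]) / before[["C"]], 1e-8)
  }
})

test_that("operator splitting error is first order in dt", {
  # frozen-state calcite dissolution is the first-order splitting piece:
  # its rate is evaluated at the step's entry state
  tt <- c(Ca = 1e-5, CO3 = 1e-5, Na = 3e-5, H = 1.6e-5)
  p <- kinetic_params(calcite_mass = 10, calcite_area = 0.05,
                      calcite_coeffs = c(0.006, 2e-4, 0))
  run <- function(dt, nstep) {
    cl <- cell_state(tt)
    cl <- integrate_cell(cl, 1, p)   # seed the cached state
    for (i in seq_len(nstep)) cl <- integrate_cell(cl, dt, p)
    cl$totals[["Ca"]]
  }
  ref <- run(500, 32)
  e1 <- abs(run(8000, 2) - ref)
  e2 <- abs(run(4000, 4) - ref)
  # halving dt roughly halves the splitting error
  expect_lt(e2, e1)
  expect_gt(e1 / e2, 1.4)
  expect_lt(e1 / e2, 3.5)
})

test_that("kinetic parameter validation rejects bad inputs", {
  expect_error(kinetic_params(k1 = -1), ">= 0")
  expect_error(kinetic_params(do_gate = -1), "do_gate")
  expect_error(kinetic_params(time_unit = 0), "time_unit")
  expect_error(kinetic_params(calcite_coeffs = 1:2), "length 3")
})
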