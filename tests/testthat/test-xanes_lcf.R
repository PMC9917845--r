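make_ramp <- function() {
  e <- seq(9600, 9760, by = 2)
  xanes_spectrum(e, 0.01 * (e - 9600), label = "ramp")
}

test_that("spectrum constructor enforces its invariants", {
  e <- seq(9600, 9760, by = 2)
  expect_error(xanes_spectrum(e, rep(1, 10)), "equal length")
  expect_error(xanes_spectrum(e[1:10], rep(1, 10)), ">= 20 points")
  expect_error(xanes_spectrum(rev(e), rep(1, length(e))),
               "strictly increasing")
})

test_that("regridding is exact for identity, linear ramps, and midpoints", {
  s <- make_ramp()
  expect_equal(regrid(s, s$energy)$absorption, s$absorption)
  # linear ramp: interpolation exact at arbitrary interior energies
  tg <- seq(9601.3, 9733.9, length.out = 25)
  expect_equal(regrid(s, tg)$absorption, 0.01 * (tg - 9600),
               tolerance = 1e-12)
  # random spectrum at midpoints equals two-point averages
  set.seed(5)
  r <- xanes_spectrum(s$energy, runif(length(s$energy)), label = "rand")
  mid <- (r$energy[-1] + r$energy[-length(r$energy)]) / 2
  expect_equal(regrid(r, mid)$absorption,
               (r$absorption[-1] + r$absorption[-length(r$absorption)]) / 2,
               tolerance = 1e-12)
  expect_error(regrid(s, c(9590, 9700)), "beyond")
})

test_that("edge normalization is idempotent and scale invariant", {
  e <- seq(9609, 9759, by = 0.5)
  step <- 0.5 + atan((e - 9659) / 2) / pi
  s <- xanes_spectrum(e, step, label = "step")
  n1 <- normalize_edge(s)
  # already-normalized ideal step: unchanged up to the line fits
  expect_lt(max(abs(n1$absorption - s$absorption)), 0.08)
  # scaling by 7 is removed entirely
  s7 <- xanes_spectrum(e, 7 * step, label = "x7")
  expect_equal(normalize_edge(s7)$absorption, n1$absorption,
               tolerance = 1e-9)
  # constructed edge with known pre/post slopes: step recovered
  a <- 0.3 + 0.001 * (e - 9609) + 2.5 * step
  s2 <- xanes_spectrum(e, a, label = "sloped")
  n2 <- normalize_edge(s2)
  post <- n2$energy > 9659 + 40
  expect_equal(mean(n2$absorption[post]), 1, tolerance = 0.05)
  flat <- xanes_spectrum(e, rep(1, length(e)), label = "flat")
  expect_error(normalize_edge(flat), "zero edge step")
})

test_that("r_factor matches hand arithmetic and its invariances", {
  e <- seq(1, 25, by = 1)
  t3 <- xanes_spectrum(e, c(1, 2, 3, rep(1, 22)), label = "t")
  f3 <- xanes_spectrum(e, c(1.1, 1.8, 3.2, rep(1, 22)), label = "f")
  byhand <- (0.1^2 + 0.2^2 + 0.2^2) / sum(c(1, 2, 3, rep(1, 22))^2)
  expect_equal(r_factor(t3, f3), byhand, tolerance = 1e-12)
  expect_identical(r_factor(t3, t3), 0)
  sc <- function(s, c) xanes_spectrum(s$energy, c * s$absorption, label = "s")
  expect_equal(r_factor(sc(t3, 3), sc(f3, 3)), byhand, tolerance = 1e-12)
  z <- xanes_spectrum(e, rep(0, 25), label = "z")
  expect_error(r_factor(z, f3), "zero-norm")
})

test_that("LCF recovers noise-free mixtures to numerical precision", {
  refs <- generate_reference_spectra("Zn", n_refs = 3, seed = 11)
  w <- c(0.60, 0.30, 0.10)
  mixt <- mix_spectra(refs, w)
  fit <- lcf_fit(mixt, refs)
  expect_lt(max(abs(fit$fractions - w)), 1e-6)
  expect_lt(fit$r_factor, 1e-12)
  # oracle: exact linear algebra on the design matrix over the fit window
  grid <- mixt$energy[mixt$energy >= 9659 - 20 & mixt$energy <= 9659 + 80]
  A <- vapply(refs, function(r) regrid(r, grid)$absorption,
              numeric(length(grid)))
  exact <- qr.solve(A, regrid(mixt, grid)$absorption)
  expect_equal(unname(fit$fractions), exact, tolerance = 1e-8)
})

test_that("LCF self-fit, sum constraint, and degenerate inputs behave", {
  refs <- generate_reference_spectra("Cu", n_refs = 3, seed = 4)
  self <- lcf_fit(refs[[2]], refs)
  expect_equal(unname(self$fractions), c(0, 1, 0), tolerance = 1e-8)
  expect_lt(self$r_factor, 1e-12)
  # unconstrained fractions may sum away from 1
  mixt <- mix_spectra(refs, c(0.7, 0.2, 0.2))
  free <- lcf_fit(mixt, refs)
  expect_gt(sum(free$fractions), 1.05)
  con <- lcf_fit(mixt, refs, sum_constrained = TRUE)
  expect_equal(sum(con$fractions), 1, tolerance = 1e-9)
  # collinear references trigger a condition-number warning
  twin <- refs[c(1, 1, 2)]
  expect_warning(lcf_fit(mix_spectra(refs[1:2], c(0.5, 0.5)), twin),
                 "collinear")
})

test_that("fraction error grows roughly linearly with additive noise", {
  refs <- generate_reference_spectra("Zn", n_refs = 3, seed = 21)
  w <- c(0.5, 0.3, 0.2)
  err <- sapply(c(0.002, 0.02), function(sg) {
    e <- replicate(8, {
      m <- mix_spectra(refs, w, noise_sd = sg,
                       seed = sample.int(1e6, 1))
      max(abs(lcf_fit(m, refs)$fractions - w))
    })
    mean(e)
  })
  expect_gt(err[2] / err[1], 3)   # ~10x noise, allow slack
  expect_lt(err[1], 0.02)
})

test_that("reported fractions follow the unconstrained-sum convention", {
  # representation check: fractions as published for the 0.2-0.4 m zinc
  # residue are storable without any sum-to-100 constraint
  row <- structure(list(fractions = c(ZnS = 3.18, ZnSO4 = 90.7,
                                      ZnCO3 = 3.75) / 100,
                        r_factor = 0.0031, fit_range = c(9639, 9739),
                        sum_constrained = FALSE),
                   class = "lcf_result")
  expect_false(isTRUE(all.equal(sum(row$fractions), 1)))
  expect_true(all(row$fractions >= 0) && row$r_factor >= 0)
  expect_output(print(row), "R-factor")
})
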