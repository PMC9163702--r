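# Hyperchromicity melting analysis: baselines, ssDNA fraction, Tm.

make_sigmoid <- function(tm = 62, width = 2, low = 1.0, high = 1.3,
                         grid = default_temperature_grid()) {
  absorbance_series(grid, low + (high - low) * stats::plogis((grid - tm) / width))
}

test_that("baseline fits recover exact plateau lines", {
  grid <- default_temperature_grid()
  a <- make_sigmoid()
  a$a260[1:3] <- 1.0; a$a260[14:16] <- 1.3      # force flat plateaus
  bl <- fit_baselines(a)
  expect_equal(unname(bl$lower), c(0, 1.0), tolerance = 1e-12)
  expect_equal(unname(bl$upper), c(0, 1.3), tolerance = 1e-12)

  # sloped but exactly collinear plateau points are recovered exactly
  a2 <- a
  a2$a260 <- a2$a260 + 0.001 * grid
  bl2 <- fit_baselines(a2)
  expect_equal(bl2$lower[["slope"]], 0.001, tolerance = 1e-12)
  expect_equal(bl2$upper[["slope"]], 0.001, tolerance = 1e-12)

  expect_error(fit_baselines(a, lower_window = c(20, 40),
                             upper_window = c(35, 90)), "overlap")
  expect_error(fit_baselines(a, lower_window = c(20, 21),
                             upper_window = c(75, 90)), "fewer than 2")
  # a window reaching into the transition triggers a warning
  expect_warning(fit_baselines(a, lower_window = c(20, 62),
                               upper_window = c(75, 90)), "transition")
})

test_that("noisy baselines stay close to truth inside their windows", {
  set.seed(5)
  worst <- 0
  for (i in 1:20) {
    a <- make_sigmoid()
    a$a260 <- a$a260 + rnorm(16, sd = 0.002)
    bl <- fit_baselines(a)
    # evaluate each fitted line at its window midpoint, where the
    # three-point fit is most precise
    lo_err <- abs(bl$lower[["intercept"]] +
                    bl$lower[["slope"]] * mean(bl$lower_window) - 1.0)
    hi_err <- abs(bl$upper[["intercept"]] +
                    bl$upper[["slope"]] * mean(bl$upper_window) - 1.3)
    worst <- max(worst, lo_err, hi_err)
  }
  expect_lt(worst, 0.005)
})

test_that("ssDNA fraction normalises between the baselines", {
  grid <- default_temperature_grid()
  a <- make_sigmoid()
  bl <- structure(list(lower = c(slope = 0, intercept = 1.0),
                       upper = c(slope = 0, intercept = 1.3),
                       lower_window = c(20, 40), upper_window = c(75, 90)),
                  class = "baseline_fit")
  on_lower <- absorbance_series(grid, rep(1.0, 16))
  expect_true(all(ssdna_fraction(on_lower, bl)$fraction == 0))
  midway <- absorbance_series(grid, rep(1.15, 16))
  expect_equal(ssdna_fraction(midway, bl)$fraction, rep(0.5, 16))
  # degenerate baselines are rejected
  bad <- bl; bad$upper <- c(slope = 0, intercept = 0.9)
  expect_error(ssdna_fraction(a, bad), "upper baseline")
  # overshoot is clipped but kept raw
  over <- absorbance_series(grid, rep(1.35, 16))
  fc <- ssdna_fraction(over, bl)
  expect_true(all(fc$fraction == 1))
  expect_true(all(fc$raw > 1))
})

test_that("Tm interpolates linearly between the bracketing points", {
  expect_equal(melting_temperature(
    list(temperature = c(60, 62), fraction = c(0.4, 0.6)))$tm, 61.0)
  expect_equal(melting_temperature(
    list(temperature = c(60, 62), fraction = c(0.45, 0.65)))$tm, 60.5)
  expect_error(melting_temperature(
    list(temperature = c(60, 62), fraction = c(0.1, 0.3))), "does not melt")
  # multiple crossings: steepest upward crossing wins, flag set
  mc <- melting_temperature(list(temperature = 1:6,
                                 fraction = c(0.2, 0.6, 0.4, 0.45, 0.9, 1)))
  expect_true(mc$multiple_crossings)
  expect_equal(mc$bracket, c(4L, 5L))
  # clean sigmoid: unique crossing, no flag
  ok <- melting_temperature(ssdna_fraction(make_sigmoid(), fit_baselines(make_sigmoid())))
  expect_false(ok$multiple_crossings)
})

test_that("melting analysis is invariant to affine absorbance transforms", {
  a <- make_sigmoid(tm = 63.2)
  base <- melt_analysis(a)
  scaled <- absorbance_series(a$temperature, 3.7 * a$a260 - 0.4)
  expect_equal(melt_analysis(scaled)$tm, base$tm, tolerance = 1e-9)
  expect_equal(melt_analysis(scaled)$fraction$fraction,
               base$fraction$fraction, tolerance = 1e-9)
})

test_that("grid refinement moves Tm by less than the coarse step", {
  coarse <- seq(40, 80, 4)
  fine <- seq(40, 80, 2)
  for (tm in c(55.7, 61.3, 66.1)) {
    t_coarse <- melting_temperature(list(
      temperature = coarse, fraction = stats::plogis((coarse - tm) / 2)))$tm
    t_fine <- melting_temperature(list(
      temperature = fine, fraction = stats::plogis((fine - tm) / 2)))$tm
    expect_lt(abs(t_coarse - t_fine), 4)
  }
})

test_that("Tm is recovered across random noiseless transitions", {
  set.seed(21)
  grid <- default_temperature_grid()
  for (i in 1:100) {
    tm <- runif(1, 55, 70)
    f <- stats::plogis((grid - tm) / 2)
    expect_lt(abs(melting_temperature(
      list(temperature = grid, fraction = f))$tm - tm), 0.2)
  }
})

test_that("extracted ssDNA fraction tracks the generator truth", {
  # per-point noise is 0.002/0.3 OD ~ 0.7% of the fraction scale, so the
  # extracted curve should track p(S3) to about 2-3 sigma pointwise and
  # much tighter on average
  for (s in 1:5) {
    ds <- simulate_series(generator_config("gdm_sulfate", seed = s))
    ma <- melt_analysis(ds$absorbance)
    dev <- abs(ma$fraction$fraction - ds$truth$profiles$S3)
    expect_lt(mean(dev), 0.015)
    expect_lt(max(dev), 0.05)
  }
})
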