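# Four-state thermodynamic model: free enthalpy, populations, fitting.

topo4 <- state_topology()

test_that("free enthalpy reproduces hand-evaluated values", {
  # entropy-anchored parameters give dG(T0) = 0 exactly
  tp <- transition_params("S1", "S2", dH0 = 120,
                          T0 = celsius_to_kelvin(36.4), dCp = 16.5)
  expect_lt(abs(gibbs_free_energy(tp, tp$T0)), 1e-12)

  # van't Hoff limit: dG = dH0 - T dS0 when dCp = 0
  tp2 <- transition_params("A", "B", dH0 = 100, dS0 = 0.3, T0 = 300, dCp = 0)
  expect_equal(gibbs_free_energy(tp2, 300), 10)

  # chloride S1 -> S2' at 23 C, evaluated independently by hand from
  # dG = [dH0 + dCp (T - T0)] - T [dH0/T0 + dCp ln(T/T0)]
  tp3 <- reference_params("chloride")[["S1->S2p"]]
  expect_equal(gibbs_free_energy(tp3, 296.15), 14.509, tolerance = 1e-4)

  expect_error(gibbs_free_energy(tp3, -5), "positive")
})

test_that("equal-population temperature is dH0/dS0 on the parameter scale", {
  tab <- reference_param_table()
  s12 <- tab[tab$anion == "sulfate" & tab$to == "S2", ]
  tp <- transition_params(s12$from, s12$to, dH0 = s12$dH0, dS0 = s12$dS0_printed,
                          T0 = celsius_to_kelvin(s12$T0_C))
  expect_equal(equal_population_temperature(tp), 38.0, tolerance = 1e-3)

  c23 <- tab[tab$anion == "chloride" & tab$to == "S3", ]
  tp2 <- transition_params(c23$from, c23$to, dH0 = c23$dH0,
                           dS0 = c23$dS0_printed,
                           T0 = celsius_to_kelvin(c23$T0_C))
  expect_equal(equal_population_temperature(tp2), 58.2, tolerance = 1e-2)

  expect_equal(equal_population_temperature(
    transition_params("A", "B", dH0 = 2, dS0 = 2, T0 = 300)), 1)
  expect_error(equal_population_temperature(
    transition_params("A", "B", dH0 = 2, dS0 = 0, T0 = 300)), "dS0")
})

test_that("state populations follow the Boltzmann partition over the topology", {
  # a single active transition gives 50/50 at its T0
  topo2 <- state_topology(c("S1", "S2"), list(c("S1", "S2")))
  tp <- transition_params("S1", "S2", dH0 = 200, T0 = 320, dCp = 4)
  p <- state_populations(topo2, list(tp), kelvin_to_celsius(320))
  expect_equal(unname(p[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  # all dG = 0 -> uniform populations over four states
  null_tp <- function(from, to)
    transition_params(from, to, dH0 = 0, dS0 = 0, T0 = 300, dCp = 0)
  p4 <- state_populations(topo4, list(null_tp("S1", "S2"),
                                      null_tp("S1", "S2p"),
                                      null_tp("S2", "S3")), 25)
  expect_equal(unname(p4[1, ]), rep(0.25, 4), tolerance = 1e-12)

  # frozen system: hugely unfavourable transitions leave everything in S1
  frozen <- function(from, to)
    transition_params(from, to, dH0 = 1e5, dS0 = 0, T0 = 300, dCp = 0)
  pf <- state_populations(topo4, list(frozen("S1", "S2"), frozen("S1", "S2p"),
                                      frozen("S2", "S3")), c(20, 50, 90))
  expect_equal(unname(pf[, "S1"]), rep(1, 3))
})

test_that("log-space evaluation matches naive weights where those are finite", {
  pars <- reference_params("sulfate")
  tt <- seq(20, 90, 7)
  p <- state_populations(topo4, pars, tt)
  R <- 8.314e-3
  for (i in seq_along(tt)) {
    TK <- celsius_to_kelvin(tt[i])
    K12 <- exp(-gibbs_free_energy(pars[["S1->S2"]], TK) / (R * TK))
    K12p <- exp(-gibbs_free_energy(pars[["S1->S2p"]], TK) / (R * TK))
    K23 <- exp(-gibbs_free_energy(pars[["S2->S3"]], TK) / (R * TK))
    w <- c(1, K12, K12p, K12 * K23)
    expect_equal(unname(p[i, ]), w / sum(w), tolerance = 1e-12)
  }
})

test_that("population curves close to one and handle both anions", {
  for (anion in c("chloride", "sulfate")) {
    pc <- population_curve(topo4, reference_params(anion), seq(15, 95, 0.5))
    sums <- rowSums(pc[, topo4$states])
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(as.matrix(pc[, topo4$states]) >= 0))
  }
})

test_that("dCp = 0 gives van't Hoff linearity of ln K in 1/T", {
  tp <- transition_params("S1", "S2", dH0 = 250, T0 = 330, dCp = 0)
  TK <- seq(280, 370, 2)
  lnK <- -gibbs_free_energy(tp, TK) / (8.314e-3 * TK)
  fit <- stats::lm(lnK ~ I(1 / TK))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lnK - mean(lnK))^2)
  expect_gt(r2, 1 - 1e-12)
})

test_that("large dCp renders the intact fraction non-monotonic below 45 C", {
  pc <- population_curve(topo4, reference_params("chloride"), seq(20, 45, 1))
  d <- diff(pc$S1)
  expect_true(any(d > 0) && any(d < 0))  # rise and decline
  # the rise peaks between the two population inversions
  expect_gt(pc$S1[which.max(pc$S1)], pc$S1[1])
})

test_that("single-transition population curves cross at that transition's T0", {
  pars <- reference_params("sulfate")
  frozen <- transition_params("S2", "S3", dH0 = 1e5, dS0 = 0, T0 = 300)
  only12 <- list(pars[["S1->S2"]],
                 transition_params("S1", "S2p", dH0 = 1e5, dS0 = 0, T0 = 300),
                 frozen)
  T0C <- kelvin_to_celsius(pars[["S1->S2"]]$T0)
  p <- state_populations(topo4, only12, T0C)
  expect_equal(unname(p[1, "S1"]), unname(p[1, "S2"]), tolerance = 1e-12)
})

test_that("noiseless profiles return the generating parameters", {
  grid <- default_temperature_grid()
  for (anion in c("chloride", "sulfate")) {
    pars <- reference_params(anion)
    fit <- fit_thermo_model(population_curve(topo4, pars, grid),
                            topology = topo4)
    expect_true(fit$converged)
    for (key in names(pars)) {
      expect_lt(abs(fit$params[[key]]$dH0 - pars[[key]]$dH0) /
                  pars[[key]]$dH0, 0.01)
      expect_lt(abs(fit$params[[key]]$T0 - pars[[key]]$T0), 0.1)
      expect_lt(abs(fit$params[[key]]$dCp - pars[[key]]$dCp) /
                  abs(pars[[key]]$dCp), 0.05)
    }
  }
})

test_that("freezing dCp at zero degrades the fit of dCp-generated profiles", {
  grid <- default_temperature_grid()
  pc <- population_curve(topo4, reference_params("chloride"), grid)
  free_fit <- fit_thermo_model(pc, topology = topo4)
  frozen_fit <- fit_thermo_model(pc, topology = topo4,
                                 lower = c(dH0 = 1, T0 = NA, dCp = -1e-9),
                                 upper = c(dH0 = 5000, T0 = NA, dCp = 1e-9))
  expect_gt(frozen_fit$residual_rms, free_fit$residual_rms)
})

test_that("fit tolerates closure noise in the profiles", {
  grid <- default_temperature_grid()
  pars <- reference_params("sulfate")
  truth <- as.matrix(population_curve(topo4, pars, grid)[, topo4$states])
  set.seed(11)
  errs <- t(replicate(20, {
    P <- pmax(truth + matrix(rnorm(length(truth), sd = 0.01), nrow(truth)), 0)
    P <- P / rowSums(P)
    fit <- fit_thermo_model(P, grid, topology = topo4)
    c(T0 = max(abs(vapply(names(pars), function(k)
        fit$params[[k]]$T0 - pars[[k]]$T0, numeric(1)))),
      dH0 = max(abs(vapply(names(pars), function(k)
        (fit$params[[k]]$dH0 - pars[[k]]$dH0) / pars[[k]]$dH0, numeric(1)))),
      sign_ok = all(vapply(names(pars), function(k)
        sign(fit$params[[k]]$dCp) == sign(pars[[k]]$dCp), logical(1))))
  }))
  expect_lt(median(errs[, "T0"]), 1)
  expect_lt(median(errs[, "dH0"]), 0.10)
  expect_gte(mean(errs[, "sign_ok"]), 0.9)
})

test_that("topology validation rejects graphs not rooted at the reference", {
  expect_error(state_topology(c("S1", "S2", "S3"),
                              list(c("S2", "S3"), c("S3", "S2"))),
               "exactly once|rooted")
  expect_error(state_topology(c("S1", "S2"), list(c("S1", "S2"),
                                                  c("S1", "S2"))),
               "exactly one")
})
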