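test_that("a 3-node circuit builds a 9-species reaction system", {
  sys <- build_system(c(-10, -12, -14, -16, -18, -20))
  expect_length(rnacircgen:::default_state(sys), 9L)
  expect_length(sys$k_r, 6L)
  expect_error(build_system(c(-10, -12)), "6 finite interaction energies")
  # compiled right-hand side agrees with the independent R-level one:
  # integrate the same rates through both code paths
  sysR <- make_reaction_system(sys$k_f, sys$k_r,
                               production = sys$production,
                               degradation = sys$degradation)
  sv <- solver_config(t_max = 1000, n_grid = 40)
  trC <- integrate_phase(sys, default_state(sys), sv)
  trR <- integrate_phase(sysR, default_state(sys), sv)
  expect_equal(trC$Y, trR$Y, tolerance = 1e-5)
})

test_that("closed systems conserve per-node copy totals", {
  # no production, no degradation: free_i + sum_j C_ij (self counted twice)
  # is constant along any trajectory
  for (s in 1:5) {
    set.seed(s)
    sys <- build_system(runif(6, -30, 0))
    sys$production <- rep(0, 3)
    sys$degradation <- 0
    tr <- integrate_phase(sys, default_state(sys),
                          solver_config(t_max = 1e4, n_grid = 80))
    tot <- function(i, cols, self) tr$Y[, i] + rowSums(
      tr$Y[, 3 + cols, drop = FALSE]) + tr$Y[, 3 + self]
    totals <- cbind(tot(1, c(1, 2, 3), 1), tot(2, c(2, 4, 5), 4),
                    tot(3, c(3, 5, 6), 6))
    rel_err <- abs(sweep(totals, 2, totals[1, ]) ) / totals[1, ]
    expect_lt(max(rel_err), 1e-6)
    expect_gt(min(tr$Y), -1e-9)  # nonnegative trajectories
  }
})

test_that("inert energies reduce to independent birth-death kinetics", {
  # all energies at 0: binding is negligible and each free RNA follows
  # x(t) = p/d + (x0 - p/d) exp(-d t)
  sys <- build_system(rep(0, 6))
  y0 <- setNames(c(50, 120, 80, rep(0, 6)), rnacircgen:::SPECIES_NAMES)
  tr <- integrate_phase(sys, y0, solver_config(t_max = 1000, n_grid = 60))
  p <- sys$production[1]; d <- sys$degradation
  for (i in 1:3) {
    analytic <- p / d + (y0[i] - p / d) * exp(-d * tr$time)
    expect_equal(tr$Y[, i], unname(analytic), tolerance = 5e-3)
  }
})

test_that("steady-state detection returns fixed points and equilibria", {
  # non-interacting birth-death settles at p/d = 100 copies
  sys0 <- make_reaction_system(k_f = 0, k_r = 0)
  ss <- simulate_steady_state(sys0, setNames(c(10, 200, 100, rep(0, 6)),
                                             rnacircgen:::SPECIES_NAMES))
  expect_true(ss$settled)
  expect_equal(unname(ss$state[1:3]), rep(100, 3), tolerance = 1e-4)

  # a state that is already stationary is returned immediately
  y_fix <- setNames(c(100, 100, 100, rep(0, 6)), rnacircgen:::SPECIES_NAMES)
  ss2 <- simulate_steady_state(sys0, y_fix)
  expect_identical(ss2$time, 0)
  expect_lte(ss2$residual, 1)

  # single pair A + B <-> C with no production/degradation reaches
  # detailed balance C / (A * B) = k_f / k_r
  kf <- c(0, 1.50958097e-3, 0, 0, 0, 0)
  kr <- c(0, 0.15, 0, 0, 0, 0)
  sys1 <- make_reaction_system(kf, kr, production = rep(0, 3),
                               degradation = 0)
  y0 <- setNames(c(60, 40, 0, rep(0, 6)), rnacircgen:::SPECIES_NAMES)
  # tight settling detection so the state is at equilibrium to solver rtol
  ss3 <- simulate_steady_state(sys1, y0,
                               solver_config(ss_rtol = 1e-9,
                                             ss_atol = 1e-12))
  st <- ss3$state
  expect_equal(st[["C12"]] / (st[["x1"]] * st[["x2"]]),
               kf[2] / kr[2], tolerance = 1e-6)
})

test_that("the two-phase protocol bookmarks inputs and outputs", {
  # fully non-interacting circuit under a doubled-production step:
  # input doubles, I2/I1 = 2
  sys0 <- make_reaction_system(k_f = 0, k_r = 0)
  resp <- run_signal_protocol(sys0,
                              solver = solver_config(ss_rtol = 1e-9,
                                                     ss_atol = 1e-12))
  expect_equal(resp$I2 / resp$I1, 2, tolerance = 1e-6)
  expect_equal(resp$O2, resp$O1, tolerance = 1e-6)

  # output node decoupled from the rest: flat output, O_peak = O1
  kf <- rep(1.50958097e-3, 6); kf[c(3, 5, 6)] <- 0
  kr <- rep(0.15, 6)
  sysd <- make_reaction_system(kf, kr)
  respd <- run_signal_protocol(sysd)
  expect_equal(respd$O_peak, respd$O1, tolerance = 1e-6)
  expect_equal(respd$O2, respd$O1, tolerance = 1e-6)

  # phase 1 is untouched by the signal configuration
  e <- c(-20, -10, -15, -5, -25, -8)
  r_step <- run_signal_protocol(e, signal = signal_config("step"))
  r_imp <- run_signal_protocol(e, signal = signal_config("impulse"))
  expect_identical(r_step$phase1_state, r_imp$phase1_state)
  expect_identical(r_step$I1, r_imp$I1)
  # the impulse adds magnitude x steady state to the input node
  expect_equal(unname(r_imp$trajectory[1, 1]), 3 * r_imp$I1,
               tolerance = 1e-9)
})

test_that("integrators from different families agree on the bookmarks", {
  set.seed(42)
  E <- matrix(runif(12 * 6, -30, 0), 12, 6)
  for (i in seq_len(nrow(E))) {
    r1 <- run_signal_protocol(E[i, ], solver = solver_config(method = "lsoda"))
    r2 <- run_signal_protocol(E[i, ], solver = solver_config(method = "radau"))
    expect_equal(r1$O_peak, r2$O_peak, tolerance = 1e-4)
    expect_equal(r1$O2, r2$O2, tolerance = 1e-4)
  }
})
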