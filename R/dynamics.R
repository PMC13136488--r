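# Mass-action dynamics of 3-node RNA circuits and the two-phase signal
# protocol.  The stiff right-hand side is compiled (src/circuit_ode.c) and
# integrated with deSolve; an R-level copy of the derivatives is kept for
# steady-state residuals and as an independent check.

SPECIES_NAMES <- c("x1", "x2", "x3", paste0("C", c(11, 12, 13, 22, 23, 33)))

#' Build the reaction system for an energy circuit
#'
#' Nine species: three free RNAs (produced at constant rate, input node 1,
#' output node 3) and six pairwise complexes, all degrading at the same
#' first-order rate.  Each unique pair binds reversibly with the shared
#' association rate and a dissociation rate derived from its binding energy;
#' self-binding consumes two copies.
#'
#' @param energies numeric length-6 vector in canonical order
#'   `[k11, k12, k13, k22, k23, k33]` (kcal/mol), or a one-row circuit
#'   data.frame.
#' @param rates a [rate_set()].
#' @return An object of class `reaction_system`.
#' @export
build_system <- function(energies, rates = rate_set()) {
  if (is.data.frame(energies)) energies <- unlist(energies[1, PAIR_NAMES])
  energies <- as.numeric(energies)
  if (length(energies) != 6L || anyNA(energies))
    stop("a 3-node circuit needs 6 finite interaction energies", call. = FALSE)
  rt <- rates_from_energy(energies, rates)
  structure(list(
    energies = setNames(energies, PAIR_NAMES),
    production = rep(rates$production, 3L),
    degradation = rates$degradation,
    k_f = rep(rates$k_f_percopy, 6L),
    k_r = rt$k_r,
    x0 = rates$x0,
    input_node = 1L, output_node = 3L
  ), class = "reaction_system")
}

# low-level constructor with explicit per-pair rates (used by tests and
# degenerate configurations such as decoupled nodes)
make_reaction_system <- function(k_f, k_r, production = rep(1.175, 3),
                                 degradation = 0.01175, x0 = 100) {
  structure(list(energies = rep(NA_real_, 6), production = production,
                 degradation = degradation, k_f = rep_len(k_f, 6L),
                 k_r = rep_len(k_r, 6L), x0 = x0,
                 input_node = 1L, output_node = 3L),
            class = "reaction_system")
}

system_parms <- function(sys) {
  c(sys$production, sys$degradation, sys$k_f, sys$k_r)
}

default_state <- function(sys) {
  setNames(c(rep(sys$x0, 3L), rep(0, 6L)), SPECIES_NAMES)
}

# R-level derivatives, vectorised over the rows of a state matrix.  Mirrors
# the compiled RHS; used for settling detection and as a cross-check.
circuit_rhs_matrix <- function(Y, sys) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  pi1 <- c(1L, 1L, 1L, 2L, 2L, 3L); pi2 <- c(1L, 2L, 3L, 2L, 3L, 3L)
  D <- matrix(0, nrow(Y), 9L)
  for (i in 1:3) D[, i] <- sys$production[i] - sys$degradation * Y[, i]
  for (p in 1:6) {
    net <- sys$k_f[p] * Y[, pi1[p]] * Y[, pi2[p]] - sys$k_r[p] * Y[, 3L + p]
    if (pi1[p] == pi2[p]) {
      D[, pi1[p]] <- D[, pi1[p]] - 2 * net
    } else {
      D[, pi1[p]] <- D[, pi1[p]] - net
      D[, pi2[p]] <- D[, pi2[p]] - net
    }
    D[, 3L + p] <- net - sys$degradation * Y[, 3L + p]
  }
  D
}

#' Solver configuration
#'
#' @param rtol,atol relative/absolute integration tolerances.
#' @param t_max horizon per phase, seconds.
#' @param n_grid number of (log-spaced) output times per phase.
#' @param method deSolve integrator (`"lsoda"` default; `"ode45"` supported
#'   for cross-checks).
#' @param ss_rtol,ss_atol steady-state detection tolerances: a state is
#'   settled when `max |dx/dt| / (ss_atol + ss_rtol * |x|) <= 1`.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-6, atol = 1e-9, t_max = 1e5,
                          n_grid = 240L, method = "lsoda",
                          ss_rtol = 1e-6, ss_atol = 1e-9) {
  structure(list(rtol = rtol, atol = atol, t_max = t_max,
                 n_grid = as.integer(n_grid), method = method,
                 ss_rtol = ss_rtol, ss_atol = ss_atol),
            class = "solver_config")
}

phase_times <- function(solver) {
  c(0, 10^seq(-2, log10(solver$t_max), length.out = solver$n_grid - 1L))
}

integrate_phase <- function(sys, y0, solver) {
  times <- phase_times(solver)
  # integrator chatter (step-size complaints on pathological generated
  # circuits) is handled through the settledness flags, not warnings
  if (all(is.finite(sys$energies))) {
    out <- suppressWarnings(
      deSolve::ode(y = y0, times = times, func = "circuit_derivs",
                   parms = system_parms(sys), dllname = "rnacircgen",
                   initfunc = "circuit_initmod", method = solver$method,
                   rtol = solver$rtol, atol = solver$atol))
  } else {
    rhs <- function(t, y, p) list(drop(circuit_rhs_matrix(rbind(y), sys)))
    out <- suppressWarnings(
      deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                   method = solver$method,
                   rtol = solver$rtol, atol = solver$atol))
  }
  Y <- unname(out[, 1L + seq_len(9L), drop = FALSE])
  colnames(Y) <- SPECIES_NAMES
  list(time = out[, 1L], Y = Y)
}

settle_index <- function(traj, sys, solver) {
  D <- circuit_rhs_matrix(traj$Y, sys)
  crit <- apply(abs(D) / (solver$ss_atol + solver$ss_rtol * abs(traj$Y)),
                1L, max)
  idx <- which(crit <= 1)
  if (length(idx)) idx[1] else NA_integer_
}

#' Relax a reaction system to steady state
#'
#' Integrates from the initial state and returns the first recorded state at
#' which the normalised derivative criterion is met, or the state at the
#' horizon flagged as unsettled.  Solver failures are returned as flagged
#' records, not errors, so batch runs continue.
#'
#' @param sys a [build_system()] result.
#' @param y0 initial copies (default: free RNAs at `x0`, complexes at 0).
#' @param solver a [solver_config()].
#' @return list with `state`, `time`, `settled`, `residual` (max normalised
#'   derivative), and the full `trajectory`.
#' @export
simulate_steady_state <- function(sys, y0 = default_state(sys),
                                  solver = solver_config()) {
  traj <- tryCatch(integrate_phase(sys, y0, solver), error = identity)
  if (inherits(traj, "error"))
    return(list(state = setNames(rep(NA_real_, 9L), SPECIES_NAMES),
                time = NA_real_, settled = FALSE, residual = NA_real_,
                trajectory = NULL, error = conditionMessage(traj)))
  i <- settle_index(traj, sys, solver)
  settled <- !is.na(i)
  if (!settled) i <- nrow(traj$Y)
  D <- circuit_rhs_matrix(traj$Y[i, , drop = FALSE], sys)
  res <- max(abs(D) / (solver$ss_atol + solver$ss_rtol * abs(traj$Y[i, ])))
  list(state = setNames(traj$Y[i, ], SPECIES_NAMES), time = traj$time[i],
       settled = settled, residual = res, trajectory = traj)
}

#' Signal configuration
#'
#' In `step` mode the input node's production rate is multiplied by
#' `magnitude` at the phase boundary; in `impulse` mode `magnitude` times the
#' steady-state copies of the input RNA are added instantaneously instead.
#'
#' @param mode `"step"` (default) or `"impulse"`.
#' @param magnitude positive signal size (default 2).
#' @return list of class `signal_config`.
#' @export
signal_config <- function(mode = c("step", "impulse"), magnitude = 2) {
  mode <- match.arg(mode)
  stopifnot(magnitude > 0)
  structure(list(mode = mode, magnitude = magnitude),
            class = "signal_config")
}

#' Run the two-phase signal-response protocol
#'
#' Phase 1 relaxes the circuit to its pre-signal steady state (bookmarks
#' `I1`, `O1`).  The signal is applied to node 1 at the phase boundary and
#' phase 2 is simulated to settling, recording the input/output extrema of
#' largest absolute deviation from the phase-2 initial value (`I_peak`,
#' `O_peak`) and the post-signal steady state (`I2`, `O2`).
#'
#' @param energies length-6 canonical energy vector or one-row circuit
#'   data.frame.
#' @param rates a [rate_set()].
#' @param signal a [signal_config()].
#' @param solver a [solver_config()].
#' @param keep_trajectory retain full trajectories (default TRUE).
#' @return Object of class `signal_response` with the bookmarks, settling
#'   flags, and the phase-2 time grid/trajectory.
#' @export
run_signal_protocol <- function(energies, rates = rate_set(),
                                signal = signal_config(),
                                solver = solver_config(),
                                keep_trajectory = TRUE) {
  sys1 <- if (inherits(energies, "reaction_system")) energies
          else build_system(energies, rates)
  ph1 <- simulate_steady_state(sys1, solver = solver)
  if (!is.null(ph1$error))
    return(failed_response(ph1$error))
  s1 <- ph1$state
  I1 <- s1[[sys1$input_node]]; O1 <- s1[[sys1$output_node]]

  sys2 <- sys1
  y0 <- s1
  if (signal$mode == "step") {
    sys2$production[sys1$input_node] <-
      sys1$production[sys1$input_node] * signal$magnitude
  } else {
    y0[sys1$input_node] <- y0[sys1$input_node] +
      signal$magnitude * s1[[sys1$input_node]]
  }
  traj <- tryCatch(integrate_phase(sys2, y0, solver), error = identity)
  if (inherits(traj, "error"))
    return(failed_response(conditionMessage(traj)))
  i2 <- settle_index(traj, sys2, solver)
  settled2 <- !is.na(i2)
  if (!settled2) i2 <- nrow(traj$Y)
  s2 <- traj$Y[i2, ]
  I2 <- s2[[sys1$input_node]]; O2 <- s2[[sys1$output_node]]

  # peaks: extrema of largest absolute deviation from the pre-signal steady
  # state (for an impulse the spiked initial value itself is the input peak)
  it <- traj$Y[, sys1$input_node]; ot <- traj$Y[, sys1$output_node]
  ip <- which.max(abs(it - I1)); op <- which.max(abs(ot - O1))

  structure(list(
    I1 = I1, O1 = O1, I2 = I2, O2 = O2,
    I_peak = it[ip], O_peak = ot[op],
    t_I_peak = traj$time[ip], t_O_peak = traj$time[op],
    settled1 = ph1$settled, settled2 = settled2,
    residual1 = ph1$residual,
    residual2 = max(abs(circuit_rhs_matrix(traj$Y[i2, , drop = FALSE], sys2)) /
                      (solver$ss_atol + solver$ss_rtol * abs(traj$Y[i2, ]))),
    t_settle_index = i2, horizon = solver$t_max,
    signal_mode = signal$mode,
    time = if (keep_trajectory) traj$time else NULL,
    trajectory = if (keep_trajectory) traj$Y else NULL,
    phase1_state = s1, failed = FALSE
  ), class = "signal_response")
}

failed_response <- function(msg) {
  structure(list(I1 = NA_real_, O1 = NA_real_, I2 = NA_real_, O2 = NA_real_,
                 I_peak = NA_real_, O_peak = NA_real_,
                 settled1 = FALSE, settled2 = FALSE, failed = TRUE,
                 error = msg),
            class = "signal_response")
}

#' @export
print.signal_response <- function(x, ...) {
  cat("<signal_response>\n")
  if (isTRUE(x$failed)) {
    cat("  failed:", x$error, "\n"); return(invisible(x))
  }
  cat(sprintf("  I1 = %.4g  I_peak = %.4g  I2 = %.4g\n", x$I1, x$I_peak, x$I2))
  cat(sprintf("  O1 = %.4g  O_peak = %.4g  O2 = %.4g\n", x$O1, x$O_peak, x$O2))
  cat(sprintf("  settled: phase1 %s, phase2 %s\n", x$settled1, x$settled2))
  invisible(x)
}
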