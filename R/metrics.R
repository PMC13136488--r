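# Functional metrics: signal sensitivity, precision, the continuous
# adaptation score, auxiliary response features, and evolutionary ruggedness.

#' Constants of the adaptation objective
#'
#' The adaptation score is a concentric quadratic gradient in
#' (log10 S, log10 P) space increasing towards the adaptable region, peaking
#' at sensitivity 1e7 and precision 10^7.5, with extra weight `alpha` on
#' sensitivity and offset `C` keeping the score positive over the
#' operational box log10 S in [-7, 2], log10 P in [-2, 7].
#'
#' @param s_centre,p_centre concentric centres in log10 units.
#' @param alpha weight on the sensitivity term.
#' @param C positive offset.
#' @return list of class `adaptation_constants`.
#' @export
adaptation_constants <- function(s_centre = 7, p_centre = 7.5,
                                 alpha = 3, C = 1000) {
  stopifnot(alpha > 0, C > 0)
  structure(list(s_centre = s_centre, p_centre = p_centre,
                 alpha = alpha, C = C),
            class = "adaptation_constants")
}

#' Sensitivity and precision of a signal response
#'
#' Sensitivity is the maximum relative output change per relative input
#' change; precision is the inverse of the relative steady-state output
#' change per relative input change.  Divisions by zero yield NaN.
#'
#' @param resp a `signal_response`.
#' @return named numeric `c(S, P)`.
#' @export
sensitivity_precision <- function(resp) {
  with(resp, {
    S <- safe_div(abs(safe_div(O_peak - O1, O1)), abs(safe_div(I_peak - I1, I1)))
    Pinv <- safe_div(abs(safe_div(O2 - O1, O1)), abs(safe_div(I2 - I1, I1)))
    P <- safe_div(1, Pinv)
    c(S = S, P = P)
  })
}

safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- NaN
  out
}

#' Continuous adaptation score
#'
#' `a = -(alpha * (log10 S - s_centre)^2 + (log10 P - p_centre)^2) + C`.
#' Nonpositive or NaN sensitivity/precision give NaN.
#'
#' @param S,P sensitivity and precision (vectorised).
#' @param constants an [adaptation_constants()].
#' @return adaptation score(s); at most `C`.
#' @export
adaptation_score <- function(S, P, constants = adaptation_constants()) {
  ls <- ifelse(is.na(S) | S <= 0, NaN, log10(S))
  lp <- ifelse(is.na(P) | P <= 0, NaN, log10(P))
  -(constants$alpha * (ls - constants$s_centre)^2 +
      (lp - constants$p_centre)^2) + constants$C
}

#' Binary adaptability classification
#'
#' A circuit adapts when both sensitivity and precision exceed their
#' thresholds.  Two conventions are in circulation for 3-node adaptation
#' studies; the default is `S > 10, P > 1`, with `S > 1, P > 10` available
#' through the thresholds.  NaN metrics classify as not adaptable.
#'
#' @param S,P sensitivity and precision (vectorised).
#' @param S_min,P_min thresholds (defaults 10 and 1).
#' @return logical vector.
#' @export
classify_adaptable <- function(S, P, S_min = 10, P_min = 1) {
  ok <- !is.na(S) & !is.na(P)
  out <- ok & S > S_min & P > P_min
  out
}

#' Auxiliary response features
#'
#' Overshoot (|O_peak - O2|), overshoot relative to the pre-signal output,
#' settling time (first time after which the output stays within a 2% band
#' of its terminal value) and response time (first time the output reaches
#' 50% of its peak deviation).
#'
#' @param resp a `signal_response` with trajectory retained.
#' @param settle_band band half-width as a fraction of the response scale.
#' @param response_frac fraction of peak deviation defining response time.
#' @return named numeric vector.
#' @export
response_features <- function(resp, settle_band = 0.02, response_frac = 0.5) {
  overshoot <- abs(resp$O_peak - resp$O2)
  ratio <- safe_div(overshoot, resp$O1)
  if (is.null(resp$trajectory))
    return(c(overshoot = overshoot, overshoot_ratio = ratio,
             settling_time = NA_real_, response_time = NA_real_))
  ot <- resp$trajectory[, 3L]; tt <- resp$time
  dev0 <- abs(ot - ot[1])
  scale <- max(abs(resp$O2 - ot[1]), abs(resp$O_peak - resp$O2),
               abs(resp$O_peak - ot[1]))
  if (scale == 0) {
    settling <- 0; response <- 0
  } else {
    inside <- abs(ot - resp$O2) <= settle_band * scale
    # first index from which the trace never leaves the band again
    stays <- rev(cumprod(rev(inside))) > 0
    settling <- if (any(stays)) tt[which(stays)[1]] else NA_real_
    hit <- dev0 >= response_frac * max(dev0)
    response <- tt[which(hit)[1]]
  }
  c(overshoot = overshoot, overshoot_ratio = ratio,
    settling_time = settling, response_time = response)
}

#' Simulate a batch of circuits and compute their metrics
#'
#' Runs the two-phase protocol for every row of a circuit table and returns
#' the full metrics record per circuit.
#'
#' @param circuits data.frame with `circuit_id` and canonical energy columns.
#' @param rates a [rate_set()].
#' @param signal a [signal_config()].
#' @param solver a [solver_config()].
#' @param constants an [adaptation_constants()].
#' @return data.frame: circuit_id, the six energies, S, P, adaptation,
#'   response features, bookmarks, and flags (`settled`, `flag` reason code).
#' @export
simulate_circuit_metrics <- function(circuits, rates = rate_set(),
                                     signal = signal_config(),
                                     solver = solver_config(),
                                     constants = adaptation_constants()) {
  E <- energy_matrix(circuits)
  rows <- lapply(seq_len(nrow(E)), function(i) {
    resp <- run_signal_protocol(E[i, ], rates, signal, solver)
    metrics_record(resp, constants)
  })
  out <- do.call(rbind, rows)
  cbind(circuit_id = circuits$circuit_id,
        as.data.frame(E), out, stringsAsFactors = FALSE)
}

metrics_record <- function(resp, constants = adaptation_constants()) {
  sp <- sensitivity_precision(resp)
  a <- adaptation_score(sp[["S"]], sp[["P"]], constants)
  feats <- response_features(resp)
  flag <- if (isTRUE(resp$failed)) "solver_failure"
          else if (!resp$settled2) "slow_responder"
          else if (is.na(sp[["S"]]) || is.na(sp[["P"]])) "nan_metric"
          else ""
  data.frame(S = sp[["S"]], P = sp[["P"]], adaptation = a,
             overshoot = feats[["overshoot"]],
             overshoot_ratio = feats[["overshoot_ratio"]],
             settling_time = feats[["settling_time"]],
             response_time = feats[["response_time"]],
             I1 = resp$I1, I2 = resp$I2, I_peak = resp$I_peak,
             O1 = resp$O1, O2 = resp$O2, O_peak = resp$O_peak,
             settled = isTRUE(resp$settled1) && isTRUE(resp$settled2),
             flag = flag, stringsAsFactors = FALSE)
}

#' Evolutionary ruggedness of a circuit
#'
#' Perturbs each of the six unique interactions individually by `epsilon`
#' (default +1 kcal/mol, towards weaker binding), re-runs the full two-phase
#' protocol, and accumulates the squared adaptation changes per unit
#' perturbation: `dk_i = (a_eps - a_0) / eps`, `r = sum(dk_i^2)`.  Any NaN
#' adaptation in the perturbations makes `r` NaN.
#'
#' @param energies canonical length-6 energy vector or one-row data.frame.
#' @param epsilon perturbation, kcal/mol (sign configurable).
#' @param rates,signal,solver,constants simulation configuration.
#' @param a0 optionally the precomputed baseline adaptation.
#' @return list with `r`, `dk` (length 6), `a0`.
#' @export
ruggedness <- function(energies, epsilon = 1, rates = rate_set(),
                       signal = signal_config(), solver = solver_config(),
                       constants = adaptation_constants(), a0 = NULL) {
  if (is.data.frame(energies)) energies <- unlist(energies[1, PAIR_NAMES])
  energies <- as.numeric(energies)
  sim_a <- function(e) {
    resp <- run_signal_protocol(e, rates, signal, solver,
                                keep_trajectory = FALSE)
    sp <- sensitivity_precision(resp)
    adaptation_score(sp[["S"]], sp[["P"]], constants)
  }
  if (is.null(a0)) a0 <- sim_a(energies)
  dk <- vapply(1:6, function(i) {
    e <- energies
    e[i] <- e[i] + epsilon
    (sim_a(e) - a0) / epsilon
  }, numeric(1))
  list(r = sum(dk^2), dk = setNames(dk, PAIR_NAMES), a0 = a0)
}

#' Ruggedness for a batch of circuits
#'
#' @inheritParams ruggedness
#' @param circuits circuit table with canonical energy columns.
#' @param metrics optional precomputed metrics table supplying baseline
#'   adaptation (matched by `circuit_id`).
#' @return data.frame: circuit_id, ruggedness, dk1..dk6.
#' @export
ruggedness_batch <- function(circuits, metrics = NULL, epsilon = 1,
                             rates = rate_set(), signal = signal_config(),
                             solver = solver_config(),
                             constants = adaptation_constants()) {
  E <- energy_matrix(circuits)
  a0s <- if (!is.null(metrics))
    metrics$adaptation[match(circuits$circuit_id, metrics$circuit_id)]
  else rep(list(NULL), nrow(E))
  rows <- lapply(seq_len(nrow(E)), function(i) {
    rg <- ruggedness(E[i, ], epsilon, rates, signal, solver, constants,
                     a0 = if (is.null(metrics)) NULL else a0s[i])
    data.frame(ruggedness = rg$r, t(setNames(rg$dk, paste0("dk", 1:6))))
  })
  cbind(circuit_id = circuits$circuit_id, do.call(rbind, rows))
}

#' Random multi-interaction perturbations (exploratory)
#'
#' Draws mutated versions of a circuit with all interactions perturbed by
#' zero-mean normal noise whose standard deviation defaults to 10% of the
#' strongest (most negative) binding energy in the reference set.  This
#' illustrates local landscape structure; it is not part of the ruggedness
#' statistic.
#'
#' @param energies canonical length-6 energy vector.
#' @param n number of mutants.
#' @param sd_energy noise standard deviation, kcal/mol.
#' @param seed RNG seed.
#' @return n x 6 matrix of mutated energy vectors.
#' @export
perturb_random <- function(energies, n = 100, sd_energy = 3, seed = 1L) {
  if (is.data.frame(energies)) energies <- unlist(energies[1, PAIR_NAMES])
  set.seed(seed)
  mut <- matrix(rnorm(n * 6, 0, sd_energy), n, 6, byrow = TRUE)
  sweep(mut, 2, as.numeric(energies), "+")
}
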