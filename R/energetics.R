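# Conversion of RNA-RNA binding free energies to mass-action rates, plus the
# pluggable engine contract for predicting pairwise minimum free energies.

#' Default kinetic parameters for circuit simulation
#'
#' The dynamics run in copies-per-cell units.  The per-copy association rate
#' is the molar rate 1e6 /M/s rescaled to a bacterial cell volume of roughly
#' 1.1 fL (via Avogadro's number), giving 1.50958097e-3 per copy per second.
#' The degradation rate corresponds to dilution at a 1200 s doubling time
#' combined with decay; production is chosen so the unbound steady state
#' equals the average 100 mRNA copies per cell.
#'
#' @param k_f_percopy association rate, copies^-1 s^-1.
#' @param k_f_molar molar association rate (informational), M^-1 s^-1.
#' @param x0 initial copies per free RNA species.
#' @param degradation first-order degradation rate, s^-1 (all species).
#' @param production production rate of each free RNA, copies/s; default
#'   `degradation * x0` so that an unbound species rests at `x0` copies.
#' @return An object of class `rate_set`.
#' @export
rate_set <- function(k_f_percopy = 1.50958097e-3, k_f_molar = 1e6,
                     x0 = 100, degradation = 0.01175,
                     production = degradation * x0) {
  stopifnot(k_f_percopy > 0, x0 > 0, degradation >= 0, production >= 0)
  structure(list(k_f_percopy = k_f_percopy, k_f_molar = k_f_molar,
                 x0 = x0, degradation = degradation,
                 production = production),
            class = "rate_set")
}

#' Equilibrium constant from the Gibbs free energy relation
#'
#' Reference conversion `K = exp(-dG / (R * T))` (molar scale).  The
#' simulation pipeline itself uses [empirical_equilibrium()]; this form is
#' provided for comparison.
#'
#' @param dG binding free energy, kcal/mol.
#' @param R gas constant, kcal/(mol K).
#' @param Temp temperature, K.
#' @return Equilibrium constant (dimensionless/molar convention).
#' @export
gibbs_equilibrium <- function(dG, R = 1.987e-3, Temp = 310) {
  if (any(Temp <= 0)) stop("temperature must be positive", call. = FALSE)
  exp(-dG / (R * Temp))
}

#' Empirical equilibrium constant from binding free energy
#'
#' The Gibbs relation overestimates how strongly predicted minimum free
#' energies translate into bound fractions observed for sRNA-mRNA pairs in
#' vivo.  An empirical reparametrisation calibrated on fluorescence
#' measurements is used instead:
#' `K = exp(-0.8 * (dG + 10)) / x0`, in per-copy units.
#'
#' @param dG binding free energy, kcal/mol.
#' @param x0 initial RNA copies per species (> 0).
#' @return Per-copy association equilibrium constant, copies^-1.
#' @export
empirical_equilibrium <- function(dG, x0 = 100) {
  if (any(x0 <= 0)) stop("x0 must be positive", call. = FALSE)
  exp(-0.8 * (dG + 10)) / x0
}

#' Association and dissociation rates from a binding energy
#'
#' The association rate is fixed; the dissociation rate follows from the
#' empirical equilibrium constant as `k_r = k_f / K`, so weaker binding
#' (less negative `dG`) dissociates faster.
#'
#' @param dG binding free energy, kcal/mol (vectorised).
#' @param rates a [rate_set()].
#' @return data.frame with columns `dG`, `K`, `k_f`, `k_r`.
#' @export
rates_from_energy <- function(dG, rates = rate_set()) {
  K <- empirical_equilibrium(dG, rates$x0)
  data.frame(dG = dG, K = K, k_f = rates$k_f_percopy,
             k_r = rates$k_f_percopy / K)
}

# ---- energy engines ---------------------------------------------------------

#' Energy engines: pluggable RNA-RNA interaction predictors
#'
#' An energy engine scores an ordered (query, target) pair of RNA sequences
#' with a minimum free energy in kcal/mol, deterministically.  Three engines
#' are provided: a constant-energy stub, a deterministic hash stub (distinct
#' but reproducible energies per pair), and an adapter around the external
#' IntaRNA 2.x executable.  Pairs for which the external predictor reports no
#' interaction score 0 (inert).
#'
#' @param energy constant energy (kcal/mol) for the constant stub.
#' @param energy_range range into which the hash stub maps pairs.
#' @return An object of class `energy_engine` with elements `name`,
#'   `deterministic`, and `predict(query, target)`.
#' @name energy_engines
NULL

#' @rdname energy_engines
#' @export
energy_engine_constant <- function(energy = -12) {
  structure(list(
    name = sprintf("constant(%g)", energy), deterministic = TRUE,
    predict = function(query, target) energy
  ), class = "energy_engine")
}

#' @rdname energy_engines
#' @export
energy_engine_hash <- function(energy_range = c(-30, 0)) {
  lo <- energy_range[1]; hi <- energy_range[2]
  structure(list(
    name = "hash", deterministic = TRUE,
    predict = function(query, target) {
      h <- 0
      for (code in utf8ToInt(paste(query, target, sep = "|")))
        h <- (h * 131 + code) %% 1048573
      lo + (h / 1048572) * (hi - lo)
    }
  ), class = "energy_engine")
}

#' @rdname energy_engines
#' @param exe path to the IntaRNA executable.
#' @export
energy_engine_intarna <- function(exe = "IntaRNA") {
  if (Sys.which(exe) == "")
    stop("external tool not installed: '", exe, "' not found on PATH; ",
         "use energy_engine_constant() or energy_engine_hash() instead",
         call. = FALSE)
  structure(list(
    name = "IntaRNA", deterministic = TRUE,
    predict = function(query, target) {
      out <- tryCatch(
        system2(exe, c("-q", query, "-t", target, "--outMode=C", "-n", "1"),
                stdout = TRUE, stderr = TRUE),
        warning = function(w) w, error = function(e) e)
      if (inherits(out, "condition"))
        stop("IntaRNA invocation failed: ", conditionMessage(out),
             call. = FALSE)
      tab <- tryCatch(read.csv(text = paste(out, collapse = "\n"), sep = ";"),
                      error = function(e) NULL)
      if (is.null(tab) || !"E" %in% names(tab) || nrow(tab) == 0)
        return(0)  # no predicted interaction: inert pair
      as.numeric(tab$E[1])
    }
  ), class = "energy_engine")
}

#' Predict all pairwise binding energies of a sequence circuit
#'
#' Scores all unique ordered pairs (including self-pairs) of the circuit's
#' RNAs with the given engine, in canonical pair order.
#'
#' @param circuit one element of [sample_sequences()] output.
#' @param engine an energy engine (see [energy_engines]).
#' @return One-row data.frame `circuit_id, k11, ..., k33` (kcal/mol).
#' @export
predict_energies <- function(circuit, engine) {
  stopifnot(inherits(engine, "energy_engine"))
  validate_rna(circuit$sequences)
  idx <- pair_index(length(circuit$sequences))
  e <- apply(idx, 1, function(p)
    engine$predict(circuit$sequences[p[1]], circuit$sequences[p[2]]))
  out <- data.frame(circuit_id = circuit$circuit_id,
                    t(setNames(e, pair_names(length(circuit$sequences)))))
  attr(out, "engine") <- engine$name
  out
}
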