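# Filtering, normalisation and labelling of simulated circuits into
# training-ready matrices, with invertible normalisation state.

#' Filter simulated circuit records
#'
#' Removes, in order: records whose sensitivity, precision or adaptation is
#' NaN; exceedingly slow responders (unsettled, or settling time beyond a
#' fraction of the phase-2 horizon); and duplicate circuits (identical
#' energy vectors after rounding, first occurrence kept).
#'
#' @param records metrics table from [simulate_circuit_metrics()].
#' @param slow_frac settling-time threshold as a fraction of the horizon.
#' @param horizon phase-2 horizon in seconds.
#' @param dup_tol rounding tolerance (kcal/mol) for duplicate detection.
#' @return list with `records` (survivors) and `removed` (named counts).
#' @export
filter_records <- function(records, slow_frac = 0.8, horizon = 1e5,
                           dup_tol = 1e-9) {
  n0 <- nrow(records)
  nan_bad <- is.na(records$S) | is.na(records$P) | is.na(records$adaptation)
  records <- records[!nan_bad, , drop = FALSE]
  slow <- (!records$settled) |
    (!is.na(records$settling_time) &
       records$settling_time > slow_frac * horizon)
  records <- records[!slow, , drop = FALSE]
  key <- apply(round(energy_matrix(records) / dup_tol), 1L, paste,
               collapse = ",")
  dup <- duplicated(key)
  records <- records[!dup, , drop = FALSE]
  removed <- c(nan = sum(nan_bad), slow = sum(slow), duplicate = sum(dup))
  if (nrow(records) == 0L)
    stop("no records survive filtering (removed: ",
         paste(names(removed), removed, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  list(records = records, removed = removed)
}

#' Fit the feature normalisation state
#'
#' Binding energies are sign-flipped (so strong binding is large), robust
#' scaled (median and interquartile range of the training data), then
#' min-max scaled to [0, 1]: the most negative training energy maps to 1.
#' Features whose IQR is zero fall back to min-max only.
#'
#' @param energies numeric training matrix (n x 6, kcal/mol).
#' @return list of class `norm_state`.
#' @export
fit_feature_norm <- function(energies) {
  E <- -as.matrix(energies)
  med <- apply(E, 2L, median)
  iqr <- apply(E, 2L, function(v) diff(quantile(v, c(0.25, 0.75),
                                                names = FALSE)))
  robust_ok <- iqr > 0
  iqr[!robust_ok] <- 1  # fall back to pure min-max for degenerate features
  med[!robust_ok] <- 0
  S <- sweep(sweep(E, 2L, med), 2L, iqr, "/")
  mn <- apply(S, 2L, min); mx <- apply(S, 2L, max)
  mx[mx == mn] <- mn[mx == mn] + 1
  structure(list(median = med, iqr = iqr, min = mn, max = mx,
                 robust_ok = robust_ok, flip = TRUE),
            class = "norm_state")
}

#' Apply / invert the feature normalisation
#'
#' @param energies raw energy matrix (kcal/mol) for `apply_feature_norm`;
#'   normalised matrix in [0, 1] for `invert_feature_norm`.
#' @param state a [fit_feature_norm()] state.
#' @return matrix of the same shape.
#' @export
apply_feature_norm <- function(energies, state) {
  E <- -as.matrix(energies)
  S <- sweep(sweep(E, 2L, state$median), 2L, state$iqr, "/")
  sweep(sweep(S, 2L, state$min), 2L, state$max - state$min, "/")
}

#' @rdname apply_feature_norm
#' @param x normalised matrix.
#' @export
invert_feature_norm <- function(x, state) {
  S <- sweep(sweep(as.matrix(x), 2L, state$max - state$min, "*"), 2L,
             state$min, "+")
  E <- sweep(sweep(S, 2L, state$iqr, "*"), 2L, state$median, "+")
  out <- -E
  colnames(out) <- PAIR_NAMES
  out
}

# min-max helper for label columns
fit_minmax <- function(v) list(min = min(v), max = max(v))
apply_minmax <- function(v, mm) (v - mm$min) / (mm$max - mm$min)

#' Build conditional label matrix
#'
#' Supported objectives: `"adaptation"` (scalar, min-max normalised);
#' `"sp"` (`[log10 S, log10 P]`); `"binary"` (`[log10 S > 0, log10 P > 1]`);
#' `"three_metric"` (`[log10 S, log10 P, overshoot/initial]`);
#' `"adaptation_ruggedness"` (normalised adaptation plus log10 ruggedness
#' min-max normalised, samples outside [0, 1] excluded).  Continuous labels
#' are min-max normalised on the fitting data; when an existing state is
#' applied, non-ruggedness labels are clipped to [0, 1].
#'
#' @param records filtered metrics table (must contain `ruggedness` for the
#'   joint objective).
#' @param objective one of the objective names above.
#' @param state optional previously fitted label state (training statistics).
#' @return list with `c` (label matrix), `state`, and `keep` (logical rows
#'   retained; ruggedness out-of-range samples are dropped).
#' @export
build_labels <- function(records, objective = "adaptation", state = NULL) {
  objective <- match.arg(objective, c("adaptation", "sp", "binary",
                                      "three_metric",
                                      "adaptation_ruggedness"))
  raw <- switch(objective,
    adaptation = cbind(adaptation = records$adaptation),
    sp = cbind(log10_S = log10(records$S), log10_P = log10(records$P)),
    binary = cbind(S_pos = as.numeric(log10(records$S) > 0),
                   P_pos = as.numeric(log10(records$P) > 1)),
    three_metric = cbind(log10_S = log10(records$S),
                         log10_P = log10(records$P),
                         overshoot_ratio = records$overshoot_ratio),
    adaptation_ruggedness = {
      if (is.null(records$ruggedness))
        stop("joint objective needs a `ruggedness` column", call. = FALSE)
      cbind(adaptation = records$adaptation,
            log10_r = log10(records$ruggedness))
    })
  if (anyNA(raw))
    stop("labels contain NaN; filter records first", call. = FALSE)
  continuous <- objective != "binary"
  if (is.null(state)) {
    state <- list(objective = objective,
                  minmax = if (continuous)
                    lapply(seq_len(ncol(raw)), function(j) fit_minmax(raw[, j])))
  }
  cmat <- raw
  keep <- rep(TRUE, nrow(raw))
  if (continuous) {
    for (j in seq_len(ncol(raw)))
      cmat[, j] <- apply_minmax(raw[, j], state$minmax[[j]])
    if (objective == "adaptation_ruggedness") {
      keep <- cmat[, ncol(cmat)] >= 0 & cmat[, ncol(cmat)] <= 1
    }
    cmat <- pmin(pmax(cmat, 0), 1)
  }
  list(c = cmat[keep, , drop = FALSE], state = state, keep = keep)
}

#' Assemble a training-ready conditioned dataset
#'
#' Filters the metrics records, splits circuits into train/test, fits
#' feature and label normalisation on the training split only, and applies
#' it to both splits.
#'
#' @param records metrics table ([simulate_circuit_metrics()], optionally
#'   with a `ruggedness` column merged in).
#' @param objective label objective (see [build_labels()]).
#' @param train_frac training fraction of the split (default 0.8).
#' @param seed split RNG seed.
#' @param slow_frac,horizon filtering parameters (see [filter_records()]).
#' @return Object of class `conditioned_dataset`: `x` (n x 6 in [0, 1]),
#'   `c` (n x c_n in [0, 1]), `train_idx`/`test_idx`, `feature_state`,
#'   `label_state`, `circuit_id`, `provenance`.
#' @export
build_dataset <- function(records, objective = "adaptation",
                          train_frac = 0.8, seed = 1L,
                          slow_frac = 0.8, horizon = 1e5) {
  flt <- filter_records(records, slow_frac = slow_frac, horizon = horizon)
  rec <- flt$records
  set.seed(seed)
  n <- nrow(rec)
  tr <- sort(sample.int(n, size = floor(train_frac * n)))
  te <- setdiff(seq_len(n), tr)

  feature_state <- fit_feature_norm(energy_matrix(rec[tr, , drop = FALSE]))
  lab_tr <- build_labels(rec[tr, , drop = FALSE], objective)
  lab_te <- build_labels(rec[te, , drop = FALSE], objective,
                         state = lab_tr$state)
  keep_tr <- tr[lab_tr$keep]; keep_te <- te[lab_te$keep]
  idx <- c(keep_tr, keep_te)

  x <- apply_feature_norm(energy_matrix(rec[idx, , drop = FALSE]),
                          feature_state)
  # features min-maxed on training statistics; clip test-side spillover
  x <- pmin(pmax(x, 0), 1)
  cmat <- rbind(lab_tr$c, lab_te$c)
  structure(list(
    x = x, c = cmat,
    train_idx = seq_along(keep_tr),
    test_idx = length(keep_tr) + seq_along(keep_te),
    feature_state = feature_state, label_state = lab_tr$state,
    circuit_id = rec$circuit_id[idx],
    raw_energies = energy_matrix(rec[idx, , drop = FALSE]),
    metrics = rec[idx, setdiff(names(rec), PAIR_NAMES), drop = FALSE],
    provenance = list(seed = seed, objective = objective,
                      train_frac = train_frac, removed = flt$removed,
                      n_total = n)
  ), class = "conditioned_dataset")
}

#' @export
print.conditioned_dataset <- function(x, ...) {
  cat(sprintf("<conditioned_dataset> %d circuits (%d train / %d test), c_n = %d, objective = %s\n",
              nrow(x$x), length(x$train_idx), length(x$test_idx),
              ncol(x$c), x$provenance$objective))
  invisible(x)
}

#' Write / read a dataset bundle
#'
#' Features and labels as CSV, normalisation state and provenance as JSON.
#'
#' @param ds a `conditioned_dataset`.
#' @param dir bundle directory (created).
#' @return the directory (write) or the restored dataset (read).
#' @export
write_dataset_bundle <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feat <- data.frame(circuit_id = ds$circuit_id,
                     split = ifelse(seq_len(nrow(ds$x)) %in% ds$train_idx,
                                    "train", "test"),
                     ds$raw_energies, ds$x, check.names = FALSE)
  names(feat) <- c("circuit_id", "split", PAIR_NAMES,
                   paste0("x", 1:6))
  write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(data.frame(circuit_id = ds$circuit_id, ds$c,
                       check.names = FALSE),
            file.path(dir, "labels.csv"), row.names = FALSE)
  # digits = I(17): doubles must survive the text roundtrip bit-exactly
  jsonlite::write_json(
    list(feature_state = unclass(ds$feature_state),
         label_state = ds$label_state),
    file.path(dir, "norm_state.json"), auto_unbox = TRUE, digits = I(17))
  jsonlite::write_json(ds$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset_bundle
#' @export
read_norm_state <- function(dir) {
  raw <- jsonlite::read_json(file.path(dir, "norm_state.json"),
                             simplifyVector = TRUE)
  fs <- raw$feature_state
  structure(list(median = as.numeric(fs$median), iqr = as.numeric(fs$iqr),
                 min = as.numeric(fs$min), max = as.numeric(fs$max),
                 robust_ok = as.logical(fs$robust_ok), flip = fs$flip),
            class = "norm_state")
}
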