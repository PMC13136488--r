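# Model quality: reconstruction R², KDE-overlap prompt adherence,
# precision/recall/F1 against prompts, embedding export and hierarchical
# motif clustering.

#' Held-out pooled reconstruction R²
#'
#' Coefficient of determination pooled over all six interaction entries of
#' the requested split, with latent noise set to zero.
#'
#' @param model trained `cvae_model`.
#' @param dataset a `conditioned_dataset`.
#' @param split `"test"` (default) or `"train"`.
#' @return R² (1 is perfect reconstruction).
#' @export
reconstruction_r2 <- function(model, dataset, split = "test") {
  idx <- if (split == "test") dataset$test_idx else dataset$train_idx
  if (length(idx) == 0L) stop("empty evaluation split", call. = FALSE)
  X <- dataset$x[idx, , drop = FALSE]
  C <- dataset$c[idx, , drop = FALSE]
  Y <- cvae_reconstruct(model, X, C)
  pooled_r2(as.vector(X), as.vector(Y))
}

pooled_r2 <- function(truth, pred) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

#' KDE overlap between prompted metric distributions
#'
#' Fits a Gaussian kernel density estimate (Scott's rule bandwidth) to each
#' group on a shared 1000-point grid spanning the pooled range padded by
#' three bandwidths, renormalises each KDE to unit area on the grid, and
#' scores each pair by the area of the pointwise minimum: 0 is no overlap,
#' 1 is complete overlap.  A prompt's adherence is its mean overlap with all
#' other prompts, and the grand mean of those is the adherence score
#' (lower = better separated prompts).
#'
#' @param groups named list of numeric vectors (one per prompt).
#' @param n_points evaluation grid size (default 1000).
#' @return list of class `adherence_report`: `overlap` matrix,
#'   `per_prompt` mean overlap vs others, `adherence` grand mean, `grid`,
#'   `kde` (groups x grid matrix).
#' @export
kde_overlap <- function(groups, n_points = 1000L) {
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) < 5L))
    stop("each group needs at least 5 samples", call. = FALSE)
  bws <- vapply(groups, function(v) {
    bw <- tryCatch(stats::bw.nrd(v), error = function(e) 0)
    if (!is.finite(bw) || bw <= 0) {
      # degenerate (zero-variance) group: epsilon bandwidth fallback
      bw <- 1e-6 * max(1, abs(mean(v)))
    }
    bw
  }, numeric(1))
  rng <- range(unlist(groups))
  pad <- 3 * max(bws)
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = n_points)
  dx <- grid[2] - grid[1]
  dens <- t(vapply(seq_along(groups), function(i) {
    d <- stats::density(groups[[i]], bw = bws[i], kernel = "gaussian",
                        from = grid[1], to = grid[length(grid)],
                        n = n_points)$y
    d / (sum(d) * dx)  # unit area on the evaluation grid
  }, numeric(n_points)))
  k <- length(groups)
  ov <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i < j) ov[i, j] <- ov[j, i] <- sum(pmin(dens[i, ], dens[j, ])) * dx
  per <- vapply(seq_len(k), function(i) mean(ov[i, -i]), numeric(1))
  structure(list(overlap = ov, per_prompt = setNames(per, names(groups)),
                 adherence = mean(per), grid = grid, kde = dens,
                 bandwidths = bws),
            class = "adherence_report")
}

#' @export
print.adherence_report <- function(x, ...) {
  cat(sprintf("<adherence_report> %d prompts, mean overlap %.4f\n",
              nrow(x$overlap), x$adherence))
  invisible(x)
}

#' Precision, recall and F1 of prompt fulfilment
#'
#' A generated circuit fulfils a prompt when its realised (re-simulated)
#' metric lies within `bound` of the prompt in normalised units.  Per
#' prompt: precision is the fulfilled fraction among its own generations,
#' recall the fraction of all circuits fulfilling the prompt that were
#' generated under it, and F1 their harmonic mean (0 when both vanish).
#'
#' @param prompts prompt value per generated circuit.
#' @param realised realised normalised metric per circuit.
#' @param bound fulfilment half-width (default 0.1).
#' @return data.frame: prompt, n, precision, recall, F1.
#' @export
precision_recall_f1 <- function(prompts, realised, bound = 0.1) {
  levs <- sort(unique(prompts))
  out <- lapply(levs, function(pv) {
    gen_under <- prompts == pv
    fulfils <- abs(realised - pv) <= bound
    tp <- sum(gen_under & fulfils)
    precision <- if (sum(gen_under) > 0) tp / sum(gen_under) else 0
    recall <- if (sum(fulfils) > 0) tp / sum(fulfils) else 0
    data.frame(prompt = pv, n = sum(gen_under),
               precision = precision, recall = recall,
               F1 = f1_score(precision, recall))
  })
  do.call(rbind, out)
}

#' @rdname precision_recall_f1
#' @param precision,recall scalar or vector rates in [0, 1].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Hierarchical motif clustering of adaptable circuits
#'
#' Agglomerative (Ward) clustering on the raw interaction 6-vectors of
#' circuits classified as adaptable; the tree is cut at `k` clusters
#' (default 5 motifs) and each motif is summarised by its median
#' interaction profile and its adaptation/ruggedness distributions.
#'
#' @param circuits circuit table with canonical energy columns (already
#'   filtered to adaptable circuits).
#' @param metrics optional metrics table aligned by `circuit_id`
#'   (adaptation/ruggedness distributions per motif).
#' @param k number of motifs.
#' @return list of class `motif_report`: `labels`, `medians` (k x 6),
#'   `sizes`, per-cluster metric summaries, `linkage`.
#' @export
cluster_motifs <- function(circuits, metrics = NULL, k = 5L) {
  E <- energy_matrix(circuits)
  if (nrow(E) < k)
    stop("fewer circuits (", nrow(E), ") than requested motifs (", k, ")",
         call. = FALSE)
  d <- dist(E)
  if (max(d) == 0) {
    # degenerate: all circuits identical, a single motif
    labels <- rep(1L, nrow(E)); k <- 1L; hc <- NULL
  } else {
    hc <- hclust(d, method = "ward.D2")
    labels <- cutree(hc, k = k)
  }
  medians <- t(vapply(seq_len(k), function(g)
    apply(E[labels == g, , drop = FALSE], 2L, median), numeric(6L)))
  rownames(medians) <- paste0("motif", seq_len(k))
  summaries <- NULL
  if (!is.null(metrics)) {
    mm <- metrics[match(circuits$circuit_id, metrics$circuit_id), ,
                  drop = FALSE]
    summaries <- lapply(seq_len(k), function(g) {
      sub <- mm[labels == g, , drop = FALSE]
      list(adaptation = summary(sub$adaptation),
           ruggedness = if (!is.null(sub$ruggedness))
             summary(sub$ruggedness))
    })
    names(summaries) <- rownames(medians)
  }
  structure(list(labels = labels, medians = medians,
                 sizes = tabulate(labels, k), metric_summaries = summaries,
                 linkage = "ward.D2 on Euclidean distance of raw energies",
                 tree = hc),
            class = "motif_report")
}

#' Export encoder embeddings
#'
#' Encoder means (mu, noise-free) per circuit with the supplied labels
#' attached, for downstream projection or plotting.
#'
#' @param model trained `cvae_model`.
#' @param X,C normalised features and labels.
#' @param extra optional data.frame of metrics to attach.
#' @return data.frame with H embedding columns (`mu1..muH`) plus labels.
#' @export
export_embeddings <- function(model, X, C, extra = NULL) {
  fw <- cvae_forward(model$params, X, C, noise = 0, model$config)
  out <- as.data.frame(fw$mu)
  names(out) <- paste0("mu", seq_len(ncol(out)))
  for (j in seq_len(ncol(C)))
    out[[paste0("label", j)]] <- as.matrix(C)[, j]
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' Re-simulate generated circuits and score prompt adherence
#'
#' Runs the two-phase protocol on each generated circuit, maps the realised
#' adaptation through the training label normalisation, and reports the KDE
#' overlap matrix, per-prompt precision/recall/F1 and the prompt-vs-realised
#' monotonicity (Spearman correlation of per-prompt medians).
#'
#' @param generated output of [cvae_generate()] with energy columns.
#' @param label_state training label state (from the dataset).
#' @param rates,signal,solver,constants simulation configuration.
#' @param bound fulfilment bound for precision/recall/F1.
#' @return list: `per_circuit` (realised metrics), `kde` adherence report,
#'   `prf` table, `medians` per prompt, `spearman`.
#' @export
evaluate_generated <- function(generated, label_state,
                               rates = rate_set(),
                               signal = signal_config(),
                               solver = solver_config(),
                               constants = adaptation_constants(),
                               bound = 0.1) {
  met <- simulate_circuit_metrics(generated, rates, signal, solver, constants)
  realised <- apply_minmax(met$adaptation, label_state$minmax[[1]])
  per <- data.frame(circuit_id = generated$circuit_id,
                    prompt = generated$prompt1,
                    adaptation = met$adaptation,
                    realised = realised)
  ok <- !is.na(per$realised)
  groups <- split(per$realised[ok], per$prompt[ok])
  kde <- if (length(groups) >= 2 && all(lengths(groups) >= 5))
    kde_overlap(groups) else NULL
  prf <- precision_recall_f1(per$prompt[ok], per$realised[ok], bound = bound)
  med <- vapply(groups, median, numeric(1))
  rho <- if (length(med) >= 3)
    cor(as.numeric(names(med)), med, method = "spearman") else NA_real_
  list(per_circuit = per, metrics = met, kde = kde, prf = prf,
       medians = med, spearman = rho)
}
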