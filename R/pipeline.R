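# End-to-end orchestration: sample -> simulate -> label -> train -> generate
# -> re-simulate -> evaluate, behind one configuration object, with a JSON
# manifest and per-stage timing.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = tempfile("rnacircgen_run_"),
    sampling = list(n_circuits = 500L, energy_range = c(-30, 0)),
    rates = list(),
    signal = list(mode = "step", magnitude = 2),
    solver = list(),
    dataset = list(objective = "adaptation", train_frac = 0.8),
    model = list(latent = 32L, hidden = 32L, n_layers = 3L),
    train = list(kl_weight = 1e-4, max_epochs = 2000L, batch_size = 256L),
    n_seeds = 1L,
    select_by = "adherence",
    generate = list(prompts = seq(0, 1, length.out = 10L),
                    n_per_prompt = 100L, n_eval_per_prompt = 30L),
    motifs = list(k = 5L, S_min = 10, P_min = 1)
  )
}

#' Pipeline configuration
#'
#' Merges user settings over the defaults; unknown top-level keys are
#' rejected.  Use [yaml::read_yaml()] output directly as `config`.
#'
#' @param config named list of overrides (possibly nested).
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(def, config)
  structure(cfg, class = "pipeline_config")
}

#' Run the full generative-design pipeline
#'
#' Samples parameter circuits, simulates their two-phase responses, computes
#' metrics (plus ruggedness for the joint objective), builds the conditioned
#' dataset, trains one or more CVAE seeds, selects a model, generates
#' prompted circuits, re-simulates them, and writes the dataset bundle,
#' checkpoint, generated table, adherence and motif reports and a manifest
#' into the run directory.  Idempotent for a fixed seed.
#'
#' @param config a [pipeline_config()] (or a plain list of overrides).
#' @return the run directory, invisibly; the manifest summarises artefacts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("rnacircgen")),
                   seed = config$seed, stages = list())
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e) e)
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      ok = !inherits(val, "error"),
      error = if (inherits(val, "error")) conditionMessage(val))
    if (inherits(val, "error")) {
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(val),
           call. = FALSE)
    }
    val
  }

  rates <- do.call(rate_set, config$rates)
  signal <- do.call(signal_config, config$signal)
  solver <- do.call(solver_config, config$solver)

  circuits <- t_stage("sample", {
    sc <- sampling_config(n_circuits = config$sampling$n_circuits,
                          energy_range = config$sampling$energy_range,
                          seed = config$seed)
    sample_energy_circuits(sc)
  })

  records <- t_stage("simulate", {
    met <- simulate_circuit_metrics(circuits, rates, signal, solver)
    if (identical(config$dataset$objective, "adaptation_ruggedness")) {
      rg <- ruggedness_batch(circuits, metrics = met, rates = rates,
                             signal = signal, solver = solver)
      met <- merge(met, rg[, c("circuit_id", "ruggedness")],
                   by = "circuit_id", sort = FALSE)
    }
    write.csv(met, file.path(config$out_dir, "metrics.csv"),
              row.names = FALSE)
    met
  })

  dataset <- t_stage("build_dataset", {
    ds <- build_dataset(records, objective = config$dataset$objective,
                        train_frac = config$dataset$train_frac,
                        seed = config$seed, horizon = solver$t_max)
    write_dataset_bundle(ds, file.path(config$out_dir, "dataset"))
    ds
  })

  fit <- t_stage("train", {
    mconf <- model_config(m = ncol(dataset$x), c_n = ncol(dataset$c),
                          hidden = config$model$hidden,
                          n_layers = config$model$n_layers,
                          latent = config$model$latent)
    tconf <- do.call(train_config, config$train)
    train_cvae_multiseed(dataset, seeds = config$seed - 1L +
                           seq_len(config$n_seeds),
                         mconf = mconf, tconf = tconf)
  })

  best <- t_stage("select", {
    if (config$n_seeds == 1L || config$select_by == "r2") {
      fit$best_r2
    } else {
      scores <- vapply(fit$models, function(mod) {
        gen <- cvae_generate(mod, config$generate$prompts,
                             n_per_prompt = config$generate$n_eval_per_prompt,
                             seed = config$seed,
                             feature_state = dataset$feature_state)
        ev <- evaluate_generated(gen, dataset$label_state, rates, signal,
                                 solver)
        if (is.null(ev$kde)) Inf else ev$kde$adherence
      }, numeric(1))
      which.min(scores)
    }
  })
  model <- fit$models[[best]]
  save_cvae_checkpoint(model, file.path(config$out_dir, "checkpoint.json"),
                       history = TRUE)

  generated <- t_stage("generate", {
    gen <- cvae_generate(model, config$generate$prompts,
                         n_per_prompt = config$generate$n_per_prompt,
                         seed = config$seed,
                         feature_state = dataset$feature_state)
    write.csv(gen, file.path(config$out_dir, "generated.csv"),
              row.names = FALSE)
    gen
  })

  evaluation <- t_stage("evaluate", {
    ev <- evaluate_generated(generated, dataset$label_state, rates, signal,
                             solver)
    jsonlite::write_json(
      list(adherence = if (!is.null(ev$kde)) ev$kde$adherence,
           overlap = if (!is.null(ev$kde)) ev$kde$overlap,
           medians = as.list(ev$medians), spearman = ev$spearman,
           prf = ev$prf,
           r2_per_seed = fit$r2, selected_seed = fit$seeds[best]),
      file.path(config$out_dir, "adherence_report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    write.csv(ev$per_circuit,
              file.path(config$out_dir, "generated_metrics.csv"),
              row.names = FALSE)
    ev
  })

  motifs <- t_stage("motifs", {
    met_gen <- evaluation$metrics
    ok <- classify_adaptable(met_gen$S, met_gen$P,
                             S_min = config$motifs$S_min,
                             P_min = config$motifs$P_min)
    if (sum(ok) >= config$motifs$k) {
      mr <- cluster_motifs(generated[ok, , drop = FALSE],
                           metrics = met_gen, k = config$motifs$k)
      jsonlite::write_json(
        list(sizes = mr$sizes, medians = mr$medians, linkage = mr$linkage),
        file.path(config$out_dir, "motif_report.json"),
        auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
      mr
    } else NULL
  })

  manifest$artefacts <- list.files(config$out_dir, recursive = TRUE)
  manifest$n_circuits <- nrow(circuits)
  manifest$selected_seed <- fit$seeds[best]
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(config$out_dir)
}

#' Save / load a CVAE checkpoint
#'
#' Weights, architecture and (optionally) training history serialised as
#' JSON at full numeric precision.
#'
#' @param model a `cvae_model`.
#' @param path JSON file path.
#' @param history include the training history.
#' @return `path` (save) or the restored `cvae_model` (load).
#' @export
save_cvae_checkpoint <- function(model, path, history = FALSE) {
  payload <- list(
    config = unclass(model$config),
    train_config = unclass(model$train_config),
    params = model$params,
    best_val_acc = model$best_val_acc,
    stopped = model$stopped,
    history = if (history) model$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_cvae_checkpoint
#' @export
load_cvae_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, raw$config[c("m", "c_n", "hidden", "n_layers",
                                            "latent", "leaky_slope")])
  params <- lapply(raw$params, function(x) {
    if (is.matrix(x)) x else as.numeric(x)
  })
  structure(list(params = params, config = cfg,
                 train_config = raw$train_config,
                 history = raw$history,
                 best_val_acc = raw$best_val_acc,
                 stopped = raw$stopped, trained = TRUE),
            class = "cvae_model")
}
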