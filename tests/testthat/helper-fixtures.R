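# Shared fixtures.  Heavy objects (the simulated training set and the
# multi-seed CVAE fit) are built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# internal helpers exercised directly by the tests
validate_rna <- rnacircgen:::validate_rna
make_reaction_system <- rnacircgen:::make_reaction_system
integrate_phase <- rnacircgen:::integrate_phase
circuit_rhs_matrix <- rnacircgen:::circuit_rhs_matrix
default_state <- rnacircgen:::default_state
apply_minmax <- rnacircgen:::apply_minmax
pooled_r2 <- rnacircgen:::pooled_r2

# minimal signal_response carrying only the bookmarks, for metric arithmetic
make_response <- function(I1, I2, I_peak, O1, O2, O_peak) {
  structure(list(I1 = I1, I2 = I2, I_peak = I_peak,
                 O1 = O1, O2 = O2, O_peak = O_peak,
                 settled1 = TRUE, settled2 = TRUE, failed = FALSE,
                 trajectory = NULL),
            class = "signal_response")
}

random_symmetric <- function(n = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n, -30, 0), n, n)
  (m + t(m)) / 2
}

# simulate adaptation for one energy vector (independent of the metrics
# batch helpers; used by oracle loops)
simulate_adaptation <- function(e, ...) {
  resp <- run_signal_protocol(e, ...)
  sp <- sensitivity_precision(resp)
  adaptation_score(sp[["S"]], sp[["P"]])
}

# medium simulated dataset shared by dataset / cvae / evaluation tests
demo_dataset <- function() memo("demo_dataset", function() {
  circuits <- sample_energy_circuits(sampling_config(n_circuits = 600,
                                                     seed = 301))
  met <- simulate_circuit_metrics(circuits)
  build_dataset(met, objective = "adaptation", seed = 301)
})

# a quickly trained model on the demo dataset (loose stopping)
demo_model <- function() memo("demo_model", function() {
  train_cvae(demo_dataset(),
             tconf = train_config(seed = 1, max_epochs = 600,
                                  batch_size = 64L))
})

# acceptance-scale fixture: 5000 parameter-sampled circuits, scalar
# adaptation labels, 80/20 split, five training seeds
acceptance_dataset <- function() memo("acceptance_dataset", function() {
  circuits <- sample_energy_circuits(sampling_config(n_circuits = 5000,
                                                     seed = 101))
  met <- simulate_circuit_metrics(circuits)
  build_dataset(met, objective = "adaptation", seed = 101)
})

acceptance_fit <- function() memo("acceptance_fit", function() {
  ds <- acceptance_dataset()
  fit <- train_cvae_multiseed(ds, seeds = 1:5)
  fit$evals <- lapply(fit$models, function(mod) {
    gen <- cvae_generate(mod, seq(0, 1, length.out = 10),
                         n_per_prompt = 60, seed = 7,
                         feature_state = ds$feature_state)
    evaluate_generated(gen, ds$label_state)
  })
  fit
})
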