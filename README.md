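# rnacircgen

Generative design of small RNA genetic circuits in R: simulate three-node
RNA binding circuits from pairwise minimum free energies, score their
signal-adaptation behaviour and evolutionary ruggedness, train a conditional
variational autoencoder (CVAE) on (circuit, function) pairs, and sample
novel circuits that follow functional prompts.

## The problem

A three-node RNA circuit is described by six pairwise binding free energies
`[k11, k12, k13, k22, k23, k33]` (kcal/mol; self-pairs included). Each
energy is converted to an equilibrium constant with an empirically
calibrated form

    K = exp(-0.8 (ΔG⁰ + 10)) / x₀        (per-copy units, x₀ = 100 copies)

and to mass-action rates via a fixed association rate
`k_f = 1.50958097e-3 copies⁻¹ s⁻¹` and `k_r = k_f / K`. The resulting
9-species ODE system (3 free RNAs, 6 complexes; production, first-order
degradation, reversible binding) is integrated in two phases: relax to a
pre-signal steady state, then double the production of the input RNA
(node 1) and follow the output RNA (node 3) to a new steady state.

From the input/output bookmarks the package computes signal **sensitivity**
`S = |((O_peak−O₁)/O₁) / ((I_peak−I₁)/I₁)|`, **precision**
`P = |((O₂−O₁)/O₁) / ((I₂−I₁)/I₁)|⁻¹`, a continuous **adaptation** score

    a = −(3 (log₁₀S − 7)² + (log₁₀P − 7.5)²) + 1000

and an evolutionary **ruggedness** `r = Σᵢ dkᵢ²` with
`dkᵢ = (a(kᵢ+ε) − a(k)) / ε`, ε = 1 kcal/mol, over the six interactions.

A CVAE (3×32 dense encoder/decoder stacks, leaky ReLU, 32-dimensional
latent, Gaussian KL regularisation) is trained on normalised circuits
conditioned on normalised functional labels; prompted decoding of
standard-normal latents generates new circuits. Prompt adherence is
quantified by the pairwise overlap of Gaussian KDE curves of the realised
metrics (0 = disjoint, 1 = identical), precision/recall/F1 against
prompts, and Ward-linkage motif clustering of adaptable circuits.

## Worked example

```r
library(rnacircgen)

circuits <- sample_energy_circuits(sampling_config(n_circuits = 1500, seed = 7))
metrics  <- simulate_circuit_metrics(circuits)
dataset  <- build_dataset(metrics, objective = "adaptation", seed = 7)
model    <- train_cvae(dataset, tconf = train_config(seed = 1))
reconstruction_r2(model, dataset)

generated <- cvae_generate(model, prompts = seq(0, 1, length.out = 10),
                           n_per_prompt = 60, seed = 3,
                           feature_state = dataset$feature_state)
adherence <- evaluate_generated(generated, dataset$label_state)
adherence$kde$adherence
```

On this run the dataset keeps 1,500 circuits (1,200 train / 300 test),
training stops early once more than 98 % of validation circuits are
reconstructed within 0.1 (normalised units), and
`reconstruction_r2(model, dataset)` prints `0.993` — 99.3 % of the
held-out variance in the six interaction strengths is recovered.
`adherence$kde$adherence` prints the mean pairwise KDE overlap of the ten
prompted adaptation distributions (`0.875` here; lower means prompts
produce more distinct circuit populations; see the methods vignette for
what is achievable at this training scale).

A one-shot pipeline (sample → simulate → label → train → generate →
re-simulate → evaluate) with a YAML-configurable entry point is available
as `run_pipeline()` and as the thin CLI in `inst/cli/rnacircgen`.

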