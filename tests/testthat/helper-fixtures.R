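# Shared fixture builders: every fixture is generated in code, seeded.

# A small null cohort (no effects) for calibration checks.
null_cohort <- function(n = 100, g = 50, seed = 1, noise_sd = 1, ...) {
  simulate_cohort(cohort_design(n, g, noise_sd = noise_sd, ...), seed = seed)
}

# A cohort whose first `n_step` genes carry a step effect at `cutoff`.
step_cohort <- function(n = 300, g = 12, delta = 1.5, cutoff = 30,
                        noise_sd = 0.5, seed = 1) {
  effects <- lapply(seq_len(g), function(i) {
    effect_spec(i, "step", age_effect = delta, true_cutoff = cutoff)
  })
  simulate_cohort(cohort_design(n, g, noise_sd = noise_sd), effects, seed = seed)
}

# Annotations enriched with radiation bins and an age class at `cutoff`.
annotate_classes <- function(ann, cutoff = 29) {
  ann$age_class <- as.character(dichotomize_age(ann$age, cutoff))
  ann
}

# Balanced assignment helper for hand-built matrices.
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}
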