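# deterministic small fixtures shared across test files

noiseless_coeffs <- function() gen_coeffs(moment_cv = 0, excursion_cv = 0)

make_trial <- function(seed = 1L, speed = 1.4, noise_sd = 0,
                       coeffs = gen_coeffs(), subject = NULL) {
  if (is.null(subject)) subject <- sample_cohort(1, seed = seed)[1, ]
  truth <- ground_truth(subject, speed, coeffs = coeffs, seed = seed + 100L)
  trial <- render_trial(subject, speed, truth, noise_sd = noise_sd,
                        seed = seed + 200L)
  list(subject = subject, truth = truth, trial = trial)
}

# small noiseless cohort dataset for pipeline-level tests
make_noiseless_dataset <- function(n_subjects = 6, seed = 42L,
                                   speeds = seq(0.9, 2.1, length.out = 5)) {
  cfg <- pipeline_config(seed = seed, n_subjects = n_subjects,
                         design = "grid", grid_speeds = speeds,
                         noise_sd = 0, coeffs = noiseless_coeffs())
  list(config = cfg, dataset = simulate_dataset(cfg))
}
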