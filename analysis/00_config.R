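# Shared configuration for the analysis scripts. Sourced, not run.
#
# The synthetic study emulates the mastodon mitogenome setting: ~16 kb
# sequences, serially sampled tips spanning the radiocarbon-to-aDNA-limit
# window, a strict clock of 3e-8 subs/site/yr, and a constant-size
# coalescent with Ne*generation-time of 1e5 years.

library(tipdater)

analysis_config <- list(
  out_dir = "results",
  seed = 2026,
  sim = list(n_tips = 16L, n_undated = 4L, pop_size = 1e5, rate = 3e-8,
             kappa = 20, alpha = 0.3, base_freqs = c(0.32, 0.26, 0.13, 0.29),
             seq_length = 16000L, missing_frac = 0.02, coverage = 10,
             deamination_rate = 0.2, tip_age_max = 250000),
  mcmc = list(chain_length = 200000L, sample_every = 200L, n_replicates = 2L)
)

dir.create(analysis_config$out_dir, showWarnings = FALSE, recursive = TRUE)
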