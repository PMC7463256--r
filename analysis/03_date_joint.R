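#!/usr/bin/env Rscript
# Stage 3: joint tip dating.
#
# All undated tips are free parameters of a single MCMC (duplicate chains),
# under the study priors: gamma(1, 200 ky) tip-age priors truncated to
# [50, 800] ky BP, Uniform[4e-10, 8e-8] clock rate, Uniform[1, 1e6]
# population size. Reports median + 95% HPD per undated tip and compares
# with the simulated truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

cfg <- c(analysis_config, list(stages = "date_joint"))
run_pipeline(cfg)

s <- read.delim(file.path(cfg$out_dir, "dating_joint.tsv"))
truth <- read.delim(file.path(cfg$out_dir, "ground_truth.tsv"))
est <- truth[truth$status == "estimated", ]
cat("Joint dating summaries (ages in years BP):\n")
print(s[, c("parameter", "median", "hpd_low", "hpd_high", "ess")], digits = 4)
for (i in seq_len(nrow(est))) {
  p <- paste0("age_", est$id[i])
  row <- s[s$parameter == p, ]
  truth_bp <- est$true_age[i] + 13000
  cat(sprintf("%s: truth %d BP %s its 95%% HPD [%d, %d]\n", p,
              round(truth_bp),
              if (row$hpd_low <= truth_bp && truth_bp <= row$hpd_high)
                "inside" else "OUTSIDE",
              round(row$hpd_low), round(row$hpd_high)))
}
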