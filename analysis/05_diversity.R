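#!/usr/bin/env Rscript
# Stage 5: clade-level F84 nucleotide diversity.
#
# Computes all pairwise F84 distances (pairwise deletion of missing sites)
# and per-clade nucleotide diversity (mean and SD of pairwise distances),
# the statistic used to contrast low-diversity expansion-front clades with
# diverse endemic ones.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

cfg <- c(analysis_config, list(stages = "diversity"))
run_pipeline(cfg)

s <- read.delim(file.path(cfg$out_dir, "diversity_summary.tsv"))
cat("Clade diversity (substitutions/site):\n")
print(s, digits = 4)
pairs <- read.delim(file.path(cfg$out_dir, "pairwise_distances.tsv"))
cat(nrow(pairs), "pairwise distances written to pairwise_distances.tsv\n")
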