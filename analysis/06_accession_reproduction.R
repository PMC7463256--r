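#!/usr/bin/env Rscript
# Stage 6 (optional, needs network/data): reproduce the published statistics
# on the real mastodon mitogenome alignment.
#
# This script is a driver for data the package cannot redistribute. To run:
#   1. download GenBank accessions MN616941-MN616973 plus NC_035800 and
#      EF632344, align them (e.g. mafft --auto), and save the alignment as
#      inst/extdata/accessions/mastodon_alignment.fasta (or adjust the paths
#      below);
#   2. provide clades.tsv (columns: tip, clade) assigning each specimen to
#      clades A/Y/G/M/N/L, and tip_dates.tsv (id, status, age_bp, lower_bp,
#      upper_bp) with the calibrated median ages for dated specimens;
#   3. provide fixed_topology.nwk (e.g. the maximum-likelihood topology).
#
# With those in place it computes the clade diversities and pairwise
# distances (F84, pairwise deletion, whole-alignment base frequencies, as
# dist.dna does) and runs the joint dating analysis at a reduced chain
# length.

library(tipdater)

data_dir <- "inst/extdata/accessions"
aln_path <- file.path(data_dir, "mastodon_alignment.fasta")
if (!file.exists(aln_path)) {
  cat("Accession alignment not found at", aln_path, "\n")
  cat("See the header of this script for how to obtain it; nothing to do.\n")
  quit(status = 0)
}

aln <- read_fasta(aln_path)
clades <- read.delim(file.path(data_dir, "clades.tsv"))
cat("Loaded", length(aln$ids), "sequences x", aln$n_sites, "sites\n")

for (v in list(list(name = "clade_Y_excl_RAM", clade = "Y",
                    exclude = "RAM_P94.16.1B"),
               list(name = "clade_Y_incl_RAM", clade = "Y", exclude = NULL),
               list(name = "clade_G_incl_VA", clade = "G", exclude = NULL),
               list(name = "clade_G_excl_VA", clade = "G",
                    exclude = c("ETMNH_19334", "ETMNH_19335")),
               list(name = "clade_A_pair", clade = "A", exclude = NULL))) {
  members <- setdiff(clades$tip[clades$clade == v$clade], v$exclude)
  nd <- nucleotide_diversity(aln, members, freqs = "global")
  cat(sprintf("%-18s pi = %.3e  sd = %s  (n = %d)\n", v$name, nd$pi,
              if (is.na(nd$sd)) "NA" else sprintf("%.3e", nd$sd),
              nd$n_members))
}

dates_path <- file.path(data_dir, "tip_dates.tsv")
tree_path <- file.path(data_dir, "fixed_topology.nwk")
if (file.exists(dates_path) && file.exists(tree_path)) {
  spec <- read_tipdates(dates_path)
  tree <- read_tree(tree_path)
  model <- default_model(aln)
  cfg <- mcmc_config(1e7, 1e4, n_replicates = 2L, seed = 99)
  clade_y <- clades$tip[clades$clade == "Y"]
  clade_a <- clades$tip[clades$clade == "A"]
  fit <- joint_dating(aln, tree, spec, clock_priors(), model, cfg,
                      clade_mrca = list(AY_split = c(clade_a[1], clade_y[1])))
  print(fit$summaries, digits = 4)
  write.table(fit$summaries, "results/accession_dating_joint.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
} else {
  cat("tip_dates.tsv / fixed_topology.nwk absent; skipping the dating run.\n")
}
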