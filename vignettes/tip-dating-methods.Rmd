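---
title: "Dating undated ancient specimens from serially sampled mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating undated ancient specimens from serially sampled mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipdater)
```

## The problem

Ancient specimens older than the effective radiocarbon limit (~50 thousand
years, ky) often cannot be dated directly. When a set of specimens of the
same species has been sequenced — here, complete mitochondrial genomes of
American mastodons, some with calibrated radiocarbon or geological ages and
some without — the dated specimens calibrate a molecular clock, and the ages
of the undated specimens can then be treated as free parameters of a Bayesian
phylogenetic model and estimated from how much evolution separates them from
the calibrated tips. `tipdater` implements that model end to end, together
with the clade-level nucleotide-diversity statistics and the ancient-DNA
consensus-curation rules that sit upstream and downstream of it, and a
synthetic-data generator that makes the whole chain verifiable by parameter
recovery.

## The model

The posterior is over a dated genealogy (node ages in years), a strict-clock
substitution rate, a coalescent population-size parameter, and the ages of
the undated tips:

* **Substitution model.** HKY with empirical base frequencies and
  4-category discrete-gamma rate variation (HKY+G4). The rate matrix is
  normalised to one expected substitution per site per unit of
  `rate x time`, so the clock rate is in substitutions/site/year. Gamma
  categories are equal-probability with rates at the quantile medians
  (`qgamma((2c-1)/8, alpha, alpha)`), mean-normalised — the usual "+G4"
  discretisation. The likelihood is computed by Felsenstein pruning over
  compressed site patterns; `N` and `-` are fully missing (partial
  likelihood of ones), so missingness never biases a branch length, it only
  removes information.
* **Tree prior.** The heterochronous (serially sampled) constant-population
  coalescent. With `k` active lineages, an interval of duration `dt`
  contributes `-k(k-1) dt / (2 N)` to the log-density and each coalescence
  contributes `-log N`. The parameter `N` is the product of effective
  population size and generation time, so it shares the tree's timescale
  (years); its prior is Uniform[1, 1e6].
* **Clock prior.** Uniform[4e-10, 8e-8] substitutions/site/year.
* **Tip-age priors.** Undated tips get a gamma(shape 1, scale 200,000 yr)
  prior — an exponential with mean 200 ky — truncated and renormalised to
  hard bounds, by default 50 ky (radiocarbon limit) and 800 ky (practical
  limit of ancient-DNA recovery), with per-tip overrides for specimens whose
  stratigraphy allows younger ages. Ages are handled internally relative to
  the youngest fixed tip (13 ky BP in the motivating data); bounds stated in
  absolute years BP are converted onto that scale. Because the exponential
  is memoryless, the absolute-vs-offset reading of the bounds changes
  nothing for the default prior; both interpretations are supported
  (`bounds_scale` in `tip_date_spec()`), with absolute as the default since
  the bounds are physical limits on calendar age.

## The sampler

`mcmc_run()` is a Metropolis–Hastings sampler with: multiplicative scale
moves on rate and population size; uniform node-age moves constrained
between a node's oldest child and its parent; a reflected random walk on the
root age; and reflected random-walk moves on each estimated tip age within
its bounds, proposed with relative weight 5 (the study design upweights tip
moves so unknown ages mix well). Narrow-exchange topology moves exist behind
a flag, but the default is a fixed user-supplied topology with free node
ages: at desk scale the topology is far better resolved than the tip ages,
and fixing it keeps chains short; this is the one deliberate departure from
a sampler that integrates over topologies.

Proposal scales auto-tune toward a 5–80% acceptance window during burn-in
only (default 10%) and are frozen afterwards to preserve detailed balance;
scales are clamped (e.g. a tip-age walk scale never exceeds its bound span)
because an almost-flat bounded target otherwise inflates the scale without
limit. The pruning likelihood is served by a small compiled engine that
caches per-node partial likelihoods: an age move only recomputes the path
from the changed node to the root, and rejected proposals restore the
overwritten blocks. No underflow rescaling is applied in the engine; at
mitogenome divergences with tens of tips the partials stay far above the
double-precision underflow threshold, which is a documented limit — hundreds
of tips or deeply saturated alignments would need a rescaling pass.

Two procedures wrap the sampler, mirroring the two published designs:

* **Joint** (`joint_dating()`): all undated tips free in one analysis, run
  in duplicate chains and pooled.
* **Individually dated** (`individual_dating()`): stage 1 dates each
  undated tip alone against only the fixed-date tips; stage 2 refits each
  stage-1 marginal as a boundary-reflected Gaussian-kernel density
  (`fit_prior()`), renormalised on the bounds; stage 3 reruns the combined
  analysis with those refits replacing the gamma priors. The reflected KDE
  was chosen over a moment-matched parametric refit because stage-1
  marginals are routinely truncated hard at a bound, which a reflected
  kernel represents and a gamma does not. With a single undated tip the two
  procedures coincide up to Monte-Carlo error, which the tests exploit as a
  self-consistency oracle.

Summaries (`summarize_trace()`) report the median, the shortest-interval 95%
HPD, a histogram mode, and an autocorrelation-time ESS (Geyer initial
positive sequence); parameters with ESS below 200 are flagged, and that
threshold is the convergence gate used throughout.

## Distances and diversity

`f84_distance()` implements the Felsenstein 1984 distance from transition
and transversion proportions with unequal base frequencies, deleting sites
pairwise where either sequence is missing. Frequencies default to the two
sequences pooled (`freqs = "pair"`); `freqs = "global"` pools the whole
alignment, which is the `ape::dist.dna` convention and is what the
diversity drivers use when reproducing published values. Saturated pairs
(non-positive logarithm arguments) are returned as flagged `NA`, never
clamped, and `nucleotide_diversity()` excludes them with a warning. Clade
diversity is the mean of all pairwise distances; the spread is reported as
the sample standard deviation (n−1), with a population-SD switch since the
convention is not fixed by the statistic itself. Two-member clades report a
distance, not a diversity.

## Consensus curation

The curation rules operate on per-position base counts: fragments shorter
than 24 bp or below MAPQ 30 are dropped (inclusive thresholds);
duplicates are collapsed on unique 5'/3' coordinates (highest MAPQ wins);
positions below 3x depth, inside a supplied region mask (e.g. the VNTR),
with a tied majority, or that are both abnormally deep (more than 3 SD
above the mean over covered positions) and multiallelic are masked to `N`;
the rest take the strict majority base. "Multiallelic" is quantified as at
least two alleles each supported by at least two reads, so a single stray
read cannot trigger masking, and the depth mean/SD use covered positions
only so uncovered flanks cannot deflate them (both choices are switches, as
the underlying convention is ambiguous). A consensus is "complete" when
strictly more than 80% of reference positions are non-`N`. Majority calling
deliberately ignores damage: the damage profile (`damage_profile()`) is a
diagnostic, and no 5'-T down-weighting is applied.

## The synthetic-data generator

`simulate_coalescent_tree()`, `simulate_sequences()` and
`degrade_to_reads()` generate data with exactly the structure the inference
assumes: serial tips on a constant-size coalescent, HKY+G4 evolution at a
given clock rate, patchy missing data in runs (mean run 300 bp by default —
consensus gaps come in blocks, not scattered sites), and ancient-DNA
fragmentation with terminal deamination. Damage is C→T at the read 5' end
with probability decaying geometrically (factor 0.5 per position) from the
configured terminal rate, and symmetrically G→A at the 3' end in the
default double-stranded mode; the magnitudes are free parameters, set to
0.2–0.3 in the drivers, which is the range typical of unrepaired ancient
libraries. Every public entry point takes a mandatory seed and is
bit-reproducible.

What the generator does not emulate: sequencing error beyond deamination,
indels and alignment error, contamination, reference bias from mapping, and
rate variation between lineages (the data are generated under the strict
clock that the model assumes). Passing recovery tests therefore validate
the implementation — the estimator applied to data from its own model —
not robustness to model violations on real data.

## Study conditions and problem sizes

The defaults throughout are the study conditions: ~16 kb sequences, clock
rate 3e-8 subs/site/yr, `Ne x generation time` = 1e5 yr, tip ages spanning
13–800 ky BP, gamma(1, 200 ky) tip priors on [50, 800] ky, tip-move weight
5, duplicate chains. The test suite and acceptance script run the recovery
study at 20 tips x 15 kb with 5 undated tips and 2e5-step chains, and the
prior-only calibration at ~1e6 steps thinned to about 1e4 samples; those
sizes give stable coverage and KS statistics while keeping a full run of
the suite in the tens of minutes. The published analysis used 5e8-step
chains on 35 mitogenomes; nothing in the implementation caps chain length,
so that scale is reachable, just slow on one core.

The prior-only calibration deserves one note: it uses two tips (one fixed,
one estimated) because for two serially sampled tips the coalescent
density integrates to one over the root age for any tip age, so the
sampled tip-age marginal should equal the truncated exponential prior
*exactly*, making the Kolmogorov–Smirnov check sharp. With more tips the
tree prior would tilt the marginal and the test would confound sampler
correctness with prior interaction.

## Numerical choices and degenerate inputs

Transition probabilities come from a spectral decomposition of the
symmetrised HKY rate matrix, computed once per model; tiny negative
eigen-roundoff entries are clipped to zero. Zero-length branches produce the
identity matrix, and a zero rate in the sequence simulator short-circuits to
copying the root draw. Majority ties, saturated distances and all-missing
alignments each have defined, conservative behaviour (mask, flag, likelihood
1). `fit_prior()` falls back to a minimal bandwidth when all samples
coincide, so a degenerate stage-1 posterior still yields a usable
near-point-mass prior. HPD ties break toward the lower start, making the
interval deterministic.

## Limitations

Fixed topology by default (above); strict clock only; no relaxed clocks,
skyline priors, or marginal-likelihood model comparison; no BAM/SAM parsing
(curation starts from read records or site counts); no contamination or
sequencing-error modelling; single-threaded. Reproducing the published
accession-level numbers requires downloading the GenBank alignment, which
the package cannot redistribute — `analysis/06_accession_reproduction.R`
documents the exact procedure.
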