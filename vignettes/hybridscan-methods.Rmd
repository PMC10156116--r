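---
title: "Methods: coalescent tests of homoploid hybrid speciation"
author: "hybridscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent tests of homoploid hybrid speciation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscan)
```

## The problem

Homoploid hybrid speciation (HHS) is the origin of a new, reproductively
independent lineage by hybridization between two species without a change
in ploidy.  The motivating system is a five-taxon group of fur seals: an
outgroup (Antarctic fur seal, `Afs`), the New Zealand fur seal (`NZfs`),
and a trio in which the Peruvian fur seal (`Pfs`) is a candidate hybrid
between the Galapagos (`Gfs`) and South American (`SAfs`) fur seals.
Distinguishing an instantaneous hybrid origin from ordinary introgression
into a pre-existing lineage is the hard part: both produce admixed
genomes, intermediate allele frequencies, and gene-tree discordance.

hybridscan implements the computational core of that inference as a
single testable pipeline: (i) a structured-coalescent simulator that
generates SNP panels, gene trees and read counts under explicit
demographic scenarios; (ii) the f-statistic family (f3, f4, D, f4-ratio,
f-branch) with block-jackknife significance; (iii) topology weighting of
per-window gene trees; (iv) ABC model choice between the instantaneous
hybrid origin and three introgression alternatives; and (v) ploidy and
aneuploidy diagnostics.

## The coalescent generator

`demographic_scenario()` describes constant-size populations connected by
population splits (merges backward in time) and instantaneous admixture
pulses.  `simulate_panel()` draws one independent genealogy per SNP
(unlinked sites), places a single mutation uniformly on the genealogy
(so every site segregates), and returns diploid dosages;
`simulate_gene_trees()` returns one genealogy per 50-kb window with free
recombination between windows and none within.  These match the
independence assumptions of the downstream statistics and keep runtimes
at desk scale.  Ties between simultaneous events are resolved by applying
pulses before merges, which is what lets a hybrid origin be written as
"pulse from one parent, then merge into the other" at the same time.

What the generator deliberately does not emulate: within-window
recombination, linkage between SNPs, mutation-model detail (every site is
a clean biallelic SNP), genotyping error and missingness (add them via
the panel tools if needed), and population growth (all sizes are
constant per branch).  Passing tests therefore demonstrate correctness of
the statistics under their own assumptions, not robustness to linkage or
genotyping artifacts in real data.

`fur_seal_history()` encodes the emulated five-taxon history: root
calibration 2.4 Ma, `NZfs` split 1.5 Ma, `Gfs`/`SAfs` split 0.64 Ma, and
a `Pfs` hybrid origin 0.43 Ma with 67% `Gfs` / 33% `SAfs` ancestry, all
converted at 11.7 years per generation.  Two defaults deserve comment
because no external value fixes them:

* **Effective sizes** (`ne = 10000` on ordinary branches,
  `ne_pfs = 150000` on the hybrid).  A hybrid lineage that still shows a
  clearly negative f3 and strong genome-wide topology discordance tens of
  thousands of generations after its origin must have experienced little
  post-origin drift; in a constant-size coalescent that is a large Ne.
  With uniform sizes the emulated `Pfs` would have sorted its ancestry
  long ago and f3 would be positive, contradicting the signal structure
  the history is meant to reproduce.
* **The SAfs deme split** (`deme_split_gen = 45000`, i.e. before the
  hybrid origin at ~36,750 generations).  The second deme exists so that
  a within-species sister of the donor is available for classical
  f4-ratio configurations, which require the sister to have diverged
  before the admixture event.  The cost is that the two demes are more
  differentiated than real SAfs populations; analyses that need realistic
  deme FST should lower this value and forgo the deme-based f4-ratio.

## f statistics

All estimators are frequency products over sites: `f3(C;A,B) =
mean((c-a)(c-b))`, `f4(A,B;C,D) = mean((a-b)(c-d))`, the D statistic as
the normalized ABBA-BABA imbalance computed from derived-allele
frequencies after `polarize_by_outgroup()`, and the f4-ratio as a
quotient of two f4 sums.  Standard errors come from a weighted
delete-one-block jackknife over blocks of equal SNP count
(`partition_blocks()`, default 10,000 SNPs per block), with significance
at `|z| > 3` throughout and no multiplicity adjustment.

**Small-sample correction.**  The plain products are biased by the
sampling variance of the allele-frequency estimates whenever a
population appears in both factors: for f3 the bias is `+Var(c_hat)`,
which with two diploids per population is large enough to push a true
hybrid's f3 positive.  Every estimator therefore takes a `corrected`
argument that removes the sampling-covariance terms using the unbiased
estimate `p(1-p)/(n-1)`.  The default is `corrected = FALSE` (the exact
algebraic product, appropriate when frequencies are population values),
and detection-oriented wrappers (`hybrid_triple_scan()`) always correct.

**Ancestry proportion from a triple.**  With only (P1, hybrid, P2,
outgroup) available, any single f4-ratio must reuse one parent and is
biased by that parent's post-admixture drift: the P1-reuse form
`f4(P1,O;X,P1)/f4(P1,O;P2,P1)` is inflated, the Green form
`f4(P1,X;P2,O)/f4(P1,P2;P2,O)` attenuated (by the factor
`(Tdiv-Th)/Tdiv`, about 0.33 in this system).  Writing both as functions
of the shared drift terms and solving gives `triple_gamma()`:
`gamma = g2 / (1 - g1 + g2)`, exact when the parents' post-admixture
drifts are symmetric and identical to the plain ratio on drift-free
mixtures.  When a genuine pre-admixture sister of a donor exists (the
second SAfs deme), the classical five-population `f4_ratio()` is
preferred; both recover the generating proportion to well within 0.1 at
50,000 SNPs.

`f_branch()` summarizes excess allele sharing on a rooted population
tree: for each branch and each non-descendant population C, the cell is
the minimum over (descendant, sister) pairs of the Green-style admixture
fraction — the minimum for conservatism — with cells whose configuration
is undefined marked inestimable.

## Topology weighting

`weight_gene_tree()` computes, per window, the fraction of
one-tip-per-group subsamples (three ingroups plus outgroup) inducing each
of the three rooted ingroup topologies.  Enumeration is exhaustive up to
10,000 combinations (the product of group sizes), Monte Carlo with 1,000
draws above that.  A subsampled quartet is resolved from pairwise MRCA
depths (the deepest MRCA identifies a cherry); polytomies contribute 1/3
to each topology, which is unbiased under ignorance and keeps weights
summing to one.  `smooth_weights()` applies a rectangular-kernel local
mean (default span 1 Mb) per scaffold with renormalization; the span is a
display choice, not an inference parameter.

## ABC scenario test

`build_scenarios()` encodes four demographic templates for the origin of
the hybrid: (1) instantaneous hybrid origin at `Th` (Gfs proportion
`alpha`); (2) a SAfs offshoot that lives `Tg` generations and receives a
Gfs pulse at `Th`; (3) the mirror image with a Gfs offshoot and duration
`Ts`; (4) fusion of two offshoots.  Priors are uniform: `Th` over the
externally estimated 0.40-0.46 Ma interval, `Tdiv` within 10% of 0.64
Ma, extant and hybrid Ne in (100; 100,000), offshoot Ne in (10; 10,000),
`alpha` in (0.05; 0.95), and `Tg`, `Ts` in (`m`; `Tdiv - Th`) where the
structural minimum `m` (0, 100 or 300 generations) is the discriminating
constraint: at `m = 0` the alternatives contain the instantaneous
scenario as a boundary case.

`summarize_panel()` computes a fixed 26-statistic vector patterned on
the one-, two- and three-sample statistics of SNP-based ABC reference
software: heterozygosity and monomorphic fraction per population;
pairwise Hudson FST, Nei distance, and the across-site variance of
squared frequency differences; f3 of the hybrid and its across-site
variance; per-population frequency means and variances; and the kurtosis
of pairwise frequency differences.  The higher moments are included
because drift confined to one ancestry component of an admixed genome
(an offshoot bottleneck) leaves first moments nearly unchanged once the
hybrid's own Ne is free to compensate; only the shape of the per-site
frequency differences carries the residual signal.

`model_choice()` retains the closest 1% of simulations by standardized
Euclidean distance (rejection posterior = scenario shares), then fits a
distance-weighted (Epanechnikov) multinomial logistic regression on the
scenario labels and evaluates it at the observed point.  The regression
uses the linear-discriminant projection of the statistics (three axes
for four scenarios) because a raw 26-covariate multinomial fit on ~200
retained rows would have more parameters than observations.
`estimate_params()` produces Epanechnikov-weighted rejection posteriors
for scenario parameters; `model_check()` projects prior cloud,
posterior-predictive cloud and observed point on the first two principal
axes of the prior-simulated statistics and flags the fit by the observed
point's Mahalanobis distance to the posterior cloud (95% chi-square
ellipse).

**Honest limitation.**  At the desk scale used throughout this package
(1,000 unlinked SNPs, 2 diploids per population, 5,000 simulations per
scenario), the four scenarios overlap heavily under their priors: the
alternatives contain near-instantaneous corners, and offshoot drift
trades off against the hybrid's own Ne, so data simulated under the
instantaneous origin receive a scenario-1 logistic posterior of roughly
0.3-0.6, not the near-certainty attainable with full-scale data (more
SNPs and individuals shrink the noise ball until the mimicking prior
volume is negligible, and two orders of magnitude more simulations
sharpen the rejection).  What does survive scaling down, and what the
test suite asserts, is the calibration structure: the generating
scenario is systematically enriched (top-model accuracy and mean
own-scenario posterior clearly above the 1/4 chance level), the
`Tg`/`Ts` posteriors concentrate at their lower bound on hybrid-origin
data, and the scenario-1 posterior increases with the structural minimum
`m`.

## Ploidy and coverage diagnostics

`simulate_read_counts()` draws, per heterozygous site, a dosage class
uniform on `1..ploidy-1`, Poisson coverage, and binomial alternate reads
with success probability `k/ploidy` perturbed by a symmetric error rate.
`allele_balance_histogram()` bins `alt/(ref+alt)` for sites with
coverage in [10, 100] at bin width 0.02.  `classify_ploidy()` detects
modes on a Gaussian-kernel smoothing of the binned mass (bandwidth = bin
width, threshold 1.3 times the uniform density, modes within 0.08
merged) rather than on the raw bins: read-count lattices make raw
histograms saw-toothed, and a tetraploid's modes at coverage 30 are too
low for a simple per-bin threshold.  Candidates 2-4 are scored by the
summed distance of expected internal peaks `{k/p}` to detected modes;
the call is undetermined if the best score exceeds 0.08 or the mode
count disagrees.  `scaffold_coverage_deviation()` screens the largest
scaffolds (default 100) for aneuploidy by percent deviation from the
length-weighted genome mean, flagged beyond 25% — the computation is
standard; the flag threshold is a reporting choice.

## Reproducibility and problem sizes

Every stochastic function takes an integer seed, and identical seeds
give bitwise-identical outputs (the compiled coalescent engine uses R's
RNG stream).  Reference tables derive per-draw seeds deterministically
from the master seed, scenario id and draw index.  The test suite and
the acceptance script run at fixed desk-scale sizes chosen as the
package's own defaults: 20,000-100,000 SNPs for f-statistic checks,
1,000 windows for topology weighting, 20,000 read-count sites for
ploidy, and reference tables of 1,000-5,000 simulations per scenario at
500-1,000 SNPs for the ABC machinery.

## Known limitations

* Unlinked-SNP simulation cannot produce ancestry-tract or LD signals;
  nothing here tests tract-length-based dating.
* The ABC test's discriminatory power at desk scale is limited (see
  above); the acceptance thresholds derived from full-scale analyses are
  reported as computed, not enforced by construction.
* `f_branch` significance uses the single minimizing configuration's
  jackknife z; no multiplicity adjustment is applied, matching the
  `|z| > 3` convention used throughout.
* The VCF reader consumes only CHROM, POS, REF, ALT and GT, treats `|`
  and `/` identically, and ignores ploidy other than 2 in genotypes.
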