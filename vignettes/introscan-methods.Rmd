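---
title: "Detecting introgressed windows with two-population summary statistics and extremely randomized trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgressed windows with two-population summary statistics and extremely randomized trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

When two closely related populations or sister species exchange migrants,
the recipient population carries genomic segments whose genealogy is
anchored in the donor. `introscan` asks, for each genomic window of a
two-population sample of phased haplotypes, whether that window experienced
recent introgression, and if so in which direction. Because labelled
examples of introgressed loci are essentially never available, the
classifier is trained entirely on coalescent simulations: windows are
simulated under a two-population isolation model without migration, and
with a pulse of admixture in each direction, and an ensemble of extremely
randomized decision trees learns to separate the three classes from a
vector of summary statistics.

## The feature vector

Each window is summarised by 31 statistics (`feature_names()` fixes their
canonical order). For each population separately: nucleotide diversity
$\pi$, the variance of per-bp pairwise distances, the densities of
segregating and private polymorphisms, Fay and Wu's $H$ and
$\theta_H$, Tajima's $D$, Kelly's $Z_{nS}$ (mean $r^2$ over SNP pairs), and
the number of distinct haplotypes — nine per population. Across
populations: Hudson-style $F_{ST}$, the nearest-neighbour statistic
$S_{nn}$, per-bp $d_{xy}$ and $d_{min}$ (mean and minimum divergence over
all cross-population haplotype pairs), $G_{min} = d_{min}/d_{xy}$, the
scaled minimum divergences $d_{d1} = d_{min}/\pi_1$ and
$d_{d2} = d_{min}/\pi_2$ with their percentile ranks $d_{d\text{-Rank}p}$
among within-population pairwise divergences, the linkage-disequilibrium
contrast $Z_X = (Z_{nS1} + Z_{nS2})/(2 Z_{nSG})$ (within-population versus
pooled LD), and three identity-by-state tract summaries: the maximum IBS
tract length over cross-population pairs and the mean tract lengths within
each population.

The rationale: a single introgressed haplotype drags $d_{min}$ down to the
coalescent scale of the *donor* population, so $d_{min}$ relative to
within-population diversity ($d_{d}$, $d_{d\text{-Rank}}$) is a sharp and
direction-informative signal; introgression also inflates within-population
LD but not pooled LD ($Z_X$), creates long shared IBS tracts across the
species boundary ($IBS_{MaxB}$), and perturbs the within-population SFS
statistics asymmetrically in donor and recipient.

Conventions that matter:

* **Per-bp denominators use the unmasked length** $L_u$, not the nominal
  window length, so masked windows are comparable to clean ones.
* **Sentinels for degenerate windows.** Statistics with empty denominators
  are set to 0 ($G_{min}$, $Z_X$, $F_{ST}$, Tajima's $D$, $Z_{nS}$); when
  $\pi_p = 0$, the $d_{dp}$ denominator is replaced by the smallest
  attainable nonzero diversity, $1/(L_u \binom{n_p}{2})$. Because training
  and test data share these conventions, the classifier learns their
  semantics; the exact sentinel choice is immaterial as long as it is
  consistent.
* **Ranks use midranks** and are reported as fractions in $[0, 1]$.
* **Missing alleles** participate pairwise-complete in divergences and
  $r^2$; haplotype distinctness treats them as wildcards (conservative,
  fewer haplotypes); sites missing in every haplotype carry no information
  and are dropped.
* **Polarization.** Simulated data are polarized (ancestral allele 0). For
  VCF input without ancestral annotation the REF allele is treated as
  ancestral and the window is flagged unpolarized; Fay and Wu's statistics
  should then be interpreted with caution (they remain well-defined
  features for a classifier trained under the same convention).
* $F_{ST}$ is computed as $1 - \bar\pi_{within}/d_{xy}$; negative
  estimates are retained.

Hot inner loops (pairwise difference counts, maximum IBS tract, mean
$r^2$) are implemented in C++ on bit-packed haplotypes; every statistic is
checked against an independent brute-force R implementation in the test
suite (tolerance $10^{-9}$ on hundreds of randomized small windows).

## The simulation engine

Simulations run through a bundled Python driver using msprime, an exact
ms-compatible coalescent-with-recombination engine that records lineage
migrations, which is how the migrant truth (which sampled haplotypes carry
introgressed material, and which tracts) is reconstructed. Scaling follows
the ms convention: a diploid reference size $N_0$ (default $10^4$; results
are invariant to it), $\theta = 4N_0\mu L$, $\rho = 4N_0 r L$, times in
units of $4N_0$ generations, migration rates $4N_0 m$. Samples are haploid
genomes, so msprime population sizes are set to $2N_0$ (verified against
the Watterson expectation in the tests).

The standard study conditions, which are also the package defaults:
$\theta = 50$ and $\rho = 250$ for a 10 kb window (Drosophila-like), 15
haploid genomes per population, constant population sizes equal to the
ancestral size, and split times $T_D \in \{0.25, 1, 4, 16\} \times 4N$.
Training grids draw the pulse time $T_M$ from
$\{0.01, 0.05, 0.10, \ldots, 0.90\} \times T_D$ and the per-lineage
migration probability $P_M$ from $\{0.05, \ldots, 0.95\}$ — 361 cells per
direction, with replicates allocated as equally as possible by an even
quota rule ($n_i = \lfloor i\,n/C \rfloor - \lfloor (i-1)\,n/C \rfloor$
over the ordered cells), so that totals smaller than the cell count still
cover the whole grid uniformly instead of clumping on the most recent
pulses; test grids add $T_M = 0.001 \times T_D$. Training examples of the two introgression
classes are conditioned (by rejection with fresh seeds, capped at $10^4$
attempts) to contain at least one migrant lineage; test examples are not.
Backwards in time, the pulse moves each lineage currently in the recipient
population into the donor with probability $P_M$, matching the forward
interpretation of $P_M$ as the probability that a lineage migrates from
source to sink.

Two further model families are provided: a ghost-donor model in which the
introgression source is a third, unsampled population splitting from the
ancestor at $T_D$, and a parameter-draw scheme for training under an
uncertain demographic history (every parameter drawn uniformly from
$[x/2, 3x/2]$ around its point estimate, $T_M \sim U(0, T_D/4]$ in
generations, $P_M \sim U(0, 1]$, $\mu = 3.5 \times 10^{-9}$, $\theta/\rho$
fixed at 0.2, continuous migration zero). A deliberately simplified
"island" model can be constructed directly from observed summaries
($N_p = \pi_p/4\mu$, $N_{anc} = N_1$, $T = d_{xy}/2\mu - 2N_{anc}$
generations) to probe robustness to model misspecification.

For base-pair-level benchmarking, 1 Mb contigs ($\theta = 5000$,
$\rho = 25000$) are simulated with the admixture pulse confined to the
central 100 kb. A coalescent engine cannot condition a pulse on the genomic
span of each lineage, so the contig is assembled from independently
simulated chunks — the central segment carries the pulse, the flanks do not
(flanks are further subdivided into 100 kb chunks because ARG cost grows
superlinearly with $\rho$). The chunk boundaries act as a handful of
forced free-recombination points among the $\sim 25000$ expected
recombination events per contig, a negligible perturbation of LD at this
scale.

What the generator deliberately does not emulate: natural selection,
mutation/recombination rate heterogeneity along real chromosomes,
genotyping and phasing error, and within-population structure. Passing
tests therefore demonstrate correctness of the method under its own model
class, not robustness to every feature of real data; the
parameter-draw and mask-mirroring utilities (`draw_drosophila_model()`,
`apply_real_mask()`) are the tools provided to narrow that gap in real
applications.

## The classifier

The three-class (or, for ROC work, binary) classifier is a probability
forest of extremely randomized trees — at each node a random subset of
features is considered and split thresholds are drawn at random —
implemented with `ranger::ranger(splitrule = "extratrees",
num.random.splits = 1)`, 100 trees by default. Before the final fit, a
cross-validated grid search selects `mtry` over $\{1, \sqrt{p}, p/2, p\}$
and `min.node.size` over $\{1, 10\}$ by 5-fold accuracy; the split
criterion is Gini impurity (the extremely-randomized split scheme in
ranger does not expose an entropy criterion; impurity-based importances
are Gini-based in any case). Training is deterministic given a seed
(single-threaded).

A window is *called* introgressed when the posterior probability of the
no-introgression class falls below a cutoff — 0.05 by default. Posterior
probabilities of tree ensembles can be miscalibrated, and the appropriate
cutoff depends on the demography: under very old splits (e.g.
$T_D = 16 \times 4N$) the 0.05 cutoff is anticonservative and a 0.01
cutoff restores a usable false positive rate. `calibrate_cutoff()`
automates the choice: it returns the largest cutoff whose empirical false
positive rate on a simulated no-migration set stays below a target. The
direction of gene flow is the larger of the two introgression posteriors,
with exact ties broken deterministically toward the first introgression
class. Feature importances use a 500-tree ensemble and are mean decreases
in Gini impurity normalized to sum to one.

## Scanning, regions, refinement, enrichment

Genome scans cut each contig into windows (10 kb by default,
non-overlapping for region calling, 1 kb steps for base-pair-resolution
work). Windows with more than 25% of their length masked are excluded and
carry no evidence; they also *break* runs during clustering, a conservative
choice for region boundaries. Regions are maximal runs of consecutive
retained windows with posterior probability of introgression above 0.90,
retained if at least one member exceeds 0.95 (both strict inequalities);
the region direction is the majority vote of member windows, ties resolved
by the maximum-posterior member. A finer classifier (1 kb windows, 100 bp
steps) can refine coarse regions with a relaxed 0.5 cutoff — lenient
because it only runs inside regions that already passed the coarse
classifier. Annotation enrichment of called regions uses a permutation
test: each region is independently re-placed uniformly among all positions
where its full span fits inside the accessible genome, the number of
annotation features overlapped is recomputed ($10^4$ permutations by
default), and the p-value carries an add-one correction.

## Numerical and design choices

* Fractional ms positions map to distinct integer bp by rounding and a
  deterministic left-to-right shift to the nearest free integer; order is
  preserved.
* Interval arithmetic is 0-based half-open everywhere; the VCF reader is
  the only place 1-based coordinates appear.
* Replicate-level seeds are derived from the user seed by a fixed integer
  recurrence kept below $2^{31}$; fixture randomness, simulation
  randomness, and classifier randomness use separate derivations so that
  test fixtures are stable.
* Windows that are entirely masked raise an error rather than returning
  sentinel-only feature vectors.

## Problem sizes used by the packaged analyses

The original study trained on $10^4$ examples per class and evaluated on
$10^4$ replicates per grid cell. The packaged acceptance analysis and test
suite use reduced sizes chosen up front — training sets of 400–1000
examples per class and test sets of 500–3000 windows, with binomial or
rank-statistic standard errors small relative to the comparisons of
interest (classification power is known to be stable down to $10^3$ and
even $10^2$ training examples per class). The deep-split scenario
($T_D = 16 \times 4N$) is the most expensive to simulate (ancestral
recombination on the long internal branches), which is why its test sets
sit at the lower end of that range. The base-pair-level contig benchmark
subsamples the $(T_M, P_M)$ grid (every other value on both axes) with one
contig per cell plus no-migration controls.

## Known limitations

* The method is windowed: tracts much shorter than the window size dilute
  the signal, and direction calls for barely-introgressed windows are
  noisy.
* Posteriors are not calibrated probabilities; use simulated nulls to pick
  operating points.
* The ghost-donor scenario is detected only weakly by a two-population
  classifier — by design it is reported as an evaluation scenario, not a
  class.
* Continuous low-level migration produces migrant windows that the
  pulse-trained classifier often misses at low rates; at high rates
  detection approaches 100%.
* No selection is modelled; strongly selected introgression or sweeps can
  distort statistics in ways the training distribution does not cover.
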