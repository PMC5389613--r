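---
title: "Methods: population genetics of bulked microsatellite samples"
author: "bulkpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics of bulked microsatellite samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkpop)
```

## The problem

Characterizing heterogeneous crop landraces one plant at a time is
expensive: a landrace population segregates at most microsatellite (SSR)
loci, so a single individual badly under-samples its allele pool. The
bulked strategy pools DNA from many plants (here 15) and genotypes the pool
as one sample. Each SSR then yields, per population, a set of
electropherogram peaks whose fragment sizes identify alleles and whose
heights are approximately proportional to allele dosage in the pool.
`bulkpop` implements the full analysis chain for such data:

1. **Peak calling** — ladder binning, stutter and noise filtering, and
   height-proportional allele-frequency estimation per bulk.
2. **Pseudo-individual simulation** — reconstruction of a diploid sample
   matching the bulk frequencies, for methods that need genotypes.
3. **Diversity statistics** — Nei gene diversity, allele counts, unique
   alleles per cluster.
4. **Distances and ordination** — proportion-of-shared-alleles (PSA)
   distance, neighbor-joining trees, principal coordinate analysis.
5. **Admixture model** — Bayesian clustering by Gibbs sampling, Evanno
   delta-K model choice, ancestry-threshold assignment, and hierarchical
   sub-structure scans.
6. **Synthetic data** — a generator with stored ground truth so every stage
   is verifiable end to end without external data.

## Peak calling

Peaks arrive as (size in bp, height, optional quality). For a locus with
repeat unit $u$ and size range $[s_{\min}, s_{\max}]$, sizes are snapped to
the ladder $s_{\min} + k\,u$; a peak farther than `bin_tolerance`
(default $u/2$) from every rung is discarded as off-ladder. A peak exactly
midway between two rungs goes to the lower rung — an arbitrary but
deterministic and documented choice.

PCR stutter produces an artifact peak one repeat unit below a true allele.
Scanning rungs from largest to smallest, a peak at $a - u$ is deleted iff
its height is below `stutter_ratio` (default 0.2) times the height of the
retained peak at $a$; second-order stutter removal at $a - 2u$ exists
behind a flag and is off by default because minus-one stutter dominates for
short repeat motifs. Peaks below `noise_floor` (default 0.05) times the
tallest retained peak are then dropped. Both thresholds are conventional
fragment-analysis values, exposed as parameters; the filtering operation is
idempotent. "Preferential amplification" is interpreted as false-peak
removal; an optional linear height re-weighting by fragment size
(`size_reweight`) is available for users who prefer an explicit correction,
but is off by default since no correction function is canonical. Quality
scores are carried through but do not gate inclusion by default.

The frequency of allele $a$ in the bulk is its filtered peak height divided
by the sum of retained heights, so each (bulk, locus) profile sums to
exactly 1. If filtering removes every peak the entry is masked missing —
never encoded as zeros, since zero is a legitimate observed frequency.

## Pseudo-individuals

Some estimators want genotypes rather than pooled frequencies. For each
population and locus the $2n$ allele copies of $n$ diploid individuals
(default $n = 15$, the number of plants pooled) are apportioned to the bulk
frequencies by largest-remainder rounding — ties broken by larger quota and
then smaller allele size, every allele with $p \ge 1/(2n)$ keeps at least
one copy, and each count is within one copy of its real-valued quota. The
copies are then shuffled and paired. If the realized heterozygosity differs
from the Hardy–Weinberg expectation $1 - \sum_a \hat p_a^2$ (computed from
the *apportioned* frequencies, for internal consistency) by more than
`het_tolerance` (default 0.05), single-allele swaps between a homozygote
and a heterozygote nudge it toward the target; swaps conserve allele counts
exactly, so the bulk frequencies are never distorted. Swap repair was
chosen over rejection sampling because it terminates by construction.
Heterozygosity is matched per locus; loci are simulated independently.

## Diversity statistics

Gene diversity at a locus is $H = 1 - \sum_a p_a^2$. Cluster summaries
average allele frequencies *unweighted* across the cluster's member
populations (populations missing a locus are skipped at that locus), then
average $H$ over loci; a pooled-count alternative would weight populations
by sample size, which is not what per-cluster "average measurement"
summaries conventionally report for bulk surveys. Allele counts are
distinct (locus, allele) pairs with pooled frequency strictly above zero —
no minimum-frequency filter. An allele is *unique* to a cluster when its
pooled frequency is positive there and zero in all other clusters of the
comparison set; for sub-clusters the comparison set is restricted to
siblings under the same parent.

## Distances, trees, ordination

The PSA distance between populations $i$ and $j$ is

$$d_{ij} = 1 - \frac{1}{L'} \sum_{l \in \text{shared}} \sum_a
  \min\!\big(p_i(l,a),\, p_j(l,a)\big),$$

with pairwise deletion of masked loci ($L'$ = number of loci scored in
both). It is bounded in $[0, 1]$ and symmetric, and is computed on the
frequency profiles; a genotype-level variant (averaging allele sharing over
individual pairs) would re-introduce simulation noise into a quantity that
is already defined on frequencies.

Neighbor joining follows Saitou–Nei with the criterion
$Q(i,j) = (n-2)\,d_{ij} - R_i - R_j$. Ties are broken by the
lexicographically smallest index pair so runs are reproducible; negative
branch estimates are clamped to zero with the deficit moved to the sibling
branch, preserving the joined pair's distance. On additive inputs the tree
reproduces the matrix exactly.

PCoA uses Gower centering of squared dissimilarities,
$B = -\tfrac12 J D^{(2)} J$, and keeps axes with positive eigenvalues;
negative eigenvalues (non-Euclidean input — PSA matrices are generally not
Euclidean) are reported, and variance explained is taken over the positive
part of the spectrum. No correction is applied by default; a Lingoes
correction is available when the negative part of the spectrum matters.

## The admixture model

Each allele copy of each sampling unit originates from one of $K$
clusters. Cluster $k$ has allele frequencies $P_{k,l}$ per locus with an
independent Dirichlet($\lambda$) prior ($\lambda = 1$); unit $j$ has an
ancestry vector $Q_j$ with a symmetric Dirichlet($\alpha$) prior; $\alpha$
is shared across units with a uniform prior on $(0, 10]$ and a random-walk
Metropolis update (proposal sd 0.025). A correlated-frequencies prior is
deliberately not implemented; the plain admixture model is the target. One
Gibbs sweep updates, in blocks: origin assignments
$Z \mid P, Q$ (categorical, $\Pr(k) \propto q_{jk} p_{k,l,a}$), then
$P \mid Z$ and $Q \mid Z$ as Dirichlet draws from prior plus counts, then
$\alpha$. The sampler is compiled (C++) with a self-contained
xoshiro256++ stream, so a run is reproducible from its seed independently
of R's RNG state.

By default the 15 pseudo-individuals of a population are the sampling
units, and the population's ancestry $\bar Q$ is the mean of its
individuals' posterior-mean $Q$ vectors; a `unit = "population"` mode
treats each population's pooled copies as a single unit instead.

The model evidence proxy is $\mathrm{LnP(D)} = \overline{\ell} -
\operatorname{var}(\ell)/2$ over post-burn-in log-likelihood samples
(recorded every `ll_every` sweeps; the thinned mean and variance estimate
the same quantities as the full trace at a fraction of the cost). Replicate
runs are label-aligned greedily by Q-column dot products. The Evanno
statistic divides the absolute second difference of mean LnP(D) by the
between-run standard deviation at each interior $K$; zero standard
deviation leaves delta-K undefined (flagged, not infinite), and all local
maxima are reported because real scans often show several competing peaks
— the final choice of $K$ belongs to the analyst.

Populations are assigned to their majority cluster when the maximum
ancestry strictly exceeds 51%, and to a "mixed" group otherwise;
assignments at or below 80% are flagged as weak ("less representative").
Sub-structure reruns the whole scan-select-assign pipeline inside each
non-mixed cluster, namespacing sub-group labels under the parent.

## Synthetic data and what the tests show

The generator draws, per locus, ancestral frequencies from a flat
Dirichlet, cluster frequencies from the F-model
$\mathrm{Dir}\big(p_{\text{anc}}(1-F)/F\big)$, population ancestries from
Dirichlet($\alpha_{\text{admix}}$), and individual genotypes from the
ancestry-weighted mixture. Defaults emulate the survey design the package
targets: 28 loci with 2–21 alleles, 15-plant bulks, drift $F = 0.2$
(admixture-recovery experiments use $F = 0.25$), ancestry concentration
0.2 (mostly near-pure populations with a minority of strongly admixed
ones). Peak rendering inverts peak calling: heights are frequencies times
an arbitrary $10^4$ intensity scale under 5% lognormal jitter, stutter
peaks are injected one repeat below each allele at height ratios
$U(0.05, 0.18)$, and small off-ladder noise peaks appear at rate 0.02 per
(bulk, locus).

The generator reproduces the *shape* of bulk SSR data, not all of its
physics: no dye-channel pull-up, no size-dependent amplification bias, no
allelic dropout, no plus-A artifacts, and loci are unlinked. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every laboratory artifact.

Problem sizes used by the test suite are chosen to keep the full suite in
the tens of minutes on a single core: the admixture recovery experiments
run 60 populations x 28 loci x 15 individuals with chains of 10,000
burn-in plus 10,000 recorded sweeps, 3 replicate runs, and $K$ scanned
1–5, repeated over five generator seeds. Under these conditions the Evanno
scan recovers the true $K = 3$ and the aligned ancestry estimates land
within a few hundredths of the truth (mean absolute error well under 0.1).
Production analyses of real data should use chains one to two orders of
magnitude longer; every chain parameter is exposed.

## Numerical choices and degenerate inputs

* Frequency rows whose sums land in $1 \pm 0.02$ (spreadsheet rounding)
  are renormalized on input; sums outside that band are a hard error
  naming the offending (population, locus) — silent repair of grossly
  wrong rows would hide corruption.
* Equidistant peak binning resolves to the lower rung; NJ criterion ties
  resolve to the smallest index pair.
* Dirichlet draws are clamped at `1e-300` before normalization; the
  categorical Z-draw falls back to a uniform pick if all weights
  underflow.
* `evanno_delta_k` refuses non-consecutive K grids; delta-K is `NA` at
  scan endpoints and wherever the between-run sd is zero.
* All-peaks-removed (bulk, locus) entries become masked missing data and
  propagate as such (pairwise deletion in PSA, absent rows in genotype
  simulation).
* Heterozygosity repair that cannot reach tolerance (e.g. two alleles
  with extreme counts) returns the best achieved value with a warning
  rather than failing.

## Limitations

* The admixture sampler implements the independent-frequencies model
  only; closely related clusters are better served by a correlated
  (F-model) prior, which is out of scope here.
* Group assignment thresholds (51%, 80%) are survey conventions, not
  estimates; they are parameters, not defaults to tune per dataset.
* PSA treats alleles as unordered size classes; no stepwise-mutation
  weighting is applied.
* The label alignment across replicate runs is greedy, which is exact in
  the well-separated regimes tested but can be suboptimal when clusters
  overlap heavily; a full assignment solver is not included.
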