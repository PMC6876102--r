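---
title: "Statistical methods for multiplex chromatin interaction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for multiplex chromatin interaction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcia)
library(data.table)
```

## The data and the problem

Droplet- and split-pool-based 3D genome assays (ChIA-Drop, SPRITE) barcode
individual chromatin complexes, so that one barcode collects the set of
genomic fragments that were together in a single molecule or nuclear
structure. Unlike Hi-C, a "contact" is therefore a *multiplex* object: a
complex with $n$ fragments carries $n-1$ neighboring distances at once.
Two artifacts dominate raw data of this kind:

* **long-range noise** -- fragments scattered over the chromosome that were
  never part of one structure, and
* **multiplets** -- two or three genuine complexes that received the same
  barcode (droplet co-encapsulation, barcode collision), which look like a
  single complex with one or two enormous internal gaps.

`mcia` implements a de-noising and significance pipeline built on distances
and information theory, a TAD caller that works directly on the multiplex
complexes, a binomial test for recurrent inter-TAD contacts, and an
enrichment test for protein-enriched libraries.

## Notation and the distance primitives

A complex with sorted, non-overlapping fragments $u^1, \dots, u^n$ has
fragment-to-fragment (F2F) distances
$x_i = \mathrm{start}(u^{i+1}) - \mathrm{end}(u^i)$ (floored at 1 bp so the
probability vector below is always defined), total distance
$d_\mathrm{tot} = \sum_i x_i$ and probability vector
$p = x / d_\mathrm{tot}$. For fragments (chr2L, 100, 500),
(chr2L, 1000, 1500), (chr2L, 6000, 6500):

```{r}
fr <- data.table(chrom = "chr2L", start = c(100, 1000, 6000),
                 end = c(500, 1500, 6500), cid = "OC8")
distance_profile(fr)
```

Complexes are stratified into *fragment classes* $F_j$ by their fragment
count $j$, because classes differ systematically in their distance
distributions.

## The two-stage distance test

**Null model.** Per chromosome, all observed F2F distances are pooled into
a bucket $B$. For each observed class $F_j$, `sample_size` (default
100,000) "expected complexes" are built by drawing $j-1$ distances i.i.d.
with replacement from $B$; only each expected complex's total distance and
the class's mean normalized entropy are retained. Every (chromosome,
class) stratum derives its own sub-seed from the user seed, so runs are
byte-reproducible and independent of iteration order.

**First test.** The raw p-value of a complex is the proportion of expected
complexes in its class with strictly smaller total distance -- small
p-values flag unusually compact complexes. P-values are BH-adjusted within
each (chromosome, class) stratum at FDR 0.1 (default). Significant
complexes are `pass1`; insignificant two-fragment complexes are `fail1`
(nothing further can be done with a single gap); the remainder is
*deferred*.

**Entropy filter.** For a deferred complex the normalized Shannon entropy

$$H_\mathrm{norm}(p) = \frac{\sum_i p_i \log_2 (1/p_i)}{\log_2 (n-1)} \in [0, 1]$$

is compared with the mean entropy of its class's expected complexes. Evenly
spaced fragments give $H_\mathrm{norm}\approx 1$; a single dominating gap
-- the multiplet signature -- drives it toward 0. Below-threshold
complexes are cut at their largest gap (left-most on ties), and also at the
second-largest gap when it is at least $\max/\tau$ ($\tau = 2$ by default;
larger $\tau$ makes the triplet cut easier). The filter is deliberately a
*filter*, not a test: no probability is attached to a cut.

**Second test.** The filtered pool (split halves plus unsplit deferred
complexes) is retested against the null of each unit's *new* class, with
BH again per class: `pass2` or `fail2`. Split products with a single
fragment are recorded as singletons and never tested. "Significant" means
`pass1` or `pass2`.

### Power: which classes can pass at all?

A useful property of the class-stratified design, worth knowing when
interpreting results: if a fraction $\phi$ of bucket distances is
long-range noise, a genuinely compact complex of class $j$ has raw p-value
of order $(1-\phi)^{\,j-1}$ times a uniform variate, since an expected
complex undercuts it only when all $j-1$ draws avoid the noise mass. With
$\phi = 1/2$ and a class that is half signal, BH at FDR $\alpha$ can only
reject when $2^{\,j-1} \ge 1/(\pi \alpha) = 20$, i.e. $j \ge 6$.
Fragment-poor complexes are thus structurally hard to call significant in
heavily contaminated libraries -- consistent with the observation on real
data that significant complexes are dominated by fragment-rich classes.
This analysis is why the synthetic generator defaults to fragment-rich
complexes (below).

## TAD calling

1. **Long-gap split.** Complexes are cut wherever a neighboring gap
   exceeds 100 kb (the upper range of typical TAD sizes; the
   `drosophila` preset), so noise complexes cannot bridge unrelated
   regions.
2. **Weighted span coverage.** Each complex with $n \ge 2$ fragments adds
   $n$ to every bin (1 kb default) its span overlaps. The contribution is
   linear in $n$, avoiding the quadratic over-weighting that pair
   enumeration would give fragment-rich complexes.
3. **Wavelet smoothing.** The track is decomposed with the biorthogonal
   1.1 wavelet (the Haar pair) to level 3, detail coefficients are zeroed
   and the signal reconstructed -- a local low-pass that preserves sharp
   change points without a hand-tuned window size. For track lengths
   divisible by $2^\ell$ this equals block means of width $2^\ell$ bins;
   the implementation is cross-checked in the test suite against reference
   output of an independent DWT implementation.
4. **Segmentation.** Candidate TADs are maximal runs of smoothed signal
   above a floor; regions between successive TADs are reported as *gaps*
   (the genome is deliberately not forced into wall-to-wall TADs).
5. **Boundary refinement.** Because the level-3 reconstruction is blocky
   (8-bin quanta), candidate edges are refined on the raw track: each edge
   walks outward while the raw signal stays above
   $\max(2 \cdot \mathrm{background},\ 1\% \cdot \mathrm{plateau})$,
   tolerating interruptions of up to 2 bins and moving at most 16 bins
   (two smoothing blocks). The background level is estimated as the median
   positive raw signal outside all candidates.

### Numerical choices in segmentation, and why

These rules were genuinely open design territory; the choices and their
rationale:

* **Candidate floor: 5% of the 95th percentile of positive smoothed
  bins.** A floor tied to the *median* positive bin collapses when sparse
  background coverage dominates the positive-bin count (the median then
  *is* the background and every background bump becomes a candidate). The
  95th percentile anchors the floor to the high-signal regime at any
  sequencing depth.
* **Walk floor: background-aware, plateau-relative.** Stray low-weight
  spans cross the inter-TAD gaps, so a positivity rule walks far past the
  true edge; a floor proportional only to the plateau stops partway up the
  coverage ramp and biases boundaries inward by (floor/slope). Requiring
  the signal to clear twice the ambient background *and* 1% of the local
  plateau separates the two scales.
* **Walk cap: 16 bins.** The refinement exists to undo block quantization
  of the smoothed candidate; letting it roam further only exposes it to
  background structures.
* **Tie-breaks.** Maximal-gap cuts in the entropy filter and all walks are
  deterministic (left-most maximum, fixed scan order), so identical inputs
  give identical outputs.

## Inter-TAD combinations and the expanded-pair binomial test

Each complex is mapped to the set of TADs that contain at least 2 of its
fragments (fragment membership by midpoint). For a combination
$\mathrm{TC}$ of $N$ TADs with pair set $\mathrm{Pa}(\mathrm{TC})$ (all
$N(N-1)/2$ TAD pairs), the statistics are: $a$ = occurrence-weighted count
of pairs shared with same-class combinations (including its own);
$b$ = occurrence-weighted count of higher-class combinations strictly
containing $\mathrm{TC}$; $x = a + b \cdot N(N-1)/2$; and
$k = \sum_{z \in \mathrm{class}} x(z)$. The combination is tested with an
exact one-sided binomial tail $P(X \ge x \mid k, 1/|G_j|)$ where $|G_j|$
is the number of distinct combinations in its class, followed by BH across
all combinations. We read the pair-counting sum as pair *membership*
(shared pairs accumulate evidence across combinations of the same class),
which is the reading under which counting a pair "appearing twice" across
two triples is meaningful; the test suite pins this down against a literal
double-loop enumeration. Combination frequency is *not* normalized by TAD
distance or size -- close, large TADs are expected to interact more, and
ranking reflects that.

## Enrichment test for protein-enriched data

For RNAPII-type libraries, each complex's binding score is
$\mathrm{covg}$ = the mean over fragments of the mean binned signal
(10-bp bins) across the fragment span. The null is empirical: the complex
is rigidly shifted (spacings preserved) to `n_samples` (default 10,000)
uniform positions that keep it fully inside the chromosome, and the raw
p-value is the proportion of placements whose coverage *strictly* exceeds
the observed one; BH per chromosome at FDR 0.1. Two deliberate
consequences of the strict inequality: a constant track gives p = 0 for
every complex (degenerate; a warning is emitted rather than silent
significance), and the test is invariant to rescaling the track. The
printed shift range is restricted to in-bounds placements so expected
complexes never leave the chromosome. Fragments overlapping annotated
repeats can be removed beforehand (`filter_repeats()`); complexes left
with fewer than 2 fragments are dropped.

## SPRITE pre-processing

SPRITE clusters are converted to complexes with the published recipe: keep
one chromosome; sweep left to right dropping any read closer than 10 kb to
the previously *retained* read (greedy de-duplication of bin-level PCR
duplicates); extend surviving positions by 1,000 bp into fragments; retain
clusters with 2--500 fragments. In SPRITE mode the distance test is
typically run with `sample_size = 10000` and `max_frags_fail = 100`
(complexes above 100 fragments fail the first test outright).

## The synthetic generator: what it emulates and what it does not

`simulate_dataset()` plants ground truth for every pipeline stage on one
synthetic chromosome (5 Mb default): TADs of 100--500 kb separated by
$\ge$ 200 kb gaps, populated by compact complexes; uniform noise
complexes; multiplets built by concatenating independent singlets from
distinct TADs (so the junction gap is $\ge$ 200 kb, over 20 times the
intra-complex scale); and, for the enrichment test, Gaussian binding peaks
on a noisy baseline with peak-bound complexes.

Key defaults and their reasoning:

* **Fragments per complex: $2 + \mathrm{Poisson}(8)$.** The power analysis
  above shows classes below $j \approx 6$ cannot reach significance in a
  half-noise library at FDR 0.1; the generator therefore emulates the
  fragment-rich regime that carries the structural signal (it is also the
  regime real significant complexes occupy). Recovery rates quoted by the
  acceptance suite are statements about this regime, not about
  two-fragment complexes.
* **Intra-complex gaps: log-uniform 2--8 kb.** A deliberately tight spread
  keeps singlet entropy high; with gap ratios up to $10^2$ within one
  complex, genuine singlets would themselves look like multiplets and no
  entropy threshold could separate the populations.
* **Baseline coverage noise: mean-corrected lognormal (sd 0.3) in 200-bp
  blocks.** A perfectly flat baseline makes the shift null degenerate
  (ties everywhere, p = 0 for every off-peak complex); real
  fragment-coverage background is uneven, and modeling that is what makes
  background p-values uniform.
* **Problem sizes.** The validation suites use 10,000 complexes for the
  multiplet filter, 20,000 (half noise, `sample_size` 10,000) for the
  distance test, 800 complexes per TAD for boundary recovery, and 2,000
  complexes with 1,000 placements for the enrichment test. The TAD depth
  is a statistical requirement, not a tuning choice: the first complex in
  a domain sits $\approx (L - \mathrm{span})/\mathrm{depth}$ inside the
  true edge, so $\pm$2-bin recovery of $\ge$90% of boundaries needs on
  the order of 700+ complexes per 500-kb TAD *regardless of the detector*.

What the generator does **not** emulate: mappability and GC bias,
restriction-site structure, inter-chromosomal complexes, barcode-sharing
beyond whole-complex concatenation, and peak shapes beyond Gaussians.
Passing the recovery suites therefore demonstrates algorithmic
correctness under the stated noise model, not performance on any
particular real library.

## Degenerate inputs and edge-case behavior

* Two-fragment complexes have undefined entropy (`NA`); they are handled
  by the `fail1` route, never by the filter.
* Zero or negative gaps cannot occur: overlapping or book-ended fragments
  are merged at parse time and gaps are floored at 1 bp.
* An all-zero coverage track makes every enrichment p-value 0; a warning
  marks the degeneracy.
* Chromosomes with fewer testable complexes than `min_complexes` (default
  20) are skipped with a warning and their complexes labeled `unassigned`.
* Raw p-values of exactly 0 are kept (no pseudo-count); BH handles them,
  and the estimator matches its definition as a proportion.

## Known limitations

* No GC/mappability correction anywhere in the pipeline.
* Inter-chromosomal complexes are split and analyzed per chromosome;
  trans contacts are out of scope.
* The inter-TAD test does not correct for TAD size or genomic distance.
* TADs are flat (no nesting/hierarchy).
* The enrichment null is Monte-Carlo; its resolution is `1/n_samples`,
  so very small p-values saturate at 0 and the BH step inherits that
  granularity.
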