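# mcia — significance testing and domain calling for multiplex chromatin interaction data

Single-molecule 3D genome assays such as ChIA-Drop and SPRITE barcode
individual chromatin complexes, so one barcode yields a *multiplex*
interaction: the set of genomic fragments captured together in a single
molecule. Two artifacts dominate raw libraries of this kind — long-range
noise fragments that were never part of one structure, and *multiplets*
(two or three genuine complexes sharing one barcode, visible as one or two
enormous internal gaps). Existing pairwise tools (Hi-C/ChIA-PET callers)
cannot score such objects without destroying the multiplexity.

`mcia` is an R package for analysts of ChIA-Drop, RNAPII ChIA-Drop and
SPRITE data. It provides:

* **Two-stage distance test with an entropy filter** — per chromosome and
  fragment class $F_j$, an empirical null is built by resampling observed
  fragment-to-fragment (F2F) distances: each of 100,000 "expected
  complexes" draws $j-1$ distances from the pooled bucket. A complex's raw
  p-value is the proportion of expected complexes with strictly smaller
  total distance; BH adjustment at FDR 0.1 gives `pass1`/`fail1`/deferred.
  Deferred complexes whose normalized Shannon entropy
  $H_\mathrm{norm}(p) = \sum_i p_i \log_2(1/p_i) / \log_2(n-1)$
  falls below the class's expected mean are split at their dominating
  gap(s) (second cut when the runner-up gap is at least $\max/\tau$,
  $\tau = 2$) and retested (`pass2`/`fail2`).
* **Wavelet TAD caller** — complexes are cut at gaps > 100 kb, converted
  into a span coverage track weighted linearly by fragment count, low-pass
  smoothed with the biorthogonal-1.1 (Haar) wavelet at level 3, and
  segmented into TADs with explicit interleaved gaps; boundaries are
  refined on the raw track.
* **Inter-TAD binomial test** — each complex maps to the set of TADs
  holding ≥ 2 of its fragments; combination recurrence is scored with
  "expanded-pair" counts ($x = a + b\,N(N-1)/2$ successes among the
  class-wise trials $k$) and an exact one-sided binomial tail with null
  success probability $1/|G_j|$, BH-adjusted.
* **Enrichment test** for protein-enriched libraries — a complex's mean
  binding coverage (10-bp binned lookup) is compared against rigid random
  placements of the same complex on the same chromosome; the p-value is
  the proportion of placements with strictly greater coverage.
* **SPRITE pre-processing** (chromosome selection, 10-kb de-duplication
  sweep, 1-kb read extension, 2–500 fragment bounds) and **juicer
  `.short` export** of complexes as all fragment pairs.
* A seeded **synthetic-data generator** with per-complex ground truth
  (planted TADs, noise, doublets/triplets, binding peaks) used by the
  validation suites.

See `vignettes/mcia-methods.Rmd` for the models, parameter choices and
their rationale, and known limitations.

## Worked example

```r
library(mcia)
library(data.table)

# the distance primitives on one three-fragment complex
fr <- data.table(chrom = "chr2L", start = c(100, 1000, 6000),
                 end = c(500, 1500, 6500), cid = "OC8")
distance_profile(fr)
#> $x_f2f: 500 4500     # neighboring gaps (bp)
#> $d_tot: 5000         # total distance
#> $p_f2f: 0.1 0.9      # probability vector
normalized_entropy(distance_profile(fr)$p_f2f)
#> [1] 0.4689956        # one dominating gap -> low entropy

# a full run on synthetic data with known truth
sim <- simulate_dataset(sim_config(complexes_per_tad = 400,
                                   noise_fraction = 0.4,
                                   multiplet_fraction = 0.1, seed = 7))
res <- run_distance_test(sim$complexes,
                         distance_test_config(sample_size = 10000, seed = 1))
res
#> mcia distance test
#>   pass1        1691
#>   fail1        2
#>   pass2        306
#>   fail2        2313
#>   singleton    3
#>   significant  1997
#>   singlets     2000
#>   doublets     299
#>   triplets     8

tads <- call_tads(significant_complexes(res), bin_size = 1000)
tads$tads[kind == "TAD", .(chrom, start, end, tad_id)]
#>     chrom   start     end     tad_id
#> 1:   chrS  915000 1388000 TAD_chrS_1
#> 2:   chrS 1909000 2152000 TAD_chrS_2
#> 3:   chrS 3224000 3364000 TAD_chrS_3
#> 4:   chrS 3717000 3839000 TAD_chrS_4
#> 5:   chrS 4453000 4643000 TAD_chrS_5
```

Reading the run: the dataset planted 2,000 intra-TAD complexes, 1,600
uniform-noise complexes and 400 multiplets. The first test passed 1,691
complexes; the entropy filter recognized 299 doublets and 8 triplets among
the deferred pool and the second test rescued 306 split halves, for 1,997
significant complexes — essentially the planted signal, with the noise
rejected. The five called TADs match the five planted domains (TAD 1 spans
915–1,388 kb against a planted 915–1,387 kb, and so on).

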