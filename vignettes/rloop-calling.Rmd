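---
title: "Calling R-loops from strand-specific ssDNA coverage"
author: "rloopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling R-loops from strand-specific ssDNA coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The signal model

Kethoxal-assisted ssDNA sequencing labels guanines on exposed
single-stranded DNA; the strand-specific variant preserves which strand a
read came from. Two transcription-associated structures dominate the
signal:

* **R-loop**: the nascent RNA invades the duplex and pairs with the
  template strand, leaving the nontemplate strand displaced as ssDNA. The
  displaced strand is labelled efficiently, the hybrid-sequestered strand
  is shielded, so coverage is *asymmetric* between the plus and minus
  strands. For a plus-strand gene the template is the minus strand and the
  displaced (labelled) strand is the plus strand.
* **Transcription bubble**: locally melted duplex exposing *both* strands,
  producing elevated but *balanced* coverage.

rloopr therefore defines an R-loop operationally as a run of genomic bins
in which read density is both high and significantly imbalanced between
strands.

## The caller, step by step

1. Tile the genome with 500-bp windows stepped every 250 bp
   (`make_windows()`). Terminal partial windows are kept and flagged; they
   face the same thresholds as full windows. This is an open choice — the
   bedtools-style windowing dialect we mirror emits them, and dropping
   them would silently blind the caller to chromosome ends.
2. Remove windows with any blacklist overlap (`subtract_blacklist()`).
   Bins are excluded whole, never trimmed.
3. Keep windows whose total overlap with the *union* of the supplied
   KAS-seq peaks is at least 250 bp (`filter_candidates()`). Peaks are
   reduced first so abutting peaks are not double-counted. These are the
   candidate bins, and they are exactly the multiple-testing universe.
4. For each candidate bin and strand, compute the mean per-base fragment
   coverage and the fragment count (`bin_density()`). Density drives the
   signal thresholds; integer counts feed the statistical test.
5. Test strand balance with a two-sided exact binomial test of
   `plus_count` against `plus_count + minus_count` trials at
   p₀ = 0.5 (`strand_imbalance_test()`). The test identity is an
   assumption of this implementation: counts are available, the test is
   exact, and it needs no dispersion estimate. Because the null is
   symmetric, the two-sided p-value is `min(1, 2·P(X ≤ min(counts)))`,
   identical to summing all outcome probabilities no larger than the
   observed one. Zero trials give p = 1.
6. Adjust p-values with Benjamini–Hochberg across candidate bins only
   (`bh_adjust()`).
7. Keep bins with mean density strictly above 20 reads-per-base,
   `|log₂((plus + 1)/(minus + 1))| ≥ 1`, and `q ≤ 0.05`
   (`call_rloop_bins()`). The comparison directions are deliberate and
   tested: density is strict (`>`), ratio and q are inclusive
   (`≥`, `≤`).
8. Merge overlapping or book-ended significant bins of the *same*
   imbalance direction into calls (`merge_rloop_bins()`). Opposite
   directions never merge: the displaced strand is a physical property of
   one structure. Call density is the mean over constituent bins of
   `|plus_density − minus_density|`; the displaced strand is the
   higher-density strand.

`call_rloops()` composes 1–8. `imbalanced_bin_census()` is the
no-threshold companion: non-overlapping 2-kb bins genome-wide, ratio and
q filters only, for volcano-style summaries.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `bin_width` / `bin_step` | 500 / 250 | bp | sliding windows halve the chance an R-loop straddles a bin boundary |
| `min_peak_overlap` | 250 | bp | restricts testing to regions with appreciable total ssDNA signal |
| `min_density` | 20 | reads/base | in balanced ssDNA data most strand-asymmetric bins fall at or below this density, so it floors the noise |
| `min_abs_log2_ratio` | 1 | — | a two-fold strand imbalance, with pseudocount 1 on both densities |
| `max_q` | 0.05 | — | BH false-discovery level over candidate bins |
| `pseudocount` | 1 | reads/base | stabilises the ratio when one strand is empty; no rule exists for zero-density strands otherwise |
| `merge_gap` | 0 | bp | 0 still merges book-ended bins (bedtools merge semantics) |
| `density_mode` | mean | — | whether "averaged density" means the strand mean, sum, or max — the printed rule is ambiguous, so it is a switch |

The density threshold is applied to raw (not library-scaled) coverage;
the within-sample strand ratio is scale-invariant but the density floor
is not, which is exactly why `min_density` is exposed rather than
hard-coded.

## What the simulator states — and what it does not

`simulate_condition()` draws, per chromosome and strand, Poisson fragment
counts with uniform placement: background at `background_depth`
reads-per-base on each strand (default 2), planted features adding
strand-specific intensity on top. An R-loop puts `depth` (default 40) on
its displaced strand and `depth / asymmetry` (default asymmetry 4) on the
paired strand; a bubble puts `depth` on both. Fragments are fixed-length
(150 bp, the average fragment length the read-extension convention also
uses) and placement is arranged so expected coverage is uniform across
the locus interior. The truth table (`expected_intensities()`) records
the expected per-strand intensity of every feature under every condition.

Perturbations:

* **RNase H** digests the RNA of RNA-DNA hybrids. Mechanistically this
  both exposes the template strand and lets the duplex re-anneal; rather
  than choose between those, the simulator converges the two strand
  intensities symmetrically toward their mean by the dose's efficiency.
  Efficiency 0 is generatively identical to control and shares control's
  random substream, so the identity limit holds bit-exactly; efficiency 1
  erases the asymmetry entirely. Efficiencies are free parameters: no
  quantitative digestion-efficiency estimates exist for permeabilised
  cells, so the default map (0, 0.3, 0.5, 0.7 across doses) is a stated
  world, not a fit.
* **DRB / triptolide** (elongation vs initiation inhibitors) zero out
  features whose per-feature retention flags say so; the designed type
  (I: DRB-retained only, II: neither, III: both) is recorded in the truth.

One master seed derives an independent substream per condition, so any
condition regenerates bit-identically on its own.

The simulator deliberately omits: sequence (no G-richness or GC-skew
propensity), mappability and GC bias, overdispersion beyond Poisson
(available behind a flag-shaped parameter but off by default — no noise
model is stated for the assay, so the simplest generative assumption is
the default), alignment artifacts, and replicate structure. A green test
on simulated data therefore establishes that the *algorithm* implements
its contract — not that real chromatin satisfies the model.

## Perturbation analysis choices

"Retained" under an inhibitor is binarised as ≥ 1 bp overlap with any
call in the treated condition; no quantitative retention rule exists, so
a density-ratio mode (retained iff the treated RPM-scaled region density
reaches 50% of control) is offered behind a flag. The logical fourth
combination — lost under DRB yet present under triptolide — falls outside
the three-type taxonomy and is surfaced as `unclassified` rather than
silently binned.

`dose_response()` measures the RPM-scaled mean `|plus − minus|` density
over a *fixed* reference region set, the first (lowest-dose) condition's
calls. Measuring on each condition's own calls would make the statistic
undefined the moment a dose abolishes all calls, and the quantity of
interest is precisely signal loss at R-loop loci. Call counts, by
contrast, are per-condition. Cross-condition densities are
reads-per-million scaled because library depths differ between
experiments; within-sample strand ratios stay raw.

## Annotation conventions

Category windows are this package's conventions, not assay constants:
promoter = TSS ± 1 kb, TES window = TES ± 1 kb, strand-aware, precedence
promoter > TES > gene body > intergenic, assignment by region midpoint so
every region counts exactly once. Metagene profiles use 3-kb flanks and a
100-bin length-normalised body (deepTools-style defaults); the
"relative R-loop density" mode plots nontemplate-minus-template coverage
oriented TSS→TES, so a genuine promoter-proximal asymmetry peaks at the
TSS for genes of either strand. Binned correlations use 5-kb
non-overlapping bins, drop blacklist bins, optionally keep only bins
overlapping a mask (peaks or calls), and take the p-value from the
t transform of Pearson's r with n − 2 degrees of freedom.

## Numerical and degenerate-input choices

* The log₂ ratio is computed as `log2(plus + 1) − log2(minus + 1)` — a
  difference of logs, not the log of a quotient — so a strand swap negates
  it bit-exactly; the strand-symmetry contract (same regions and
  q-values, flipped displaced strand) is tested as exact equality.
* The binomial closed form `min(1, 2·pbinom(min(k, n−k), n, ½))` is valid
  only because p₀ = 0.5 makes the null symmetric; tests pin it to
  brute-force tail enumeration and to `binom.test`.
* Zero fragments in a bin: densities 0, counts 0, p = 1 — no data is no
  evidence.
* An empty candidate set is a warning plus empty outputs, not an error;
  `max_q = 0` is allowed and acts as an impossible threshold (exact
  binomial p-values are strictly positive).
* Tightening `min_density`, `min_abs_log2_ratio`, or `max_q` can never
  add significant bins or called bp, but it *can* split one merged call
  into two and so raise the call count; the monotonicity property is
  therefore stated (and tested) at the bin level.
* Per-call density averages constituent bins rather than recomputing on
  the merged span: deterministic, and unaffected by how much non-
  significant sequence a merge happens to skip.

## Known limitations

Other non-B structures that expose one strand preferentially would be
indistinguishable from R-loops in this signal; the caller names what the
statistic supports — strand-imbalanced ssDNA — and the R-loop
interpretation rides on the assay. Replicates are pooled before calling
(no combination rule is stated for the assay; a strict per-replicate mode
is available). Single-molecule phasing, peak calling, and expression
quantification are out of scope: peaks and gene models are inputs.
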