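---
title: "Strand cross-correlation QC for ChIP-seq: model, metrics and validation"
author: "strandcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand cross-correlation QC for ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandcc)
```

## Why strand cross-correlation

In single-end ChIP-seq, sequenced fragments are read from their 5' ends:
forward-strand reads pile up on the left flank of a protein-binding site and
reverse-strand reads on the right flank, roughly one fragment length apart.
Correlating the forward read-start density against the reverse density
shifted by `x` therefore produces a peak at the mean fragment length, and
the height of that peak reflects how strongly reads concentrate around
binding events — a signal-to-noise readout that needs no peak caller. This
package computes such profiles, explains them with a generative model, and
turns them into quality-control metrics.

Both densities are *binarised*: `f(i)` (and `g(i)` for the reverse strand)
record only whether at least one read 5' end falls at position `i`. The 5'
end of a forward read is its leftmost base; for a reverse read whose
leftmost aligned base is `b` with read length `R`, it is `b + R - 1`.
Binarisation makes PCR-duplicate removal implicit and the estimators
tractable.

## The generative model

A genome of length `G` carries `n` binding events. Each event has a
forward-enriched region of width `w` and a reverse-enriched region of the
same width whose 5'-end coordinates start `d` bp after the forward region
ends, so matched forward/reverse 5' ends are exactly `d + w` apart — the
fragment length. Of `M` mapped reads (`M/2` per strand) a fraction `alpha`
are signal reads, uniform over the enriched regions; the rest are noise,
uniform over the genome. `M_u <= M` counts reads surviving duplicate
collapse. All parameters live in a `model_params()` object.

Key quantities derived from the model (all implemented in the `theory`
functions and checked against each other by the test suite):

* **Degree of saturation** `M*alpha / (2*n*w)`: expected signal reads per
  strand over available enriched positions. Above 1, signal reads must
  duplicate ("saturated"); the closed forms switch accordingly
  (`degree_of_saturation()`, `saturation_regime()`).
* **Expected coefficient at any shift** via the four index-class sizes
  (both positions enriched, forward only, reverse only, neither) and the
  per-position probabilities of the unsaturated case (`expected_dx()`,
  `expected_ncc_at()`, `expected_ncc_profile()`).
* **Theoretical maximum** at `x = d + w`; its headline approximation is
  `M * alpha^2 / (2*n*w)` (`theoretical_max()`, three `level`s from exact
  to headline). In the saturated regime the maximum is
  `n*w / (M_u/2 * (1 - alpha) + n*w)`, which tends to 1 as `alpha -> 1`.
* **Theoretical minimum** at non-overlapping shifts: a small negative
  value, approximately `-M*alpha*(M*(1-alpha)^2 + G*alpha) / ((2G-M)*G)`,
  i.e. near 0 when `M << G` (`theoretical_min()`). Its magnitude grows
  like `M*alpha^2 / (2G)`, which matters when interpreting reduced-scale
  simulations: with `M/G = 0.01` the exact minimum at `alpha = 1` is about
  `5e-3`, not 0.
* **FRiP** relates to `alpha` by
  `FRiP = alpha + n(2w+d)/G * (1 - alpha)`; `alpha_from_frip()` inverts it
  exactly given post-peak-calling estimates (note `w + d` is the fragment
  length, so territory per peak is `w + fragment_length`).

The saturated regime is implemented only through the two printed closed
forms (minimum ~ 0 and the maximum above); fully exact saturated
expressions are out of scope and the functions document that the `level`
argument is ignored there.

## Estimators

`ncc_profile()` computes, per chromosome and shift, the Pearson correlation
of `f(i)` and `g(i + x)` over the overlap window `i in [0, L - x)`:

* `"exact"` (default): means and variances per shift over the window — the
  unapproximated coefficient, reproduced to machine precision by a naive
  position-by-position `cor()` in the tests.
* `"global"`: the approximate form used by the theory — genome-wide mean
  `mu = M_c/2L`, variance `mu(1 - mu)`, and the shifted-AND count `|D_x|`.
  For sparse densities (`M << L`) the two agree to well under `1e-3`,
  which the suite checks.

`mscc_profile()` is the same coefficient restricted to *doubly mappable*
positions (`forward_mask[i] == 1` and `reverse_mask[i + x] == 1`), the
correction that removes the read-length "phantom" peak. Masks come from
binarised BigWig tracks (`load_mappability_bigwig()`, scores below 1 set
to 0), from exact k-mer uniqueness on small synthetic genomes
(`compute_exact_mappability()`), or implicitly for ideal genomes
(`flat_mappability()`).

Counting `|D_x|` is the only expensive step. Two engines produce identical
integer counts: a sparse pair-enumeration over the position sets (cost
proportional to the number of read pairs within the shift window) and a
zero-padded FFT cross-correlation of indicator vectors (cost independent of
density). The default picks by the expected pair count; both are exposed
for testing. For a fully mappable genome the doubly mappable index set at
every shift is a contiguous window, so MSCC reuses the same machinery with
closed-form window bounds instead of materialising genome-length masks.

Degenerate cases propagate as missing values, never as zeros: windows
shorter than 4 positions, zero-variance strands, and empty doubly mappable
sets all yield `NA` coefficients.

## Merging chromosomes

Per-chromosome coefficients are combined by Fisher's r-to-z transformation
with a weighted mean of the z values and a back-transform
(`merge_profiles()`). The weight is `max(count - 3, 1)` — the inverse
variance of z for a coefficient estimated from `count` positions; since the
merging rule's weighting is a genuinely open choice, chromosome length is
available as an alternative. Coefficients of exactly ±1 (which occur in
tiny synthetic examples, not in data) are clamped to `1 - 1e-8` with a
warning so z stays finite. Chromosomes undefined at a shift drop out of
that shift's average.

## QC metrics

* `estimate_fragment_length()`: argmax of the merged profile, excluding a
  window of ±10 bp (configurable) around the read length where the phantom
  peak sits. MSCC does not need the exclusion but keeps it by default for
  uniformity. Ties break to the smallest shift so output is deterministic.
* `estimate_w_fwhm()`: under the model the fragment peak is a triangle of
  base `2w`, so its FWHM estimates `w`. The half-maximum level is measured
  above the profile minimum over the computed range (the baseline is
  otherwise undefined in general), with linear interpolation at the
  crossings. `adjust_w()` divides by a through-origin calibration slope
  (`fit_w_slope()`); the default slope 1 reflects that any calibration is
  dataset-specific.
* `vsn()`: the virtual signal-to-noise `VSN = (2w/M) * max(MSCC)`. Under
  the model `VSN ~ alpha^2 / n`, making it comparable across sequencing
  depths; the suite verifies down-sampling stability within 30% at half
  the read count.
* `nsc_rsc()`: the legacy ratios, using the empirical minimum of the
  merged profile over the computed shift range as `cc_min` (the theoretical
  non-overlap shift is not observable directly; a largest-shift convention
  can be emulated by restricting the shift range). NSC is flagged undefined
  when `cc_min <= 0` — which the model says is the typical sign of the
  minimum — one reason VSN is the preferred metric here.

## Cohort workflow

Given a table of peak-calling summaries (`peak_call_summary()`), each
sample's `alpha` is recovered from FRiP, and `fit_n_alpha_regression()`
fits `log10(n)` on `log10(alpha)` by unweighted OLS (log-log space because
the empirical relation is a power law; base 10 for readability). For a new
sample, `expected_from_vsn()` intersects that line with the hyperbola
`alpha^2 / n = VSN`, giving `alpha = (VSN * 10^a)^(1/(2-b))`; solutions
always satisfy the defining identity exactly, and a flag marks `alpha`
outside (0, 1]. The slope `b = 2` is the degenerate direction where the
two relations are parallel and no finite solution exists.

## Simulator semantics

`simulate_sites()` places site footprints (`2w + d` bp) by seeded rejection
sampling, disjoint and in bounds, apportioned to chromosomes by length
(largest-remainder rounding, retry cap 1000·n). `simulate_reads()` draws
exact per-category counts by default (`round(M*alpha/2)` signal and
`round(M*(1-alpha)/2)` noise per strand); a multinomial option draws the
split instead.

One semantic choice matters for comparing simulations with the closed
forms: the unsaturated case of the model assumes reads occupy *unique*
positions. The simulator therefore samples positions **without
replacement** within each category whenever the category fits its index
space (signal within the enriched regions when `M*alpha/2 <= n*w`, noise
within the chromosome). Sampling with replacement would lose 15–20% of
set bits to collisions at a degree of saturation of 0.5 — a pure
simulation artifact relative to the unsaturated closed forms. When a
category exceeds its space (the saturated regime, where duplication *is*
the model), draws are with replacement and duplicates collapse in the
density; `dedup_count()` reports `M_u`.

Noise reads are restricted to placements that admit a full-length read
(forward 5' in `[0, L-R]`, reverse in `[R-1, L-1]`), so simulated
alignments always round-trip through SAM/BED without clipping.

`simulate_genome()` builds random sequence and oversows it with copies of
one repeat unit on non-overlapping unit-length slots, so the covered
fraction tracks `repeat_fraction` and `repeat_fraction = 1` produces a
tandem-tiled (essentially unmappable) chromosome. Reads discarded at
non-uniquely-mappable placements — what an aligner does to multi-mappers —
then induce the phantom correlation at shift `R - 1` in NCC which MSCC
conditions away; the suite reproduces this qualitatively.

## Validation design and problem sizes

The package validates itself end to end on simulations whose sizes were
chosen up front to make each check well powered while keeping the default
suite quick:

* **Engine equivalence**: 200 random instances up to 2 kb, shifts up to
  200, against naive windowed Pearson at `1e-12`.
* **Closed-form consistency**: `expected_dx()` with the max/min set sizes
  against `theoretical_max()`/`theoretical_min()` on a 100-point grid, to
  `1e-12` absolute (the minimum is a ~1e-6 quantity obtained by
  cancellation of ~1e-5 terms, so absolute is the meaningful scale).
* **Simulation vs theory**: `G = 1e7`, `M = 1e5`, `n = 1000`, `w = 100`,
  `d = 200`, `R = 50`, `alpha` in {1, 0.5, 0.1}, 5 seeds; the coefficient
  at `x = 300` agrees with `M*alpha^2/(2nw)` within a few percent. At this
  `M/G` the exact minimum magnitude at high `alpha` is `1.3e-3`–`5e-3`
  (see above), visibly away from the asymptotic 0 of the `M << G` limit.
* **Low-alpha detectability**: at `alpha = 1e-3` a peak is only resolvable
  when `M*alpha` clears the coefficient sampling floor `~1/sqrt(G)`; the
  detection study uses `G = 4e7` (4 chromosomes), `M = 2e7`, `n = 200`,
  chosen a priori from the detection z
  `~ (M*alpha/sqrt(G)) * (1 + s/2 * (1-pN)/pN)` with `s` the degree of
  saturation, and averages 5 replicate profiles before testing the peak
  against background mean + 3 SD.
* **Fragment-length exactness**: single-bp argmax recovery needs the
  apex-to-neighbour gap `cc_max/w` to clear per-shift counting noise
  `~sqrt(cc_max/(G*sigma))`, hence a deeply sequenced scenario
  (`M = 1e6`, `n = 5000`); FWHM is checked within 20% of `w` there.
* **VSN accuracy**: checked within 25% of `alpha^2/n` for `alpha` of 0.5
  and 0.1 at the standard scale; `alpha = 0.01` uses `M = 1.25e6`,
  `n = 250` for the same power reason.

What these simulations do **not** emulate about real data: non-uniform
read distributions within enriched regions (fragmentation and sonication
bias), distributions over `w` and `d`, GC and amplification bias, actual
alignment (reads are placed, not mapped), and mismatch-tolerant
mappability (exact k-mer uniqueness is stricter; real tracks should be
loaded from BigWig, not recomputed). Passing the suite therefore
demonstrates correctness of the estimators and internal consistency of
model, simulator and metrics — not that the model captures every feature
of real ChIP-seq profiles, whose background can decline over tens of kb
and lift the empirical minimum above the model's.

## Numerical choices

* Internal coordinates are 0-based half-open everywhere; only the SAM/BED
  readers and writers convert. All formulas are coordinate-free.
* Default `mapq_min = 0` (metric comparisons are run without read
  filtering); a pipeline-style threshold such as 6 is a flag away.
* Mixed read lengths use the modal length with a warning — the model
  assumes one `R`.
* Default shift range 0–1000 bp covers `d + w = 300` and the phantom at
  `R = 50` with margin; several validation runs use 0–500 for speed.
* FFT counts are rounded to integers (they are exact counts; padding to
  `L + max_shift` prevents circular wrap).
* The fragment-length argmax tie-break, the FWHM baseline, the Fisher
  weights and the phantom exclusion half-width are the package's choices
  where the method leaves them open; each is a documented argument.
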