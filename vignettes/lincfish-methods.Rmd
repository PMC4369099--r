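---
title: "Methods: models, parameters and design choices in lincfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lincfish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lincfish` quantifies single-molecule RNA FISH experiments: each RNA
molecule is a diffraction-limited fluorescent spot in a 3-D stack, and the
analysis must count those spots per cell, decide which are nuclear, verify
that the signal is genuine, and summarize abundance and cell-to-cell
variability. This vignette is the package's account of how each stage
works, which knobs matter, and where the design was genuinely open.

## The imaging model

A stack is a `(z, y, x)` array: ~25 optical slices at 0.3 µm spacing,
0.125 µm lateral pixels (a 100x objective on a CCD). A molecule produces a
3-D Gaussian intensity profile with lateral sigma ~1.3 px and axial sigma
~1.2 slices, sitting on a smooth, nonuniform background with Gaussian read
noise. Cell and nucleus segmentations are 2-D label images applied to all
slices — cells are segmented by hand in this kind of experiment, and the
nucleus outline is taken from DAPI after a maximal projection across z, so
the masks have no z-structure.

## Spot detection

1. **Filtering** (`log_filter()`): each z-slice is convolved with a
   mean-subtracted, sign-flipped Laplacian-of-Gaussian kernel
   (`log_kernel()`, sigma matched to the PSF, default 1.3 px). The kernel
   is zero-sum, so smooth background — constant or gently sloping — maps to
   ~0 while spot-sized structure is enhanced. Filtering is 2-D because the
   axial sampling (0.3 µm) is coarse relative to the lateral PSF and the
   subsequent amplitude fit is 2-D.
2. **Candidates** (`candidate_maxima()`): a particle candidate is a strict
   3-D regional maximum (26-neighborhood) of the filtered stack with
   positive response inside a cell mask. Because one molecule spans
   adjacent slices, no two candidates may lie within a 3-voxel Euclidean
   exclusion radius; the brighter wins. A relative floor of `1e-9 * max`
   discards numerical dust from the FFT convolution on flat images.
3. **Plateau threshold** (`threshold_curve()`,
   `select_plateau_threshold()`): candidate intensities are scanned over 60
   log-spaced thresholds; the count of candidates strictly above each
   threshold is non-increasing. Dim background maxima die quickly as the
   threshold rises, genuine spots persist, so the log-log curve shows a
   shelf whose height is the molecule count. The automatic rule computes
   the smoothed log-log slope and accepts interior local minima of |slope|
   that are (a) preceded at lower thresholds by a descent at least
   `rise = 0.5` steeper and (b) supported by at least `min_count = 10`
   particles; the flattest qualifying minimum wins. Condition (a) is what
   rejects pure background: its curve steepens monotonically and never
   produces a qualifying minimum, raising a "no plateau" error that the
   pipeline converts to a zero count with a status flag — the signature of
   a probe set with no discernible signal. Condition (b) exists because
   with a handful of discrete candidates the curve's quantized tail has
   flat runs that mimic a plateau. A manual override is supported and
   recorded (`chosen_by = "manual_override"`), mirroring the
   confirm-or-adjust step a microscopist would perform. Thresholds are per
   channel and per image, since background varies between hybridizations.
4. **Amplitude** (`fit_gaussian_amplitude()`): a radially symmetric 2-D
   Gaussian plus constant offset is least-squares fit (Levenberg–Marquardt)
   on a 7x7 px window of the candidate's brightest slice — the smallest
   window that robustly contains a diffraction-limited spot. Flat windows
   or failed fits fall back to the raw filtered value with `fit_ok =
   FALSE`; windows clipped by the image edge are fit as-is.
5. **Autofluorescence** (`exclude_autofluorescent()`): the GFP channel
   carries no probe, so spots detected there are autofluorescent particles.
   Any RNA spot within 2 px laterally and 1 slice axially of a same-cell
   GFP spot is flagged and excluded from counts.

## Two-stage co-localization

`match_spots()` is greedy mutual-nearest-neighbor matching: candidate pairs
within the lateral window and within 1 slice axially are sorted by distance
(ties broken by index in the first, then second list, for determinism) and
accepted when both members are free. The result is injective and symmetric.
`colocalize_two_stage()` matches at a coarse window (default 4 px), takes
the per-axis median displacement of matched pairs as the rigid
inter-channel shift (robust to a minority of mismatches; fewer than 3 pairs
gives a zero shift flagged low-confidence), shifts the second channel, and
re-matches at a fine window (default 2 px). The window defaults are
config-exposed: no published values exist for them, and chromatic shifts of
1–3 px between dyes are typical.

`overlap_significance()` asks whether two RNA species co-localize beyond
chance given cell geometry: the second species' lateral positions are
resampled uniformly within the supplied mask (each spot keeps its z-slice),
matching is rerun, and `p = (1 + #{null >= observed}) / (1 + n_perm)`. The
uniform-within-nucleus null is this package's choice for nuclear RNAs — it
conditions on spot numbers and the compartment, not on any finer spatial
structure, so clustering of either species inflates significance and the
test should be read as "more overlap than uniform placement explains". The
matched count is integer-valued, so p-values are discretely conservative
when expected chance overlap is very small; calibration is tight (type-I
within a couple of points of nominal) once expected overlap reaches a few
pairs.

## Probe-set validation (even/odd two-color)

Half the oligonucleotides (evens) carry one dye, half (odds) another. A
genuine target yields the same molecules in both channels; a rogue
oligonucleotide binding an abundant off-target RNA inflates one channel
only. Counting in half-probe-set channels is unreliable by the plateau
method (fewer bound oligos, lower contrast), so validation is deliberately
threshold-free: from each channel the `x = max(50, round(5 m))` brightest
spots are taken (`selection_count()`), where `m` is the mean per-cell count
measured with the full single-colored probe set, and their two-stage
co-localized count per cell is compared with the single-color count
distribution by a two-sided Mann–Whitney U test (`validate_probe_set()`);
P < 0.05 is `invalid_quantitative`. Two choices were open: the multiplier's
rounding (5m is rounded to the nearest integer; the floor of 50 comes from
the rule itself) and the test's sidedness (two-sided, since the criterion
is any distributional difference). The qualitative criterion — a visible
pattern mismatch between channels — is a judgement call, so it enters as an
input flag rather than an algorithm.

## Nuclear localization and classes I–V

A spot is nuclear when its rounded (y, x) falls in the nucleus label (z
collapsed, matching the DAPI max-projection heuristic). Three summaries:
molecule-level (nuclear spots / all spots), cell-level (fraction of cells
with > 50% nuclear spots), and the median per-cell nuclear fraction used
for classification. Cells without spots carry no information and are
excluded.

The published class rules are: median fraction > 0.65 → one of I/II/III
(split by foci); < 0.35 with mean count > 20 → V; otherwise IV. The I/II/III
split was done by eye in the original workflow; `lincfish` codifies it so
it is testable: foci are single-linkage clusters of >= 5 nuclear spots at
cut distance 3 px (`detect_nuclear_foci()`), and a pair is class I when
>= 80% of nuclear molecules sit in foci with at most ~2 foci per cell,
class II when foci are present but not dominant, class III when absent.
These numbers (5, 3 px, 80%, 2) are package choices, config-tunable, with a
`manual_class` override recorded in the output. The rule is deterministic
and monotone: raising every cell's nuclear fraction can never demote a pair
from I/II/III to IV/V.

Mitotic cells (flagged in the cell metadata) are excluded from interphase
classification; the number of mitotic cells retaining foci is reported
separately, since nuclear foci are expected to dissolve during mitosis.

**Limitation**: cluster-based foci detection needs *resolvable* spots. In
rendered (or real) images, the molecules of a tight focus merge into one or
two bright maxima under the 3-voxel exclusion rule, so image-derived spot
tables under-report foci; brightness-based reasoning (a focus spot's
amplitude is a multiple of the single-molecule amplitude) or manual
inspection is required there. The classifier is therefore validated on
ground-truth spot tables, where foci are explicit.

## Single-cell statistics

* `summarize_counts()`: mean, median, sd and CV over all imaged cells
  including zeros; CV uses the population (n) denominator by default,
  switchable. Histograms use 3-molecule bins to 50 and 10-molecule bins to
  300 (right-open; the last bin absorbs larger counts).
* `poisson_reference()`: CV = 1/sqrt(mean), the constitutive-expression
  reference curve.
* `mean_median_regression()`: OLS of median on mean across genes with the
  Pearson r. Unimodal genes track the identity; a bimodal gene's rare high
  cells inflate the mean but not the median, pulling it below the line.
* `jackpot_bound()`: observing no high-expressing cell among n cells bounds
  an undetected subpopulation at f = 1 − (1 − power)^(1/n); the identity
  1 − (1 − f)^n = power holds to machine precision.
* `correlate_with_marker()` / `correlate_panel()`: Pearson correlation
  after removing cells where either gene's count exceeds its
  median + 5 × MAD (scaled MAD; the multiplier and rule are reported in the
  output — the robust-symmetric rule was chosen for auditability, the
  original study's exact rule being unpublished). Sign labels across a
  panel are assigned at Benjamini–Hochberg FDR 0.05; BH is this package's
  choice for the multiplicity correction.

## The synthetic-data generator

`generate_experiment()` emulates what the analyses assume: elliptical cells
on a non-overlapping grid with concentric elliptical nuclei (half the cell
radii); per-cell counts from a Poisson, negative-binomial or two-component
mixture model (`count_model()` — the mixture defaults, 25% of cells at
107 ± 26 molecules versus 9 ± 1.2, reproduce the heterogeneous-lncRNA
exemplar); molecules placed uniformly in the nucleus or cytoplasm by a
`nuclear_fraction` Bernoulli draw; optional nuclear foci as k co-located
molecules in a 2-px disc; spots rendered as separable 3-D Gaussians with
log-normal amplitude variation (sd 20%, mimicking probe-number variation,
and keeping profiles fittable); a polynomial background gradient plus
Gaussian read noise (`snr` = median amplitude / noise sd; default 10, a
bright, well-hybridized probe set); dual-label channels with independent
sub-pixel jitter and a rigid shift on the second channel; rogue-oligo foci
in one channel only; and autofluorescent particles shared between the GFP
and RNA channels. All randomness flows from one seed; identical configs
give bit-identical outputs.

What it does **not** emulate — and hence what passing tests cannot show
about real data: optical aberrations and depth-dependent PSFs,
photobleaching, Poisson shot noise (the SNR contract is defined against
read-noise sd alone), irregular cell shapes and segmentation errors,
3-D nuclear geometry, cell-volume covariation with expression, and the
empirical amplitude/background distributions of real probe sets, which are
unpublished; `snr` is therefore an explicit free knob.

## Problem sizes

The package's own verification uses desk-scale simulations chosen to make
the statistical checks meaningful: 20 single-cell stacks of 25 × 128 × 128
voxels with 50–200 molecules for counting accuracy (median relative error
compared against the 10% design target); 10 dual-label cells at 50
molecules with a (2, 1) px shift for co-localization recovery (target
>= 95%); 1,000 cells for mixture-weight recovery (± 4 points); 500
replicates for Mann–Whitney type-I calibration; 300 simulated cells × 199
permutations for overlap-test calibration; and 60 class-conditional cohorts
(5 classes × 12 pairs, 6 cells each) for classification recovery
(>= 90%). `scripts/acceptance.R` re-runs the first four from a single
command-line seed.

## Degenerate inputs and numerical conventions

Coordinates are 0-based `(z, y, x)` voxels in all tables; y and x are
sub-pixel after the Gaussian fit. Masks are label images with background 0.
Empty spot lists match to nothing; an all-equal intensity set yields a
single-point threshold curve (and no plateau); an all-zero count vector is
`no_signal`; regressions refuse degenerate (zero-variance) predictors;
matching ties are index-ordered; `p = 1` when no overlap is observed.
Stacks round-trip bit-exactly through 16-bit TIFF for integer values in
[0, 65535]; rendered stacks are quantized on write.
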