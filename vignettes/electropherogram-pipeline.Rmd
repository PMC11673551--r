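---
title: "From capillary trace to annotated N-glycan peak table: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From capillary trace to annotated N-glycan peak table: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycge)
```

## The measurement and its model

In xCGE-LIF glycomics, N-glycans released from plasma glycoproteins are
labelled with APTS and electrophoresed through a capillary gel alongside a
LIZ-labelled oligonucleotide ladder. The instrument records fluorescence
per scan in two dye channels. Migration time is not reproducible across
runs — gel temperature, field and injection all drift — but the ladder
co-migrates with the analytes, so expressing positions in *nucleotide
units* of the ladder removes most run-to-run variation. Each glycan
species then appears as an approximately Gaussian peak at a reproducible
nucleotide coordinate inside the 150–350 nt "glycomic region", and its
height or area is proportional to abundance.

The pipeline is therefore: extract channels, calibrate scan→nt against
the ladder, excise 150–350 nt, denoise, remove baseline, call and
quantify peaks, and transfer structural annotations from a reference
profile by elastic alignment.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| glycan / ladder tags | `DATA,1` / `DATA,105` | — | 3130XL dye-to-channel layout (522 / 655 nm); other instruments differ, so both are configuration, not science |
| region | [150, 350] | nt | the plasma N-glycome window on the normalized axis |
| resampling step | 0.05 | nt | ≈ the scan density of a 7000-scan acquisition mapped through a typical migration law; finer steps add no information |
| smoothing σ | 5 | measurement points | protocol-stated; note it is defined on the sampled axis, so its physical width in nt depends on the step |
| ARPLS λ | 1e5 | — | unstated by the protocol; mid-range of the values the ARPLS literature recommends for this grid density, exposed in config |
| ARPLS ratio / max_iter | 1e-6 / 100 | — | standard convergence settings |
| detection threshold | 0.01 | fraction of region max | protocol-stated: height *and* topological prominence must both reach 1 % |
| boundaries | ±3 | fitted σ | protocol-stated; captures 99.73 % of a Gaussian peak's mass |
| DTW band | ±10 | nt | bounds pathological warps; real replicate shifts are well under this |

## Numerical choices

**Ladder calling.** Apexes are gated at 10 % height and prominence of the
ladder maximum, candidates closer than 20 scans are merged (integer
quantization can split one fragment's apex into equal-height twins, and no
realistic migration law places two fragments that close), and the expected
fragment count must be met unambiguously — a surplus is accepted only when
the prominence ranking separates cleanly (factor ≥ 2), otherwise the run
fails calibration rather than guessing. A mis-called ladder would silently
shift every downstream coordinate.

**Migration map.** A Fritsch–Carlson monotone piecewise cubic through the
(apex scan, fragment size) knots, the convention of local sizing in
fragment analysis; a piecewise-linear option exists for degenerate
ladders. Monotonicity is verified on a dense grid and violations are
errors. Whether the original protocol used local interpolation or a
global fit is not stated; local is the default here because it is what
fragment-analysis software conventionally does.

**Smoothing order.** Denoising happens after excision on the resampled
nt axis: the σ of the filter is specified in *measurement points*, which
only has a stable meaning on the uniform resampled grid. Reflection
padding avoids edge droop at the 150 nt boundary where real peaks sit.

**ARPLS degeneracy guard.** The reweighting scales residuals by the
standard deviation of the *negative* residuals. On noiseless input that
scale collapses toward machine precision, the logistic becomes a step
function at zero, and the iteration starts peeling smooth convex
stretches of genuine baseline off the fit exactly as if they were peaks
(we observed the residual against an exponential drift growing by ~0.1
per iteration while a plain Whittaker smoother tracked the same drift to
4e-3). The implementation therefore declares convergence when that scale
falls below 1e-4 of the signal range. Real, noisy spectra never reach
this regime; the guard only stabilizes synthetic noiseless input.

**Peak shape fit.** The Gaussian is fitted by bounded quasi-Newton least
squares in apex-height units (so results are exactly scale-equivariant,
and zero-residual noiseless peaks converge — `nls()` fails on a perfect
fit). The initial σ comes from the half-width at half-maximum rather
than window moments: the prominence saddles of the region's *tallest*
peak span the whole spectrum, and a moment estimate over that support
explodes to an envelope fit of the entire profile (σ in the hundreds of
nt), which is also why the fit window is capped at ±5 initial σ. On
non-convergence, or on an exact apex plateau (detector saturation), a
flagged moment-based σ is used instead.

**Integration.** Composite Simpson on the sampled grid between the ±3σ
boundaries; an even interval count gets a trapezoid patch on the final
interval; fewer than three samples fall back to the trapezoid rule, and
both departures are flagged in the result. Boundaries clipped by the
region edge are flagged, and the area then covers the truncated support.

**Ties and determinism.** A plateau's apex is its leftmost sample. All
simulator randomness flows from a single integer seed, and `cmd_process`
output is bit-identical across runs on the same input.

**Overlap.** Adjacent peaks whose ±3σ intervals intersect are flagged,
never deconvolved: the protocol's own treatment of a tail-overlap
artifact peak was manual exclusion, so exclusion is left to the caller
and areas are integrated independently (double counting is possible and
the flag is the warning).

## Alignment and annotation

Spectra are max-height normalized before DTW, otherwise amplitude
differences dominate the warping; baseline-corrected spectra are aligned
because peak positions, not drift, should drive the path. "An optimal
warping path connects two peaks" is read as the *apex-window rule*: some
path pair must lie within ±1 sample of both apexes. A half-prominence
*span rule* is also implemented (`rule = "span"`) for crowded profiles;
the choice is recorded in the match table. One-to-many connections keep
the apex-closest pair as primary and report the rest as secondary.
Path monotonicity guarantees no crossing matches.

The packaged reference is a *structure catalog* (ref_id → Oxford
strings), not a located spectrum: the original reference electropherogram
exists only as a figure, so DTW matching requires a user-supplied
reference spectrum and located peak list. Catalog cells that concatenate
several structures were split into separate strings; where a plateau of
two reference peaks is annotated jointly, the printed order was split
two-and-two, which is a convention, not information from the source. The
packaged manual-override file demonstrates the visual-matching mechanism:
an artifact peak forced to NA, a tail-overlap peak excluded, a plateau
assigned two reference ids.

## Reproducibility statistics

For a set of technical replicates on a common grid: average pairwise
Pearson ρ of the intensity vectors (raw, and after max-height
normalization — the flag mirrors the reported statistic pair; Pearson ρ
itself is scale-invariant, so differences between the two columns on real
data reflect detrending interactions, not scaling); the median over pairs
of the integer lag maximizing the cross-correlation of mean-centered,
max-normalized spectra (positive = second replicate delayed; medians of
even pair counts can be half-integer); and per-peak CVs. Peaks are
grouped across replicates by apex proximity within ±1 nt after per-pair
lag correction; groups missing from any replicate are reported separately
and never enter the median.

## What the simulator emulates — and what it does not

`simulate_run` builds a glycan channel as planted Gaussians placed
through a strictly monotone quadratic migration law (widths scaled by the
local law derivative so nt-axis σ is preserved), plus constant / linear /
exponential-decay baseline drift and additive white Gaussian noise; the
ladder channel carries narrow Gaussians at the law's images of the
fragment sizes. Replicates share the scene and draw an integer scan shift
of the glycan channel only (injection jitter that survives calibration
because it desynchronizes the dye channels), a global amplitude factor,
and fresh noise. Defaults: 7000 scans with the glycomic window in the
central half, 30 peaks spanning two orders of magnitude in height, 1 %
noise, 5 % amplitude jitter, 3-scan shift jitter — values a routine
plasma run plausibly shows; none is stated by the protocol, and they were
fixed once, before the tests were frozen.

Not emulated: detector saturation (except as synthetic plateaus in unit
tests), shot noise (fluorescence at these intensities is near-Gaussian;
an option exists conceptually but is off), capillary-to-capillary
mobility differences, dye pull-up/bleed-through (off by default), and the
field-strength dependence of absolute migration. A green test on
simulated data therefore establishes algorithmic correctness against
planted truth — not instrument robustness.

One statistical caveat is worth stating precisely: with noise at exactly
1 % of the region maximum — the detection threshold itself — extreme-value
statistics of smoothed white noise give each spectrum a ~0.5 %
probability of one spurious threshold crossing. The 100 %-precision
property at the "≤ 1 % noise" boundary is thus a high-probability
statement, not a theorem; the acceptance suite runs it over a fixed seed
sequence and the caveat lives here rather than in a loosened assertion.

## Known limitations

- No deconvolution of fused peaks; the overlap flag is the only remedy.
- Annotation quality is bounded by the user's reference spectrum; the
  packaged catalog carries structures but no positions.
- The ±1 nt replicate peak-grouping tolerance assumes lag correction has
  removed systematic shift; pathological replicates with > 1 nt residual
  warp would fragment groups (they are then reported as incomplete, not
  silently pooled).
- ARPLS λ is a global smoothness choice; strongly curved baselines at the
  region edges are the least-constrained part of the fit.
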