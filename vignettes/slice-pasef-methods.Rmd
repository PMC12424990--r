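---
title: "Slicing the precursor ion space: models and methods in slicepasef"
author: "slicepasef authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slicing the precursor ion space: models and methods in slicepasef}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicepasef)
```

## The problem

On a trapped-ion-mobility (TIMS) quadrupole time-of-flight instrument, ions
accumulated in the TIMS device are released serially by reduced ion mobility
(1/K0) while the quadrupole (Q1) transmits one m/z window at a time. One
accumulation-and-release event with its set of paired (ion-mobility interval
x Q1 window) *slice-steps* is a **frame**; a group of frames whose windows
jointly cover the targeted precursor space once is a **subcycle**; the full
DIA cycle may alternate several subcycle variants.

Classical dia-PASEF uses a few fixed-width, non-overlapping Q1 windows per
frame, stacked diagonally in m/z x mobility space. Any precursor is then
fragmented during only one of the cycle's frames: with 8 equal-fill MS2
frames, each precursor receives 1/8 = 12.5% of the total MS2 accumulation
time (its **MS/MS duty cycle**), and ions eluting from the TIMS device
outside the currently transmitted m/z region are lost. Slice-PASEF instead
slices the precursor space into quasi-continuous mobility slices whose Q1
windows follow the local m/z distribution of the multiply-charged
population. In the 1-frame (1F) variant a single MS2 frame samples the whole
multiply-charged space: every isolated precursor has a 100% duty cycle and,
at a 100 ms fill time, the cycle takes 100 ms instead of 8 x 100 ms,
yielding many more chromatographic points per peak. The 2F and 4F variants
split each slice's window into 2 or 4 m/z segments acquired in separate
frames, trading duty cycle (1/2, 1/4) for reduced spectral complexity, with
segment boundaries that may shift by half a segment between subcycles.

The package implements this method family end to end at desk scale:
synthetic precursor clouds, scheme design, analytic figures of merit,
in-silico acquisition into boundary-annotated frame spectra, and an
ion-mobility-aware matching and quantification engine.

## The synthetic precursor cloud

`generateSyntheticCloud()` emulates the ion map of a tryptic whole-proteome
digest, which is the geometric substrate the designer needs: per charge
state, m/z and mobility change proportionally, so the cloud is generated as

* a charge state z drawn from `chargeProbs` (defaults 0.15 / 0.55 / 0.30
  for 1+ / 2+ / 3+),
* a neutral peptide mass from a per-charge log-normal (medians 720, 1500
  and 2700 Da), converted to m/z with the proton mass 1.00728 Th,
* 1/K0 = intercept(z) + slope(z) x m/z + Gaussian scatter
  (`imScatterSd = 0.025`).

The default trend coefficients (slopes 8.0e-4, 6.2e-4, 5.6e-4; intercepts
0.55, 0.40, 0.42 for z = 1, 2, 3) place the singly-charged trend at higher
1/K0 than the multiply-charged trends at equal m/z, so diagonal designs
derived from the 2+/3+ envelope exclude singly-charged ions by geometry
rather than by an explicit filter. The coefficients and scatter were
calibrated once so that charge 2-3 ions inside narrow mobility bins
(width 0.01, spanning 1/K0 0.85-1.15) spread over a mean interquartile
range of about 70 m/z, the figure that motivates ~50-Th-or-wider slice
windows; `scripts/acceptance.R` recomputes this number from scratch.

Elution apexes are uniform over the gradient and every peak is a Gaussian
parameterised by its full width at half maximum (default 3 s) -- no
tailing, no saturation. Each precursor carries 3-10 fragment ions with m/z
uniform in the MS2 scan range and Dirichlet-distributed relative
intensities: the matching engine needs positions and intensities, not
fragmentation chemistry. The generator therefore does **not** emulate
peptide sequences, isotope envelopes, correlated fragment patterns, charge
state coelution, or detector effects; tests that pass on these clouds
validate the geometry and arithmetic of the method family, not
identification performance on real data.

## Scheme design

All intervals are half-open, `[lo, hi)`, in both coordinates, so abutting
steps or segments never isolate a point twice and every point of a
partition belongs to exactly one member -- this is what makes the duty
arithmetic exact.

`design1F()` partitions the cloud's mobility range into `nImSteps`
(default 20) equal slices. Each slice's Q1 window spans the `[qLo, qHi]`
empirical quantiles of the m/z of multiply-charged ions in the slice,
padded by `padMz` (5 Th) and widened symmetrically to at least
`minWidthMz` (50 Th). Quantiles are lower-interpolation order statistics
(the value at index `ceiling(q * n)`): trivially reproducible by a
sort-and-index oracle. The envelope quantiles default to 0.005/0.995: with
lower-interpolation quantiles these leave at least 99% of the
multiply-charged intensity inside the designed windows on default clouds,
which is the point of 1F slicing (capturing essentially the whole
multiply-charged space); the marginally tighter 0.01/0.99 setting is one
knob away. Slices containing no ions inherit windows linearly interpolated
from their nearest non-empty neighbours (constant at the edges):
quasi-continuous slicing must not leave holes.

`designMultiframe()` splits each 1F window into `nFrames` (2 or 4)
contiguous segments; frame *j* of a subcycle takes segment *j* across all
slices, so the per-step union of the multi-frame windows reconstructs the
1F window exactly. Boundaries are either equal-width (`"midpoint"`) or
per-slice intensity-weighted quantiles of the isolated ions
(`"balanced"`), which equalises precursor signal across frames for a given
sample. With `shiftSubcycles` (default) the cycle alternates two subcycle
variants whose boundaries are offset by half a segment (half the mean
segment width, clamped to the window edges) -- the simplest shift schedule
consistent with overlapping-window acquisition; richer schedules would be a
config extension, not a redesign.

`designDiapasefReference()` builds the classical comparison scheme:
`nFrames x windowsPerFrame` fixed-width windows tiling the m/z range, the
window of rank *k* occupying the *k*-th of equally many mobility strata,
and frame *f* carrying ranks `f, f + nFrames, ...`. Any consistent diagonal
interleave gives the same figures of merit; this round-robin one is chosen
because it spaces each frame's windows evenly across the mobility range.
A width that does not tile the range exactly is rejected with the width
that would.

Collision energies are filled per step from a piecewise-linear ramp over
1/K0, clamped outside the anchors. The default anchors are 20 eV at
1/K0 = 0.60 and 59 eV at 1/K0 = 1.60 (instrument-vendor settings are often
quoted with the leading "0." of the mobility elided; the ramp here treats
the low anchor as 0.60 V s/cm^2).

`computeFrameRepeats()` closes the design loop on chromatography: short
subcycles can be repeated `r` times (spectra merged downstream) to raise
signal-to-noise while keeping at least `minPoints` (default 3) cycles per
peak FWHM; the function returns the largest such `r`, or 1 with a warning
when even a single acquisition violates the floor.

## Figures of merit

`precursorDutyCycle()` is the fraction of the cycle's **MS2** fill time
during which a point of the precursor space is being fragmented. MS1
frames are excluded from numerator and denominator, which is what makes a
1F scheme score exactly 100% and the 8-frame reference exactly 12.5% even
when MS1 scans are present; including MS1 would turn these printed
constants into configuration-dependent quantities. Fill-time weighting is
used throughout, so unequal fills are handled, and frame repeats cancel
out of the duty ratio while scaling the cycle time.

`schemeMetrics()` aggregates over a cloud: the intensity-weighted mean
duty cycle and the intensity fraction isolated at least once (coverage)
over multiply-charged ions, with unweighted per-ion versions reported
alongside; the cycle time as the sum of all fill times (MS1 and repeats
included); and points-per-peak as FWHM / cycle time. Per-frame overhead
(quadrupole settling, TOF extraction) is deliberately not modelled -- the
package predicts fill-time arithmetic, not wall-clock cycle times of a
specific instrument generation.

## In-silico acquisition

`simulateAcquisition()` tiles a retention-time window with cycles and
emits, per physical frame occurrence, one annotated peak per (isolated
precursor x fragment): intensity = precursor intensity x Gaussian elution
factor at the frame time x fragment relative intensity x (fill time /
100 ms), with the isolating step's Q1 boundaries attached to the peak.
The fill-time proportionality (referenced to 100 ms) is the accumulation
premise on which all duty-cycle arithmetic rests. Peaks are ideal
centroids; `mzJitterPpm` and `imJitterSd` add measurement noise, and
`noisePeaksPerFrame` adds spurious background peaks.

`intensityCv` is modelled as a single mean-1 log-normal factor drawn per
precursor per simulated run and applied to all of that precursor's peaks.
This represents run-to-run variation in recovered abundance (injection,
ionisation, transmission) rather than per-spectrum shot noise, and it is
the model under which the coefficient of variation measured on replicate
quantities recovers the injected value -- per-peak noise would largely
average out of any area-based quantity and make the knob uninterpretable.

Quadrupole switches are counted by `q1SwitchCount()` and classified into
overlapping shifts (quasi-continuous slicing) and discontinuous jumps
(stacked dia-PASEF windows). The optional loss model attenuates the first
`switchLossSpan` (10%) of each post-jump step by `switchLossFraction`; the
real magnitude of switch losses is known only qualitatively, so the model
defaults to off and any nonzero setting is a what-if.

## Matching and quantification

The matcher re-implements the sliced-data processing concepts on the
simulator's boundary-annotated peaks:

* **Frame candidacy** (`candidateFrames()`): because sliced frames span
  broad m/z ranges, whether a precursor must be queried against a frame is
  decided by its expected ion mobility in addition to its m/z -- a frame
  is a candidate iff it holds a peak whose annotated Q1 boundaries contain
  the precursor m/z and whose mobility is within `imTol` of the
  precursor's. Only peaks with matching boundaries take part downstream.
* **Best-peak fragment intensity** (`fragmentIntensityMultiframe()`): each
  fragment is compared against all frames of a subcycle and takes the
  intensity of the most intense matching peak; ties break towards the
  lowest frame index so reprocessing is deterministic.
* **Repeat merging** (`mergeRepeats()`): peaks of consecutive repeats with
  identical boundaries, m/z within tolerance and mobility within tolerance
  are combined with summed intensity (additive-noise signal averaging) and
  intensity-weighted mean positions; total intensity is conserved exactly.

Defaults: 15 ppm m/z tolerance at both levels (a typical fixed DIA search
setting for this instrument class) and 0.05 1/K0 -- about twice the
simulator's default mobility jitter; both are config-exposed.
Two-dimensional peak picking is out of scope: merging operates on already
centroided peaks.

`extractXic()` produces one point per DIA cycle (repeats merged, best frame
per subcycle, summed over fragments and subcycles). The quantity is the
trapezoidal area of the contiguous region at or above half the apex,
measured in intensity x *cycle* units rather than intensity x seconds. This
choice is deliberate: a faster-cycling scheme collects proportionally more
ions over a peak, and an area over cycle index grows with both per-frame
signal and sampling rate, so the quantified ratio between two schemes
reproduces their duty-cycle ratio (a time-based area would be
sampling-rate-invariant and hide exactly the effect the method family is
about). `quantifyXic(method = "total")` integrates the whole trace instead,
which is the robust variant used for scheme-ratio checks where the
half-apex region of a coarsely sampled trace would carry discretisation
error. The measured points-at-FWHM is the count of cycles at or above half
the apex.

`cvSummary()` divides the standard deviation (n - 1 denominator) of
untransformed quantities by their mean and reports the CV only for
precursors with at least 3 replicates; fewer replicates or a zero mean are
flagged as suppressed.

## Method-definition files

Schemes serialise to a comma-separated text table, one row per slice-step:
`#MS Type,Cycle Id,Start IM,End IM,Start Mass,End Mass,CE`, with `MS Type`
in {MS1, PASEF}, `Cycle Id` the frame index within the cycle, floats at 4
decimals and CE blank when unset -- the shape of text-table method files
that instrument control software imports. Because that row schema cannot
carry fill times, repeat counts or subcycle grouping, the writer prepends
`##`-prefixed metadata lines with exactly those fields, making
`readMethodTable(writeMethodTable(x))` a field-wise identity at 4-decimal
precision; plain files without metadata are still readable with documented
defaults (subcycles delimited by MS1 rows, 100 ms, 1 repeat). Parsing is
deliberately permissive: geometric nonsense (inverted intervals,
overlapping mobility ranges, sub-minimum widths) is the business of
`validateScheme()`, which returns a severity-tagged report instead of
refusing to read.

## Numerical choices and degenerate inputs

* Half-open intervals everywhere; boundary probes are tested explicitly.
* Lower-interpolation quantiles (`ceiling(q n)`), exactly reproducible by
  brute force on any bin.
* Empty design slices: linear interpolation between non-empty neighbours,
  constant extrapolation at the edges; a single non-empty slice propagates
  its window everywhere.
* Degenerate envelopes (all ions at one m/z) fall back to the minimum
  window width, centred.
* Simulated peaks with elution factor below 1e-12 are dropped.
* `nIons <= 0` yields an empty cloud (not an error); an empty cloud makes
  duty and coverage NaN with a warning.
* Boundary shifts in multi-frame designs are clamped to the window edges;
  ties in best-peak selection break to the lowest frame index.

## Problem sizes

The shipped tests run the full stack at deliberately modest sizes: default
clouds of 50,000 ions for envelope statistics, 10,000 for
parameter-recovery checks, and a few hundred precursors over 10-40 s
retention windows for simulation/matching checks (about 240 jointly
covered precursors for the duty-ratio oracle and 5 replicate runs for CV
recovery). These sizes give sub-percent Monte-Carlo error on every
quantity asserted while keeping a full run in the low minutes on one core;
nothing in the implementation is specific to them.

## Known limitations

* No peptide chemistry: no sequences, digestion, CCS physics or isotope
  envelopes; fragment m/z are random, so real chimeric-spectrum behaviour
  is only coarsely represented.
* No instrument overheads or TOF/detector models; cycle times are pure
  fill-time sums.
* No FDR machinery, spectral libraries, retention-time alignment or
  cross-run features: the matcher quantifies known ground-truth precursors
  against simulated streams.
* The identification and quantification gains reported for this method
  family on real samples depend on raw LC-MS data and a full search
  engine; this package reproduces the acquisition-geometry arithmetic and
  processing concepts that underlie them, not those benchmark figures.
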