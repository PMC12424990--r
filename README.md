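# slicepasef

Desk-scale design, evaluation and in-silico simulation of **Slice-PASEF**
and **dia-PASEF** acquisition schemes for trapped-ion-mobility (TIMS)
time-of-flight mass spectrometers, with an ion-mobility-aware fragment
matching and quantification engine. It is written for mass-spectrometry
method developers who want to reason about isolation-window geometry, duty
cycles and chromatographic sampling before (or without) touching an
instrument, and for computational proteomics developers who want a small,
fully testable model of sliced-quadrupole DIA data processing.

## The model

A DIA-PASEF cycle is a hierarchy *subcycle → frame → slice-step*, where a
slice-step pairs an ion-mobility interval `[im_lo, im_hi)` with a Q1
isolation window `[mz_lo, mz_hi)` (all intervals half-open). For a
precursor at `(m/z, 1/K0)` the **MS/MS duty cycle** is

    duty(m/z, 1/K0) = Σ fill·repeats over MS2 frames isolating the point
                      ─────────────────────────────────────────────────
                      Σ fill·repeats over all MS2 frames in the cycle

MS1 frames count in the cycle time but not in the duty cycle. A classical
8-frame dia-PASEF scheme with disjoint 25-Th windows gives every covered
precursor duty 1/8 = 12.5% and an 800 ms cycle at 100 ms fill; a 1-frame
Slice-PASEF scheme, whose quasi-continuous mobility slices carry Q1
windows that follow the multiply-charged ion density (≥ 50 Th wide,
singly-charged ions excluded by geometry), gives duty 100% in a 100 ms
cycle — an 8× sensitivity and 8× sampling-rate advantage that the package
verifies analytically and by simulation. 2F/4F variants split each slice
window into 2 or 4 segments (duty 1/2 and 1/4) with boundaries that can be
intensity-balanced and shifted by half a segment between subcycles.

The in-silico stream annotates every fragment peak with the Q1 boundaries
that produced it; the matcher decides frame candidacy from the precursor's
m/z *and* ion mobility against those per-peak boundaries, takes per
fragment the most intense matching peak across the frames of a subcycle,
merges frame repeats by summation, and quantifies per-cycle extracted ion
chromatograms (trapezoidal area of the region at or above half the apex).
Coefficients of variation are sd (n−1) / mean, reported at n ≥ 3.

## Worked example

```r
library(slicepasef)
cloud  <- generateSyntheticCloud(cloudGenConfig(nIons = 20000, seed = 1))
cloud
#> IonCloud: 20000 precursors, 129559 fragment ions
#>   m/z 400.0-1200.0 Th, 1/K0 0.600-1.300, gradient 300 s
#>   charge states: 1+ (3085), 2+ (11030), 3+ (5885)

scheme <- design1F(cloud)
scheme
#> AcquisitionScheme 'slice-1F'
#>   1 subcycle(s), 2 frame(s) (1 MS2), 20 slice-step(s)
#>   m/z 395.4-1204.6 Th, 1/K0 0.600-1.300
#>   cycle time 200 ms (fill times incl. MS1 and repeats)

schemeMetrics(scheme, cloud)
#> CycleMetrics
#>   cycle time      : 200.0 ms
#>   MS/MS duty cycle: 99.4 % (intensity-weighted), 99.4 % (per ion)
#>   coverage        : 99.4 % (intensity), 99.4 % (per ion)
#>   points per peak : 15.00
```

The synthetic cloud follows per-charge linear 1/K0-vs-m/z trends with
Gaussian scatter; 20,000 precursors are generated here, of which the
multiply-charged ones drive the design. The 1F design slices the mobility
range into 20 steps whose windows track the 2+/3+ envelope (that is why
the scheme's m/z range slightly exceeds the cloud's): 99.4% of
multiply-charged intensity is isolated in every 200 ms cycle (100 ms MS1 +
100 ms MS2), i.e. 15 points per 3-s chromatographic peak, and each
isolated precursor has a 100% MS/MS duty cycle.

The end-to-end comparison against the 8-frame reference is one command:

```r
res <- cmdDemo(runConfig(overrides = list(out_dir = "demo_out",
                                          cloud = list(n_ions = 1500),
                                          sim = list(rt_window_s = 15))))
#> Slice-PASEF demo: 1F slicing vs 8-frame reference dia-PASEF
#> 1F duty cycle (isolated precursors)        : 100.0 %
#> reference duty cycle (isolated precursors) : 12.5 %
#> 1F coverage          : 100.0 %
#> reference coverage   : 19.1 %
#> 1F cycle time        : 100 ms
#> reference cycle time : 800 ms
#> duty ratio (isolated, 1F/ref)               : 8.00
#> simulated MS2 signal ratio (jointly covered): 8.47
```

Both schemes are simulated noiselessly over the same 15 s window; summing
the fragment signal of jointly covered precursors recovers the analytic
8× duty advantage (the residual deviation is retention-time
discretisation of the 800 ms reference cycle). A command-line front end
with `generate`, `design`, `validate`, `evaluate`, `compare`, `simulate`,
`match` and `demo` subcommands is installed at
`system.file("cli", "slice-pasef.R", package = "slicepasef")`.

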