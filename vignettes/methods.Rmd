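---
title: "Doubling-normalised dose-response analysis of kinetic proliferation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubling-normalised dose-response analysis of kinetic proliferation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldrc)
```

## The analysis problem

A live-cell imaging instrument reports a growth metric — here percent
confluence, the fraction of the imaged surface covered by cells — per well
every couple of hours over several days. A compound screen doses a dilution
series of each inhibitor against a proliferating cell line, with
solvent-only *vehicle control* wells as the untreated reference. The
analysis question is: at what concentration does each compound halve the
proliferative read-out (the EC50)?

A naive answer reads confluence at a fixed wall-clock time. That conflates
potency with growth rate: a slow line assayed at 72 h has completed fewer
divisions than a fast one, and effects that need a round of replication to
appear are under-sampled. `celldrc` instead reads values at a **cut time**
defined by the *untreated culture's doublings*: the time at which the
vehicle-control curve has doubled `k` times from a baseline, restricted to
the exponential phase and to a maximum allowable confluence. EC50s from
different lines or growth conditions then correspond to the same amount of
untreated proliferation.

## The analysis unit

All downstream quantities are relative to one pooled vehicle-control curve,
so the container of the analysis (`make_drc_set`) enforces that every well
in a set shares a single (growth condition, cell type) pair.
`split_drc_sets` partitions a mixed plate into such sets — a true partition
(disjoint, exhaustive), property-tested in the suite. Growth condition is
part of the key, not just the cell line: the same line under, say, hypoxia
versus normoxia proliferates differently and needs its own control curve.
Changing a set's cut time invalidates any attached dose-response results,
preventing EC50s computed at a stale cut time from surviving.

## Growth-curve smoothing

Curves are fitted with base R `loess`: local quadratic regression with
tricube weights. Two fits serve different purposes:

* **grouped** — one curve per (compound, concentration), pooling all
  replicate wells' points. Pooled points are handed to the smoother
  untouched (no pre-averaging), so a group with three replicates carries
  three times the weight at each timepoint and the fit's variance shrinks
  accordingly (verified by Monte Carlo in the test suite).
* **individual** — one curve per well, supplying the replicate-level
  values later read off at the cut time.

Parameters that matter:

* `span` (default 0.5, dimensionless fraction of points per local window).
  Kinetic exports are densely and near-uniformly sampled, so 0.5 smooths
  measurement noise without flattening the sigmoid; 0.25 is appropriate
  when curvature localisation matters (e.g. the phase-detection tests).
  The span is never silently changed, except for a floor guaranteeing at
  least four points per window on very short series.
* degree is fixed at 2: local quadratics reproduce affine data to machine
  precision (the suite's primary regression test for the backend) and track
  curvature with far less bias than local lines.
* prediction uses the exact local fit (`surface = "direct"`), not the
  interpolation shortcut — determinism and exactness matter more here than
  the speed difference at these data sizes.

No extrapolation: prediction outside the observed time range is an error by
design, because every cut-time decision must be supported by data.

## The cut-time algorithm

On a uniform grid over the control curve's time range (step defaulting to
the median sampling interval, typically 2 h):

1. **Curvature profile.** Second differences
   `d2[i] = y[i+1] − 2 y[i] + y[i−1]` of the predicted values; zero for
   affine growth, positive while accelerating, negative while
   decelerating.
2. **End of exponential phase.** The grid time minimising the `window_n =
   30`-point centered moving average of `d2` — where growth decelerates
   most rapidly. Windows are truncated at the sequence ends. Two degenerate
   outcomes fall back to the end of the data with a warning: a flat
   profile (no deceleration at all, e.g. linear growth) and a minimum
   inside the first full window, which reflects seeding/lag settling
   rather than the approach to confluence. When the minimum is attained at
   several grid points the earliest is used — a convention, documented as
   such. For a closed-form logistic with rate `r` the minimiser of `y''`
   sits at the inflection plus `ln(2 + √3)/r`; the detected time tracks
   this analytic value well within a window width in the tests.
3. **Truncation.** The curve is cut at the earliest of: the phase end, the
   (bisection-refined) crossing of `max_val`, and the end of the data. The
   default `max_val = 80` is stored in metric units — with percent
   confluence it keeps the read-out below the crowded regime where
   contact inhibition, not compound, limits growth.
4. **Target and inversion.** With baseline value `y(t0)`, the target is
   `y(t0)·2^k`. The earliest grid time on the truncated curve reaching the
   target is refined by bisection between the bracketing grid points to
   0.01 h — well below any biological or instrument resolution. `k = 0`
   returns the baseline time itself. If the target is not reached the
   result is `capped = TRUE`: the truncation time is returned with
   `log2(y(trunc)/y(t0))` achieved doublings, so a capped run still reports
   how far the culture got.

Whether the 30-point window refers to raw timepoints or grid points is a
genuine ambiguity; this package defines it on the differencing grid and
exposes both `window_n` and `grid_step_h`, so either reading is available.
With the default grid step equal to the sampling interval the two coincide.

## Dose-response fitting

The four-parameter log-logistic in the LL.4 convention,

$$f(x) = c + \frac{d - c}{1 + \exp\{b(\ln x - \ln e)\}},$$

is fitted per compound to the replicate-level (concentration, value) pairs
— not to means, so dose levels with more surviving replicates weigh more.
Fitting is multi-start Levenberg–Marquardt least squares (via
`minpack.lm::nlsLM`), self-started from the data: `d` at the maximum
response, `c` at the minimum, `e` at the dose nearest the half-range
crossing plus the geometric mid-dose, hill-slope starts
`±{0.5, 1, 2, 4}`. The best residual sum of squares wins; exact ties break
toward the shallowest `|log b|`. `e` is optimised on the log scale, which
enforces positivity without constraints. Since `(b, c, d)` and
`(−b, d, c)` describe the identical curve, fits are canonicalised to
`c ≤ d`, making `b > 0` always mean "response decreases with dose" and
making dose-scale equivariance (`x → kx` gives `e → ke`, `b, c, d`
unchanged) well defined. Non-convergence is recorded on the model object —
a screen with one refractory compound still yields the other EC50s — and
asking `calculate_ec50` for an unconverged model is an error naming the
compound.

The reported EC50 is the *relative* EC50, the dose of half-maximal effect
between the fitted asymptotes, which in this parameterisation is exactly
`e`. Zero-dose control rows cannot enter a log-dose fit and are excluded
from fitting (but exported); an absolute EC50 against the control level is
deliberately out of scope.

## What the simulator emulates — and what it does not

`simulate_plate` generates plates with known ground truth. Untreated
confluence follows a lagged logistic,
`y(t) = K / (1 + ((K − y0)/y0) e^{−r(t − lag)})` with `r = ln 2 /`
doubling time; a logistic rather than exponential law is essential because
the phase-detection step is only exercised by curves that decelerate.
Compounds act *cytostatically*: concentration `C` scales the rate by
`1 − I_max · C^h/(C^h + EC50^h)` — proliferation inhibition, the use case
the workflow targets. Noise is additive Gaussian on confluence, clipped at
zero, seeded and isolated from the global RNG stream.

Default conditions: 6 compounds with pEC50 5.5–7.0 (micromolar EC50s 3.16
down to 0.1), unit hill slope, full inhibition at saturation; 8 half-log
doses from 10 µM, 3 replicates; 6 vehicle wells; doubling time 18 h, y0 =
5 %, K = 100 %, 6 h lag; imaging 0–96 h every 2 h; noise sd 1.5. The
layout (150 wells) is placed on a 384-well (16×24) plate. A plate read
every 2 h for 4 days with half-log dosing and triplicates is a typical
screening design; noise of 1.5 confluence units is on the pessimistic side
of instrument repeatability.

Because a finite cut time reads the inhibition of an *exponential* process,
the apparent EC50 at the read-out differs from the rate-inhibition EC50
(for two doublings, by roughly 0.2–0.3 log10 towards lower doses). Pipeline
estimates are therefore judged against `apparent_ec50_oracle`: the 4PL fit
to the *noiseless* response evaluated on a dense 200-point log-dose grid at
the same cut time. In the acceptance run the pipeline recovers the oracle
within 0.2 log10 units for 100 % of compound × seed pairs over 20 seeds,
with a median absolute error near 0.01 log10.

Not emulated: cytotoxic (confluence-decreasing) kinetics, heteroscedastic
or spatially structured noise, edge effects, and segmentation artefacts.
Passing tests on simulated plates demonstrate the algorithmic chain is
correct under its stated model; they do not certify instrument-specific
behaviour of real exports.

## File formats and numerical conventions

* The plate-map XML dialect (`<platemap><well row= col= control=>` with
  `<compound/> <growthcondition/> <celltype/>` children) and tab-delimited
  table carry exactly the fields the workflow needs; vendor binary formats
  are out of scope. Both round-trip exactly through the package's writers.
* Kinetic imports tolerate `#` metadata lines, a date-time column before
  `Elapsed` (ignored — elapsed hours are the single time authority), CRLF
  endings and a UTF-8 BOM. Missing cells are an error, never imputed:
  silent imputation would bias the smoother. Comma decimal separators are
  rejected rather than misread.
* All text exports format numbers at 6 significant digits (full precision
  for round-trip-critical fields), so identical inputs give byte-identical
  outputs; the determinism check in the acceptance script relies on this.
* Test and acceptance workloads are sized to run in about a minute on one
  CPU: 20 seeds for end-to-end recovery, 100 plates for round-trips, 50
  for partition checks, 100 draws for 4PL identifiability.

## Known limitations

* The cut time derives from a single pooled control curve; plates whose
  controls drift spatially violate the pooling assumption undetected.
* The exponential-phase detector needs the deceleration to be inside the
  observed window; cultures that never slow down fall back to the data end
  (with a warning), which can place the cut time in late, less informative
  growth.
* No confidence intervals on EC50s (no profile likelihood or bootstrap);
  the `rss` and convergence flags are the only fit diagnostics exported.
* LL.4 is the only response family; partial inhibitors with pronounced
  asymmetry would be better served by five-parameter or Weibull models.
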