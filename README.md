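# actiphen

Rest–activity rhythm phenotyping from minute-level wrist actigraphy.

## What problem this solves

Minute-level actigraphy (e.g., the per-minute MIMS activity values
`PAXMTSM` in the NHANES Physical Activity Monitor files) records a week of
wrist movement per subject. Researchers studying how chronotype and
activity change with age need a way to reduce those ~10,000 noisy minutes
per subject to a handful of interpretable, comparable markers — and to do
it reproducibly at cohort scale. actiphen implements that reduction as a
tested pipeline for biostatisticians and sleep/circadian researchers:

1. **Screen** each subject for a robust 24-h rhythm: sample
   autocorrelation of the hourly activity series to lag 168 h, smoothed,
   peak spacings tested against 24 h with
   `chi2 = sum((interval - 24)^2 / 24)` and accepted when the upper-tail
   p-value *exceeds* a threshold (default 0.01) and the mean spacing is
   within 2 h of 24.
2. **Compress** each accepted recording to an average day
   `Y_t = mean_d y_{t,d}` (per-minute mean over available days) and its
   hourly profile `y_pa`.
3. **Cluster** hourly profiles within each age group (19–30, 31–50, 51–70,
   71–80 by default) with k-means, choosing k from the curvature of the
   WCSS curve.
4. **Fit** each profile with a two-level piecewise-constant model

   ```
   PLA_t = alpha  for t in [b1, b2)   (wrapping midnight)
           beta   otherwise
   ```

   by exact exhaustive search; the boundaries of the lower-level segment
   are the sleep-onset (SOT) and wake-time (WT) proxies.
5. **Derive markers** from the 4th-order finite-difference derivative of
   the profile: winding-down period (time with negative derivative),
   winding-down activity, overall activity, and time to alertness (from
   the derivative's inactive-to-active zero crossing to its maximum).
6. **Compare groups** with weighted 1-Wasserstein distances between marker
   CDFs (clusters weighted by population) plus a permutation test, and
   regress time to alertness on wake time per group.

A seeded synthetic-cohort generator with known ground truth
(`generateCohort()`) makes every stage testable without access to NHANES.

## Worked example

```r
library(actiphen)

scenarios <- list(
  groupScenario("19-30", 30, c(19, 30), sotMeanH = 23.5),
  groupScenario("71-80", 30, c(71, 80), sotMeanH = 21.5,
                arrhythmicFraction = 0.2))
report <- runPipeline(pipelineConfig(scenarios = scenarios, masterSeed = 1,
                                     nPermutations = 2000))
print(report)
#> actiphen pipeline report: 60 read, 60 in age range, 52 accepted
#> accepted per group:
#>   19-30: 30  (k = 9)
#>   31-50: 0
#>   51-70: 0
#>   71-80: 22  (k = 5)
```

All 30 younger subjects pass the periodicity screen; 8 of the 30 older
subjects were generated arrhythmic (non-24-h template period) and are
rejected by the ACF screen, leaving 22. The per-cluster parameter table is
the machine-readable analogue of a published sleep-window table:

```r
head(report$clusterTable[, c("group", "cluster", "count", "sot_h", "wt_h",
                             "alpha", "beta", "tta_h")])
#>   group cluster count sot_h wt_h    alpha     beta    tta_h
#> 1 19-30       1     2     0    8 3.380170 14.87111 2.054316
#> 2 19-30       2     3    23    7 3.190872 14.77428 2.038183
#> 3 19-30       3     4    23    7 2.766215 14.63132 2.428937
#> 4 19-30       4     3     0    9 2.817876 14.60803 2.079514
#> 5 19-30       5     4     0    7 2.319356 14.29166 1.863472
#> 6 19-30       6     3    23    8 3.013063 14.76334 2.210395
```

Young clusters put sleep onset at 23:00–00:00 and wake at 07:00–09:00 with
a nocturnal level near 3 a.u. against a diurnal level near 15 a.u. The
groups differ significantly in sleep onset:

```r
subset(report$comparisons, marker == "sot_h",
       select = c(marker, group_a, group_b, w1, p_value))
#>   marker group_a group_b       w1    p_value
#> 4  sot_h   19-30   71-80 2.630303 0.00149925
```

a 1-Wasserstein distance of about 2.6 h between the SOT distributions
(the generative gap was 2 h), with permutation p ≈ 0.0015.

Individual stages are exported too — `screenSubject()`, `fitPiecewise()`,
`computeMarkers()`, `wassersteinPermutationTest()` — and
`inst/scripts/actiphen.R` wraps `simulate` / `screen` / `run` for shell
use.

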