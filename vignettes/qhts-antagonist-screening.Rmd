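---
title: "Models and methods behind qhtscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qhtscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtscreen)
```

qhtscreen implements the analysis chain of a quantitative high-throughput
antagonist screen: a cell-based luciferase reporter read out across a full
titration of every library compound, a fluorescent viability counter-screen
on the same wells, and the statistics that turn tens of thousands of raw
well reads into a ranked, cytotoxicity-triaged list of candidate
antagonists. This vignette explains each model, the tunable parameters and
their defaults, the numerical choices, and what the synthetic data used in
validation does and does not tell you about real screens.

## The assay model

A well's luminescence reports the activity of the target-driven reporter
in surviving cells. The vehicle (DMSO) wells define the 0% level, a
saturating dose of a reference antagonist defines −100%, and every well is
scaled between them:

$$\%\,\mathrm{activity} = \frac{V_{compound} - V_{DMSO}}{V_{DMSO} -
V_{pos}} \times 100.$$

Medians of the control wells anchor the scale, so a handful of stuck or
splashed control wells cannot shift a plate; means enter only through the
QC statistics (CV, S/B, Z′), which are defined on means and SDs. The
fluorescence channel is normalized identically against vehicle and
full-kill cytotoxicity-control wells to give % viability.

Normalization is affine-invariant: multiplying every raw signal on a
plate by a common factor changes nothing downstream, which is why the
generator's arbitrary instrument scale (vehicle mean 3540 units) is
irrelevant.

### Pattern correction

Plate stacks carry systematic spatial structure — edge effects, dispenser
gradients. The correction implemented here subtracts, at every well
position, the median normalized activity that DMSO-only plates (run at the
start and end of the stack) show at that position. It is the simplest
estimator consistent with those inputs, and deliberately replaceable: it
handles any stack-constant surface, is idempotent once the surface is
removed, and leaves positions it has no evidence about (the DMSO plates'
own control columns) untouched. It cannot correct drift that changes
within the stack, and it adds the DMSO plates' own noise (halved by the
median of two plates) to every corrected well — the vehicle-well noise
band widens accordingly, and the package estimates that band *after*
correction for exactly that reason.

## Hill fitting

Each compound/readout series is fitted with the four-parameter Hill
equation

$$a(c) = a_0 + (a_\infty - a_0)\,\frac{c^n}{k^n + c^n},$$

with efficacy defined as $a_\infty - a_0$ exactly. Numerical choices:

* **Optimizer.** Bounded Levenberg–Marquardt least squares, with $k$
  fitted as $\log_{10} k$ (potencies are log-distributed; the transform
  makes the problem far better conditioned).
* **Bounds.** $k \in [\min(c)/10,\ 10\max(c)]$ — one decade of
  extrapolation beyond the tested range, never more; $n \in [0.3, 8]$;
  asymptotes in $[-200, 200]$%. A fit never reports parameters outside
  these boxes (boundary values are pinned back after the
  $10^{\log_{10}k}$ round-trip, which can undershoot by one ulp).
* **Starts.** Three deterministic starting points built from the data
  ($a_0$ from the lowest-concentration response, $a_\infty$ from the
  highest, $k$ from the concentration nearest the half-range, $n \in
  \{1, 2\}$, plus a mid-range $k$); best final loss wins, ties broken
  toward the smaller $k$. No randomness anywhere in the fit.
* **Sparse series.** With fewer than 4 usable points $n$ is pinned at 1
  (3-parameter fit); with fewer than 2 no fit is attempted and the series
  is reported unconverged (inactive downstream). Failures never raise —
  `converged = FALSE` is a first-class result.
* **Outlier masking.** After the first fit, a single point whose residual
  exceeds 3 robust SDs (1.4826 × MAD) may be masked and the fit repeated
  once. One point, one repeat — enough to absorb an isolated dispense
  failure without giving the optimizer license to carve the data.

At the plate noise this design emulates (7% CV on raw signal, which the
signal-to-background ratio stretches to ≈10 percentage points of activity
noise), a 7-point series spaced 5.6-fold apart simply does not pin an
individual IC50 tightly: the median relative error is ≈24%, and weighted
least squares with the exact signal-variance model recovers less than two
points of that (this is a sampling limit, not an optimizer one). The
estimator is, however, unbiased on the log scale, so means over replicates
converge fast — 35 replicate positive-control titrations recover the true
IC50 to well within the plate-to-plate SD, which is exactly how the
reference compound is tracked in production screening.

## Curve classes, curve rank, outcomes

Classes follow the standard qHTS taxonomy: 1 = complete curve (both
asymptotes observed), 2 = incomplete (lower asymptote only), 3 = single
point of activity, 4 = inactive; 1 and 2 split into subclasses .1/.2 by
efficacy and fit quality; the sign carries the direction (negative =
inhibition). "Observed" is judged against the vehicle noise band (3 robust
SDs of vehicle % activity, ≈29–38% here depending on pattern-correction
noise): a point is active if it lies outside the band, an asymptote is
observed if the corresponding extreme response lies within a band-width of
the fitted plateau. Subclass thresholds (|efficacy| ≥ 80%, $r^2 \ge 0.9$)
are exposed as arguments; they are conventional values, since the class
definitions in the qHTS literature leave them to the implementation.

Curve rank compresses class and efficacy into a signed integer in
$[-9, 9]$ with 0 reserved for class 4. Each class owns a two-rank span
(1.1 → 8–9, 1.2 → 6–7, 2.1 → 4–5, 2.2 → 2–3, 3 → 1–2), the upper rank
taken at high |efficacy|. The exact production mapping used by screening
centers is not published; this one preserves the properties that matter —
the printed range, class ordering, within-class monotonicity in efficacy,
and ±9 attained only by class ±1.1 — and the table is a single documented
structure should a different convention be needed.

One deliberate deviation from naive plumbing: **class 3 efficacy**. A
single point of activity cannot support an extrapolated asymptote, so the
call-level efficacy of a class-3 curve is its extreme observed response,
not the fitted $a_\infty - a_0$. With the asymptote version, one-point
noise spikes regularly extrapolated past the −50% activity threshold and
were called active; with the observed-point version the synthetic screen's
precision rises from ≈0.88 to ≈0.94 with no loss of recall. The fitted
object itself still reports $a_\infty - a_0$, which downstream potency
arithmetic needs.

The activity outcome combines the antagonist readout with the viability
counter-screen: **active** requires curve rank < −1, efficacy < −50%, and
either no viability response or an antagonist potency at least 6-fold
separated from the viability potency (the rescue clause exists precisely
for compounds that are both antagonistic and eventually cytotoxic);
**inactive** is |rank| < 1; everything else is **inconclusive**. The
6-fold comparison uses fitted IC50s; a missing viability fit counts as
viability-inactive. Confirmation selection applies efficacy < −50%,
IC50 < 10 µM and the same no-toxicity clause; follow-up selection
tightens efficacy to < −75% and drops the fold-rescue ("no toxicity"
taken literally).

A known, quantified leak: cytotoxic compounds whose viability curve is
incomplete (kill threshold near the top tested concentration) get an
unstable viability IC50, and in a few percent of cases the fitted ratio
clears 6-fold by chance, letting the compound through as active. On the
full synthetic screen this costs ≈5 points of precision. It is a property
of the rule at this noise level, not of the implementation; tightening it
would require replicate titrations or confidence intervals on the ratio,
both out of scope.

## Cluster enrichment

Compounds are clustered on a rectangular self-organizing map (online
Kohonen updates, Gaussian neighborhood shrinking from half the grid
diagonal to a single cell, learning rate decaying linearly 0.5 → 0.01
over 20 epochs, all randomness under one seed). Any numeric fingerprint
works; precomputed cluster labels can bypass the SOM entirely, since the
statistics downstream are the actual contribution.

Each cluster is tested with a one-sided Fisher's exact test on the 2×2
table (in-cluster vs rest × active vs not). P-values match direct
hypergeometric tail summation to 10⁻¹²; no multiplicity correction is
applied by default (clusters are reported at raw p < 0.05, with
`p_adjust` exposed). One caveat inherent to exact tests: with small
clusters or few actives the test is conservative — the attainable size at
α = 0.05 can be well under 5% — so calibration claims are only meaningful
in regimes dense enough for the discrete null to approach uniformity (the
test suite's calibration case was sized from exact hypergeometric
calculations: 20 clusters of 200 in a library of 4,000 with 20% actives,
attainable size 4.5%).

## Follow-up statistics

**IC50 shift.** A competitive-like antagonist co-treated with increasing
agonist doses shifts right. Each co-treatment condition is fitted
independently; the shift is the max/min ratio of fitted IC50s across
conditions (invariant to condition labeling), and the compound is flagged
target-dependent when the shift strictly exceeds 2-fold. Any unconverged
condition makes the whole result indeterminate — a silent pass on a
failed fit would be worse than no answer. The module accepts arbitrary
condition sets rather than a fixed agonist ladder.

**ΔΔCt.** `Fold = 2^−ΔΔCt` with ΔCt = Ct(target) − Ct(housekeeping) per
replicate and ΔΔCt referenced to the mean control ΔCt. Folds are computed
per replicate and then summarized — matching mean-of-triplicates ± SD
reporting — rather than propagating errors through mean Ct. The fold is
invariant under any plate-wide Ct shift. No amplification-efficiency
correction is applied (pure 2^−ΔΔCt).

**Dunnett.** Many-to-one comparisons use the exact multivariate-t
distribution of the max-|t| statistic with the correlation structure
$\rho_{ij} = \sqrt{n_i n_j/((n_i+n_0)(n_j+n_0))}$ implied by the shared
control (0.5 when balanced), evaluated by `mvtnorm` quadrature under a
locally pinned RNG so repeated calls agree to the 10⁻⁷ integration
tolerance. With one comparison the adjusted p reduces to the pooled
two-sample t p-value, and the implied critical values reproduce the
published two-sided Dunnett table (e.g. 2.88 for three comparisons at 8
df, α = 0.05). Stars follow the usual thresholds (0.05, 0.01, 0.001). A
zero within-group variance (detected relative to machine precision, since
ANOVA sums of squares of constant data return ~10⁻³² rather than 0) is
refused rather than returning p = 0.

## The synthetic screen generator

The generator exists so every stage above can be validated against known
truth. Its defaults are the study conditions the package is calibrated
around:

| parameter | default | meaning |
|---|---|---|
| `n_compounds` | 5,099 | library size |
| `n_concentrations` | 7 | titration points per compound |
| `conc_top`, `conc_bottom` | 46 µM, 1.5 nM | geometric series endpoints |
| `plate_format` | 1536 | 32 × 48 wells, 4 control columns |
| `dmso_cv` | 0.0704 | vehicle-well CV (multiplicative noise) |
| `signal_to_background` | 3.54 | vehicle / positive-control mean signal |
| `pos_control_cv` | derived (0.1132) | solves the Z′ = 0.572 identity |
| `fraction_true_antagonists` | 0.018 | ≈92 planted actives |
| `fraction_cytotoxic` | 0.02 | planted cytotoxic compounds |
| `spatial_artifact_amplitude` | 0 | plate-surface artifact (opt-in) |

The dilution series is spaced exactly geometrically between the printed
endpoints: real dilution protocols quote endpoints, and no round step
ratio reproduces both, so the endpoints win. The positive-control CV is
not independent — given the vehicle statistics and a target Z′, the Z′
identity determines it (`(1−Z′)(S/B−1)/3 − cv_v·S/B` relative to a unit
positive-control mean) — deriving it keeps all three QC statistics
jointly satisfiable instead of over-constrained. Noise is multiplicative
Gaussian per channel because well CVs are quoted as percentages of
signal. Planted antagonists draw IC50 log-uniformly from 0.05–5 µM
(comfortably inside the titration window), efficacy from −100 to −70%,
Hill slope 0.9–2.1; cytotoxic compounds kill with IC50 0.5–20 µM, and
their luminescence is coupled to survival (dead cells produce no reporter
signal), which is what makes the 6-fold triage rule exercisable at all.
Cluster labels come from a mixture in which three designated clusters
receive 70% of antagonists, so enrichment has a planted signal to find.

What the generator does **not** emulate: liquid-handling mechanics,
within-stack drift, plate-to-plate batch effects beyond independent
noise, correlated well failures, bell-shaped (non-monotone) responses,
and compound classes that are simultaneously antagonist and cytotoxic.
Passing tests therefore demonstrate the statistical machinery is correct
and well-calibrated under the stated assay model — not that any given
real screen satisfies that model. The QC metrics are the instrument for
checking the latter.

Problem sizes used in validation were chosen to keep the suite quick on a
laptop while leaving no estimator undersampled: the end-to-end case runs
the full 5,099-compound library (about 15 s, thanks to a fast path that
skips optimization for series with no point outside the noise band —
their class is already determined), parameter-recovery properties use
200–300 simulated curves, and the calibration case uses 400 permuted
cluster tests.
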