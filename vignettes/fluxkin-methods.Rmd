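---
title: "Models and methods behind fluxkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluxkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The measurement and the model

A kinetic flow-cytometry run records single cells continuously while
the sample sits on the cytometer: each event carries its acquisition
time, its surface-marker intensities, and the fluorescence of the
calcium indicator Fluo-4. The experiment emulated throughout this
package is a 17-minute (1020 s) acquisition with a 2-minute
unstimulated baseline and BCR crosslinking at *t* = 120 s.

Cells are not tracked individually — at every instant the cytometer
sees a fresh random draw from the population — so the analysable object
is the *population median* of Fluo-4 as a function of time, computed in
fixed-width time bins per gated subset. Medians rather than means
because cytometry intensities are heavily right-skewed, and because
under the package's multiplicative log-normal noise model the median of
the observed intensity equals the noiseless signal exactly, making the
binned series an unbiased (in location) estimate of the true kinetic.

The kinetic itself is modelled as a **double logistic**,

$$f(t) = S + \frac{A_1}{1+e^{-r_1(t-\tau_1)}} -
              \frac{A_2}{1+e^{-r_2(t-\tau_2)}},$$

the simplest smooth family with the qualitative shape of a BCR
activation response: flat at the resting level $S$ before stimulation,
a rise of amplitude $A_1$ (store release plus CRAC-channel influx), a
partial decline of amplitude $A_2 \le A_1$, and a plateau at
$S + A_1 - A_2$. Its limits at $\mp\infty$ are $S$ and $S+A_1-A_2$; for
the parameter regimes used here (rise faster than decay, decay midpoint
well after stimulation) it rises to a single maximum and then
decreases. That shape contract is asserted by dense-grid sign checks in
the test suite — note it is a property of the realistic parameter
region, not of the family as a whole: if the slow decay term's leading
tail is already active at stimulation while the rise is not, the curve
can dip slightly before rising, which is why the shape test pins the
generator's stated parameter sets rather than arbitrary coefficients.

## The ten derived parameters

Every fitted curve is standardised by its limit at $-\infty$ (division
by $S$), so curves from different subsets, samples and days start at 1
and are comparable. On the standardised curve over $[0, t_{end}]$
(default $t_{end} = 1020$ s, configurable to the actual measurement
length) the package derives:

| parameter | definition | units |
|---|---|---|
| starting value | limit at $-\infty$, $\equiv 1$ | relative |
| maximum value | max on $[0,t_{end}]$ (1-s grid + golden-section refinement) | relative |
| time to maximum | its argmax | s |
| time to first 50% | ascending crossing of $(1+\max)/2$, by root-finding | s |
| slope at first 50% | analytic $f'/S$ there, always $>0$ | 1/s |
| time from first 50% to max | difference of the above | s |
| time from max to second 50% | descending crossing of $(\max+\mathrm{end})/2$ | s |
| slope at second 50% | analytic $f'/S$ there, always $<0$ | 1/s |
| ending value | limit at $+\infty$ | relative |
| AUC | $\int_0^{t_{end}} f/S\,dt$, closed form | relative·s |

plus the **raw baseline MFI** (median Fluo-4 of pre-stimulation events,
unstandardised) as the basal-calcium readout.

Two conventions deserve a note. The "50% levels" are midpoints —
between start and maximum on the way up, between maximum and ending
value on the way down — the only reading consistent with reporting
both a "time from first 50% to maximum" and a "time from maximum to
second 50%". And the AUC uses the closed-form softplus primitive of the
logistic, $\int \mathrm{plogis}(r(t-\tau))dt = \log(1+e^{r(t-\tau)})/r$;
adaptive quadrature serves as the independent oracle in the tests, not
as the implementation.

Degenerate geometry is flagged rather than fudged: when the maximum
sits at the domain boundary with the curve still rising (pure-rise
fits, $A_2 \approx 0$), the descending-phase parameters are reported as
`NA` with `descending = FALSE`; a flat fit reports max = end = 1 and
AUC $= t_{end}$.

## Fitting

`fit_double_logistic()` minimises the residual sum of squares of the
seven-coefficient model over the (bin centre, median) pairs with
bounded L-BFGS-B. Everything is deterministic: data-driven
initialisation ($S_0$ from pre-stimulation bins, ending level from the
last 60 s, amplitudes from the observed extremes, midpoints from first
half-level crossings, both rates at 0.05/s), a fixed list of five
perturbed restarts, and per-coefficient `parscale` so that rates
(~0.01/s) and midpoints (~100 s) move on comparable scales — without
this the optimizer stalls far from the optimum. L-BFGS-B occasionally
terminates a line search abnormally at an excellent solution; the
fitter restarts once from that point and accepts it only if the restart
confirms a stationary value. Anything else is an explicit
"unusable fit" error, which the pipeline records as an exclusion
(mirroring the exclusion rule for curves that cannot be fitted from too
few events) — samples are listed, never silently dropped.

Numerical tolerances: `optim` runs at `factr = 1e2`; on noiseless
series the seven coefficients are recovered to better than $10^{-3}$
relative (acceptance-tested at 100 random parameter sets), and crossing
times agree with a 0.01-s brute-force scan to within 0.05 s.

# Gating

Positivity thresholds come from FMO controls: the threshold is the
0.995 quantile of the control distribution — 0.5% of the control
counted positive is a conventional cut where no percentile is dictated,
and it is exposed as `fmo_quantile`. Events exactly at a
threshold count negative — a deterministic tie-break. CD19⁻ events are
non-B; CD19⁺ events map by the IgD/CD27 sign pattern to naive (+,−),
non-switched (+,+), switched (−,+) and double-negative (−,−) memory,
each with a CD25 status. The Fluo-4 loading gate doubles as viability:
only live cells with intact membranes retain the de-esterified dye. In
the synthetic world there are no scatter channels, so the lymphocyte
gate is the all-events gate; with real FCS scatter channels an optional
rectangular gate can be configured. CD5 is part of the staining panel
and carried through I/O, but no reported subset uses it, so gating
ignores it deliberately.

# The synthetic world

`generate_event_stream()` draws acquisition times uniformly over the
window, assigns each event to a mixture component (four B subsets ×
CD25±, plus non-responding non-B cells), and samples marker intensities
log-normally per component. Defaults, chosen once:

* B cells are 20% of events; naive/NSw/Sw/DN are 60/20/12/8% of B
  cells, 12% CD25⁺ each — ballpark figures for adult peripheral blood.
* negative and positive marker populations sit at log 10 and log 1000
  with SD 0.35 (~13 SDs apart), so gating recovery against ground truth
  is essentially limited only by the 0.5% FMO tail.
* the shared base kinetic: $S = 100$, $A_1 = 1.2S$, $r_1 = 0.05$/s,
  $\tau_1 = 210$ s (90 s after stimulation), $A_2 = 0.55 A_1$,
  $r_2 = 0.015$/s, $\tau_2 = 420$ s; CD25⁺ compartments respond 1.4×
  more strongly (they are the functionally hyper-responsive
  compartment), non-B cells are flat.
* within-sample Fluo-4 noise is multiplicative log-normal with
  $\sigma = 0.06$. This value is a calibration the generator's contract
  prescribes: with 50,000 events in 5-s bins, every binned median must
  sit within 2% of the true curve (bin-median standard error is
  $1.2533\,\sigma/\sqrt{n_{bin}}$), which bounds $\sigma$ at about
  0.07. Real per-cell dye variation is larger; here it would only
  dilute the median's precision, while the biologically meaningful
  variation is carried between samples (next point).
* between-sample biological variability: log-normal multipliers on the
  resting level (SD 0.10) and the amplitudes (SD 0.15). Group effects
  (e.g. an amplitude multiplier of 1.3 for a hyper-reactive arm)
  multiply on top.
* 2% of cells per sample fail indicator loading, placing default
  cohorts above — but near — the 95% loading-viability gate.
* pre-stimulation Fluo-4 is flat at $S$ by construction; the default
  rise midpoint sits 90 s post-stimulation with $r_1 = 0.05$/s so the
  model-implied value at 120 s differs from $S$ by under 2% of the rise
  amplitude, keeping the flat-baseline convention and the
  double-logistic description mutually consistent.

What the generator does **not** emulate: instrument drift within a run,
scatter channels and debris/doublets, spectral spillover (unless
explicitly mixed in), autofluorescence, or cell-intrinsic
heterogeneity of kinetic timing within a subset. A green end-to-end
test therefore establishes that the pipeline recovers known mixture
proportions, kinetics and group effects under clean but realistic
noise — not that it is robust to every artefact of real acquisitions.

Determinism is a contract: every per-sample stream is seeded by a
documented splitting scheme from the design's master seed
(`97·master + 7919·index mod 2³¹−1`), identical designs regenerate
byte-identical files, and an identical config yields a byte-identical
results bundle.

# Cohort statistics

**Grubbs screening.** Outliers are removed only when extreme: iterative
two-sided Grubbs at α = 0.01 (the convention adopted for "extreme"
since no number is stated), capped at ⌊n/5⌋ removals so small samples
cannot be hollowed out. The pipeline applies it per
group × subset × parameter — the finest stratum in which values are
exchangeable.

**Two-way comparisons.** The group × subset cell-means model with
pooled within-cell variance feeds Tukey-adjusted pairwise contrasts at
the three levels reported in cohort figures: between groups ignoring
subsets (unweighted marginal means — a Type-III-style treatment of
unbalance), between groups within a subset, and between subsets within
a group. Studentised-range p-values use `ptukey` with the number of
marginal means at that level; with balanced data and one subset the
machinery reduces exactly to one-way `TukeyHSD`, which the tests verify
as an independent oracle. Contrasts touching cells with fewer than two
observations are reported but flagged not-estimable.

**Paired pre/post comparisons.** A linear mixed model per subset —
random subject intercept, fixed visit effect, REML via `nlme` — uses
every subject, including those missing one visit; Sidak adjustment
($p_{adj} = 1-(1-p)^m$) spans the subsets analysed. The degrees of
freedom are `nlme`'s within-subject (containment) df rather than a
Satterthwaite approximation, which is not available in the supported
dependency set; for the paired designs at hand (one within-subject
factor, modest missingness) the two agree closely, and the simulation
tests show detection rates within a few points of the complete-pairs
paired-*t* oracle. If the model degenerates (e.g. post ≡ pre), the
comparison falls back to the exact answer (estimate 0, p = 1) or a
paired *t* on complete pairs.

**Sample size.** `required_sample_size()` iterates the exact
noncentral-*t* power of a two-sided two-sample test (α = 0.05, power
0.80 by convention — both exposed as arguments since neither is stated
for the original power analysis) and returns the smallest per-group n;
a pilot effect of d = 1.2 gives the n = 12 replicate count used
throughout the default designs.

**Null calibration.** Tukey controls the family-wise error within one
parameter's family of contrasts. The end-to-end null check is therefore
made on a single parameter family (AUC): across ten parameter families
the probability of *some* significant contrast under the null exceeds
any per-family α by construction, and no adjustment across parameters
is part of the emulated analysis.

# Pipeline conventions

Bins are 5 s wide with at least 5 events (defaults; the binning is not
dictated by the emulated analysis, so these are chosen to resolve ~200
points over the window while keeping medians stable), bins failing the
minimum are dropped, and a sample × subset needing a curve but lacking
8 usable bins spanning both sides of stimulation is excluded with a
recorded reason. Exclusion accounting is an invariant: analysed plus
excluded equals the number of input samples, per subset. All stage
outputs are plain CSV plus a JSON run manifest (package version, seed,
configuration echo — no timestamps, preserving byte-identical re-runs).

# Known limitations

* The double-logistic family cannot represent oscillatory or biphasic
  responses; such data end in lack-of-fit, not in a warning.
* Slopes are analytic derivatives of the fitted curve; if the model is
  misspecified the slopes inherit the misspecification (finite
  differences on raw medians would instead inherit the noise).
* The FCS reader covers list-mode float data (the overwhelmingly common
  export format) — not integer bit-packed or analysis segments.
* Compensation matrices are inputs; estimating them from bead controls
  is out of scope.
* Group comparisons assume homoscedastic cells (pooled MSE), as does
  the emulated ordinary two-way ANOVA.
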