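---
title: "Agreement analysis for continuous paired temperature monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement analysis for continuous paired temperature monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempagree)
```

## The problem

Intraoperative core temperature in small children is monitored continuously;
the standard of care is a rectal probe, but non-invasive skin-surface
devices (dual-heat-flux forehead sensors) are attractive whenever invasive
probes are infeasible. Evaluating such a device is a method-comparison
problem with repeated measurements: each patient contributes a stream of
paired readings on a 2-min grid, readings within a patient are strongly
correlated, and the clinical consequence of a measurement error depends on
where on the temperature scale it occurs. `tempagree` implements the full
analysis: stream cleaning, repeated-measures limits of agreement, a
clinical error grid, and precision-based design.

## Cleaning model

Two rules, applied per (patient, sensor) stream, both motivated by the
physics of the devices:

* the first `discard_first_n = 2` readings are dropped — the skin sensor
  needs a few minutes to build its isothermal equilibrium;
* scanning the remainder in time order, the first reading below
  `floor_c = 30` °C, or differing by more than `jump_threshold_c = 1` °C
  from the immediately preceding retained reading, is taken as probe
  dislocation, and it and everything after it is discarded.

Both comparisons are strict: a change of exactly 1 °C and a reading of
exactly 30 °C survive. Censoring (rather than interior deletion) is
deliberate — once a probe has dislodged there is no evidence it ever
reseated, so the output of `clean_series()` is always a prefix of the
post-equilibration stream, which also makes the rule idempotent. The rules
are applied per sensor: a dislodged rectal probe truncates only the rectal
stream, and pairing then naturally truncates the analysis set. The floor
rule is applied to both sensors symmetrically; whether a sub-30 °C reading
can physically occur rectally is debatable, but applying it symmetrically
is harmless (it fires only on artifact) and keeps the rule set simple.
Streams are paired by exact equality of the 2-min grid time by default
(`pairing_tolerance_min = 0`); a positive tolerance switches to
nearest-in-time matching for asynchronously recorded sources.

## Agreement model

For patient $i = 1,\dots,n$ with $m_i$ paired differences
$d_{ij} = T^{\mathrm{DHF}}_{ij} - T^{\mathrm{Rec}}_{ij}$
($N = \sum_i m_i$), we assume the one-way random-effects structure
$d_{ij} = \mu + b_i + e_{ij}$ with
$b_i \sim (0, \sigma_b^2)$, $e_{ij} \sim (0, \sigma_w^2)$. The SD of a
single difference is $\sigma_d = \sqrt{\sigma_b^2 + \sigma_w^2}$ and the
95% limits of agreement are $\bar d \pm z\,\sigma_d$ with $z = 1.959964$.

Estimation is by the unbalanced one-way ANOVA (method of moments):
$MSW = \sum_{ij}(d_{ij}-\bar d_i)^2/(N-n)$,
$MSB = \sum_i m_i(\bar d_i - \bar d_w)^2/(n-1)$ with $\bar d_w$ the
observation-weighted grand mean, $m_0 = (N - \sum_i m_i^2/N)/(n-1)$,
$\hat\sigma_w^2 = MSW$ and $\hat\sigma_b^2 = \max(0, (MSB - MSW)/m_0)$.
A negative moment estimate is truncated to zero so $\sigma_d$ stays real;
the fit flags this (`$truncated`). The reported bias is the unweighted mean
of the per-patient means, so a patient monitored for six hours counts the
same as one monitored for thirty minutes; the observation-weighted
alternative is available (`bias_weighting = "observation"`) since either
convention is defensible. With $m_i \equiv 1$ the whole machinery collapses
exactly to the classic Bland–Altman analysis (mean ± z·SD of the $n$
differences), which the test suite checks to machine precision.

Confidence intervals for the limits use the MOVER construction: the
t-margin for $\bar d$ (on $n-1$ df, with
$\widehat{\mathrm{Var}}(\bar d) = \hat\sigma_b^2/n +
\hat\sigma_w^2/(n\,m_h)$, $m_h$ the harmonic mean of the $m_i$) is combined
with chi-square margins for $z\hat\sigma_d$ by the
square-root-of-summed-squared-margins rule. The variance margins are built
on the two independent ANOVA pieces $B = MSB/m_0$ (df $n-1$) and
$W = (1 - 1/m_0)\,MSW$ (df $N-n$), whose sum is $\hat\sigma_d^2$. Each
limit also gets a delta-method standard error,
$\mathrm{SE}^2 = \mathrm{Var}(\bar d) + z^2\,\mathrm{Var}(\hat\sigma_d)$
with $\mathrm{Var}(\hat\sigma_d) \approx
\mathrm{Var}(\hat\sigma_d^2)/(4\hat\sigma_d^2)$. Simulation at the study's
dimensions (51 patients, 26 pairs each, 500 replicates in the acceptance
suite) shows the intervals covering the true limits at the nominal 95%
within binomial tolerance, and the delta-method SE matching the Monte-Carlo
spread of the estimated limits within a few percent.

$z$ is fixed at the normal quantile 1.959964 rather than a t-quantile: the
"95% limits of agreement" are a population prediction band by convention,
while the *interval* pieces do use t and chi-square reference
distributions.

### Proportional bias

`trend_test()` regresses $d_{ij}$ on the pair mean. With ~30 correlated
pairs per patient, naive OLS standard errors would be several-fold
anti-conservative, so the default uses cluster-robust (HC1) variance by
patient with a t reference on $G-1$ degrees of freedom ($G$ = number of
patients); a random-intercept mixed model with Satterthwaite df is the
alternative. Under a generator configuration where the null holds exactly,
1000-replicate simulation in the acceptance suite puts the empirical size
at the nominal 5% within binomial tolerance.

Note one structural subtlety of difference-versus-mean regression: a
between-patient device offset enters both the difference and (halved) the
pair mean, so a nonzero $\sigma_b$ alone induces a positive population
slope even without proportional bias, and a true proportional bias $\beta$
appears in the regression attenuated to roughly $\beta/(1+\beta/2)$ plus a
noise-asymmetry term. The recovery tests therefore compare the estimate
against the closed-form population slope implied by the generator, not
naively against $\beta$.

## Error grid

The `(T_{Rec}, T_{DHF})` plane is divided by the treatment thresholds —
warming indicated strictly below 35.6 °C, cooling strictly above 37.9 °C,
nothing otherwise (an actively warmed population under a 26 °C ambient
standard) — and by the ±0.5 °C tolerance band:

* **A** — $|T_{DHF}-T_{Rec}| \le 0.5$ °C (inclusive): clinically
  irrelevant error;
* **B** — larger error, same decision either way;
* **C** — reference says no treatment, device triggers one (unnecessary
  treatment);
* **D** — reference indicates treatment, device misses it;
* **E** — the two imply opposite treatments.

Zone A takes precedence where the tolerance band straddles a treatment
threshold (e.g. reference 35.55 °C, device 35.95 °C): an error within the
device's clinically accepted tolerance is not counted as a wrong decision
even when it flips the nominal threshold. Only under a precedence rule do
the five zones partition the plane with A exactly the diagonal band; the
non-precedence variant is available (`a_precedence = FALSE`).
`grid_geometry()` constructs the zone polygons by clipping the 3×3
decision blocks against the band and carries each piece's defining
inequalities, so the geometry can be (and is, on a 0.01 °C lattice)
cross-checked point-for-point against the classifier.

## Precision-based design

For the single-pair design the SE of each limit is
$\sigma_d\sqrt{1/n + z^2/(2(n-1))}$. This exact form matters: with a
planning SD of 0.25 °C and a target SE of 0.05 °C it gives $n = 74$,
whereas the common $\sqrt{3\sigma^2/n}$ approximation gives 75.
`n_for_target_se()` searches integers exhaustively under an analytic upper
bound instead of inverting and rounding, eliminating off-by-one ambiguity;
its result always satisfies $SE(n^\ast) \le \mathrm{target} <
SE(n^\ast-1)$. `se_loa_repeated()` extends the formula to $m$ repeated
differences per patient using the planning variance
$\mathrm{Var}(\bar d) = (\sigma_b^2 + \sigma_w^2/m)/n$ and chi-square
variances of the ANOVA pieces (df $n-1$ and $n(m-1)$); at $m=1$ with the
whole variance between subjects it reduces algebraically to the single-pair
formula, and `n_for_target_se_repeated()` inverts it the same way. The
repeated-measures inversion is validated by simulation (the planning SE
matches the replicate spread of estimated limits), since it is the step a
study team would rerun once pilot variance components are in hand.

## Synthetic cohorts

`generate_cohort()` emulates the measurement process the cleaning and
agreement modules assume:

* latent core trajectory per patient: start $\sim N(36.7, 0.4^2)$ °C, a
  piecewise-linear drift (default −0.01 °C/min for 30 min, then plateau —
  mild redistribution cooling under active warming), plus AR(1)
  fluctuations (coefficient 0.8, innovation SD 0.1 °C on the 2-min grid).
  The autocorrelation matters: white-noise cores would trip the 1 °C jump
  rule spuriously;
* reference reading = core + $N(0, 0.10^2)$; device reading = core +
  0.413 + `bias1`·(core − 36.7) + patient offset ($SD$ 0.5 °C) +
  $N(0, 0.15^2)$. The proportional bias is anchored at 36.7 °C so the
  constant 0.413 °C stays interpretable as the bias at the cohort center;
* per-patient retained-pair counts from a discretized log-normal
  (meanlog $\log 26$, sdlog 0.65, clipped at 3), giving median ≈ 26,
  quartiles ≈ 16–39 and ≈ 1650 pairs for 51 patients; two extra leading
  readings feed the equilibration discard;
* optional dislocation artifacts (probability 0.05 per stream): a
  sustained jump whose realized first step is drawn above 1.2 °C — sized
  against the previous *observed* reading so noise can never mask it below
  the detection threshold — or a sub-30 °C tail. The truth record stores
  every latent quantity.

The cohort-shape defaults (51 patients, the pair-count distribution, the
0.413 °C bias) describe a realistic pediatric evaluation cohort; the
within-patient variability settings are plausible intraoperative values
chosen once, not estimates from any dataset. With
`bias1 = 0` and no artifacts, the implied difference components are exactly
$\sigma_b^2 = 0.5^2$ and $\sigma_w^2 = 0.15^2 + 0.10^2$, which the
end-to-end recovery tests target.

What the generator does *not* emulate: thermoregulatory physiology,
feedback between the measured temperature and warming management, sensor
drift or hysteresis, and non-stationary noise. Passing recovery tests on
synthetic cohorts therefore demonstrates the estimators' correctness under
the assumed variance structure, not device performance on real patients.

## Numerical and scale choices

* Problem sizes in the validation suite: 500 replicates for interval
  coverage at 51 × 26, 1000 replicates for the trend test's size, 100
  datasets for the classic-limit equivalence, a 0.01 °C lattice over
  [33, 40]² (491k points) for the error-grid partition — sizes at which
  the binomial/Monte-Carlo tolerances are decisive yet the whole suite
  runs in a few minutes.
* Quartiles everywhere use linear interpolation (R's default type 7).
* Degenerate inputs: zero-variance differences yield zero-width limits and
  a `degenerate` flag rather than an error; an all-singleton design warns
  and takes the classic path; an empty cleaned series is a valid empty
  result, not an error.
* Temperatures are serialized with at least 3 decimals so a round trip can
  never move a value across a cleaning threshold.

## Limitations

The MOVER interval df convention for the between component ($n-1$ via MSB)
follows the standard formulation; on heavily unbalanced designs the
effective df are approximate, which is visible only as mild conservatism in
simulation. The bias-weighting convention (equal patients vs equal
observations) changes the reported bias on unbalanced cohorts; both are
exposed. The error-grid thresholds encode one specific perioperative
management policy and should be reconfigured for other populations.
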