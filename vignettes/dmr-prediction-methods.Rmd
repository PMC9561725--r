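---
title: "Modelling early treatment kinetics to predict deep molecular response in CML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early treatment kinetics to predict deep molecular response in CML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmlkinetics)
```

## The clinical problem

Chronic myeloid leukemia (CML) is driven by the BCR-ABL1 fusion kinase.
Tyrosine kinase inhibitors (TKIs) such as nilotinib clear the leukemic
clone in most chronic-phase patients, and the practical treatment goal
is *deep molecular response* (DMR): a BCR-ABL1/ABL1 transcript ratio on
the international scale (IS) of at most 0.01% (MR4.0) or 0.0032%
(MR4.5). Patients who will not reach DMR on their current TKI benefit
from an early switch, so the question this package addresses is: **can
DMR achievement within two years be predicted from only the first three
clinic visits (months 0, 3, 6)?**

Baseline prognostic scores (EUTOS, ELTS) and milestone IS staging
(Optimal/Warning/Failure at months 3, 6, 12) were designed for other
endpoints; the package implements them as comparators.

## The kinetic model

Each patient's white blood cells are split into a normal compartment
`x(t)` and a leukemic compartment `y(t)` (cells/µl). Under effective
therapy each relaxes exponentially toward a patient-specific plateau:

$$\frac{dx}{dt} = a\,(x^* - x), \qquad \frac{dy}{dt} = b\,(y^* - y),$$

with recovery rate $a$ and plateau $x^*$ for normal cells, and reduction
rate $b$ and plateau $y^*$ for leukemic cells. Being linear and scalar,
these have the exact solutions
$x(t) = x^* + (x_0 - x^*)e^{-at}$ and
$y(t) = y^* + (y_0 - y^*)e^{-bt}$; the package never runs a numerical
integrator in the pipeline (one is used only as an independent oracle in
the tests).

The two measured quantities are the total count and the transcript
ratio:

$$\mathrm{WBC}(t) = x(t) + y(t), \qquad
  \mathrm{IS}(t) = \max\!\left(\frac{y(t)}{c\,x(t) + y(t)} \cdot k_{IS}
  \cdot 100,\; 0.0032\right).$$

Here $c$ is the ratio of per-cell ABL1 expression in normal versus
leukemic cells — shared by the whole cohort and estimated from data —
and $k_{IS} = 1.2$ is the laboratory conversion factor onto the
international scale. The 0.0032% floor is the assay detection limit;
measurements below it are reported *at* it (censoring), and the model
prediction carries the same clamp so that a censored measurement facing
a sub-limit prediction contributes zero residual.

The pair `(y*, b)` — how low the leukemic compartment is heading and how
fast it gets there — is the classifier's feature plane. `(x*, a)` carry
no response information and are nuisance parameters.

### Key constants

| constant | default | meaning |
|---|---|---|
| `k_is` | 1.2 | IS laboratory conversion factor |
| `detection_limit` | 0.0032 % | IS reporting floor |
| `x_star_min`, `x_star_max` | 3100, 9800 cells/µl | healthy WBC plateau band |
| `penalty_weight` | 100 | weight of the soft constraint penalty |
| `dt` | 3 months | nominal visit spacing |

## Descriptive IS features

Before any mechanistic fitting, each patient's log10-IS series is
summarized by a two-segment curve: linear decline from the measured
baseline to a convergence level reached at a breakpoint $\tau$, constant
afterwards. The slope is the *IS decreasing rate* and the level the *IS
convergence value*; responders decline faster and converge lower. The
intercept is anchored at the measured month-0 value, leaving two free
parameters. For fixed $\tau$ the level is a linear least-squares
problem, so `fit_piecewise()` profiles it in closed form and searches
$\tau$ on a 400-point grid over $(0, 24]$ months with local refinement —
this provably dominates any coarser two-dimensional grid. Flat series
leave $\tau$ unidentified; ties break toward the smallest value. This
fit is descriptive only; the classifier does not use it.

## Cohort fitting

All patients are fitted jointly by minimizing squared natural-log
residuals of both IS and WBC over the full grid, plus a ramp penalty
$W \sum R(\cdot)$, $R(u) = \max(u, 0)$, $W = 100$, keeping $x^*$ in the
healthy band, $y^*$ above the detectability bound
$y^*_{min}(c, x^*) = d\,c\,x^*/(100 k_{IS} - d)$ (the plateau at which
the modelled IS sits exactly on the floor), and rates positive. The
penalty is a fixed-weight soft constraint, not an adaptively updated
multiplier.

Numerical choices, made once:

* **Parameterization.** All six per-patient parameters are optimized on
  the log scale, which enforces positivity, equalizes scales that span
  five orders of magnitude, and makes the rate-positivity ramps vacuous.
* **Inner solver.** The objective is an exact sum of squares (each ramp
  term enters as a squared square root), so per-patient blocks use
  Levenberg-Marquardt (`minpack.lm::nls.lm`).
* **Shared ratio.** $c$ is the only coupling between patients, so it is
  profiled out: the profile is evaluated on a 9-point grid over
  $\log c \in [\log 0.3, \log 6]$ swept in increasing order, then
  refined by Brent search inside the bracketing interval. Every profile
  evaluation refits all patients from two starts — the warm solution
  carried along the sweep and a fresh data-driven start at that $c$
  (first three inverted leukemic counts give closed-form rate/plateau
  guesses). Both pieces matter: the fresh start stops individual
  patients from intermittently landing in local minima (which makes the
  profile ragged), and the deterministic grid stops the refinement from
  trusting unimodality far from the optimum, where censored responder
  tails genuinely distort the profile.
* **Initial values.** Counts at the first visit are split into
  $(x_0, y_0)$ by inverting the measurement model; $x^*$ starts at the
  last visit's inverted normal count clipped to the band; $y^*$ at the
  last inverted leukemic count or just above the detectability bound.
* **Identifiability.** For patients whose true plateau lies below the
  detection floor, $y^*$ is not identifiable from censored tails — the
  penalty pins it near $y^*_{min}$, which is exactly what the classifier
  needs (a "very low plateau" signal). $c$ itself is only weakly
  identified at 10% noise (estimates of 1.5–1.9 against a generating
  1.5 are typical); the decision thresholds adapt to whatever scale the
  training-cohort $c$ implies, so classification is robust to this.
* **Determinism.** The only stochastic element is the jittered
  multistart in the final polish; it derives from the `seed` argument.

## Three-visit estimator

For a new patient only months 0, 3, 6 are available. Inverting each
(IS, WBC) pair with the training $c$ gives three leukemic counts
$\hat y(0), \hat y(\Delta t), \hat y(2\Delta t)$, and the geometric
structure of the exponential approach yields closed forms:

$$\hat y^* = \frac{\hat y(0)\hat y(2\Delta t) - \hat y(\Delta t)^2}
  {\hat y(0) - 2\hat y(\Delta t) + \hat y(2\Delta t)}, \qquad
  \hat b = \frac{1}{\Delta t}\ln
  \frac{\hat y(0) - \hat y(\Delta t)}{\hat y(\Delta t) - \hat y(2\Delta t)}.$$

These are exact on noiseless model data. Edge cases, decided once:

* A patient whose IS already meets the response criterion within the
  three visits is a responder by definition (`early_dmr`); the closed
  forms are skipped. For the CMR criterion, whose definition requires
  the floor at two *consecutive* visits, the early rule is read as two
  consecutive floor visits among the first three.
* Zero curvature, non-decreasing or non-contracting triples make the
  closed forms uncomputable; the estimate is returned `valid = FALSE`
  with a reason code and the classifier predicts non-response — the
  clinically conservative call, since rising counts are exactly the
  patients one should not leave on a failing drug.
* Negative $\hat y^*$ (super-exponential noisy declines) is floored at
  0; the region test is unaffected in ordering.
* In double precision the plateau can only be recovered to roughly
  $\varepsilon \cdot y_0/y^*$ relative error; for responder plateaus
  seven orders of magnitude below the initial load this is about 1e-8,
  a conditioning fact, not an algorithmic one.

## Threshold classifier and cross-validation

A patient is predicted to reach DMR when
$\hat y^* \le Y$ **and** $\hat b \ge B$, both inclusive. The thresholds
are trained by exhaustive grid search; the rate axis uses step 0.05
(1/month) from 0 to just past the largest training rate. For the
plateau axis, a fixed linear step of 0.1 cells/µl would be meaningless
over values spanning 1e-1 to 1e5, so $Y$ is scanned on the log10 scale
with step 0.1, half a decade beyond the training estimates on each
side. This scale choice for the printed step sizes is a documented
interpretation.

Ties among maximizers of the training objective are resolved as
follows: accuracy takes the pair closest (Euclidean in the
$(\log_{10} Y, B)$ plane) to the mean of all maximizers, residual ties
going to smaller $Y$ then larger $B$; sensitivity restricts to maximal
specificity and then takes the widest surviving region (largest $Y$,
smallest $B$); specificity restricts to maximal sensitivity and takes
the tightest (smallest $Y$, largest $B$). Early responders are fixed
positives and invalid estimates fixed negatives at every grid cell.

Leave-one-out cross-validation holds out each patient in turn: the
remaining patients are refitted (giving $c$ and their full-series
$(y^*, b)$ estimates, which train the thresholds), and the held-out
patient is predicted from its first three visits only. Aggregate
accuracy is, by construction, the mean of per-patient correctness
scores; sensitivity, specificity and F1 are pooled over the folds.

## Comparator scores

EUTOS ($4 \times$ spleen cm $+ 7 \times$ basophil %; High above 87),
ELTS ($0.0025 (\mathrm{age}/10)^3 + 0.0615\,\mathrm{spleen} +
0.1052\,\mathrm{blasts} + 0.4104 (\mathrm{platelets}/1000)^{-0.5}$;
High above 2.2185, Low at or below 1.5680) and milestone staging
(Optimal/Warning/Failure with IS cutoffs 10%/—, 10%/1% and 1%/0.1% at
months 3, 6, 12) are mapped to response predictions by
Low/Optimal → positive. Two conventions deserve note: an IS exactly at
a staging cutoff takes the better stage (the worse stages are defined
by strict inequalities); and the ELTS Low boundary is taken inclusive
($\le 1.5680$) — source descriptions disagree between "<" and "or
lower", and only scores exactly on the boundary are affected. The
later confirmed-failure refinement of 3-month staging is intentionally
not implemented: on a 3-monthly grid no confirmatory measurement before
month 6 exists, so it cannot change any result.

## The synthetic cohort generator

No patient-level clinical data ship with the package; every analysis
runs on synthetic cohorts that emulate the structure the method
assumes. The generator draws a responder flag (18:14 split by default),
then per-patient kinetics from class-specific ranges, simulates the
exact trajectories, forms WBC and IS through the measurement model,
applies independent multiplicative lognormal noise to WBC and to
pre-clamp IS, clamps IS at the floor, and optionally drops visits.

Default study conditions (chosen once; `default_paper_like_config()`):
32 patients on the 9-visit grid, shared $c = 1.5$, normal plateaus
spanning the healthy band [3100, 9800], recovery rates [0.2, 1.0]/month,
diagnosis-like initial loads ($x_0 \in$ [1000, 4000],
$y_0 \in$ [2e4, 1e5], leukemic dominating), and 10% lognormal noise.
Responders get $b \in$ [0.65, 2.0]/month and plateaus log-uniform in
[0.005, 0.06] cells/µl — the upper end chosen so the *worst-case* draw
(largest $y_0$, slowest $b$, smallest $x^*$) still crosses the IS floor
by month 24, making the class flag provably consistent with the
data-derived label. Non-responders get $b \in$ [0.05, 0.28]/month and
plateaus in [1, 80] cells/µl (IS plateaus roughly 0.01–1%). The classes
are separable in the $(y^*, b)$ plane by construction, as the observed
cohort was.

What the generator does **not** emulate: visit-date jitter (nominal
months only), relapse and resistance-driven IS rebound, dose changes,
drug switches, and the transient lymphocytosis peculiar to dasatinib.
Noise is lognormal because the fitting loss is squared error on log
scales — it is the conjugate choice, not a validated error model of
qPCR and cell counters. Passing tests therefore demonstrate internal
consistency and correct implementation of the method under its own
assumptions, not clinical performance on real cohorts.

## Problem sizes and budgets

The packaged analyses use the 32-patient default cohort; the full
cross-validation refits 31 patients 32 times and takes a few minutes on
one core. Unit tests run smaller cohorts (4–16 patients) so the whole
suite stays fast. Property tests use 200–1000 randomized draws under
fixed seeds.

## Known limitations

* Even with measurement noise removed, leave-one-out prediction is not
  guaranteed perfect: responder plateaus below the detection floor
  leave irreducible censored-tail residuals whose trade-off biases the
  profiled shared ratio $c$ by ~10%, and — because baseline IS sits
  near the $k_{IS} \cdot 100$ saturation — that bias distorts the
  held-out three-point plateau extrapolation non-uniformly. On the
  default cohort one responder of 18 is narrowly misclassified this
  way (31/32 correct). The training-side estimates are immune (their
  plateaus are pinned at the detectability bound), so the asymmetry is
  intrinsic to predicting from three unconstrained points with a
  cohort-trained scale.

* The method assumes monotone exponential approach; real IS series with
  rebound (resistance) violate the model and the estimator flags such
  triples rather than modelling them.
* The shared-$c$ assumption is a modelling convenience; per-patient
  expression ratios are not identifiable from two observables.
* No uncertainty quantification is attached to the estimates or the
  thresholds; the classifier is a point-decision rule.
* Comparator scores on synthetic cohorts use covariates drawn
  independently of the kinetics, so their benchmark values here say
  nothing about their clinical performance — they serve as wiring tests
  of the score calculators and of the benchmark plumbing.
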