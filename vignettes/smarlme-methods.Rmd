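---
title: "SMARLME: model, estimation, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SMARLME: model, estimation, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smarlme)
```

## The model

For subjects $i = 1..N$, outcome variables $j = 1..p$ and equally spaced
times $t = 1..T$, the SMARLME model is

$$
Y_{it} \;=\; \sum_{\tau=1}^{d} \rho_\tau\, f(Y_{i(t-\tau)})
\;+\; X_i^\top\beta \;+\; Z_i b_i \;+\; \epsilon_{it},
\qquad \lVert \rho \rVert_0 \le n,
$$

with i.i.d. Gaussian residuals $\epsilon_{it}$, Gaussian random effects
$b_i$ independent of $\epsilon$, a lag window ("history period") $d$, and
elementwise predictor transforms $f$ — by default the pair
$\{\mathrm{identity}, \exp\}$, so saturating (Hill-type) feedback kinetics
can be carried by a *linear* model in transformed lags.  The coefficient
matrices $\rho_\tau$ are vectorised column-major ($k$ fastest, then target
$j$, then transform, then $\tau$) into a single vector $\rho$ whose number
of nonzero entries is capped at the budget $n$.  The stacked regression
system $y = A\rho$ has one row per target observation and a block-sparse
$A$: a column keyed to target $j$ is nonzero only on rows whose target
variable is $j$ (the Kronecker block structure of a vectorised VAR).

Assumptions worth keeping in view: complete, equally spaced sampling; a
common residual variance across variables and times; time-independent (or
indicator-interacted) covariates shared across the $p$ outcomes; a single
subject random intercept by default (a general diagonal random-effect
design is accepted).

## Estimation

**Sparse stage (FoBa).**  The $\ell_0$-constrained least squares problem
is solved by an adaptive forward–backward greedy search.  A forward step
selects $\arg\max_c |(A^\top b)_c|$ for the current residual $b$ (ties go
to the lowest column index), refits the active coefficients by solving
the normal equations on the active Gram block, and records the RSS gain.
A backward sweep then deletes any active column whose removal (with
refit) raises the RSS by less than $\nu$ times the most recent forward
gain, repeating until no deletion qualifies.  The search stops at the
budget, at numerical convergence ($\max|A^\top b| < 10^{-10}\lVert y
\rVert_2$, or the best candidate already active), or at an iteration cap.
All refits are $O(|\text{support}|^3)$ against a cached Gram matrix, so
replication studies run in milliseconds per fit; rank-deficient active
sets fall back to a least-norm pseudo-inverse with a warning.

On quasi-collinear designs (periodic trajectories are the prime example)
the add-one/remove-one alternation can revisit a support; the solver
detects the revisit, stops, and reports `converged = FALSE`.  The result
is still the deterministic outcome of a fixed rule, and is reproducible.

Two tunables matter.  The backward threshold $\nu$ (default 0.5, the
adaptive-FoBa convention) controls how aggressively the support is
pruned: the bundled oscillator study uses $\nu = 0.9$, which prunes the
25-column budget to a support well below it.  Column standardisation is
*off* by default — the forward rule then uses raw inner products, which
deliberately favours the larger-scale exponential channels; a
`standardize` flag provides unit-norm screening instead, and its effect
is pinned down in the test suite.

**Mixed stage and alternation.**  Estimation alternates between the
sparse stage and a maximum-likelihood linear mixed-effects stage
(`lme4::lmer`, ML rather than REML so that log-likelihoods are
comparable across budgets and iterations; BIC selection requires a single
likelihood definition).  The sparse stage runs on pseudo-outcomes with
the current fixed and random effects removed,
$Y^* = Y - X\hat\beta - Z\hat b$; the mixed stage, given the selected
support, re-estimates $\beta$ *and* the active AR coefficients in one
joint ML fit.  The joint refit is the package's one deliberate departure
from a pure two-stage update: the two schemes share their fixed points
(verified numerically to 1000 iterations), but the pure alternation
converges along a near-flat ridge — the trade-off between the AR "level
mass" $\sum\hat\rho$ and the fixed-effect intercept — at a linear rate
close to 1, while the joint refit resolves that ridge in one linear
solve and converges in a handful of outer iterations.  Outer convergence
is declared when the max-norm changes of $\rho$ and $\beta$ drop below
$10^{-6}$ (cap 50 iterations); a combined-RSS increase on three
consecutive iterations aborts with the diagnostic trace.  With budget 0
the fit is, bit for bit, the plain mixed model; with no covariates it is
exactly the sparse solver.

**Budget choice.**  `bic_sweep()` fits an ascending budget grid starting
at 0 (warm-starting each support from the previous one) and reports
$\mathrm{BIC} = -2\ell + k\log n_{\mathrm{obs}}$ with
$k = k_{\mathrm{fixed}} + k_{\mathrm{varcomp}} + \lVert\hat\rho\rVert_0$
and $n_{\mathrm{obs}}$ the number of stacked rows.  Both the budget and
the realised support size are reported; the backward sweep usually makes
the latter smaller.

**Identifiability caveat.**  With a free random intercept and
unconstrained self-lag coefficients, subject-constant level structure is
only weakly identified: lagged outcomes contain each subject's level, so
the likelihood can trade $\sigma_b^2$ against additional AR mass, and the
ML solution absorbs part of the level into $\hat\rho$ while attenuating
subject-constant components of $\beta$ (a dynamic-panel endogeneity; we
verified on simulated panels that the absorbed solution genuinely
dominates the generating parameters in ML deviance, for the pure
alternation and the joint refit alike).  What the estimator does recover
reliably is the sparse support, the within-subject fluctuation dynamics,
and time-varying contrasts such as intervention effects — which are also
attenuated toward their AR-conditional (one-step) scale.  This matches
the model's intended reading: after AR adjustment an intervention
coefficient measures the per-hour shift given the history, not the
equilibrium shift, which is why AR-adjusted intervention effects are
systematically smaller than mean-model ones.  Analyses that need
equilibrium-scale effects should divide by $1 - \sum_k\hat\rho_{kj\cdot}$
for the target equation, with the caveat above.

## Edge policy and the lag design

Under the default `zero_pad` policy the stacked system has rows from
$t = 2$ onward and any lag reaching before the first observation
contributes an exact zero — the staggered block layout of the vectorised
VAR.  Under `drop_initial` only rows with $t > d$ are kept.  Zero padding
retains the early transient (useful information when trajectories start
off-equilibrium) but makes long-lag columns step-like when outcomes have
large levels — on the blood-pressure design (levels near 110 mmHg) the
padded lag-23 column is approximately an intervention-indicator lookalike
and confounds the daily-lag selection, so the blood-pressure analyses in
the tests and examples use `drop_initial`.  Both policies agree exactly
on all rows with $t > d$.

## The oscillator simulator

The two-variable circadian model couples PER ($Y_1$) and dCLOCK ($Y_2$)
through the free dCLOCK level $Y_2 - Y_1$, with a logistic switch of
scale $\alpha$ replacing the hard threshold, delays
$\tau_1 = \tau_2 = 12$ h, and an implicit hourly update (the unique
algebraic solution of the discretised kinetics, which place the new value
on both sides):

$$
Y_1(t) = \frac{Y_1(t-1) + v_1 / \left(1 + K_1 + K_1 e^{\alpha (Y_1 - Y_2)_{t-\tau_1}}\right)}{1 + k_1},
\qquad
Y_2(t) = \frac{Y_2(t-1) + v_2 / \left(1 + \left[K_2\left(1 + e^{-\alpha (Y_2 - Y_1)_{t-\tau_2}}\right)\right]^{-1}\right)}{1 + k_2}.
$$

Defaults: $v_1 = 0.5$, $v_2 = 0.25$, $k_1 = k_2 = 0.5$, $K_1 = 0.3$,
$K_2 = 0.1$, $\alpha = 10$.  Two renderings of the dCLOCK synthesis term
circulate that differ in the sign of the switching argument.  The
package's default is the *repression* form shown above (dclock
transcription repressed by free dCLOCK, so PER binding de-represses it —
the positive loop as biologically described): under it both proteins
oscillate in anti-phase with amplitudes of the same order.  The mirrored
*activation* form is available via `dclock_feedback = "activation"`; it
leaves dCLOCK nearly constant (variance $\sim 2\times10^{-4}$) and is
kept only for comparability.

Two numerical facts about this map shape everything downstream.  First,
its attractor is a quasi-periodic invariant circle with a near-period of
about 27 h, *not* an exactly periodic orbit: the best integer-shift
mismatch stays near $10^{-2}$ even after $10^6$ burn-in steps, and
trajectories from different initial histories agree in geometry
(variance, range, period) but not pointwise, because their phases on the
circle differ.  The tests assert attractor geometry and near-periodicity
at tolerance 0.05 accordingly.  Second, because the near-period is ~27 h,
the strongest long-lag regression structure sits at lag 13 (half the
cycle) next to the structural delay at lag 12, and the fitted coefficient
values are sensitive to the exact 72-h window phase.  Reported
coefficient-level results should therefore always be read together with
the frozen configuration below.

**Frozen study configuration** (`osc_study_config()`): constant initial
history $Y_1 = Y_2 = 0.3$, burn-in 480 h (20 nominal days, far past
transient decay), 72 retained hours, 100 replicate subjects per noisy
panel, history period $d = 17$ (large enough that a lag-17 position is
representable), `zero_pad` edges, transforms $\{$identity, exp$\}$,
budget $n = 25$, $\nu = 0.9$, no standardisation.  Under this
configuration the no-noise fit selects 15 positions, all on exponential
columns, with one-step $R^2 > 0.99$ per variable; the pooled signal
variance of the retained window is 0.067 (per-variable 0.087 and 0.030),
giving a signal-to-noise ratio of 6.7 at noise SD 0.1 under the pooled
convention (variance of the $2\times72$ retained values about their
grand mean).

The replication harness adds seeded Gaussian observation noise
($\sigma \in \{0.01, 0.05, 0.1\}$ in the bundled studies), refits FoBa
per replication, and summarises each coefficient position by selection
count, signed mean deviation from the no-noise reference ("bias" — the
absolute version is reported alongside, since both conventions appear in
practice), MSE, and their across-replication SDs.  By default the
summaries average over the replications that selected the position
(count as denominator); zero-imputation over all replications is a flag.
Default replication count is 100; sub-seeds derive deterministically
from the master seed, so batches are bit-reproducible.

## The synthetic blood-pressure generator

`generate_bp_panel()` emulates the *structure* of a parallel-arm feeding
trial with two concatenated 24-h ambulatory blood-pressure series: three
diet arms in equal allocation, a pre/post intervention indicator
$\delta_t$ ($0$ for $t \le 24$, $1$ for $t \ge 25$), race and age as
subject covariates, eight fixed-effect predictors (intercept, two arm
dummies, three arm-by-intervention interactions, race, age), a subject
random intercept, and a sparse circular AR structure over $d = 23$ lags
($p^2 d = 92$ identity columns): self lag-1 mass 0.35, self lag-23 mass
0.25 per outcome, plus a small lag-1 cross term.  Generating values
(AR-conditional scale): intercept 30, interventions $-1.1/-2.2/-2.4$,
age 0.08 per year, $\sigma_b = 1.5$, $\sigma = 2$ — producing equilibrium
levels near 110 mmHg with realistic within-subject noise.  History
initialises at each subject's pre-period equilibrium; lags cross the
pre/post boundary by default (`sever_boundary = TRUE` restarts the
history at the post-period equilibrium).  It is a synthetic stand-in: no
real trial values are reproduced, and passing its recovery tests shows
the pipeline recovers *this* structure, not that any published estimate
is matched.  Real ambulatory data differ in ways the generator does not
emulate: diurnal mean curves, heteroscedastic and serially dependent
measurement error, missed readings, and arm-specific AR dynamics.

## Numerical choices and degenerate inputs

* Active-set refits solve the Gram normal equations via a dense
  factorisation (supports are at most a few dozen); singular blocks fall
  back to a least-norm SVD solution with a warning.
* Argmax ties in the forward step break to the lowest column index;
  everything downstream is deterministic given the seed.
* The `exp` transform maps arguments above 700 to `Inf`, which the
  design builder reports as a numeric-domain error naming the offending
  (subject, variable, time) cell.
* Degenerate inputs fail fast with targeted messages: `d >= T`,
  collinear fixed-effect columns (named), fewer than two subjects,
  ragged or duplicated CSV rows (with row numbers).  Constant fitted
  series make lagged correlations undefined; they are returned as `NaN`
  with a warning.
* Variance components estimated at zero are reported with a `boundary`
  flag rather than an error.

## Problem sizes in the bundled tests

The suite favours many small seeded panels: design/solver oracles run on
panels up to $2 \times 2 \times 10$ against brute-force scalar loops and
exhaustive best-subset search (200 instances, $\le 10$ columns); mixed
-model checks use up to 500 subjects; recovery studies use 60–100
subjects with 40–60 time points and 4–10 seeds; replication-study checks
use 10–100 replications at 20–100 subjects.  These sizes were chosen so
the full suite exercises every claim in minutes on a single core; the
same code scales to the full 1,000-replication studies via
`run_replications(..., n_reps = 1000)` or the `simstudy` CLI flag.

## Known limitations

* Stationarity of the fitted AR structure is neither enforced nor
  tested; fitted models may be non-stationary, which matters for
  long-horizon simulation but not for one-step fitting.
* Inference on $\beta$ (Wald SEs and p-values from the normal
  approximation) ignores the model-selection step; post-selection
  corrections are out of scope.
* Subject-constant level effects are attenuated by the free self-lags
  (see the identifiability caveat); only AR-conditional effects are
  directly interpretable.
* The oscillator's quasi-periodicity makes coefficient-level results
  window-dependent; compare runs only under identical frozen
  configurations.
* Crossed or nested random effects, non-Gaussian outcomes, REML, and
  irregular sampling are unsupported.
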