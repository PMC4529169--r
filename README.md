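# smarlme

Sparse multivariate autoregressive linear mixed-effects (SMARLME) models
for intensive longitudinal data.

## The problem

Densely sampled biomedical time series — hourly blood-pressure
recordings, circadian protein levels — often carry dependence at *long,
unknown* lags: hour 24 predicts hour 1 of the next day, a transcription
factor feeds back on its repressor 12 hours later.  A conventional AR(m)
model must either truncate the history (missing the daily cycle) or
spend `m p²` parameters on it (overfitting).  SMARLME keeps the whole
history but constrains the coefficient vector to be sparse:

    Y_it = Σ_{τ=1..d} ρ_τ f(Y_{i,t-τ}) + X_iᵀ β + Z_i b_i + ε_it ,
    subject to  ‖ρ‖₀ ≤ n

where `Y_it` is the p-vector of outcomes for subject `i` at time `t`,
`ρ_τ` are (possibly transformed, e.g. exponential) lag-τ coefficient
matrices vectorised into `ρ`, `β` are shared fixed effects, `b_i` is a
subject random intercept, and `‖ρ‖₀ ≤ n` caps the number of nonzero AR
coefficients.  The ℓ0-constrained least-squares problem is solved by an
adaptive forward–backward greedy algorithm (FoBa): forward steps add the
design column most correlated with the residual; backward steps delete
columns whose removal barely increases the residual sum of squares, so
the realised support is usually much smaller than the budget `n`.  The
AR and mixed-effects parts are estimated by alternating pseudo-outcome
stages, and the budget is chosen by a BIC sweep.

The package is aimed at biostatisticians analysing pre/post-intervention
panels (e.g. 24-hour ambulatory blood pressure around a diet
intervention) and at systems biologists inferring delayed feedback
structure (e.g. the Drosophila PER/dCLOCK oscillator) from sampled
trajectories.  Everything needed to exercise the method ships with the
package: a delay-feedback circadian-oscillator simulator, a
replication-study harness (selection counts, bias, MSE per coefficient
position), and a synthetic blood-pressure trial generator.

## Worked example

Fit the no-noise circadian oscillator study (simulate the delayed
feedback system, build the lagged design with identity and exponential
channels, run FoBa with budget 25):

```r
library(smarlme)
nt <- no_noise_truth()          # frozen study configuration
print(nt$truth)
#> sparse_coef: 15 nonzero of 136 (budget 25), RSS = 0.0222551
sel <- nt$truth$support
head(cbind(nt$design$column_keys[sel, ], estimate = round(nt$truth$rho[sel], 5)))
#>    k j tau transform estimate
#> 5  1 1   1       exp  0.27833
#> 6  2 1   1       exp -0.16060
#> 8  2 2   1       exp  0.29914
#> 14 2 1   2       exp  0.04809
#> 16 2 2   2       exp -0.06627
#> 22 2 1   3       exp  0.10392
```

The backward sweep prunes the 25-column budget down to 15 active
coefficients, all on exponential-transform columns — the linear channel
is never selected, because the generating kinetics are Hill-type and the
`exp` channel linearises them.  The dominant coefficients sit at lag 1
(the carry-over of each protein level) and at lag 13 (half the ~27-hour
cycle of this attractor); the fitted one-step-ahead curves reproduce the
trajectories with R² > 0.99 per variable.

Fitting a synthetic pre/post blood-pressure trial end-to-end (two
outcomes, 48 hourly points, 8 fixed-effect predictors, subject random
intercept, circular AR structure over 23 lags):

```r
gen <- generate_bp_panel(bp_design(n_subjects = 100), seed = 11)
covs <- bp_covariates(gen$subjects, edge_policy = "drop_initial", d = 23)
fit <- smarlme(gen$panel, covs, d = 23, budget = 12,
               transforms = transform_spec("identity"),
               edge_policy = "drop_initial")
print(fit)
#> SMARLME fit
#>   AR support: 12 nonzero (budget 12), d = 23
#>   fixed effects: 8; BIC = 21529.10, AIC = 21385.72
#>   converged: TRUE after 2 outer iteration(s)
summary(fit)$beta[c("veg_fruit_intv", "dash_intv"), ]
#>                 Estimate       SE         p
#> veg_fruit_intv -1.909214 0.262776 3.715e-13
#> dash_intv      -2.073994 0.261490 2.166e-15
```

The recovered support contains the generating self-lags (1 and 23, both
outcomes; e.g. lag-23 estimates 0.347 and 0.329 against a generating
0.25), and the diet-by-intervention effects land near the generating
values (−2.2 and −2.4 here) where the plain mixed model without the AR
part overstates them — the attenuation of intervention effects under AR
adjustment that motivates the model.  `bic_sweep()` automates the budget
choice; `model_correlations()` reproduces the lagged-correlation
diagnostic with its circular (U-shaped) structure in daily data.

A thin command-line wrapper over the same functions is installed at
`inst/cli/smarlme.R` with subcommands `simulate-oscillator`,
`simulate-bp`, `fit`, `sweep` and `simstudy`.

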