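#' Covariate set for the mixed-effects stage
#'
#' Packages the fixed-effect design and the random-effect design for
#' [fit_lme()].  `X` may be given per subject (one row per subject,
#' expanded to observation rows by the caller through `expand_covariates()`)
#' or directly per observation row.  The default random-effect structure is
#' a single subject intercept; a general per-observation `Z` is accepted,
#' with independent (diagonal-covariance) random effects per column.
#'
#' @param X numeric matrix of fixed-effect regressors (include an intercept
#'   column explicitly if wanted); one row per subject or per observation.
#' @param subject for observation-level `X`: integer/factor vector of
#'   subject ids, one per row of `X`.  For subject-level `X` leave `NULL`.
#' @param Z optional per-observation random-effect design matrix; `NULL`
#'   means a random subject intercept.
#' @return A `covariate_set`.
#' @export
covariate_set <- function(X, subject = NULL, Z = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("covariates must not contain missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  }
  structure(list(X = X, subject = subject, Z = Z,
                 per_subject = is.null(subject)),
            class = "covariate_set")
}

# replicate subject-level covariate rows onto stacked observation rows
expand_covariates <- function(covariates, row_subject) {
  if (covariates$per_subject) {
    X <- covariates$X[row_subject, , drop = FALSE]
    subject <- row_subject
  } else {
    if (nrow(covariates$X) != length(row_subject)) {
      stop("observation-level covariates: nrow(X) must equal the number of stacked rows")
    }
    X <- covariates$X
    subject <- covariates$subject
  }
  list(X = X, subject = subject, Z = covariates$Z)
}

#' Linear mixed-effects fit on (pseudo-)outcomes
#'
#' Maximum-likelihood fit of
#' \deqn{y_r = x_r^T \beta + z_r^T b_{i(r)} + \epsilon_r}
#' with i.i.d. Gaussian residuals and Gaussian random effects independent of
#' the residuals (diagonal random-effect covariance).  ML (not REML) is used
#' throughout so that log-likelihoods remain comparable across sparsity
#' budgets and alternating iterations.
#'
#' @param y numeric response vector (stacked observation rows).
#' @param X fixed-effect design matrix, one row per element of `y`.
#' @param subject subject id per element of `y` (at least 2 distinct
#'   subjects are required for variance-component identifiability).
#' @param Z optional per-observation random-effect design; `NULL` fits a
#'   random subject intercept.
#' @return A `mixed_fit`: `beta`, `se_beta`, `p_beta` (Wald, normal
#'   approximation), `b` (predicted random effects, one row per subject),
#'   `sigma2_resid`, `sigma2_ranef` (vector, one per random-effect column),
#'   `loglik`, `n_obs`, `k_fixed`, `k_varcomp`, `boundary` (TRUE when a
#'   variance component is estimated at zero), `subjects` (the id levels).
#' @export
fit_lme <- function(y, X, subject, Z = NULL) {
  X <- as.matrix(X)
  if (anyNA(y) || !all(is.finite(y))) stop("`y` must be finite")
  if (length(unique(subject)) < 2L) {
    stop("at least 2 subjects are required to identify the variance components")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  dat <- data.frame(.y = y, .subj = factor(subject))
  Xn <- X
  colnames(Xn) <- paste0(".x", seq_len(ncol(X)))
  dat <- cbind(dat, as.data.frame(Xn))
  if (is.null(Z)) {
    form <- stats::as.formula(paste(".y ~ 0 +",
                                    paste(colnames(Xn), collapse = " + "),
                                    "+ (1 | .subj)"))
  } else {
    Z <- as.matrix(Z)
    Zn <- Z
    colnames(Zn) <- paste0(".z", seq_len(ncol(Z)))
    dat <- cbind(dat, as.data.frame(Zn))
    form <- stats::as.formula(paste(
      ".y ~ 0 +", paste(colnames(Xn), collapse = " + "),
      "+ (0 +", paste(colnames(Zn), collapse = " + "), "|| .subj)"))
  }
  fit <- suppressMessages(lme4::lmer(form, data = dat, REML = FALSE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore",
                                       calc.derivs = FALSE)))
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_resid <- vc$vcov[vc$grp == "Residual"]
  s2_ranef <- vc$vcov[vc$grp != "Residual" & is.na(vc$var2)]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(se) <- colnames(X)
  p <- 2 * stats::pnorm(-abs(beta / se))
  b <- as.matrix(lme4::ranef(fit)$.subj)
  structure(list(beta = beta, se_beta = se, p_beta = p,
                 b = b,
                 subjects = levels(dat$.subj),
                 sigma2_resid = s2_resid,
                 sigma2_ranef = s2_ranef,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = length(y),
                 k_fixed = ncol(X),
                 k_varcomp = length(s2_ranef) + 1L,
                 boundary = any(s2_ranef < 1e-10)),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("mixed_fit: %d fixed effects, %d obs, logLik = %.3f%s\n",
              x$k_fixed, x$n_obs, x$loglik,
              if (x$boundary) " (variance at boundary)" else ""))
  tab <- data.frame(Estimate = x$beta, SE = x$se_beta,
                    `p value` = signif(x$p_beta, 3), check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

#' Information criteria for a (sparse-augmented) mixed fit
#'
#' `BIC = -2 logLik + k log(n_obs)` and `AIC = -2 logLik + 2k`, where
#' `k = k_fixed + k_varcomp + k_extra` counts the fixed effects, the
#' variance components, and the nonzero autoregressive coefficients added
#' by the sparse stage.  `n_obs` is the number of stacked pseudo-outcome
#' rows.  With `k_extra = 0` this is the plain mixed-model criterion.
#'
#' @param fit a `mixed_fit`.
#' @param k_extra number of nonzero AR coefficients (0 for the plain LME).
#' @param n_obs number of observations; defaults to `fit$n_obs`.
#' @return Named list `loglik`, `AIC`, `BIC`.
#' @export
loglik_and_ic <- function(fit, k_extra = 0L, n_obs = fit$n_obs) {
  k <- fit$k_fixed + fit$k_varcomp + k_extra
  list(loglik = fit$loglik,
       AIC = -2 * fit$loglik + 2 * k,
       BIC = -2 * fit$loglik + k * log(n_obs))
}

# fitted fixed + random part on observation rows
.lme_linpred <- function(fit, X, subject, Z = NULL) {
  idx <- match(as.character(subject), fit$subjects)
  eta <- drop(as.matrix(X) %*% fit$beta)
  out <- if (is.null(Z)) {
    eta + fit$b[idx, 1L]
  } else {
    eta + rowSums(as.matrix(Z) * fit$b[idx, , drop = FALSE])
  }
  unname(out)
}
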