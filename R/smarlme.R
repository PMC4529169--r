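#' Pseudo-outcomes with the autoregressive part removed
#'
#' Subtracts the current sparse AR prediction from the stacked targets:
#' \eqn{Y^\dagger = Y - A\hat\rho}.  With `rho = 0` this is the raw
#' stacked outcome (the first alternating iteration).
#'
#' @param panel a [ts_panel()] (used only for a consistency check).
#' @param design a [build_design()] result.
#' @param rho a `sparse_coef` or a plain numeric vector aligned to the
#'   design columns.
#' @return Numeric vector row-aligned with `design$A`.
#' @export
pseudo_outcome_lme <- function(panel, design, rho) {
  r <- if (inherits(rho, "sparse_coef")) rho$rho else as.numeric(rho)
  if (length(r) != ncol(design$A)) {
    stop("`rho` length ", length(r), " does not match design columns ", ncol(design$A))
  }
  nz <- which(r != 0)
  if (!length(nz)) return(design$y)
  design$y - drop(design$A[, nz, drop = FALSE] %*% r[nz])
}

#' Pseudo-outcomes with the fixed and random effects removed
#'
#' Subtracts the current mixed-model prediction from the stacked targets:
#' \eqn{Y^* = Y - X\hat\beta - Z\hat b_i}.
#'
#' @inheritParams pseudo_outcome_lme
#' @param covariates expanded covariates as returned by
#'   `expand_covariates()` (list with `X`, `subject`, `Z`), row-aligned
#'   with the design.
#' @param mixed a `mixed_fit`.
#' @return Numeric vector row-aligned with `design$A`.
#' @export
pseudo_outcome_ar <- function(panel, design, covariates, mixed) {
  if (nrow(covariates$X) != length(design$y)) {
    stop("covariate rows (", nrow(covariates$X),
         ") do not match stacked rows (", length(design$y), ")")
  }
  design$y - .lme_linpred(mixed, covariates$X, covariates$subject, covariates$Z)
}

#' Fit a sparse multivariate autoregressive linear mixed-effects model
#'
#' Estimates the model
#' \deqn{Y_{it} = \sum_{\tau=1}^{d} \rho_\tau f(Y_{i,t-\tau}) + X_i^T\beta
#'       + Z_i b_i + \epsilon_{it}, \qquad \|\rho\|_0 \le n}
#' by alternating two stages until the parameters stabilise: (a) a
#' maximum-likelihood linear mixed-effects fit on pseudo-outcomes with the
#' current AR part removed, and (b) an l0-constrained least-squares fit
#' (forward-backward greedy search, [foba_solve()]) on pseudo-outcomes
#' with the current fixed and random effects removed.  With `budget = 0`
#' the fit reduces exactly to the plain mixed model; with
#' `covariates = NULL` it reduces to the pure sparse autoregression.
#'
#' @param panel a [ts_panel()].
#' @param covariates a [covariate_set()], or `NULL` for a pure AR fit.
#' @param d maximum lag of the autoregression.
#' @param budget sparsity budget `n` (number of nonzero AR coefficients
#'   allowed); 0 disables the AR part.
#' @param transforms a [transform_spec()]; default `{identity, exp}`.
#' @param edge_policy see [build_design()].
#' @param nu,standardize,foba_tol,foba_max_iter passed to [foba_solve()].
#' @param tol outer-loop convergence tolerance on the max-norm change of
#'   `rho` and `beta`.
#' @param max_outer maximum alternating iterations.
#'
#' @return A `smarlme` fit: list with `sparse` (`sparse_coef`), `mixed`
#'   (`mixed_fit` or `NULL`), `n_budget`, `trace` (per-iteration
#'   data.frame: `rho_change`, `beta_change`, `rss`, `loglik`),
#'   `converged`, `bic`, `aic`, `fitted` (one-step-ahead fitted values on
#'   the stacked rows), `row_keys`, `column_keys`, `d`, `edge_policy`,
#'   `call`.
#'
#' @examples
#' set.seed(1)
#' pan <- ts_panel(array(rnorm(5 * 1 * 30), c(5, 1, 30)))
#' cov <- covariate_set(cbind(intercept = rep(1, 5)))
#' fit <- smarlme(pan, cov, d = 2, budget = 1)
#' coef(fit)$beta
#' @export
smarlme <- function(panel, covariates = NULL, d, budget,
                    transforms = transform_spec(),
                    edge_policy = c("zero_pad", "drop_initial"),
                    nu = 0.5, standardize = FALSE,
                    tol = 1e-6, max_outer = 50L,
                    foba_tol = 1e-10, foba_max_iter = 100L) {
  edge_policy <- match.arg(edge_policy)
  design <- build_design(panel, d, transforms, edge_policy)
  budget <- as.integer(budget)
  if (budget < 0L) stop("`budget` must be >= 0")
  cl <- match.call()

  if (is.null(covariates)) {
    if (budget == 0L) stop("nothing to fit: budget = 0 and no covariates")
    sp <- foba_solve(design$A, design$y, budget, nu = nu,
                     standardize = standardize, tol = foba_tol,
                     max_iter = foba_max_iter)
    fitted <- drop(design$A %*% sp$rho)
    rss <- sum((design$y - fitted)^2)
    out <- list(sparse = sp, mixed = NULL, n_budget = budget,
                trace = data.frame(iter = 1L, rho_change = NA_real_,
                                   beta_change = NA_real_, rss = rss,
                                   loglik = NA_real_),
                converged = sp$converged, bic = NA_real_, aic = NA_real_,
                fitted = fitted, y = design$y,
                row_keys = design$row_keys, column_keys = design$column_keys,
                d = design$d, edge_policy = edge_policy, call = cl)
    class(out) <- "smarlme"
    return(out)
  }

  cov_rows <- expand_covariates(covariates, design$row_keys$i)
  r <- ncol(cov_rows$X)
  rho_prev <- numeric(ncol(design$A))
  beta_prev <- NULL
  sp <- NULL
  trace <- NULL
  converged <- FALSE
  rss_prev <- Inf
  n_increase <- 0L

  # initialisation: with rho = 0 the model is the plain LME on the raw
  # stacked outcomes
  mixed <- fit_lme(design$y, cov_rows$X, cov_rows$subject, cov_rows$Z)
  if (budget == 0L) {
    sp <- structure(list(rho = rho_prev, support = integer(0),
                         budget_n = 0L,
                         objective = sum((design$y -
                           .lme_linpred(mixed, cov_rows$X, cov_rows$subject,
                                        cov_rows$Z))^2),
                         gains = numeric(0), converged = TRUE,
                         iterations = 0L),
                    class = "sparse_coef")
    trace <- data.frame(iter = 1L, rho_change = 0,
                        beta_change = 0, rss = sp$objective,
                        loglik = mixed$loglik)
    converged <- TRUE
  }

  s <- 0L
  while (budget > 0L && s < max_outer) {
    s <- s + 1L
    # (a) sparse stage on pseudo-outcomes with fixed/random effects removed
    y_star <- pseudo_outcome_ar(panel, design, cov_rows, mixed)
    sp <- foba_solve(design$A, y_star, budget, nu = nu,
                     standardize = standardize, tol = foba_tol,
                     max_iter = foba_max_iter,
                     init_support = sp$support)
    # (b) mixed stage: given the selected support, beta and the active AR
    # coefficients are re-estimated in one joint ML fit (this removes the
    # slow ridge between the AR level mass and the fixed-effect intercept
    # that pure coordinate alternation converges along; see the vignette)
    if (length(sp$support)) {
      XJ <- cbind(cov_rows$X, design$A[, sp$support, drop = FALSE])
      colnames(XJ) <- c(colnames(cov_rows$X), paste0(".rho", sp$support))
      joint <- fit_lme(design$y, XJ, cov_rows$subject, cov_rows$Z)
      sp$rho[] <- 0
      sp$rho[sp$support] <- unname(joint$beta[-seq_len(r)])
      mixed <- joint
      mixed$beta <- joint$beta[seq_len(r)]
      mixed$se_beta <- joint$se_beta[seq_len(r)]
      mixed$p_beta <- joint$p_beta[seq_len(r)]
      mixed$k_fixed <- r
    } else {
      mixed <- fit_lme(design$y, cov_rows$X, cov_rows$subject, cov_rows$Z)
    }
    linpred <- .lme_linpred(mixed, cov_rows$X, cov_rows$subject, cov_rows$Z)
    ar_part <- if (length(sp$support)) {
      drop(design$A[, sp$support, drop = FALSE] %*% sp$rho[sp$support])
    } else 0
    rss <- sum((design$y - ar_part - linpred)^2)
    rho_change <- max(abs(sp$rho - rho_prev))
    beta_change <- if (is.null(beta_prev)) Inf else max(abs(mixed$beta - beta_prev))
    trace <- rbind(trace, data.frame(iter = s, rho_change = rho_change,
                                     beta_change = beta_change, rss = rss,
                                     loglik = mixed$loglik))
    if (max(rho_change, beta_change) < tol) {
      converged <- TRUE
      break
    }
    if (rss > rss_prev * (1 + 1e-8)) {
      n_increase <- n_increase + 1L
      if (n_increase >= 3L) {
        stop("divergent alternation: combined RSS increased for 3 consecutive ",
             "outer iterations; trace:\n",
             paste(utils::capture.output(print(trace)), collapse = "\n"))
      }
    } else n_increase <- 0L
    rho_prev <- sp$rho
    beta_prev <- mixed$beta
    rss_prev <- rss
  }

  ic <- loglik_and_ic(mixed, k_extra = length(sp$support), n_obs = length(design$y))
  linpred <- .lme_linpred(mixed, cov_rows$X, cov_rows$subject, cov_rows$Z)
  ar_part <- if (length(sp$support)) {
    drop(design$A[, sp$support, drop = FALSE] %*% sp$rho[sp$support])
  } else 0
  out <- list(sparse = sp, mixed = mixed, n_budget = budget,
              trace = trace, converged = converged,
              bic = ic$BIC, aic = ic$AIC,
              fitted = ar_part + linpred, y = design$y,
              row_keys = design$row_keys, column_keys = design$column_keys,
              d = design$d, edge_policy = edge_policy, call = cl)
  class(out) <- "smarlme"
  out
}

#' @export
print.smarlme <- function(x, ...) {
  cat("SMARLME fit\n")
  cat(sprintf("  AR support: %d nonzero (budget %d), d = %d\n",
              length(x$sparse$support), x$n_budget, x$d))
  if (!is.null(x$mixed)) {
    cat(sprintf("  fixed effects: %d; BIC = %.2f, AIC = %.2f\n",
                x$mixed$k_fixed, x$bic, x$aic))
  }
  cat(sprintf("  converged: %s after %d outer iteration(s)\n",
              x$converged, nrow(x$trace)))
  invisible(x)
}

#' @export
summary.smarlme <- function(object, ...) {
  sup <- object$sparse$support
  ar_tab <- if (length(sup)) {
    cbind(object$column_keys[sup, , drop = FALSE],
          estimate = object$sparse$rho[sup])
  } else NULL
  out <- list(ar = ar_tab,
              beta = if (!is.null(object$mixed)) {
                data.frame(Estimate = object$mixed$beta,
                           SE = object$mixed$se_beta,
                           p = object$mixed$p_beta)
              } else NULL,
              sigma2_resid = object$mixed$sigma2_resid,
              sigma2_ranef = object$mixed$sigma2_ranef,
              bic = object$bic, aic = object$aic,
              n_budget = object$n_budget,
              support_size = length(sup),
              converged = object$converged)
  class(out) <- "summary.smarlme"
  out
}

#' @export
print.summary.smarlme <- function(x, ...) {
  cat(sprintf("SMARLME summary (budget %d, support %d, converged %s)\n",
              x$n_budget, x$support_size, x$converged))
  if (!is.null(x$ar)) {
    cat("\nAR coefficients:\n"); print(x$ar, digits = 5)
  }
  if (!is.null(x$beta)) {
    cat("\nFixed effects:\n"); print(x$beta, digits = 4)
    cat(sprintf("\nsigma^2 (residual): %.4g;  sigma^2 (random effects): %s\n",
                x$sigma2_resid,
                paste(signif(x$sigma2_ranef, 4), collapse = ", ")))
  }
  if (is.finite(x$bic)) cat(sprintf("BIC = %.2f, AIC = %.2f\n", x$bic, x$aic))
  invisible(x)
}

#' @export
coef.smarlme <- function(object, ...) {
  list(rho = object$sparse$rho,
       support = object$sparse$support,
       beta = if (!is.null(object$mixed)) object$mixed$beta else NULL)
}

#' @export
fitted.smarlme <- function(object, ...) object$fitted

#' @export
residuals.smarlme <- function(object, ...) object$y - object$fitted

#' Sweep the sparsity budget and pick the minimum-BIC model
#'
#' Fits [smarlme()] for each budget in `n_grid` (ascending, starting at 0
#' so the plain mixed model anchors the comparison), warm-starting the AR
#' support from the previous budget, and returns all fits plus the index
#' of the minimum-BIC fit.  Budget and realised support size are reported
#' separately: the backward sweep typically returns fewer nonzeros than
#' the budget allows.
#'
#' @inheritParams smarlme
#' @param n_grid integer vector of budgets, sorted ascending, starting at 0.
#' @param ... further arguments passed to [smarlme()].
#' @return List with `fits` (one `smarlme` per budget), `best` (index of
#'   the BIC minimiser), and `table` (data.frame: `budget`,
#'   `support_size`, `loglik`, `aic`, `bic`).
#' @export
bic_sweep <- function(panel, covariates, d, n_grid, ...) {
  n_grid <- as.integer(n_grid)
  if (is.unsorted(n_grid, strictly = TRUE)) stop("`n_grid` must be strictly ascending")
  if (n_grid[1L] != 0L) stop("`n_grid` must start at 0 (the plain LME anchor)")
  fits <- vector("list", length(n_grid))
  prev_support <- NULL
  for (g in seq_along(n_grid)) {
    fits[[g]] <- smarlme(panel, covariates, d = d, budget = n_grid[g], ...)
    prev_support <- fits[[g]]$sparse$support
  }
  tab <- data.frame(
    budget = n_grid,
    support_size = vapply(fits, function(f) length(f$sparse$support), 0L),
    loglik = vapply(fits, function(f) if (is.null(f$mixed)) NA_real_ else f$mixed$loglik, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    bic = vapply(fits, function(f) f$bic, 0))
  list(fits = fits, best = which.min(tab$bic), table = tab)
}

#' Lagged correlations of model-predicted values
#'
#' Computes, for every ordered variable pair `(j, j2)` and lag
#' `tau = 1..d`, the correlation between the one-step-ahead fitted values
#' \eqn{\hat Y_{ijt}} and \eqn{\hat Y_{ij_2,t-\tau}} across all subjects
#' and admissible times - the model analogue of the empirical
#' lag-correlation diagnostic (circular structures in daily data show up
#' as a U-shape with a second peak near the daily lag).
#'
#' @param fit a `smarlme` fit.
#' @param panel the panel the model was fitted to.
#' @return data.frame `j`, `j2`, `tau`, `correlation` (NaN, with a
#'   warning, for degenerate constant series).
#' @export
model_correlations <- function(fit, panel) {
  p <- n_vars(panel); T <- n_times(panel); N <- n_subjects(panel)
  yhat <- array(NA_real_, c(N, p, T))
  yhat[cbind(fit$row_keys$i, fit$row_keys$j, fit$row_keys$t)] <- fit$fitted
  ts_avail <- sort(unique(fit$row_keys$t))
  out <- expand.grid(j = seq_len(p), j2 = seq_len(p), tau = seq_len(fit$d),
                     KEEP.OUT.ATTRS = FALSE)
  out$correlation <- NA_real_
  warned <- FALSE
  for (r in seq_len(nrow(out))) {
    tau <- out$tau[r]
    ts2 <- ts_avail[ts_avail - tau >= min(ts_avail)]
    a <- as.vector(yhat[, out$j[r], ts2, drop = FALSE])
    b <- as.vector(yhat[, out$j2[r], ts2 - tau, drop = FALSE])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      if (!warned) {
        warning("constant fitted values: correlation undefined (NaN)")
        warned <- TRUE
      }
      out$correlation[r] <- NaN
    } else {
      out$correlation[r] <- stats::cor(a, b)
    }
  }
  out
}

#' One-step-ahead predictions on a (new) panel
#'
#' Rebuilds the lagged design for `panel` under the fit's settings and
#' returns \eqn{\hat Y_{ijt} = A\hat\rho + X\hat\beta + Z\hat b_i}
#' (observed history, estimated coefficients).  Random effects are only
#' available for the subjects the model was fitted on; for new subjects
#' they are set to zero.
#'
#' @param object a `smarlme` fit.
#' @param panel a [ts_panel()]; defaults to re-using the training fitted
#'   values.
#' @param covariates a [covariate_set()] matching `panel` (required when
#'   the fit has a mixed part and `panel` is supplied).
#' @param transforms the transform set used at fit time.
#' @param ... unused.
#' @return data.frame `i`, `j`, `t`, `predicted`.
#' @export
predict.smarlme <- function(object, panel = NULL, covariates = NULL,
                            transforms = transform_spec(), ...) {
  if (is.null(panel)) {
    return(cbind(object$row_keys, predicted = object$fitted))
  }
  design <- build_design(panel, object$d, transforms, object$edge_policy)
  nz <- object$sparse$support
  pred <- if (length(nz)) {
    drop(design$A[, nz, drop = FALSE] %*% object$sparse$rho[nz])
  } else rep(0, length(design$y))
  if (!is.null(object$mixed)) {
    if (is.null(covariates)) stop("`covariates` are required for a mixed fit")
    rows <- expand_covariates(covariates, design$row_keys$i)
    idx <- match(as.character(rows$subject), object$mixed$subjects)
    eta <- drop(as.matrix(rows$X) %*% object$mixed$beta)
    bvec <- ifelse(is.na(idx), 0, object$mixed$b[pmax(idx, 1L), 1L])
    pred <- pred + eta + bvec
  }
  cbind(design$row_keys, predicted = pred)
}

#' Observed and fitted time courses
#'
#' Plots, per outcome variable, the observed series of a few subjects with
#' the model's one-step-ahead fitted values overlaid.
#'
#' @param x a `smarlme` fit.
#' @param panel the panel the model was fitted to.
#' @param subjects subject indices to draw (default: up to 3).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.smarlme <- function(x, panel, subjects = NULL, ...) {
  p <- n_vars(panel)
  if (is.null(subjects)) subjects <- seq_len(min(3L, n_subjects(panel)))
  yhat <- array(NA_real_, dim(panel))
  yhat[cbind(x$row_keys$i, x$row_keys$j, x$row_keys$t)] <- x$fitted
  op <- graphics::par(mfrow = c(p, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  vn <- attr(panel, "variable_names")
  for (j in seq_len(p)) {
    obs <- t(unclass(panel)[subjects, j, , drop = FALSE][, 1, ])
    graphics::matplot(obs, type = "p", pch = 1, cex = 0.5,
                      xlab = "time", ylab = vn[j], ...)
    graphics::matlines(t(yhat[subjects, j, , drop = FALSE][, 1, ]), lty = 1)
  }
  invisible(x)
}
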