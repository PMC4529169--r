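# l0-constrained least squares by the adaptive forward-backward greedy
# algorithm.  All active-set refits solve the normal equations on the
# cached Gram matrix, so a full solve costs O(|support|^3) regardless of
# the number of rows.

foba_state_new <- function(A, y, standardize = FALSE) {
  if (nrow(A) != length(y)) stop("A and y are not row-aligned")
  scale <- rep(1, ncol(A))
  if (standardize) {
    scale <- sqrt(colSums(A^2))
    scale[scale == 0] <- 1
    A <- sweep(A, 2L, scale, "/")
  }
  list(G = crossprod(A),            # t(A) %*% A
       c = drop(crossprod(A, y)),   # t(A) %*% y
       yy = sum(y^2),
       n_col = ncol(A),
       scale = scale,
       support = integer(0),
       coef = numeric(0),           # coefficients on the (scaled) support
       rss = sum(y^2),
       gains = numeric(0),          # squared-error reduction per forward step
       rank_warned = FALSE)
}

# least-squares coefficients on a support, via the Gram normal equations;
# least-norm pseudo-inverse fallback on rank deficiency
.foba_refit <- function(state, support) {
  if (!length(support)) return(numeric(0))
  Gs <- state$G[support, support, drop = FALSE]
  cs <- state$c[support]
  co <- tryCatch(solve(Gs, cs), error = function(e) NULL)
  if (is.null(co)) {
    sv <- svd(Gs)
    pos <- sv$d > max(sv$d) * 1e-12
    co <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], cs)) / sv$d[pos])
    co <- drop(co)
    attr(co, "rank_deficient") <- TRUE
  }
  drop(co)
}

.foba_rss <- function(state, support, coef) {
  if (!length(support)) return(state$yy)
  drop(state$yy - 2 * sum(coef * state$c[support]) +
         crossprod(coef, state$G[support, support, drop = FALSE] %*% coef))
}

# residual correlations t(A) %*% (y - A rho) for the current state
.foba_corr <- function(state) {
  if (!length(state$support)) return(state$c)
  state$c - drop(state$G[, state$support, drop = FALSE] %*% state$coef)
}

#' One forward step of the greedy search
#'
#' Adds the column with the largest absolute residual correlation
#' \eqn{|A^T b|} (ties broken by lowest index) to the active set, refits
#' the active coefficients by solving the normal equations, and records
#' the squared-error gain of the step.
#'
#' @param state a solver state as stored in the `trace` of [foba_solve()];
#'   created internally.
#' @return The updated state, with attribute `"stopped"` set to
#'   `"converged"` when the best candidate is already active (numerical
#'   convergence).
#' @keywords internal
#' @export
foba_forward_step <- function(state) {
  corr <- .foba_corr(state)
  i <- which.max(abs(corr))
  if (i %in% state$support) {
    attr(state, "stopped") <- "converged"
    return(state)
  }
  support <- c(state$support, i)
  coef <- .foba_refit(state, support)
  if (isTRUE(attr(coef, "rank_deficient")) && !state$rank_warned) {
    warning("rank-deficient active set; using least-norm solution")
    state$rank_warned <- TRUE
  }
  rss <- .foba_rss(state, support, coef)
  state$gains <- c(state$gains, state$rss - rss)
  state$support <- support
  state$coef <- as.numeric(coef)
  state$rss <- rss
  state
}

#' Backward sweep of the greedy search
#'
#' Repeatedly deletes from the active set any column whose removal (with a
#' refit on the reduced set) increases the residual sum of squares by less
#' than `nu` times the gain of the most recent forward step; refits after
#' every removal.
#'
#' @inheritParams foba_forward_step
#' @param nu backward threshold in (0, 1); `nu -> 0` disables deletion.
#' @return The updated state.
#' @keywords internal
#' @export
foba_backward_sweep <- function(state, nu) {
  if (!length(state$gains)) return(state)
  thresh <- nu * state$gains[length(state$gains)]
  repeat {
    if (length(state$support) <= 1L) break
    inc <- vapply(seq_along(state$support), function(g) {
      sup <- state$support[-g]
      co <- .foba_refit(state, sup)
      .foba_rss(state, sup, co) - state$rss
    }, numeric(1))
    g <- which.min(inc)
    if (inc[g] < thresh) {
      state$support <- state$support[-g]
      state$coef <- as.numeric(.foba_refit(state, state$support))
      state$rss <- .foba_rss(state, state$support, state$coef)
    } else break
  }
  state
}

#' Sparse least squares by forward-backward greedy search (FoBa)
#'
#' Solves \eqn{\min_\rho \|y - A\rho\|_2^2} subject to
#' \eqn{\|\rho\|_0 \le n} by alternating forward selection (add the column
#' most correlated with the residual) and backward deletion (drop columns
#' whose removal barely increases the residual sum of squares).  The
#' backward step typically returns supports well below the budget `n`.
#'
#' @param A numeric design matrix.
#' @param y numeric response, row-aligned with `A`.
#' @param n cardinality budget (`>= 1`); capped at `ncol(A)` with a warning.
#' @param nu backward deletion threshold in (0, 1): a column is deleted when
#'   its removal increases the RSS by less than `nu` times the last forward
#'   gain.  Default 0.5 (the adaptive-FoBa convention).
#' @param standardize scale columns to unit Euclidean norm before the
#'   search (coefficients are returned on the original scale).  Off by
#'   default: the forward rule then uses the raw inner products, so
#'   channels with larger scale (e.g. exponential transforms) are favoured.
#' @param tol forward stop: the search ends when
#'   \eqn{\max|A^T b| < } `tol` \eqn{\cdot \|y\|_2}.
#' @param max_iter cap on forward iterations; also terminates
#'   add-one/remove-one cycling on quasi-collinear designs (reported via
#'   `converged = FALSE`).
#' @param init_support optional integer vector of columns used to warm-start
#'   the active set (refit, then continue the search); entries beyond the
#'   budget are dropped from the end.
#'
#' @return A `sparse_coef`: list with `rho` (full-length coefficient
#'   vector, exactly zero off the support), `support` (integer indices),
#'   `budget_n`, `objective` (final RSS), `gains` (per-forward-step RSS
#'   reductions), `converged`, `iterations`.
#'
#' @examples
#' A <- qr.Q(qr(matrix(rnorm(80), 20, 4)))
#' y <- A[, 3]
#' foba_solve(A, y, n = 2)$support
#' @export
foba_solve <- function(A, y, n, nu = 0.5, standardize = FALSE,
                       tol = 1e-10, max_iter = 100L, init_support = NULL) {
  if (nrow(A) != length(y)) stop("dimension mismatch: nrow(A) != length(y)")
  if (n < 0) stop("`n` must be >= 0")
  if (n > ncol(A)) {
    warning("budget n = ", n, " exceeds ncol(A) = ", ncol(A), "; capped")
    n <- ncol(A)
  }
  state <- foba_state_new(A, y, standardize = standardize)
  if (length(init_support) && n > 0L) {
    init_support <- utils::head(unique(as.integer(init_support)), n)
    state$support <- init_support
    state$coef <- as.numeric(.foba_refit(state, init_support))
    state$rss <- .foba_rss(state, state$support, state$coef)
  }
  ny <- sqrt(state$yy)
  converged <- FALSE
  seen <- character(0)
  it <- 0L
  while (n > 0L) {
    if (length(state$support) >= n) { converged <- TRUE; break }
    if (max(abs(.foba_corr(state))) < tol * max(ny, .Machine$double.eps)) {
      converged <- TRUE; break
    }
    it <- it + 1L
    if (it > max_iter) break
    state <- foba_forward_step(state)
    if (identical(attr(state, "stopped"), "converged")) { converged <- TRUE; break }
    state <- foba_backward_sweep(state, nu)
    sig <- paste(sort(state$support), collapse = ",")
    if (sig %in% seen) { break }   # cycling: support revisited
    seen <- c(seen, sig)
  }
  if (n == 0L) converged <- TRUE
  ord <- order(state$support)
  rho <- numeric(state$n_col)
  rho[state$support] <- state$coef / state$scale[state$support]
  structure(list(rho = rho,
                 support = state$support[ord],
                 budget_n = as.integer(n),
                 objective = as.numeric(state$rss),
                 gains = state$gains,
                 converged = converged,
                 iterations = it),
            class = "sparse_coef")
}

#' @export
print.sparse_coef <- function(x, ...) {
  cat(sprintf("sparse_coef: %d nonzero of %d (budget %d), RSS = %.6g\n",
              length(x$support), length(x$rho), x$budget_n, x$objective))
  invisible(x)
}
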