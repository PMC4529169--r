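#' Transform set for lagged predictors
#'
#' The autoregression can include elementwise transforms of the lagged
#' outcomes as extra predictor channels; the default pair
#' `{identity, exp}` linearises smooth nonlinear feedback (the exponential
#' channel carries saturating Hill-type kinetics surprisingly well).
#' Transforms are applied before lagging, which is equivalent because lags
#' are pure shifts.
#'
#' @param labels character vector naming the transforms to use, a subset of
#'   `"identity"` and `"exp"`, or a named list of pure elementwise functions.
#' @return A `transform_spec`: named list of functions with unique labels.
#' @export
transform_spec <- function(labels = c("identity", "exp")) {
  builtin <- list(identity = identity,
                  exp = function(x) {
                    y <- exp(x)
                    y[x > 700] <- Inf   # overflow guard; flagged by the caller
                    y
                  })
  if (is.character(labels)) {
    unknown <- setdiff(labels, names(builtin))
    if (length(unknown)) stop("unknown transform(s): ", paste(unknown, collapse = ", "))
    fns <- builtin[labels]
  } else if (is.list(labels)) {
    if (is.null(names(labels)) || any(names(labels) == "")) {
      stop("a transform list must be fully named")
    }
    fns <- labels
  } else stop("`labels` must be a character vector or a named list of functions")
  if (anyDuplicated(names(fns))) stop("transform labels must be unique")
  structure(fns, class = "transform_spec")
}

#' Stacked lagged design matrix for sparse vector autoregression
#'
#' Builds the regression system `y = A rho` for the autoregressive part of
#' the model: each row of `A` is one target observation \eqn{Y_{ijt}} and
#' each column is one transformed lagged predictor
#' \eqn{f(Y_{i,k,t-\tau})}, present only on rows whose target variable is
#' `j` (the block-diagonal Kronecker structure).
#'
#' Rows are ordered time-major, then target variable, then subject (subject
#' fastest) - the stacked `vec` convention.  Columns are ordered predictor
#' variable `k` fastest, then target variable `j`, then transform block,
#' then lag `tau`; this ordering is part of the public contract and is what
#' [key_of_column()] / [column_of_key()] expose.
#'
#' Under `edge_policy = "zero_pad"` rows start at `t = 2` and any lag
#' reaching before the first observation contributes an exact zero (the
#' staggered block structure); under `"drop_initial"` rows start at
#' `t = d + 1`, discarding the transient.
#'
#' @param panel a [ts_panel()].
#' @param d maximum lag (history period), `1 <= d < T`.
#' @param transforms a [transform_spec()].
#' @param edge_policy `"zero_pad"` (default) or `"drop_initial"`.
#' @return A `lag_design` with elements `A` (matrix), `y` (stacked target
#'   vector, row-aligned with `A`), `column_keys` (data.frame `k, j, tau,
#'   transform`), `row_keys` (data.frame `i, j, t`), `d`, `edge_policy`,
#'   `p`, `n_transforms`.
#'
#' @examples
#' pan <- ts_panel(matrix(rnorm(10), 2, 5))
#' des <- build_design(pan, d = 2)
#' dim(des$A)
#' @export
build_design <- function(panel, d,
                         transforms = transform_spec(),
                         edge_policy = c("zero_pad", "drop_initial")) {
  stopifnot(inherits(panel, "ts_panel"))
  edge_policy <- match.arg(edge_policy)
  N <- n_subjects(panel); p <- n_vars(panel); T <- n_times(panel)
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be a positive integer")
  if (d >= T) stop(sprintf("invalid history: d = %d must be < T = %d", d, T))

  labs <- names(transforms)
  nf <- length(labs)
  # transformed copies of the panel, with provenance check for the error message
  tr_arr <- vector("list", nf)
  for (f in seq_len(nf)) {
    v <- transforms[[f]](unclass(panel))
    if (anyNA(v) || !all(is.finite(v))) {
      bad <- which(!is.finite(v) | is.na(v), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-finite value after transform '%s' at (i = %d, k = %d, t = %d)",
                   labs[f], bad[1L], bad[2L], bad[3L]))
    }
    tr_arr[[f]] <- array(v, dim(panel))
  }

  ts_used <- if (edge_policy == "zero_pad") 2:T else (d + 1L):T
  nt <- length(ts_used)
  n_rows <- nt * p * N
  column_keys <- expand.grid(k = seq_len(p), j = seq_len(p),
                             transform = labs, tau = seq_len(d),
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)[, c("k", "j", "tau", "transform")]
  n_cols <- nrow(column_keys)

  row_keys <- data.frame(
    i = rep(seq_len(N), times = nt * p),
    j = rep(rep(seq_len(p), each = N), times = nt),
    t = rep(ts_used, each = N * p))

  A <- matrix(0, n_rows, n_cols)
  for (ci in seq_len(n_cols)) {
    k <- column_keys$k[ci]; j <- column_keys$j[ci]
    tau <- column_keys$tau[ci]
    fi <- match(column_keys$transform[ci], labs)
    rws <- which(row_keys$j == j & row_keys$t - tau >= 1L)
    if (length(rws)) {
      A[rws, ci] <- tr_arr[[fi]][cbind(row_keys$i[rws], k, row_keys$t[rws] - tau)]
    }
  }
  y <- unclass(panel)[cbind(row_keys$i, row_keys$j, row_keys$t)]

  structure(list(A = A, y = y,
                 column_keys = column_keys, row_keys = row_keys,
                 d = d, edge_policy = edge_policy, p = p,
                 n_transforms = nf, transform_labels = labs),
            class = "lag_design")
}

#' @export
print.lag_design <- function(x, ...) {
  cat(sprintf("lag_design: %d x %d (d = %d, %s, transforms: %s)\n",
              nrow(x$A), ncol(x$A), x$d, x$edge_policy,
              paste(x$transform_labels, collapse = ", ")))
  invisible(x)
}

#' Stacked target vector
#'
#' The target vector aligned row-for-row with the design matrix of
#' [build_design()]; provided separately so the stacking convention can be
#' used without building `A`.
#'
#' @inheritParams build_design
#' @return Numeric vector of stacked \eqn{Y_{ijt}} values.
#' @export
stack_targets <- function(panel, edge_policy = c("zero_pad", "drop_initial"), d = 1L) {
  stopifnot(inherits(panel, "ts_panel"))
  edge_policy <- match.arg(edge_policy)
  N <- n_subjects(panel); p <- n_vars(panel); T <- n_times(panel)
  if (edge_policy == "drop_initial" && d >= T) stop("invalid history: d >= T")
  ts_used <- if (edge_policy == "zero_pad") 2:T else (d + 1L):T
  i <- rep(seq_len(N), times = length(ts_used) * p)
  j <- rep(rep(seq_len(p), each = N), times = length(ts_used))
  t <- rep(ts_used, each = N * p)
  unclass(panel)[cbind(i, j, t)]
}

#' Column key lookup
#'
#' `key_of_column()` maps a column index of a [build_design()] matrix to its
#' interpretation `(k, j, tau, transform)`; `column_of_key()` is the inverse.
#' Ordering contract: `k` fastest, then `j`, then transform block, then
#' `tau`.
#'
#' @param design a `lag_design`.
#' @param col column index.
#' @return `key_of_column()`: a one-row data.frame `k, j, tau, transform`;
#'   `column_of_key()`: an integer column index.
#' @export
key_of_column <- function(design, col) {
  stopifnot(inherits(design, "lag_design"))
  if (any(col < 1L | col > nrow(design$column_keys))) {
    stop("column index out of range: ", paste(col, collapse = ", "))
  }
  design$column_keys[col, , drop = FALSE]
}

#' @rdname key_of_column
#' @param k,j,tau,transform key components (predictor variable, target
#'   variable, lag, transform label).
#' @export
column_of_key <- function(design, k, j, tau, transform = "identity") {
  stopifnot(inherits(design, "lag_design"))
  ck <- design$column_keys
  idx <- which(ck$k == k & ck$j == j & ck$tau == tau & ck$transform == transform)
  if (length(idx) != 1L) {
    stop(sprintf("unknown column key (k = %s, j = %s, tau = %s, transform = %s)",
                 k, j, tau, transform))
  }
  idx
}
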