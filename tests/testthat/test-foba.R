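test_that("orthonormal columns: exact representation found in one step", {
  withr::with_seed(1, {
    A <- qr.Q(qr(matrix(rnorm(160), 20, 8)))
  })
  y <- A[, 3]
  fit <- foba_solve(A, y, n = 5)
  expect_identical(fit$support, 3L)
  expect_equal(fit$rho[3], 1, tolerance = 1e-10)
  expect_lt(fit$objective, 1e-20)
})

test_that("orthogonal columns reduce to top-n screening by |A'y|", {
  withr::with_seed(2, {
    A <- qr.Q(qr(matrix(rnorm(300), 30, 10))) %*% diag(runif(10, 0.5, 2))
    y <- rnorm(30)
  })
  n <- 4
  fit <- foba_solve(A, y, n = n, nu = 0.5)
  scores <- abs(drop(crossprod(A, y)))
  expect_setequal(fit$support, order(scores, decreasing = TRUE)[seq_len(n)])
  # coefficients equal the univariate projections
  proj <- drop(crossprod(A, y)) / colSums(A^2)
  expect_equal(fit$rho[fit$support], proj[fit$support], tolerance = 1e-10)
})

test_that("zero response yields the empty model", {
  A <- matrix(rnorm(40), 10, 4)
  fit <- foba_solve(A, rep(0, 10), n = 3)
  expect_length(fit$support, 0)
  expect_equal(fit$objective, 0)
  expect_true(all(fit$rho == 0))
})

test_that("noiseless sparse recovery matches the exhaustive-search optimum", {
  withr::with_seed(3, {
    A <- matrix(rnorm(160), 20, 8)
    rho_true <- numeric(8); rho_true[c(2, 6)] <- c(1.5, -0.8)
  })
  y <- drop(A %*% rho_true)
  fit <- foba_solve(A, y, n = 5)
  expect_setequal(fit$support, c(2L, 6L))
  expect_equal(fit$rho, rho_true, tolerance = 1e-8)
  expect_equal(fit$objective, exhaustive_best_rss(A, y, 2), tolerance = 1e-8)
})

test_that("forward-step RSS matches an independent normal-equations refit", {
  withr::with_seed(4, {
    A <- matrix(rnorm(160), 20, 8)
    y <- rnorm(20)
  })
  state <- smarlme:::foba_state_new(A, y)
  rss_seen <- state$rss
  for (step in 1:5) {
    state <- foba_forward_step(state)
    co <- qr.coef(qr(A[, state$support, drop = FALSE]), y)
    rss_oracle <- sum((y - A[, state$support, drop = FALSE] %*% co)^2)
    expect_equal(state$rss, rss_oracle, tolerance = 1e-8)
    expect_lte(state$rss, rss_seen + 1e-12)   # non-increasing over forward steps
    rss_seen <- state$rss
  }
})

test_that("backward sweep removes a redundant column and respects its bound", {
  # y built from columns 1 and 2; column 3 nearly duplicates column 1, so
  # once 1 and 2 are active, 3 is deleted by the backward rule
  withr::with_seed(5, {
    A <- matrix(rnorm(120), 40, 3)
    A[, 3] <- A[, 1] + 1e-3 * rnorm(40)
    y <- drop(A[, 1:2] %*% c(1, 1))
  })
  state <- smarlme:::foba_state_new(A, y)
  for (s in 1:3) state <- foba_forward_step(state)
  rss_full <- state$rss
  swept <- foba_backward_sweep(state, nu = 0.5)
  expect_setequal(swept$support, c(1L, 2L))
  # deletion was admissible: RSS increase below nu * last forward gain
  expect_lt(swept$rss - rss_full, 0.5 * state$gains[length(state$gains)])
})

test_that("nu -> 0 disables deletion: output equals pure forward selection", {
  withr::with_seed(6, {
    A <- matrix(rnorm(200), 25, 8)
    y <- rnorm(25)
  })
  fit0 <- foba_solve(A, y, n = 5, nu = 1e-12)
  # pure forward selection oracle
  state <- smarlme:::foba_state_new(A, y)
  for (s in 1:5) state <- foba_forward_step(state)
  expect_identical(sort(fit0$support), sort(state$support))
  expect_equal(fit0$objective, state$rss, tolerance = 1e-10)
})

test_that("the greedy search attains the exhaustive optimum on small noiseless problems", {
  hits <- 0L
  n_trials <- 200L
  for (trial in seq_len(n_trials)) {
    prob <- withr::with_seed(1000 + trial, {
      m <- sample(12:20, 1)
      nc <- sample(5:10, 1)
      k <- sample(1:3, 1)
      A <- matrix(rnorm(m * nc), m, nc)
      rho <- numeric(nc)
      rho[sample(nc, k)] <- runif(k, 0.5, 2) * sample(c(-1, 1), k, replace = TRUE)
      list(A = A, y = drop(A %*% rho), k = k)
    })
    fit <- foba_solve(prob$A, prob$y, n = prob$k + 2)
    best <- exhaustive_best_rss(prob$A, prob$y, prob$k)
    if (fit$objective <= best + 1e-8 * max(1, best)) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("budget edge cases: capping, shape errors, determinism", {
  A <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  expect_warning(fit <- foba_solve(A, y, n = 9), "capped")
  expect_lte(length(fit$support), 4L)
  expect_error(foba_solve(A, rnorm(9), n = 2), "dimension mismatch")
  f1 <- foba_solve(A, y, n = 3)
  f2 <- foba_solve(A, y, n = 3)
  expect_identical(f1, f2)
})

test_that("standardization changes the selection rule, not the model class", {
  # one dominant-scale irrelevant column: raw inner products pick it first,
  # unit-norm screening does not
  withr::with_seed(8, {
    A <- matrix(rnorm(300), 50, 6)
    A[, 6] <- 40 * rnorm(50)
    y <- drop(A[, 1:2] %*% c(1, -1)) + 0.01 * rnorm(50)
  })
  std <- foba_solve(A, y, n = 2, standardize = TRUE)
  expect_setequal(std$support, c(1L, 2L))
  # coefficients are reported on the original scale
  co <- qr.coef(qr(A[, std$support]), y)
  expect_equal(unname(std$rho[std$support]), unname(co), tolerance = 1e-8)
})
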