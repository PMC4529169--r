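# the scaled-down study configuration used by these tests: fewer replicate
# subjects keep each replication fast while preserving the design
small_cfg <- osc_study_config(n_subjects = 20L)

test_that("zero-noise replications are identical and deterministic", {
  rr <- run_replications(0, 3, seed = 1, config = small_cfg)
  expect_true(all(!vapply(rr$fits, is.null, TRUE)))
  expect_identical(rr$fits[[1]]$rho, rr$fits[[2]]$rho)
  expect_identical(rr$fits[[2]]$rho, rr$fits[[3]]$rho)
  # and equal to the no-noise reference fit
  nt <- no_noise_truth(small_cfg)
  expect_equal(rr$fits[[1]]$rho, nt$truth$rho, tolerance = 1e-10)
})

test_that("a replication batch is bit-reproducible under its master seed", {
  r1 <- run_replications(0.05, 3, seed = 11, config = small_cfg)
  r2 <- run_replications(0.05, 3, seed = 11, config = small_cfg)
  for (k in 1:3) expect_identical(r1$fits[[k]]$rho, r2$fits[[k]]$rho)
})

test_that("summaries implement the declared bias and MSE arithmetic", {
  nt <- no_noise_truth(small_cfg)
  truth <- nt$truth
  pos <- truth$support[1]
  # two synthetic replications deviating by +0.01 and -0.01 at one position
  mk <- function(delta) {
    f <- truth
    f$rho[pos] <- f$rho[pos] + delta
    f
  }
  reps <- structure(list(fits = list(mk(0.01), mk(-0.01)),
                         errors = c(NA_character_, NA_character_),
                         sigma = 0, seeds = 1:2, config = small_cfg),
                    class = "replication_set")
  s <- summarize_replications(reps, truth)
  row <- s[s$position == pos, ]
  expect_equal(row$count, 2)
  expect_equal(row$bias, 0, tolerance = 1e-12)
  expect_equal(row$abs_bias, 0.01, tolerance = 1e-12)
  expect_equal(row$mse, 1e-4, tolerance = 1e-12)
  # all-identical replications: zero bias and MSE, full count
  reps0 <- structure(list(fits = list(truth, truth), errors = rep(NA_character_, 2),
                          sigma = 0, seeds = 1:2, config = small_cfg),
                     class = "replication_set")
  s0 <- summarize_replications(reps0, truth)
  expect_true(all(s0$count == 2))
  expect_true(all(abs(s0$bias) < 1e-12 & s0$mse < 1e-12))
})

test_that("zero-imputed summaries use all replications as denominator", {
  nt <- no_noise_truth(small_cfg)
  truth <- nt$truth
  pos <- truth$support[1]
  off <- truth
  off$rho[pos] <- 0   # one replication misses the position
  reps <- structure(list(fits = list(truth, off), errors = rep(NA_character_, 2),
                         sigma = 0, seeds = 1:2, config = small_cfg),
                    class = "replication_set")
  sel <- summarize_replications(reps, truth)
  all_ <- summarize_replications(reps, truth, denominator = "all")
  row_sel <- sel[sel$position == pos, ]
  row_all <- all_[all_$position == pos, ]
  expect_equal(row_sel$count, 1)
  expect_equal(row_sel$bias, 0, tolerance = 1e-12)
  expect_equal(row_all$bias, -truth$rho[pos] / 2, tolerance = 1e-12)
})

test_that("noise degrades selection and accuracy monotonically", {
  nt <- no_noise_truth(small_cfg)
  sigmas <- c(0.01, 0.05, 0.1)
  sums <- lapply(sigmas, function(s) {
    summarize_replications(run_replications(s, 10, seed = 21, config = small_cfg),
                           nt$truth)
  })
  # dominant lag-1 positions: MSE non-decreasing with noise
  lead <- nt$truth$support[which.max(abs(nt$truth$rho[nt$truth$support]))]
  mses <- vapply(sums, function(s) {
    v <- s$mse[s$position == lead]
    if (length(v)) v else NA_real_
  }, numeric(1))
  mses <- mses[!is.na(mses)]
  expect_true(all(diff(mses) >= -1e-6))
  # total selection mass over the reference support does not grow with noise
  hits <- vapply(sums, function(s) sum(s$count[s$position %in% nt$truth$support]),
                 numeric(1))
  expect_true(hits[1] >= hits[3])
})

test_that("the no-noise fit reproduces the generating curves almost perfectly", {
  nt <- no_noise_truth()
  pred <- drop(nt$design$A %*% nt$truth$rho)
  for (j in 1:2) {
    rows <- nt$design$row_keys$j == j
    r2 <- 1 - sum((nt$design$y[rows] - pred[rows])^2) /
      sum((nt$design$y[rows] - mean(nt$design$y[rows]))^2)
    expect_gt(r2, 0.99)
  }
})

test_that("solver failures are recorded without aborting the batch", {
  cfg <- small_cfg
  cfg$n_subjects <- -1L   # every replication's noise step fails
  rr <- run_replications(0.01, 2, seed = 1, config = cfg)
  expect_true(all(vapply(rr$fits, is.null, TRUE)))
  expect_true(all(!is.na(rr$errors)))
})
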