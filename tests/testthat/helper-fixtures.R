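# Small panels and designs shared across tests; everything is generated in
# code at test time.

random_panel <- function(N, p, T, seed = 1) {
  withr::with_seed(seed, ts_panel(array(rnorm(N * p * T), c(N, p, T))))
}

# scalar three-nested-loop assembly of the AR prediction
# sum_{tau,k,f} rho_{kjf tau} f(Y_{i,k,t-tau}); the independent oracle for
# the vectorised design
scalar_ar_sum <- function(panel, rho, keys, i, j, t) {
  out <- 0
  for (ci in seq_len(nrow(keys))) {
    if (keys$j[ci] != j) next
    tau <- keys$tau[ci]
    if (t - tau < 1) next
    v <- unclass(panel)[i, keys$k[ci], t - tau]
    if (keys$transform[ci] == "exp") v <- exp(v)
    out <- out + rho[ci] * v
  }
  out
}

# exhaustive best-subset least squares: the independent oracle for foba
exhaustive_best_rss <- function(A, y, kmax) {
  best <- sum(y^2)      # empty support
  for (k in seq_len(kmax)) {
    for (S in utils::combn(ncol(A), k, simplify = FALSE)) {
      co <- qr.coef(qr(A[, S, drop = FALSE]), y)
      co[is.na(co)] <- 0
      rss <- sum((y - A[, S, drop = FALSE] %*% co)^2)
      if (rss < best) best <- rss
    }
  }
  best
}
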