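#' Parameters of the delay-feedback circadian oscillator
#'
#' The two-variable Drosophila circadian model: `Y1` (PER protein) and
#' `Y2` (dCLOCK protein) are coupled through delayed feedback in the free
#' dCLOCK level (`Y2 - Y1`).  PER synthesis is activated by free dCLOCK
#' with delay `tau1`; dclock transcription is repressed by free dCLOCK
#' with delay `tau2` (so PER binding de-represses it - the positive loop).
#' The hard threshold on free dCLOCK is smoothed by a logistic with scale
#' `alpha`.
#'
#' @param v1,v2 synthesis rates (concentration per hour).
#' @param k1,k2 first-order degradation rates (per hour).
#' @param K1,K2 half-saturation constants of the activation/repression
#'   kinetics.
#' @param alpha logistic scale of the free-dCLOCK switch.
#' @param tau1,tau2 feedback delays in hours (positive integers).
#' @param dt time step (fixed at 1 hour; kept for completeness).
#' @return An `oscillator_params` list.
#' @export
oscillator_params <- function(v1 = 0.5, v2 = 0.25, k1 = 0.5, k2 = 0.5,
                              K1 = 0.3, K2 = 0.1, alpha = 10,
                              tau1 = 12L, tau2 = 12L, dt = 1) {
  pars <- list(v1 = v1, v2 = v2, k1 = k1, k2 = k2, K1 = K1, K2 = K2,
               alpha = alpha, tau1 = as.integer(tau1), tau2 = as.integer(tau2),
               dt = dt)
  if (any(unlist(pars[c("v1", "v2", "k1", "k2", "K1", "K2", "alpha")]) <= 0)) {
    stop("all kinetic parameters must be positive")
  }
  if (pars$tau1 < 1L || pars$tau2 < 1L) stop("delays must be >= 1")
  structure(pars, class = "oscillator_params")
}

#' Simulate the discretized delay-feedback oscillator
#'
#' Iterates the implicit hourly update (the unique algebraic solution of
#' the discretized kinetics, in which the new value appears linearly on
#' both sides):
#' \deqn{Y_1(t) = \frac{Y_1(t-1) + v_1 / (1 + K_1 + K_1 e^{\alpha(Y_{1,t-\tau_1} - Y_{2,t-\tau_1})})}{1 + k_1}}
#' \deqn{Y_2(t) = \frac{Y_2(t-1) + v_2 / (1 + [K_2(1 + e^{s\,\alpha(Y_{2,t-\tau_2} - Y_{1,t-\tau_2})})]^{-1})}{1 + k_2}}
#' with `s = -1` under the default `dclock_feedback = "repression"`
#' (dclock transcription repressed by free dCLOCK, the biologically
#' coherent form under which both proteins oscillate in anti-phase) and
#' `s = +1` under `"activation"` (a mirrored rendering that appears in
#' some write-ups of the discretization; it leaves dCLOCK nearly
#' constant).  The discrete-time attractor is a quasi-periodic invariant
#' circle with a near-period of about 27 hours; see the package vignette.
#'
#' @param params an [oscillator_params()].
#' @param burn_in steps discarded before retention (default 480 = 20
#'   nominal days, ample to reach the attractor); must be at least the
#'   maximum delay.
#' @param T_keep retained steps (default 72 hours).
#' @param init constant initial history `c(Y1, Y2)` for `t <= max(delay)`.
#' @param dclock_feedback `"repression"` (default) or `"activation"`.
#' @return A single-subject [ts_panel()] with variables `PER`, `dCLOCK`.
#' @export
simulate_oscillator <- function(params = oscillator_params(),
                                burn_in = 480L, T_keep = 72L,
                                init = c(0.3, 0.3),
                                dclock_feedback = c("repression", "activation")) {
  dclock_feedback <- match.arg(dclock_feedback)
  sgn <- if (dclock_feedback == "repression") -1 else 1
  maxd <- max(params$tau1, params$tau2)
  if (burn_in < maxd) stop("`burn_in` must be >= the maximum delay")
  if (T_keep < 1L) stop("`T_keep` must be >= 1")
  total <- burn_in + T_keep
  Y1 <- numeric(total + maxd); Y2 <- numeric(total + maxd)
  Y1[seq_len(maxd)] <- init[1L]; Y2[seq_len(maxd)] <- init[2L]
  pr <- params
  for (t in (maxd + 1L):(total + maxd)) {
    f1 <- pr$v1 / (1 + pr$K1 + pr$K1 *
                     exp(pr$alpha * (Y1[t - pr$tau1] - Y2[t - pr$tau1])))
    f2 <- pr$v2 / (1 + 1 / (pr$K2 * (1 + exp(sgn * pr$alpha *
                     (Y2[t - pr$tau2] - Y1[t - pr$tau2])))))
    Y1[t] <- (Y1[t - 1L] + f1) / (1 + pr$k1)
    Y2[t] <- (Y2[t - 1L] + f2) / (1 + pr$k2)
    if (!is.finite(Y1[t]) || !is.finite(Y2[t])) {
      stop("numeric blow-up at simulation step ", t - maxd)
    }
  }
  idx <- (maxd + burn_in + 1L):(maxd + total)
  ts_panel(rbind(Y1[idx], Y2[idx]), variable_names = c("PER", "dCLOCK"))
}

#' Replicate a true curve across subjects with observation noise
#'
#' Replicates the (single-subject) true trajectory across `n_subjects`
#' and adds i.i.d. Gaussian noise \eqn{N(0, \sigma^2)} per cell.
#'
#' @param truth a single-subject [ts_panel()].
#' @param sigma noise standard deviation (`>= 0`).
#' @param n_subjects number of replicate subjects.
#' @param seed integer seed (local to this call; the global RNG state is
#'   preserved).
#' @return A [ts_panel()] with `n_subjects` subjects.
#' @export
add_noise <- function(truth, sigma, n_subjects, seed) {
  stopifnot(inherits(truth, "ts_panel"), sigma >= 0, n_subjects >= 1)
  if (n_subjects(truth) != 1L) stop("`truth` must be a single-subject panel")
  p <- n_vars(truth); T <- n_times(truth)
  base <- array(rep(unclass(truth), each = n_subjects), c(n_subjects, p, T))
  noise <- withr_seed(seed, array(stats::rnorm(n_subjects * p * T, 0, sigma),
                                  c(n_subjects, p, T)))
  ts_panel(base + noise, variable_names = attr(truth, "variable_names"),
           time_unit = attr(truth, "time_unit"))
}

# evaluate `expr` under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Signal-to-noise ratio of a simulated study
#'
#' Variance of the no-noise signal divided by the noise variance
#' \eqn{\sigma^2}.  The signal variance pools both variables over the
#' retained window (the pooling convention is documented in the vignette;
#' per-variable values are returned as an attribute).
#'
#' @param truth single-subject no-noise [ts_panel()].
#' @param sigma noise standard deviation (`> 0`).
#' @return SNR (numeric scalar) with attributes `signal_variance` (pooled)
#'   and `per_variable` (named vector of per-variable variances).
#' @export
snr <- function(truth, sigma) {
  if (sigma <= 0) stop("`sigma` must be > 0 for a defined SNR")
  v_pooled <- stats::var(as.vector(unclass(truth)))
  v_per <- apply(unclass(truth), 2L, function(m) stats::var(as.vector(m)))
  names(v_per) <- attr(truth, "variable_names")
  structure(v_pooled / sigma^2,
            signal_variance = v_pooled, per_variable = v_per)
}

#' Detect the near-period of a retained trajectory
#'
#' Scans integer shifts and returns the one minimising the maximum
#' absolute mismatch `|Y(t) - Y(t - P)|` over all variables, together
#' with that mismatch.  On a quasi-periodic attractor the mismatch is
#' small but does not vanish.
#'
#' @param panel a single-subject [ts_panel()].
#' @param max_period largest shift scanned.
#' @return List `period`, `mismatch`.
#' @export
detect_period <- function(panel, max_period = floor(n_times(panel) / 2)) {
  Y <- unclass(panel)[1L, , , drop = TRUE]
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  T <- ncol(Y)
  errs <- vapply(2:max_period, function(P) {
    max(abs(Y[, (P + 1L):T, drop = FALSE] - Y[, 1L:(T - P), drop = FALSE]))
  }, numeric(1))
  best <- which.min(errs)
  list(period = best + 1L, mismatch = errs[best])
}
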