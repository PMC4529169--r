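#' Design of the synthetic blood-pressure trial
#'
#' A DASH-style parallel-arm feeding-trial structure: two outcomes (SBP,
#' DBP) measured hourly over two concatenated 24-hour periods (24 pre- +
#' 24 post-intervention points), three diet arms (control,
#' vegetable/fruit, DASH) with equal allocation, a pre/post intervention
#' indicator \eqn{\delta_t} (0 for `t <= 24`, 1 for `t >= 25`), a race
#' indicator and age as subject covariates, a subject random intercept,
#' and a sparse "circular" autoregressive structure over `d = 23` lags
#' (mass at short lags and near the daily lag 23, so the total AR
#' parameter space is \eqn{p^2 d = 92} identity-transform columns).
#'
#' The eight fixed-effect predictors are: intercept, veg/fruit arm, DASH
#' arm, control x intervention, veg/fruit x intervention, DASH x
#' intervention, race, age.  `true_beta` is on the AR-conditional scale
#' (the equilibrium level is `true_beta` effects divided by one minus the
#' total AR mass), and is shared by both outcomes.
#'
#' @param n_subjects number of subjects (default 340).
#' @param true_beta length-8 named numeric vector of generating fixed
#'   effects.
#' @param rho_entries data.frame `k, j, tau, value` of nonzero AR
#'   coefficients (identity transform) used to generate; the default has
#'   self lag-1 and lag-23 mass plus a small lag-1 cross term.
#' @param sigma_b random-intercept SD.
#' @param sigma residual SD.
#' @param age_range uniform range for age (years).
#' @param prob_race Bernoulli probability of the race indicator.
#' @return A `bp_design` list (with `timepoints = 48`, `d = 23`, `p = 2`).
#' @export
bp_design <- function(n_subjects = 340L,
                      true_beta = c(intercept = 30, veg_fruit = 0.4,
                                    dash = 0.1, control_intv = -1.1,
                                    veg_fruit_intv = -2.2, dash_intv = -2.4,
                                    race = 0.0, age = 0.08),
                      rho_entries = data.frame(
                        k = c(1L, 2L, 1L, 2L, 2L),
                        j = c(1L, 2L, 1L, 2L, 1L),
                        tau = c(1L, 1L, 23L, 23L, 1L),
                        value = c(0.35, 0.35, 0.25, 0.25, 0.10)),
                      sigma_b = 1.5, sigma = 2,
                      age_range = c(22, 75), prob_race = 0.5) {
  stopifnot(length(true_beta) == 8L, n_subjects >= 3L)
  structure(list(n_subjects = as.integer(n_subjects),
                 timepoints = 48L, pre_points = 24L,
                 p = 2L, d = 23L,
                 true_beta = true_beta, rho_entries = rho_entries,
                 sigma_b = sigma_b, sigma = sigma,
                 age_range = age_range, prob_race = prob_race),
            class = "bp_design")
}

# observation-level fixed-effect matrix for the 8-predictor BP model
bp_model_matrix <- function(arm, race, age, delta) {
  cbind(intercept = 1,
        veg_fruit = as.numeric(arm == "veg_fruit"),
        dash = as.numeric(arm == "dash"),
        control_intv = as.numeric(arm == "control") * delta,
        veg_fruit_intv = as.numeric(arm == "veg_fruit") * delta,
        dash_intv = as.numeric(arm == "dash") * delta,
        race = race,
        age = age)
}

#' Generate a synthetic blood-pressure panel
#'
#' Simulates forward
#' \deqn{Y_{ijt} = \sum_{\tau} \rho_{kj\tau} Y_{ik(t-\tau)} + x_{it}^T\beta
#'       + b_i + \epsilon_{ijt}}
#' with \eqn{b_i \sim N(0, \sigma_b^2)}, \eqn{\epsilon \sim N(0,\sigma^2)},
#' initial history set to the subject's pre-intervention equilibrium mean.
#' The pre and post series are concatenated into one 48-point series per
#' subject; by default lags are allowed to reach across the pre/post
#' boundary (`sever_boundary = TRUE` restarts the history at the
#' post-period equilibrium instead).
#'
#' This generator is a synthetic stand-in for a real feeding-trial panel:
#' it emulates the design structure (arms, intervention indicator,
#' circular AR mass, random intercepts), not any real data values.
#'
#' @param design a [bp_design()].
#' @param seed integer seed.
#' @param sever_boundary sever the AR history at the intervention boundary.
#' @return List `panel` (a [ts_panel()] `N x 2 x 48` with variables
#'   `SBP`, `DBP`), `covariates` (an observation-level [covariate_set()]
#'   aligned to the zero-pad stacked rows with `d = design$d`),
#'   `subjects` (data.frame `arm`, `race`, `age`, `b`), `truth` (list
#'   `beta`, `rho_entries`, `sigma_b`, `sigma`).
#' @export
generate_bp_panel <- function(design = bp_design(), seed = 1L,
                              sever_boundary = FALSE) {
  stopifnot(inherits(design, "bp_design"))
  N <- design$n_subjects; p <- design$p; T <- design$timepoints
  d <- design$d
  # total lag-mass matrix B[j, k] = sum_tau rho_{k j tau}; the process has a
  # finite equilibrium mu = (I - B)^{-1} fx when the row mass stays below 1
  B <- matrix(0, p, p)
  for (e in seq_len(nrow(design$rho_entries))) {
    B[design$rho_entries$j[e], design$rho_entries$k[e]] <-
      B[design$rho_entries$j[e], design$rho_entries$k[e]] +
      design$rho_entries$value[e]
  }
  if (max(rowSums(abs(B))) >= 0.98) {
    stop("explosive AR structure: per-equation lag mass >= 1")
  }
  eq_gain <- solve(diag(p) - B, rep(1, p))   # equilibrium per unit of fx
  arms <- c("control", "veg_fruit", "dash")

  sim <- withr_seed(seed, {
    arm <- rep(arms, length.out = N)[sample.int(N)]
    race <- stats::rbinom(N, 1L, design$prob_race)
    age <- stats::runif(N, design$age_range[1L], design$age_range[2L])
    b <- stats::rnorm(N, 0, design$sigma_b)
    eps <- array(stats::rnorm(N * p * T, 0, design$sigma), c(N, p, T))
    list(arm = arm, race = race, age = age, b = b, eps = eps)
  })

  re <- design$rho_entries
  beta <- design$true_beta
  # H is the lag buffer the AR terms read from; it equals the recorded
  # series except when the history is severed at the intervention boundary
  H <- array(0, c(N, p, d + T))
  X0 <- bp_model_matrix(sim$arm, sim$race, sim$age, delta = 0)
  fx0 <- drop(X0 %*% beta) + sim$b
  for (j in seq_len(p)) H[, j, seq_len(d)] <- fx0 * eq_gain[j]
  Y <- array(0, c(N, p, T))
  delta_of_t <- function(t) as.numeric(t > design$pre_points)

  for (t in seq_len(T)) {
    tt <- d + t
    if (sever_boundary && t == design$pre_points + 1L) {
      X1 <- bp_model_matrix(sim$arm, sim$race, sim$age, delta = 1)
      fx1 <- drop(X1 %*% beta) + sim$b
      for (j in seq_len(p)) H[, j, tt - seq_len(d)] <- fx1 * eq_gain[j]
    }
    Xt <- bp_model_matrix(sim$arm, sim$race, sim$age, delta = delta_of_t(t))
    fx <- drop(Xt %*% beta) + sim$b
    for (j in seq_len(p)) {
      ar <- rep(0, N)
      rj <- re[re$j == j, , drop = FALSE]
      for (e in seq_len(nrow(rj))) {
        ar <- ar + rj$value[e] * H[, rj$k[e], tt - rj$tau[e]]
      }
      ynew <- ar + fx + sim$eps[, j, t]
      if (any(abs(ynew) > 1e4)) {
        stop("explosive trajectory in synthetic BP generator (|Y| > 1e4)")
      }
      Y[, j, t] <- ynew
      H[, j, tt] <- ynew
    }
  }
  panel <- ts_panel(Y, variable_names = c("SBP", "DBP"))

  subjects <- data.frame(arm = sim$arm, race = sim$race, age = sim$age,
                         b = sim$b)
  covs <- bp_covariates(subjects, timepoints = T, pre_points = design$pre_points,
                        p = p, edge_policy = "zero_pad", d = d)

  list(panel = panel,
       covariates = covs,
       subjects = subjects,
       truth = list(beta = beta, rho_entries = re,
                    sigma_b = design$sigma_b, sigma = design$sigma))
}

#' Observation-level covariates for a synthetic blood-pressure panel
#'
#' Expands the subject table of [generate_bp_panel()] into the
#' eight-predictor fixed-effect design aligned with the stacked rows of a
#' lag design built under the given edge policy (`zero_pad` rows start at
#' `t = 2`; `drop_initial` rows start at `t = d + 1`).
#'
#' @param subjects data.frame with columns `arm`, `race`, `age` (one row
#'   per subject).
#' @param timepoints,pre_points series length and pre-intervention length.
#' @param p number of outcome variables.
#' @param edge_policy,d as used for the matching [build_design()] call.
#' @return An observation-level [covariate_set()].
#' @export
bp_covariates <- function(subjects, timepoints = 48L, pre_points = 24L,
                          p = 2L, edge_policy = c("zero_pad", "drop_initial"),
                          d = 23L) {
  edge_policy <- match.arg(edge_policy)
  N <- nrow(subjects)
  ts_used <- if (edge_policy == "zero_pad") 2:timepoints else (d + 1L):timepoints
  row_i <- rep(seq_len(N), times = length(ts_used) * p)
  row_t <- rep(ts_used, each = N * p)
  Xobs <- bp_model_matrix(subjects$arm[row_i], subjects$race[row_i],
                          subjects$age[row_i],
                          delta = as.numeric(row_t > pre_points))
  covariate_set(Xobs, subject = row_i)
}
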