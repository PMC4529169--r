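#' Read / write subject covariates as CSV
#'
#' Schema: header `subject,<covariate columns>`, one row per subject,
#' numeric covariate values.
#'
#' @param path file path.
#' @return `read_covariates()` returns a [covariate_set()] with
#'   subject-level `X` (rows ordered by subject id).
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1L] != "subject") {
    stop("covariates CSV must start with a `subject` column")
  }
  if (anyDuplicated(df$subject)) stop("duplicate subject rows in covariates CSV")
  df <- df[order(df$subject), , drop = FALSE]
  X <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("covariate columns must be numeric")
  rownames(X) <- NULL
  covariate_set(X)
}

#' @rdname read_covariates
#' @param covariates a [covariate_set()] with subject-level `X`.
#' @export
write_covariates <- function(covariates, path) {
  if (!covariates$per_subject) {
    stop("only subject-level covariate sets are written to CSV")
  }
  df <- data.frame(subject = seq_len(nrow(covariates$X)), covariates$X)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration from a YAML file
#'
#' Reads a flat YAML mapping of fit settings (`d`, `budget`, `nu`,
#' `edge_policy`, `transforms`, `tol`, `seed`, ...), filling unset entries
#' with the given defaults.
#'
#' @param path YAML file path (`NULL` returns the defaults).
#' @param defaults named list of default values.
#' @return Named list of settings.
#' @export
read_config <- function(path = NULL, defaults = list()) {
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config YAML must be a mapping")
    cfg[names(user)] <- user
  }
  cfg
}

# stable fingerprint of a config list (written into run manifests)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Write a JSON run manifest
#'
#' Records the command, settings (with an md5 fingerprint), the seed and
#' key results of a pipeline run; re-running with the settings and seed in
#' a manifest reproduces stochastic outputs bit-identically.
#'
#' @param path output JSON path.
#' @param command command label.
#' @param config named list of settings (must include any seed used).
#' @param results named list of key results (JSON-serialisable).
#' @return `path` invisibly.
#' @export
write_manifest <- function(path, command, config, results = list()) {
  jsonlite::write_json(
    list(command = command,
         package_version = as.character(utils::packageVersion("smarlme")),
         config = config,
         config_hash = config_hash(config),
         results = results),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the subcommands used by the bundled `smarlme` Rscript
#' (`inst/cli/smarlme.R`): `simulate-oscillator`, `simulate-bp`, `fit`,
#' `sweep` and `simstudy`.  Returns an exit code instead of calling
#' `quit()`, so it is testable in-process: 0 on success, 2 on a usage
#' error, 1 on a runtime failure.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit code.
#' @export
run_cli <- function(argv) {
  usage <- paste(
    "usage: smarlme <command> [options]",
    "commands:",
    "  simulate-oscillator --sigma S --subjects N --hours T --seed K --out panel.csv",
    "  simulate-bp --subjects N --seed K --out-panel bp.csv --out-cov cov.csv --out-truth truth.json",
    "  fit --panel panel.csv [--covariates cov.csv] --d D --budget N [--config model.yaml] --out fit.json",
    "  sweep --panel panel.csv [--covariates cov.csv] --d D --budgets 0:10 --out sweep.csv",
    "  simstudy --sigma S1,S2 --reps R --budget N --seed K --out table.csv",
    sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  cmd <- argv[1L]
  rest <- argv[-1L]
  opts <- tryCatch(parse_cli_options(rest),
                   error = function(e) { message("bad flags: ", conditionMessage(e),
                                                 "\n", usage); NULL })
  if (is.null(opts)) return(2L)
  handler <- switch(cmd,
                    "simulate-oscillator" = cli_simulate_oscillator,
                    "simulate-bp" = cli_simulate_bp,
                    "fit" = cli_fit,
                    "sweep" = cli_sweep,
                    "simstudy" = cli_simstudy,
                    NULL)
  if (is.null(handler)) { message("unknown command: ", cmd, "\n", usage); return(2L) }
  tryCatch({ handler(opts); 0L },
           usage_error = function(e) { message(conditionMessage(e), "\n", usage); 2L },
           error = function(e) { message("error: ", conditionMessage(e)); 1L })
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i + 1L > length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

need_opt <- function(opts, key) {
  if (is.null(opts[[key]])) {
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = paste0("missing required flag --", key),
                        call = NULL)))
  }
  opts[[key]]
}

cli_simulate_oscillator <- function(opts) {
  sigma <- as.numeric(need_opt(opts, "sigma"))
  subjects <- as.integer(need_opt(opts, "subjects"))
  hours <- as.integer(opts[["hours"]] %||% 72L)
  seed <- as.integer(need_opt(opts, "seed"))
  out <- need_opt(opts, "out")
  truth <- simulate_oscillator(T_keep = hours)
  panel <- if (sigma > 0) add_noise(truth, sigma, subjects, seed) else truth
  write_panel(panel, out)
  write_manifest(paste0(out, ".manifest.json"), "simulate-oscillator",
                 list(sigma = sigma, subjects = subjects, hours = hours,
                      seed = seed),
                 list(panel = out, n_subjects = n_subjects(panel)))
}

cli_simulate_bp <- function(opts) {
  subjects <- as.integer(need_opt(opts, "subjects"))
  seed <- as.integer(need_opt(opts, "seed"))
  out_panel <- need_opt(opts, "out-panel")
  out_cov <- need_opt(opts, "out-cov")
  out_truth <- opts[["out-truth"]]
  gen <- generate_bp_panel(bp_design(n_subjects = subjects), seed = seed)
  write_panel(gen$panel, out_panel)
  utils::write.csv(data.frame(subject = seq_len(subjects), gen$subjects),
                   out_cov, row.names = FALSE, quote = FALSE)
  if (!is.null(out_truth)) {
    jsonlite::write_json(gen$truth, out_truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  write_manifest(paste0(out_panel, ".manifest.json"), "simulate-bp",
                 list(subjects = subjects, seed = seed),
                 list(panel = out_panel, covariates = out_cov))
}

.cli_load_inputs <- function(opts) {
  panel <- read_panel(need_opt(opts, "panel"))
  covs <- if (!is.null(opts[["covariates"]])) read_covariates(opts[["covariates"]]) else NULL
  list(panel = panel, covariates = covs)
}

cli_fit <- function(opts) {
  inp <- .cli_load_inputs(opts)
  cfg <- read_config(opts[["config"]],
                     defaults = list(nu = 0.5, edge_policy = "zero_pad",
                                     transforms = c("identity", "exp"),
                                     standardize = FALSE))
  d <- as.integer(need_opt(opts, "d"))
  budget <- as.integer(need_opt(opts, "budget"))
  out <- need_opt(opts, "out")
  fit <- smarlme(inp$panel, inp$covariates, d = d, budget = budget,
                 transforms = transform_spec(cfg$transforms),
                 edge_policy = cfg$edge_policy, nu = as.numeric(cfg$nu),
                 standardize = isTRUE(cfg$standardize))
  sup <- fit$sparse$support
  result <- list(
    support = if (length(sup)) cbind(fit$column_keys[sup, , drop = FALSE],
                                     estimate = fit$sparse$rho[sup]) else NULL,
    support_size = length(sup),
    beta = if (!is.null(fit$mixed)) {
      data.frame(term = names(fit$mixed$beta), estimate = unname(fit$mixed$beta),
                 se = unname(fit$mixed$se_beta), p = unname(fit$mixed$p_beta))
    } else NULL,
    bic = fit$bic, aic = fit$aic, converged = fit$converged)
  jsonlite::write_json(result, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  if (!is.null(opts[["out-fitted"]])) {
    utils::write.csv(cbind(fit$row_keys, fitted = fit$fitted),
                     opts[["out-fitted"]], row.names = FALSE)
  }
  write_manifest(paste0(out, ".manifest.json"), "fit",
                 c(cfg, list(d = d, budget = budget,
                             seed = opts[["seed"]] %||% NA)),
                 list(support_size = length(sup), bic = fit$bic))
}

cli_sweep <- function(opts) {
  inp <- .cli_load_inputs(opts)
  d <- as.integer(need_opt(opts, "d"))
  spec <- need_opt(opts, "budgets")
  parts <- as.integer(strsplit(spec, ":", fixed = TRUE)[[1L]])
  grid <- if (length(parts) == 2L) parts[1L]:parts[2L] else as.integer(strsplit(spec, ",")[[1L]])
  out <- need_opt(opts, "out")
  sw <- bic_sweep(inp$panel, inp$covariates, d = d, n_grid = grid)
  utils::write.csv(sw$table, out, row.names = FALSE)
  write_manifest(paste0(out, ".manifest.json"), "sweep",
                 list(d = d, budgets = spec, seed = opts[["seed"]] %||% NA),
                 list(best_budget = sw$table$budget[sw$best],
                      best_bic = sw$table$bic[sw$best]))
}

cli_simstudy <- function(opts) {
  sigmas <- as.numeric(strsplit(need_opt(opts, "sigma"), ",")[[1L]])
  reps <- as.integer(need_opt(opts, "reps"))
  seed <- as.integer(need_opt(opts, "seed"))
  budget <- as.integer(opts[["budget"]] %||% 25L)
  out <- need_opt(opts, "out")
  cfg <- osc_study_config(budget = budget)
  truth <- no_noise_truth(cfg)$truth
  tabs <- lapply(sigmas, function(s) {
    rr <- run_replications(s, reps, seed, cfg)
    cbind(sigma = s, summarize_replications(rr, truth))
  })
  utils::write.csv(do.call(rbind, tabs), out, row.names = FALSE)
  write_manifest(paste0(out, ".manifest.json"), "simstudy",
                 list(sigma = sigmas, reps = reps, budget = budget, seed = seed),
                 list(table = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
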