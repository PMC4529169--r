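#' Multivariate longitudinal panel
#'
#' A `ts_panel` holds a complete, equally spaced outcome tensor
#' \eqn{Y_{ijt}} indexed by subject \eqn{i = 1..N}, variable
#' \eqn{j = 1..p} and time \eqn{t = 1..T}.  All model-fitting and
#' simulation functions in the package consume and produce this class.
#'
#' @param values numeric array of dimension `N x p x T`; a `p x T` matrix is
#'   promoted to a single-subject panel.
#' @param variable_names optional character vector of length `p`; defaults to
#'   `"Y1", "Y2", ...`.
#' @param time_unit unit label for the time axis (metadata only).
#'
#' @return An object of class `ts_panel`: the array with attributes
#'   `variable_names` and `time_unit`.
#'
#' @examples
#' y <- ts_panel(array(rnorm(2 * 2 * 10), c(2, 2, 10)),
#'               variable_names = c("SBP", "DBP"))
#' dim(y)
#' @export
ts_panel <- function(values, variable_names = NULL, time_unit = "hour") {
  if (is.matrix(values)) {
    values <- array(values, c(1L, nrow(values), ncol(values)))
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be an N x p x T array (or a p x T matrix for N = 1)")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("panel values must be finite and complete (no missing entries)")
  }
  dm <- dim(values)
  if (dm[1L] < 1L || dm[2L] < 1L || dm[3L] < 2L) {
    stop("panel requires N >= 1 subjects, p >= 1 variables, T >= 2 time points")
  }
  if (is.null(variable_names)) variable_names <- paste0("Y", seq_len(dm[2L]))
  if (length(variable_names) != dm[2L]) {
    stop("`variable_names` must have length p = ", dm[2L])
  }
  structure(values,
            variable_names = as.character(variable_names),
            time_unit = time_unit,
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  dm <- dim(x)
  cat(sprintf("ts_panel: %d subject(s) x %d variable(s) x %d time point(s) [%s]\n",
              dm[1L], dm[2L], dm[3L], attr(x, "time_unit")))
  cat("variables:", paste(attr(x, "variable_names"), collapse = ", "), "\n")
  invisible(x)
}

n_subjects <- function(panel) dim(panel)[1L]
n_vars     <- function(panel) dim(panel)[2L]
n_times    <- function(panel) dim(panel)[3L]

#' Convert a panel to/from long format
#'
#' The long format has one row per `(subject, time, variable)` cell with
#' columns `subject`, `time`, `variable`, `value`; it is the on-disk dialect
#' used by [read_panel()] and [write_panel()].
#'
#' @param x a `ts_panel`.
#' @param row.names,optional,... ignored; present for method compatibility.
#' @return A `data.frame` in long format.
#' @export
as.data.frame.ts_panel <- function(x, row.names = NULL, optional = FALSE, ...) {
  dm <- dim(x)
  vn <- attr(x, "variable_names")
  out <- expand.grid(subject = seq_len(dm[1L]),
                     variable = seq_len(dm[2L]),
                     time = seq_len(dm[3L]),
                     KEEP.OUT.ATTRS = FALSE)
  out$value <- as.vector(unclass(x))   # array order: i fastest, then j, then t
  out$variable <- vn[out$variable]
  out <- out[order(out$subject, out$time, out$variable),
             c("subject", "time", "variable", "value")]
  rownames(out) <- NULL
  out
}

#' Read / write a panel as long-format CSV
#'
#' The schema is strict: header `subject,time,variable,value`, one row per
#' cell, a complete and contiguous time grid per subject, and the same
#' variable set for every subject.  Violations are reported with the
#' offending row numbers.
#'
#' @param path file path.
#' @param time_unit passed to [ts_panel()].
#' @return `read_panel()` returns a `ts_panel`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path, time_unit = "hour") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "time", "variable", "value")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("panel CSV must have header `subject,time,variable,value`; got: ",
         paste(names(df), collapse = ","))
  }
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))
    stop("non-numeric `value` at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  key <- paste(df$subject, df$time, df$variable, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject,time,variable) at data row(s): ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  }
  subs <- sort(unique(df$subject))
  vars <- sort(unique(df$variable))
  times <- sort(unique(df$time))
  if (!all(diff(times) == diff(times)[1L])) {
    stop("time grid is not equally spaced: ", paste(times, collapse = ","))
  }
  full <- length(subs) * length(vars) * length(times)
  if (nrow(df) != full) {
    stop(sprintf("ragged panel: %d rows but %d subjects x %d variables x %d times = %d cells",
                 nrow(df), length(subs), length(vars), length(times), full))
  }
  arr <- array(NA_real_, c(length(subs), length(vars), length(times)))
  i <- match(df$subject, subs)
  j <- match(df$variable, vars)
  t <- match(df$time, times)
  arr[cbind(i, j, t)] <- df$value
  ts_panel(arr, variable_names = vars, time_unit = time_unit)
}

#' @rdname read_panel
#' @param panel a `ts_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
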