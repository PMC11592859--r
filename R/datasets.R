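#' Continuous dataset container
#'
#' A light container for tabular numeric data: a samples-by-variables matrix
#' with unique variable names and a missing-value mask. This is the input
#' type for [quantile_discretize()].
#'
#' @param values Numeric matrix, rows = samples, columns = variables.
#' @param names Character vector of unique variable names; defaults to the
#'   column names of `values`.
#' @return An object of class `continuous_dataset` with fields `values`,
#'   `names` and `missing_mask`.
#' @seealso [discrete_dataset()], [load_table()]
#' @export
continuous_dataset <- function(values, names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("`values` must be a numeric matrix")
  if (is.null(names)) names <- paste0("V", seq_len(ncol(values)))
  names <- as.character(names)
  if (length(names) != ncol(values))
    stopf("%d names supplied for %d columns", length(names), ncol(values))
  if (anyDuplicated(names)) stopf("variable names must be unique")
  colnames(values) <- names
  structure(
    list(values = values, names = names, missing_mask = is.na(values)),
    class = "continuous_dataset"
  )
}

#' Discrete dataset container
#'
#' Holds an integer state matrix (samples by variables) where column `v`
#' takes values in `0:(n_states[v] - 1)` with no missing entries. All
#' information-theoretic estimators in the package operate on this type.
#'
#' @param states Integer matrix of 0-based state codes.
#' @param names Unique variable names (default: column names or `V1..Vk`).
#' @param n_states Per-variable state count; defaults to `max(column) + 1`.
#' @param bin_edges Optional per-variable list of quantile cut points kept
#'   for provenance when the data came from [quantile_discretize()].
#' @return An object of class `discrete_dataset`.
#' @examples
#' d <- discrete_dataset(cbind(a = c(0L, 1L, 0L), b = c(1L, 1L, 0L)))
#' n_vars(d)
#' @export
discrete_dataset <- function(states, names = colnames(states),
                             n_states = NULL, bin_edges = NULL) {
  states <- as.matrix(states)
  if (anyNA(states)) stopf("discrete datasets cannot contain missing values")
  if (!is.numeric(states) || any(states != floor(states)))
    stopf("`states` must be an integer matrix")
  storage.mode(states) <- "integer"
  if (any(states < 0L)) stopf("state codes must be non-negative")
  if (is.null(names)) names <- paste0("V", seq_len(ncol(states)))
  names <- as.character(names)
  if (length(names) != ncol(states) || anyDuplicated(names))
    stopf("variable names must be unique and match the number of columns")
  observed <- apply(states, 2L, function(x) max(x) + 1L)
  if (is.null(n_states)) n_states <- observed
  n_states <- as.integer(n_states)
  if (length(n_states) != ncol(states) || any(observed > n_states))
    stopf("`n_states` inconsistent with observed state codes")
  colnames(states) <- names
  structure(
    list(states = states, names = names, n_states = n_states,
         bin_edges = bin_edges),
    class = "discrete_dataset"
  )
}

#' @export
print.continuous_dataset <- function(x, ...) {
  cat(sprintf("<continuous_dataset> %d samples x %d variables (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask)))
  invisible(x)
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("<discrete_dataset> %d samples x %d variables, states per variable %s\n",
              nrow(x$states), ncol(x$states),
              paste(range(x$n_states), collapse = "-")))
  invisible(x)
}

#' @rdname discrete_dataset
#' @param x A dataset object.
#' @export
n_vars <- function(x) UseMethod("n_vars")

#' @export
n_vars.discrete_dataset <- function(x) ncol(x$states)

#' @export
n_vars.continuous_dataset <- function(x) ncol(x$values)

#' @rdname discrete_dataset
#' @export
n_samples <- function(x) UseMethod("n_samples")

#' @export
n_samples.discrete_dataset <- function(x) nrow(x$states)

#' @export
n_samples.continuous_dataset <- function(x) nrow(x$values)

check_vars <- function(data, vars, min_len = 1L) {
  vars <- as.integer(vars)
  if (length(vars) < min_len)
    stopf("at least %d variable indices required", min_len)
  if (anyDuplicated(vars)) stopf("variable indices must be distinct")
  if (any(vars < 1L) || any(vars > n_vars(data)))
    stopf("variable index out of bounds (dataset has %d variables)", n_vars(data))
  vars
}

#' Load a delimited table as a continuous dataset
#'
#' Reads a CSV/TSV file with a header row. Cells matching a missing-value
#' sentinel (`NA`, `NaN`, `null`, or empty) set the missing mask; any other
#' non-numeric cell is a parse error naming the offending row and column.
#'
#' @param path Path to a readable delimited text file with a header row.
#' @param delimiter Field separator, `","` (default) or `"\t"`.
#' @param na_strings Character vector of missing-value sentinels.
#' @return A [continuous_dataset()].
#' @export
load_table <- function(path, delimiter = ",",
                       na_strings = c("NA", "NaN", "nan", "null", "")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      na.strings = character(0)),
    error = function(e) stopf("cannot parse %s: %s", path, conditionMessage(e))
  )
  if (nrow(raw) == 0L || ncol(raw) == 0L) stopf("no data rows in %s", path)
  vals <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    miss <- is.na(cell) | cell %in% na_strings
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stopf("non-numeric cell '%s' at row %d, column '%s'",
            cell[bad[1L]], bad[1L], colnames(raw)[j])
    vals[, j] <- num
  }
  colnames(vals) <- colnames(raw)
  continuous_dataset(vals)
}

#' Write a discrete dataset as integer CSV plus a JSON sidecar
#'
#' The CSV holds the 0-based state codes; the sidecar records per-variable
#' state counts and (when available) the quantile bin edges, so a
#' discretization can be audited or reapplied.
#'
#' @param data A [discrete_dataset()].
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_discrete <- function(data, path) {
  stopifnot(inherits(data, "discrete_dataset"))
  utils::write.csv(as.data.frame(data$states), path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(names = data$names, n_states = data$n_states,
         bin_edges = data$bin_edges %||% lapply(data$names, function(.) NULL)),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(sidecar)
}

#' Read back a discrete dataset written by [write_discrete()]
#' @param path CSV path previously passed to [write_discrete()].
#' @return A [discrete_dataset()].
#' @export
read_discrete <- function(path) {
  states <- as.matrix(utils::read.csv(path, check.names = FALSE))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    discrete_dataset(states, names = meta$names, n_states = meta$n_states)
  } else {
    discrete_dataset(states)
  }
}
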