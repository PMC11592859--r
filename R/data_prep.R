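#' Sturges-rule bin count
#'
#' Number of quantile bins for a sample of size `n_samples` under the
#' Sturges rule, `ceiling(log2(n)) + 1`. Used as the default state count
#' when discretizing continuous variables.
#'
#' @param n_samples Positive integer sample size.
#' @return A positive integer bin count.
#' @examples
#' sturges_bins(1684) # 12
#' @export
sturges_bins <- function(n_samples) {
  n_samples <- check_count(n_samples, "n_samples")
  as.integer(ceiling(log2(n_samples)) + 1L)
}

#' Quantile-discretize continuous variables
#'
#' Maps each continuous column to integer state codes by empirical-quantile
#' cut points so that bin occupancies are as equal as ties permit. Columns
#' that already hold at most `n_bins` distinct integer values (pre-existing
#' discrete variables such as sex or questionnaire scores) pass through
#' unchanged, re-coded to contiguous 0-based states.
#'
#' Ties are resolved by rank with stable ordering: all samples sharing a
#' value receive the bin of the group's smallest rank, i.e. ties break
#' toward the lower bin. This makes the mapping deterministic and monotone
#' (`x <= y` implies `state(x) <= state(y)`).
#'
#' Columns containing missing values are refused: imputation is out of
#' scope here and must happen upstream.
#'
#' @param data A [continuous_dataset()] or numeric matrix.
#' @param n_bins Positive integer, or `"sturges"` (default) for
#'   [sturges_bins()] on the sample size.
#' @return A [discrete_dataset()] with per-variable `bin_edges` recorded
#'   for genuinely discretized columns.
#' @examples
#' d <- continuous_dataset(cbind(x = rnorm(64), y = rnorm(64)))
#' quantile_discretize(d, n_bins = 4)
#' @export
quantile_discretize <- function(data, n_bins = "sturges") {
  if (is.matrix(data)) data <- continuous_dataset(data)
  stopifnot(inherits(data, "continuous_dataset"))
  n <- nrow(data$values)
  if (identical(n_bins, "sturges")) n_bins <- sturges_bins(n)
  n_bins <- check_count(n_bins, "n_bins")

  k <- ncol(data$values)
  states <- matrix(0L, n, k)
  n_states <- integer(k)
  bin_edges <- vector("list", k)
  names(bin_edges) <- data$names

  for (j in seq_len(k)) {
    x <- data$values[, j]
    if (anyNA(x))
      stopf("column '%s' has missing values; impute before discretizing",
            data$names[j])
    ux <- sort(unique(x))
    if (length(ux) == 1L) {
      warnf("column '%s' is constant: zero entropy, single state", data$names[j])
      states[, j] <- 0L
      n_states[j] <- 1L
      next
    }
    if (length(ux) <= n_bins && all(x == floor(x))) {
      # existing discrete variable: pass through, contiguous 0-based codes
      states[, j] <- match(x, ux) - 1L
      n_states[j] <- length(ux)
      next
    }
    # rank-then-cut; ties share the group's minimum rank => lower bin
    r <- rank(x, ties.method = "min")
    s <- as.integer(ceiling(r * (n_bins / n)) - 1L)
    su <- sort(unique(s))
    states[, j] <- match(s, su) - 1L
    n_states[j] <- length(su)
    bin_edges[[j]] <- unname(stats::quantile(
      x, probs = seq_len(n_bins - 1L) / n_bins, type = 1
    ))
  }
  discrete_dataset(states, names = data$names, n_states = n_states,
                   bin_edges = bin_edges)
}
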