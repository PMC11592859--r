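#' Pairwise metric matrix
#'
#' Symmetric variable-by-variable matrix of one named pairwise metric,
#' used to weight candidate selection in the guided searches and as the
#' edge ordering of the clique heuristic. Diagonal entries are `NA`
#' (self-comparisons are excluded throughout).
#'
#' Available metrics (all from plug-in entropies, bits):
#' \describe{
#'   \item{mi}{`I(i;j)`.}
#'   \item{inverse_mi}{`1 - I(i;j)/max(I)`; in `[0,1]`, 0 only at the
#'     argmax pair(s). When every pair has zero MI the maximum is
#'     degenerate and the matrix is defined as all ones (with a warning).}
#'   \item{inverse_mi_squared}{`inverse_mi^2`.}
#'   \item{conditional_entropy}{`(H(i|j) + H(j|i))/2`, the symmetrized
#'     conditional entropy.}
#'   \item{mi_ent}{entropy-MI composite: the stored values are
#'     `exp(I(i,j)/2)` with the per-variable entropies attached as an
#'     attribute; search modules compose the candidate weight
#'     `H(c) * mean_m exp(I(m,c)/2)` from these parts.}
#'   \item{vi}{variation of information `H(i)+H(j)-2 I(i;j)` (a metric).}
#'   \item{nvi}{`vi / H(i,j)` (0 when both variables are constant).}
#'   \item{overlap}{information overlap `I / min(H(i), H(j))`.}
#'   \item{noverlap}{normalized overlap `I / H(i,j)`.}
#' }
#'
#' @param data A [discrete_dataset()] with >= 2 variables.
#' @param metric Metric name (see Details).
#' @return A symmetric matrix of class `pairwise_matrix` with attributes
#'   `metric`, `entropies` (per-variable H) and `mi` (the raw MI matrix).
#' @export
pairwise_matrix <- function(data, metric = c("mi", "inverse_mi",
                                             "inverse_mi_squared",
                                             "conditional_entropy", "mi_ent",
                                             "vi", "nvi", "overlap",
                                             "noverlap")) {
  stopifnot(inherits(data, "discrete_dataset"))
  metric <- match.arg(metric)
  k <- n_vars(data)
  if (k < 2L) stopf("need at least 2 variables")
  H <- vapply(seq_len(k), function(j) joint_entropy(data, j), 0)
  mi <- matrix(NA_real_, k, k, dimnames = list(data$names, data$names))
  hij <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      h2 <- joint_entropy(data, c(i, j))
      v <- max(H[i] + H[j] - h2, 0)
      mi[i, j] <- mi[j, i] <- v
      hij[i, j] <- hij[j, i] <- h2
    }
  }
  vals <- switch(metric,
    mi = mi,
    inverse_mi = ,
    inverse_mi_squared = {
      mx <- max(mi, na.rm = TRUE)
      m <- if (mx <= 0) {
        warnf("all pairwise MI are zero; inverse_mi degenerates to all ones")
        ifelse(is.na(mi), NA_real_, 1)
      } else 1 - mi / mx
      if (metric == "inverse_mi_squared") m^2 else m
    },
    conditional_entropy = {
      m <- (outer(H, H, "+")) / 2 - mi
      diag(m) <- NA_real_
      m
    },
    mi_ent = exp(mi / 2),
    vi = {
      m <- outer(H, H, "+") - 2 * mi
      diag(m) <- NA_real_
      pmax(m, 0)
    },
    nvi = {
      m <- (outer(H, H, "+") - 2 * mi) / hij
      m[hij == 0] <- 0
      pmax(m, 0)
    },
    overlap = {
      mn <- outer(H, H, pmin)
      m <- mi / mn
      m[mn == 0] <- 0
      m
    },
    noverlap = {
      m <- mi / hij
      m[hij == 0] <- 0
      m
    }
  )
  dimnames(vals) <- list(data$names, data$names)
  structure(vals, metric = metric, entropies = H, mi = mi,
            class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> metric '%s', %d variables\n",
              attr(x, "metric"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

# Jensen-Shannon divergence among m distributions (uniform weights), bits.
jsd_multi <- function(ps) {
  kmax <- max(lengths(ps))
  ps <- lapply(ps, function(p) c(p, rep(0, kmax - length(p))))
  mix <- Reduce(`+`, ps) / length(ps)
  hfun <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hfun(mix) - mean(vapply(ps, hfun, 0))
}

# RV coefficient between column-centered one-hot expansions of two
# discrete variables; a discrete analogue of co-inertia.
rv_indicator <- function(x, y, kx, ky) {
  onehot <- function(v, k) {
    m <- matrix(0, length(v), k)
    m[cbind(seq_along(v), v + 1L)] <- 1
    m
  }
  X <- scale(onehot(x, kx), scale = FALSE)
  Y <- scale(onehot(y, ky), scale = FALSE)
  sxy <- crossprod(X, Y); sxx <- crossprod(X); syy <- crossprod(Y)
  denom <- sqrt(sum(sxx^2) * sum(syy^2))
  if (denom == 0) return(NA_real_)
  sum(sxy^2) / denom
}

pearson_chisq <- function(x, y) {
  tab <- table(x, y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e, na.rm = TRUE)
}

#' Per-triplet aggregate features
#'
#' Computes the pairwise-derived features used to characterize (and, with
#' an external regressor, predict) a triplet's synergy: MI aggregates,
#' entropy aggregates, variation-of-information sums, overlap measures,
#' the dual-entropy composite (identically the mean pairwise MI), rank
#' correlations, a pairwise chi-squared statistic, a three-distribution
#' Jensen-Shannon divergence, and a co-inertia (RV) coefficient.
#'
#' Rank correlations are computed on the original pre-discretization
#' values when `original` is supplied, else on the state codes, and are
#' aggregated as the mean absolute correlation over the three pairs. A
#' constant column makes them undefined; they are reported as `NA` rather
#' than raising an error.
#'
#' @param data A [discrete_dataset()].
#' @param triplet Three distinct variable indices.
#' @param original Optional [continuous_dataset()] aligned with `data`.
#' @return One-row data frame of named features.
#' @export
triplet_features <- function(data, triplet, original = NULL) {
  stopifnot(inherits(data, "discrete_dataset"))
  triplet <- check_vars(data, triplet, min_len = 3L)
  if (length(triplet) != 3L) stopf("`triplet` must have exactly 3 indices")
  pairs <- list(triplet[c(1, 2)], triplet[c(1, 3)], triplet[c(2, 3)])
  H <- vapply(triplet, function(j) joint_entropy(data, j), 0)
  hij <- vapply(pairs, function(p) joint_entropy(data, p), 0)
  mi <- vapply(seq_len(3L), function(m) {
    H[c(1, 1, 2)[m]] + H[c(2, 3, 3)[m]] - hij[m]
  }, 0)
  mi <- pmax(mi, 0)
  vi <- H[c(1, 1, 2)] + H[c(2, 3, 3)] - 2 * mi
  nvi <- ifelse(hij > 0, vi / hij, 0)
  mins <- pmin(H[c(1, 1, 2)], H[c(2, 3, 3)])
  ov <- ifelse(mins > 0, mi / mins, 0)
  nov <- ifelse(hij > 0, mi / hij, 0)

  rank_vals <- if (!is.null(original)) {
    lapply(triplet, function(j) original$values[, j])
  } else {
    lapply(triplet, function(j) data$states[, j])
  }
  const <- vapply(rank_vals, function(v) length(unique(v)) < 2L, TRUE)
  cor_pair <- function(method) {
    if (any(const)) return(NA_real_)
    vals <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p) {
      abs(stats::cor(rank_vals[[p[1]]], rank_vals[[p[2]]], method = method))
    }, 0)
    mean(vals)
  }
  chisq <- sum(vapply(pairs, function(p)
    pearson_chisq(data$states[, p[1]], data$states[, p[2]]), 0))
  ps <- lapply(triplet, function(j)
    tabulate(data$states[, j] + 1L, data$n_states[j]) / n_samples(data))
  rvs <- vapply(pairs, function(p)
    rv_indicator(data$states[, p[1]], data$states[, p[2]],
                 data$n_states[p[1]], data$n_states[p[2]]), 0)

  data.frame(
    mi_sum = sum(mi),
    mi_spread = max(mi) - min(mi),
    entropy_spread = max(H) - min(H),
    mi_min = min(mi),
    mi_max = max(mi),
    entropy_mean = mean(H),
    vi = sum(vi),
    nvi = sum(nvi),
    overlap = sum(ov),
    noverlap = sum(nov),
    dual_entropy = mean(H[c(1, 1, 2)] + H[c(2, 3, 3)] - hij),
    spearman = cor_pair("spearman"),
    kendall = cor_pair("kendall"),
    chisq = chisq,
    jsd3 = jsd_multi(ps),
    coinertia = mean(rvs)
  )
}

#' Export a per-triplet feature table
#'
#' One row per triplet: the three indices and names, every feature from
#' [triplet_features()], and the synergy under the selected measure(s)
#' (both raw and canonical). Column order is stable, so identical inputs
#' produce byte-identical files.
#'
#' @param data A [discrete_dataset()].
#' @param triplets List of index triples, or a 3-row/3-column matrix; use
#'   `utils::combn(n_vars(data), 3)` for all triplets.
#' @param path Output CSV path.
#' @param measures Named list of [synergy_measure()] objects to score with.
#' @param original Optional [continuous_dataset()] for rank correlations.
#' @return Invisibly, the exported data frame.
#' @export
export_feature_table <- function(data, triplets, path,
                                 measures = list(o_information = synergy_measure()),
                                 original = NULL) {
  stopifnot(inherits(data, "discrete_dataset"))
  if (is.matrix(triplets)) {
    if (nrow(triplets) != 3L) triplets <- t(triplets)
    triplets <- lapply(seq_len(ncol(triplets)), function(m) triplets[, m])
  }
  feat_cols <- names(triplet_features(
    discrete_dataset(cbind(a = 0:1, b = 0:1, c = 0:1)), 1:3))
  rows <- lapply(triplets, function(tr) {
    tr <- sort(as.integer(tr))
    f <- triplet_features(data, tr, original = original)
    base <- data.frame(i = tr[1], j = tr[2], k = tr[3],
                       label = paste(data$names[tr], collapse = ";"))
    for (mn in names(measures)) {
      raw <- measures[[mn]]$raw_fun(data, tr)
      f[[paste0(mn, "_raw")]] <- raw
      f[[paste0(mn, "_canonical")]] <- measures[[mn]]$canonical(raw)
    }
    cbind(base, f)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    empty <- stats::setNames(
      as.data.frame(matrix(numeric(0), 0,
                           4 + length(feat_cols) + 2 * length(measures))),
      c("i", "j", "k", "label", feat_cols,
        as.vector(t(outer(names(measures), c("_raw", "_canonical"), paste0)))))
    empty
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
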