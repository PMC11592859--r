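#' Plug-in entropy of a histogram
#'
#' Maximum-likelihood ("plug-in") Shannon entropy in bits of a discrete
#' distribution given as a histogram of non-negative counts. Zero-count
#' cells contribute nothing.
#'
#' @param counts Non-negative integer histogram with total count >= 1.
#' @return Entropy in bits.
#' @examples
#' entropy(c(50, 50)) # 1 bit
#' entropy(c(75, 25)) # ~0.8113 bits
#' @export
entropy <- function(counts) {
  if (length(counts) == 0L || any(counts < 0) || anyNA(counts))
    stopf("`counts` must be a non-negative histogram")
  total <- sum(counts)
  if (total < 1) stopf("all-zero histogram has no entropy")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

# Entropy in bits from a 0-based integer code vector with `nlev` levels.
entropy_codes <- function(codes, nlev) {
  p <- tabulate(codes + 1L, nlev)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

# Collapse the listed columns into a single 0-based joint code vector.
# Mixed-radix packing when the joint alphabet is small; otherwise codes are
# re-indexed through match() so tabulate() stays bounded by n_samples.
joint_codes <- function(data, vars) {
  st <- data$states
  ks <- data$n_states[vars]
  code <- as.numeric(st[, vars[1L]])
  mult <- as.numeric(ks[1L])
  if (length(vars) > 1L) {
    for (m in 2L:length(vars)) {
      code <- code + mult * as.numeric(st[, vars[m]])
      mult <- mult * ks[m]
    }
  }
  if (mult <= 2^31 - 1 && mult <= 16 * nrow(st)) {
    list(codes = as.integer(code), nlev = as.integer(mult))
  } else {
    u <- unique(code)
    list(codes = match(code, u) - 1L, nlev = length(u))
  }
}

#' Joint entropy of a set of variables
#'
#' Entropy in bits of the empirical joint distribution over the listed
#' variables of a discrete dataset.
#'
#' @param data A [discrete_dataset()].
#' @param vars One or more distinct variable indices.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(data, vars) {
  stopifnot(inherits(data, "discrete_dataset"))
  vars <- check_vars(data, vars, min_len = 1L)
  jc <- joint_codes(data, vars)
  entropy_codes(jc$codes, jc$nlev)
}

#' Mutual information between two variables
#'
#' `I(i; j) = H(i) + H(j) - H(i, j)` in bits, from plug-in entropies.
#' Symmetric and non-negative up to floating tolerance. Self-MI (`i == j`)
#' is rejected: it is excluded from every pairwise matrix in the package.
#'
#' @param data A [discrete_dataset()].
#' @param i,j Distinct variable indices.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(data, i, j) {
  stopifnot(inherits(data, "discrete_dataset"))
  if (length(i) != 1L || length(j) != 1L || i == j)
    stopf("`i` and `j` must be two distinct variable indices")
  vars <- check_vars(data, c(i, j), min_len = 2L)
  joint_entropy(data, vars[1L]) + joint_entropy(data, vars[2L]) -
    joint_entropy(data, vars)
}

#' O-information of a variable set
#'
#' The synergy-redundancy balance of `n >= 3` variables,
#' \deqn{\Omega = (n-2) H(X_1..X_n) + \sum_j [H(X_j) - H(X_{-j})],}
#' in bits. Negative values indicate a synergy-dominated set, positive
#' values redundancy domination. At `n = 3` this equals the
#' inclusion-exclusion co-information. The value is invariant under
#' permutation of the set and relabeling of states.
#'
#' @param data A [discrete_dataset()].
#' @param vars At least three distinct variable indices.
#' @return O-information in bits (raw orientation: negative = synergy).
#' @seealso [synergy_measure()] for the canonical higher-is-more-synergistic
#'   orientation used by all searches.
#' @export
o_information <- function(data, vars) {
  stopifnot(inherits(data, "discrete_dataset"))
  vars <- check_vars(data, vars, min_len = 3L)
  n <- length(vars)
  h_all <- joint_entropy(data, vars)
  acc <- (n - 2) * h_all
  for (m in seq_len(n)) {
    acc <- acc + joint_entropy(data, vars[m]) - joint_entropy(data, vars[-m])
  }
  acc
}

# Fast O-information for a triplet given raw state columns; used by the
# search inner loops where generic dispatch would dominate runtime.
o_information3_cols <- function(s1, s2, s3, k1, k2, k3) {
  h1 <- entropy_codes(s1, k1); h2 <- entropy_codes(s2, k2); h3 <- entropy_codes(s3, k3)
  c12 <- s1 + k1 * s2
  c13 <- s1 + k1 * s3
  c23 <- s2 + k2 * s3
  h12 <- entropy_codes(c12, k1 * k2)
  h13 <- entropy_codes(c13, k1 * k3)
  h23 <- entropy_codes(c23, k2 * k3)
  h123 <- entropy_codes(c12 + k1 * k2 * s3, k1 * k2 * k3)
  h1 + h2 + h3 - h12 - h13 - h23 + h123
}

#' Bias-corrected O-information
#'
#' Subtracts a permutation-null estimate of the small-sample bias from the
#' raw O-information: each of `n_perm` replicates permutes every column of
#' the set independently (destroying all dependence while preserving the
#' marginals), and the mean null O-information is subtracted from the raw
#' value. Fully reproducible from `seed`.
#'
#' @param data A [discrete_dataset()].
#' @param vars At least three distinct variable indices.
#' @param n_perm Number of permutation replicates (>= 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Bias-corrected O-information in bits.
#' @export
bias_corrected_o_information <- function(data, vars, n_perm = 100, seed = NULL) {
  stopifnot(inherits(data, "discrete_dataset"))
  vars <- check_vars(data, vars, min_len = 3L)
  n_perm <- check_count(n_perm, "n_perm")
  raw <- o_information(data, vars)
  n <- n_samples(data)
  null_mean <- with_seed(seed, {
    tot <- 0
    sub <- data$states[, vars, drop = FALSE]
    for (b in seq_len(n_perm)) {
      perm <- sub
      for (m in seq_along(vars)) perm[, m] <- perm[sample.int(n), m]
      d <- discrete_dataset(perm, names = as.character(seq_along(vars)),
                            n_states = data$n_states[vars])
      tot <- tot + o_information(d, seq_along(vars))
    }
    tot / n_perm
  })
  raw - null_mean
}

#' Minimal-mutual-information PID synergy (bivariate)
#'
#' Synergy atom of the minimal-mutual-information (MMI) bivariate partial
#' information decomposition: the redundancy between two sources about a
#' target is anchored at `max(I(t;s1), I(t;s2))` for the synergy atom, so
#' \deqn{Syn = I(t; s_1, s_2) - \max(I(t;s_1), I(t;s_2)).}
#' Non-negative up to floating tolerance; shipped as the optimizer-free
#' built-in realization of the pluggable PID interface.
#'
#' @param data A [discrete_dataset()].
#' @param sources Two distinct source variable indices.
#' @param target Target variable index, distinct from both sources.
#' @return Synergy in bits.
#' @export
mmi_pid_synergy <- function(data, sources, target) {
  stopifnot(inherits(data, "discrete_dataset"))
  if (length(sources) != 2L || length(target) != 1L)
    stopf("`sources` must be two indices and `target` one")
  idx <- check_vars(data, c(sources, target), min_len = 3L)
  s1 <- idx[1L]; s2 <- idx[2L]; t <- idx[3L]
  ht <- joint_entropy(data, t)
  i_joint <- ht + joint_entropy(data, c(s1, s2)) - joint_entropy(data, c(s1, s2, t))
  i1 <- mutual_information(data, s1, t)
  i2 <- mutual_information(data, s2, t)
  i_joint - max(i1, i2)
}

#' Improvement factor of a pair about a target
#'
#' Ratio of the joint mutual information of two variables about a target to
#' the sum of their individual pairwise MI values,
#' `I(a,b; t) / (I(a;t) + I(b;t))`. Values above 1 flag super-additive
#' (synergistic) joint information. When the denominator is at or below
#' `eps` the factor is undefined and an error is raised rather than
#' silently returning infinity (an exact XOR has zero pairwise MI).
#'
#' @param data A [discrete_dataset()].
#' @param pair Two distinct variable indices.
#' @param target Target variable index.
#' @param eps Denominator tolerance in bits (default `1e-12`).
#' @return Dimensionless improvement factor.
#' @seealso [improvement_factor_all()] for all three orientations of a
#'   triplet at once.
#' @export
improvement_factor <- function(data, pair, target, eps = 1e-12) {
  stopifnot(inherits(data, "discrete_dataset"))
  if (length(pair) != 2L || length(target) != 1L)
    stopf("`pair` must be two indices and `target` one")
  idx <- check_vars(data, c(pair, target), min_len = 3L)
  a <- idx[1L]; b <- idx[2L]; t <- idx[3L]
  ia <- mutual_information(data, a, t)
  ib <- mutual_information(data, b, t)
  denom <- ia + ib
  if (denom <= eps)
    stopf("undefined improvement factor: pairwise MI sum %.3g <= eps", denom)
  i_joint <- joint_entropy(data, t) + joint_entropy(data, c(a, b)) -
    joint_entropy(data, c(a, b, t))
  i_joint / denom
}

#' @rdname improvement_factor
#' @param triplet Three distinct variable indices; each in turn plays the
#'   target role (which orientation is relevant is application-specific, so
#'   all three are reported).
#' @return For `improvement_factor_all()`: a data frame with one row per
#'   orientation (`target`, `factor`; `NA` where undefined).
#' @export
improvement_factor_all <- function(data, triplet, eps = 1e-12) {
  triplet <- check_vars(data, triplet, min_len = 3L)
  if (length(triplet) != 3L) stopf("`triplet` must have exactly 3 indices")
  res <- lapply(seq_len(3L), function(m) {
    f <- tryCatch(improvement_factor(data, triplet[-m], triplet[m], eps = eps),
                  error = function(e) NA_real_)
    data.frame(target = triplet[m], factor = f)
  })
  do.call(rbind, res)
}

#' Bootstrap significance of a synergy score
#'
#' Percentile bootstrap over resampled rows for the raw value of a synergy
#' measure on one variable set. A set is declared significant under the
#' dual condition: the confidence interval excludes zero AND the bootstrap
#' p-value falls below `alpha`. Degenerate resamples (a column collapsing
#' to a single state) are skipped and counted.
#'
#' @param data A [discrete_dataset()].
#' @param vars Variable set to test.
#' @param measure A [synergy_measure()] (default O-information).
#' @param n_boot Bootstrap replicates; >= 100 recommended.
#' @param alpha Significance level for both the CI and the p-value.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `observed` (raw value), `ci` (percentile interval),
#'   `p_value`, `significant`, and `n_degenerate`.
#' @export
bootstrap_significance <- function(data, vars, measure = synergy_measure(),
                                   n_boot = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(data, "discrete_dataset"))
  vars <- check_vars(data, vars, min_len = 2L)
  n_boot <- check_count(n_boot, "n_boot")
  n <- n_samples(data)
  observed <- measure$raw_fun(data, vars)
  boots <- with_seed(seed, {
    out <- numeric(n_boot)
    keep <- logical(n_boot)
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      sub <- data$states[rows, vars, drop = FALSE]
      if (any(apply(sub, 2L, function(x) length(unique(x))) < 2L)) next
      d <- discrete_dataset(sub, names = as.character(seq_along(vars)),
                            n_states = data$n_states[vars])
      out[b] <- measure$raw_fun(d, seq_along(vars))
      keep[b] <- TRUE
    }
    list(values = out[keep], n_degenerate = sum(!keep))
  })
  if (boots$n_degenerate > 0)
    warnf("%d degenerate bootstrap resamples skipped", boots$n_degenerate)
  v <- boots$values
  if (length(v) < 2L) stopf("too few usable bootstrap replicates")
  ci <- stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  # two-sided bootstrap p-value for H0: raw value = 0 (add-one adjusted)
  p <- 2 * min((sum(v <= 0) + 1) / (length(v) + 1),
               (sum(v >= 0) + 1) / (length(v) + 1))
  p <- min(p, 1)
  list(observed = observed, ci = ci, p_value = p,
       significant = (ci[1] > 0 || ci[2] < 0) && p < alpha,
       n_degenerate = boots$n_degenerate)
}

#' Size of the fixed-cardinality search space
#'
#' Exact binomial coefficient `C(k, n)`: the number of distinct variable
#' sets of size `n` drawn from `k` variables. Computed with integer-exact
#' incremental arithmetic (each partial product is an integer).
#'
#' @param k Number of variables (>= 0).
#' @param n Set size, `0 <= n <= k`.
#' @return Exact count as a double (integral; errors past 2^53).
#' @examples
#' search_space_size(400, 3) # 10586800
#' @export
search_space_size <- function(k, n) {
  k <- check_count(k, "k", min = 0L)
  n <- check_count(n, "n", min = 0L)
  if (n > k) stopf("`n` must not exceed `k`")
  n <- min(n, k - n)
  res <- 1
  if (n > 0) {
    for (i in seq_len(n)) res <- (res * (k - n + i)) / i
  }
  if (res > 2^53) stopf("C(%d, %d) exceeds exact double range", k, n)
  res
}

# ---- synergy measures and records ------------------------------------------

#' Synergy measures with a canonical orientation
#'
#' A `synergy_measure` bundles a raw scoring function with its orientation
#' so every search can maximize a single canonical score where larger
#' always means more synergistic. Raw O-information is negated
#' (negative = synergy-dominated); PID synergy is already non-negative
#' and passes through. Custom measures plug in via `score_fun`.
#'
#' For the MMI-PID measure on a triplet, the score is the maximum synergy
#' over the three target orientations (the most synergistic reading of the
#' set); it is defined for order-3 sets only.
#'
#' @param name `"o_information"`, `"mmi_pid"`, or a label for a custom
#'   measure supplied through `score_fun`.
#' @param bias_correction For O-information, subtract the permutation-null
#'   mean (see [bias_corrected_o_information()])?
#' @param n_perm Permutation replicates for the bias correction.
#' @param score_fun Optional `function(data, vars)` returning a raw value
#'   for a custom measure.
#' @param direction `"negate"` or `"identity"`: how raw values map to the
#'   canonical higher-is-more-synergistic scale (required for custom
#'   measures; fixed for the built-ins).
#' @return An object of class `synergy_measure` with fields `name`,
#'   `raw_fun`, `canonical` and `direction`.
#' @export
synergy_measure <- function(name = c("o_information", "mmi_pid"),
                            bias_correction = FALSE, n_perm = 100,
                            score_fun = NULL,
                            direction = c("negate", "identity")) {
  if (!is.null(score_fun)) {
    direction <- match.arg(direction)
    stopifnot(is.function(score_fun), is.character(name))
    canon <- if (direction == "negate") function(x) -x else identity
    return(structure(list(name = name, raw_fun = score_fun,
                          canonical = canon, direction = direction),
                     class = "synergy_measure"))
  }
  name <- match.arg(name)
  if (name == "o_information") {
    raw_fun <- if (bias_correction) {
      function(data, vars) bias_corrected_o_information(data, vars, n_perm = n_perm)
    } else {
      function(data, vars) o_information(data, vars)
    }
    label <- if (bias_correction) "o_information_bc" else "o_information"
    structure(list(name = label, raw_fun = raw_fun,
                   canonical = function(x) -x, direction = "negate"),
              class = "synergy_measure")
  } else {
    raw_fun <- function(data, vars) {
      if (length(vars) != 3L)
        stopf("the MMI-PID measure scores order-3 sets only")
      max(mmi_pid_synergy(data, vars[c(2L, 3L)], vars[1L]),
          mmi_pid_synergy(data, vars[c(1L, 3L)], vars[2L]),
          mmi_pid_synergy(data, vars[c(1L, 2L)], vars[3L]))
    }
    structure(list(name = "mmi_pid", raw_fun = raw_fun,
                   canonical = identity, direction = "identity"),
              class = "synergy_measure")
  }
}

#' @export
print.synergy_measure <- function(x, ...) {
  cat(sprintf("<synergy_measure> %s (canonical = %s raw)\n", x$name,
              if (x$direction == "negate") "-" else "+"))
  invisible(x)
}

# Scoring closure with a per-dataset memo cache. Every score request counts
# as one oracle call (the cache only saves wall time, not bookkeeping, so
# call-count contracts of the searches stay exact). A fast path covers
# uncorrected O-information on triplets, the searches' dominant workload.
make_scorer <- function(data, measure, cache = TRUE) {
  calls <- 0L
  memo <- new.env(parent = emptyenv())
  fast3 <- identical(measure$name, "o_information")
  st <- data$states
  ks <- data$n_states
  raw_of <- function(vars) {
    if (fast3 && length(vars) == 3L) {
      o_information3_cols(st[, vars[1L]], st[, vars[2L]], st[, vars[3L]],
                          ks[vars[1L]], ks[vars[2L]], ks[vars[3L]])
    } else {
      measure$raw_fun(data, vars)
    }
  }
  score <- function(vars) {
    calls <<- calls + 1L
    if (!cache) return(measure$canonical(raw_of(vars)))
    key <- set_key(vars)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- measure$canonical(raw_of(vars))
    memo[[key]] <- val
    val
  }
  list(score = score, calls = function() calls)
}

new_records <- function(sets, raw, canonical, measure_name, var_names) {
  # lexicographic tie-break on full index tuples
  keys <- vapply(sets, function(s) paste(sprintf("%06d", s), collapse = ","), "")
  ord <- order(-canonical, keys)
  df <- data.frame(
    rank = seq_along(sets),
    indices = vapply(sets, function(s) paste(s, collapse = ";"), "")[ord],
    label = vapply(sets, function(s)
      paste(var_names[s], collapse = ";"), "")[ord],
    raw_value = raw[ord],
    canonical_score = canonical[ord],
    measure = rep(measure_name, length(sets)),
    stringsAsFactors = FALSE
  )
  df$set <- I(sets[ord])
  class(df) <- c("synergy_records", "data.frame")
  df
}

#' Exhaustively score all fixed-size variable sets
#'
#' Enumerates every `C(k, n)` variable set, scores it with the chosen
#' synergy measure, and returns the records sorted by canonical score
#' (higher = more synergistic), ties broken lexicographically by indices.
#' Serves as ground truth for validating the guided searches; refuses to
#' run past `cap` enumerated sets.
#'
#' @param data A [discrete_dataset()].
#' @param n Set size (>= 3 for O-information, 3 for MMI-PID).
#' @param measure A [synergy_measure()].
#' @param top_m Optionally keep only the strongest `top_m` records.
#' @param cap Refuse to enumerate more than this many sets (default 2e5);
#'   use [anneal()], [pso_optimize()] or [clique_scan()] beyond it.
#' @return A `synergy_records` data frame: `rank`, `indices` (";"-joined,
#'   1-based), `label`, `raw_value`, `canonical_score`, `measure`, and a
#'   `set` list column of integer index vectors.
#' @export
brute_force_scan <- function(data, n = 3, measure = synergy_measure(),
                             top_m = NULL, cap = 2e5) {
  stopifnot(inherits(data, "discrete_dataset"))
  n <- check_count(n, "n", min = 2L)
  k <- n_vars(data)
  if (k < n) stopf("dataset has %d variables, need at least %d", k, n)
  total <- search_space_size(k, n)
  if (total > cap)
    stopf(paste("C(%d, %d) = %s sets exceeds the enumeration cap (%s);",
                "use a search module (anneal, pso_optimize, clique_scan)"),
          k, n, format(total, big.mark = ","), format(cap, big.mark = ","))
  combs <- utils::combn(k, n)
  scorer <- make_scorer(data, measure, cache = FALSE)
  raw_dir <- measure$direction
  canonical <- numeric(ncol(combs))
  for (m in seq_len(ncol(combs))) canonical[m] <- scorer$score(combs[, m])
  raw <- if (raw_dir == "negate") -canonical else canonical
  sets <- lapply(seq_len(ncol(combs)), function(m) combs[, m])
  rec <- new_records(sets, raw, canonical, measure$name, data$names)
  if (!is.null(top_m)) rec <- rec[seq_len(min(top_m, nrow(rec))), , drop = FALSE]
  rec
}

#' Write synergy records to CSV
#'
#' Deterministic column order: rank, indices, label, raw_value,
#' canonical_score, measure.
#'
#' @param records A `synergy_records` data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_records <- function(records, path) {
  cols <- c("rank", "indices", "label", "raw_value", "canonical_score", "measure")
  utils::write.csv(as.data.frame(records)[, cols], path, row.names = FALSE)
  invisible(path)
}
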