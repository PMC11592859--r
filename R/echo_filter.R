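# Echo regularization of synergy-record lists.
#
# An "echo" is a spurious synergistic set created when a strong pairwise
# association makes two variables nearly interchangeable inside a genuine
# synergistic set. The filters below remove such near-duplicates from a
# ranked record list.

sorted_records <- function(records) {
  if (is.unsorted(-records$canonical_score)) {
    warnf("records not sorted by canonical score; re-sorting")
    records <- records[order(-records$canonical_score), , drop = FALSE]
    records$rank <- seq_len(nrow(records))
  }
  records
}

new_filter_result <- function(records, accepted_idx, rejected_idx,
                              partner, quantity, parameters) {
  accepted <- records[accepted_idx, , drop = FALSE]
  rejected <- records[rejected_idx, , drop = FALSE]
  rejected$partner_indices <- vapply(partner, function(s)
    paste(s, collapse = ";"), "")
  rejected$deciding_quantity <- quantity
  structure(list(accepted = accepted, rejected = rejected,
                 parameters = parameters),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d accepted, %d rejected\n",
              nrow(x$accepted), nrow(x$rejected)))
  invisible(x)
}

#' MI-threshold echo filter
#'
#' Iteratively accepts the most synergistic remaining record; for every
#' lower-ranked remaining record sharing all but one variable with it, the
#' MI between the two non-shared variables decides: above `threshold` the
#' lower-ranked record is removed as an echo. The accepted list keeps the
#' original rank order, so surviving records have both high synergy and
#' low cross-record mutual information.
#'
#' @param records A `synergy_records` data frame sorted by canonical score
#'   descending (unsorted input is re-sorted with a warning).
#' @param mi A [pairwise_matrix()] of metric `"mi"` (or any matrix whose
#'   `[x, y]` entry is the deciding pairwise quantity).
#' @param threshold Rejection threshold on the non-shared pair's MI
#'   (>= 0).
#' @param top_n Only the strongest `top_n` records are filtered (default
#'   all).
#' @return A `filter_result`: `accepted` and `rejected` record frames (the
#'   latter with `partner_indices` and `deciding_quantity` columns) plus
#'   the filter `parameters`.
#' @export
mi_threshold_filter <- function(records, mi, threshold, top_n = NULL) {
  if (threshold < 0) stopf("`threshold` must be non-negative")
  records <- sorted_records(records)
  if (!is.null(top_n)) records <- records[seq_len(min(top_n, nrow(records))), ]
  m <- nrow(records)
  sets <- records$set
  status <- rep("pending", m)
  partner <- vector("list", m)
  quantity <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (status[i] != "pending") next
    status[i] <- "accepted"
    s <- sets[[i]]
    for (j in seq_len(m)) {
      if (j <= i || status[j] != "pending") next
      r <- sets[[j]]
      shared <- intersect(s, r)
      if (length(shared) != length(s) - 1L) next
      x <- setdiff(s, shared)
      y <- setdiff(r, shared)
      q <- unclass(mi)[x, y]
      if (q > threshold) {
        status[j] <- "rejected"
        partner[[j]] <- s
        quantity[j] <- q
      }
    }
  }
  acc <- which(status == "accepted")
  rej <- which(status == "rejected")
  new_filter_result(records, acc, rej, partner[rej], quantity[rej],
                    list(filter = "mi_threshold", threshold = threshold,
                         top_n = top_n %||% m))
}

#' Merged-set echo filter
#'
#' Iteratively takes the most synergistic remaining set `S`; for every
#' remaining set `R` sharing all but one element with `S`, the synergy of
#' the merged set (the union of `S` and `R`, order `n + 1`) is computed. If the merged
#' set scores below `R` (canonical scale by default), `R` adds nothing
#' beyond the union and is rejected as an echo. `S` is then accepted, both
#' groups are removed, and the loop repeats until no records remain.
#'
#' @param records A sorted `synergy_records` data frame.
#' @param data The [discrete_dataset()] the records were scored on.
#' @param measure A [synergy_measure()] used for the merged sets.
#' @param compare `"canonical"` (default; reject when the canonical score
#'   of the union falls below that of `R`) or `"raw"` (the literal
#'   lower-raw-value reading; for O-information the two disagree in
#'   sign).
#' @return A `filter_result`; the deciding quantity is the merged set's
#'   score on the chosen scale.
#' @export
merged_set_filter <- function(records, data, measure = synergy_measure(),
                              compare = c("canonical", "raw")) {
  compare <- match.arg(compare)
  records <- sorted_records(records)
  m <- nrow(records)
  sets <- records$set
  k <- n_vars(data)
  val_of <- function(raw) if (compare == "canonical") measure$canonical(raw)
                          else raw
  rec_val <- val_of(records$raw_value)
  status <- rep("pending", m)
  partner <- vector("list", m)
  quantity <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (status[i] != "pending") next
    s <- sets[[i]]
    for (j in seq_len(m)) {
      if (j == i || status[j] != "pending") next
      r <- sets[[j]]
      if (length(intersect(s, r)) != length(s) - 1L) next
      u <- sort(union(s, r))
      if (length(u) > k) {
        warnf("merged set exceeds variable count; comparison skipped")
        next
      }
      uval <- val_of(measure$raw_fun(data, u))
      if (uval < rec_val[j]) {
        status[j] <- "rejected"
        partner[[j]] <- s
        quantity[j] <- uval
      }
    }
    if (status[i] == "pending") status[i] <- "accepted"
  }
  acc <- which(status == "accepted")
  rej <- which(status == "rejected")
  new_filter_result(records, acc, rej, partner[rej], quantity[rej],
                    list(filter = "merged_set", compare = compare))
}

#' Grid scan of the MI-threshold filter
#'
#' Runs [mi_threshold_filter()] for every combination of list depth
#' (`top_n_grid`) and MI threshold (`threshold_grid`) and records the
#' proportion of records accepted and rejected in each cell — the
#' echo-prevalence landscape of a result list.
#'
#' @param records A sorted `synergy_records` data frame.
#' @param mi Pairwise MI matrix (see [mi_threshold_filter()]).
#' @param top_n_grid Vector of list depths.
#' @param threshold_grid Vector of MI thresholds.
#' @return List of two `length(top_n_grid)` by `length(threshold_grid)`
#'   proportion matrices, `accepted` and `rejected` (rows named by depth,
#'   columns by threshold; each cell pair sums to 1).
#' @export
echo_grid_scan <- function(records, mi, top_n_grid, threshold_grid) {
  if (!length(top_n_grid) || !length(threshold_grid))
    stopf("grids must be non-empty")
  acc <- matrix(NA_real_, length(top_n_grid), length(threshold_grid),
                dimnames = list(top_n_grid, signif(threshold_grid, 4)))
  rej <- acc
  for (a in seq_along(top_n_grid)) {
    for (b in seq_along(threshold_grid)) {
      fr <- mi_threshold_filter(records, mi, threshold_grid[b],
                                top_n = top_n_grid[a])
      tot <- nrow(fr$accepted) + nrow(fr$rejected)
      acc[a, b] <- nrow(fr$accepted) / tot
      rej[a, b] <- nrow(fr$rejected) / tot
    }
  }
  list(accepted = acc, rejected = rej)
}

#' Substitution robustness of highly synergistic sets
#'
#' For each highly correlated variable pair `(a, b)` and each direction,
#' takes every record at or above `synergy_cutoff` (canonical scale) that
#' contains the source variable, substitutes the partner for it,
#' re-scores, and reports `100 * k / N`: the percentage of eligible
#' records still at or above the cutoff after substitution. A substitution
#' that would duplicate an index makes that record ineligible. High
#' percentages mean the pair is interchangeable inside synergistic sets
#' (echo-like); low percentages show that dropping one of two correlated
#' variables before the synergy analysis would lose genuine synergies.
#'
#' @param data A [discrete_dataset()].
#' @param records A `synergy_records` data frame.
#' @param correlated_pairs List of length-2 integer vectors `(a, b)`.
#' @param synergy_cutoff Canonical-score cutoff defining "highly
#'   synergistic" (explicit; no default).
#' @param measure A [synergy_measure()].
#' @return Data frame with one row per pair and direction: `from`, `to`,
#'   `n_eligible`, `n_retained`, `percentage` (`NA` when no record is
#'   eligible).
#' @export
substitution_robustness <- function(data, records, correlated_pairs,
                                    synergy_cutoff,
                                    measure = synergy_measure()) {
  stopifnot(inherits(data, "discrete_dataset"))
  rows <- list()
  for (pair in correlated_pairs) {
    pair <- as.integer(pair)
    if (length(pair) != 2L || pair[1] == pair[2])
      stopf("correlated pairs must be two distinct indices")
    for (dir in list(pair, rev(pair))) {
      a <- dir[1]; b <- dir[2]
      high <- records[records$canonical_score >= synergy_cutoff, , drop = FALSE]
      has_a <- vapply(high$set, function(s) a %in% s, TRUE)
      cand <- high$set[has_a]
      eligible <- 0L
      retained <- 0L
      for (s in cand) {
        if (b %in% s) next  # substitution would duplicate an index
        eligible <- eligible + 1L
        sub <- sort(c(setdiff(s, a), b))
        sc <- measure$canonical(measure$raw_fun(data, sub))
        if (sc >= synergy_cutoff) retained <- retained + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        from = a, to = b, n_eligible = eligible, n_retained = retained,
        percentage = if (eligible > 0) 100 * retained / eligible else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a filter result to CSV files
#'
#' Serializes `accepted` and `rejected` (with partner and deciding
#' quantity) to two CSVs with deterministic column order.
#'
#' @param result A `filter_result`.
#' @param accepted_path,rejected_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_filter_result <- function(result, accepted_path, rejected_path) {
  stopifnot(inherits(result, "filter_result"))
  cols <- c("rank", "indices", "label", "raw_value", "canonical_score",
            "measure")
  utils::write.csv(as.data.frame(result$accepted)[, cols], accepted_path,
                   row.names = FALSE)
  utils::write.csv(
    as.data.frame(result$rejected)[, c(cols, "partner_indices",
                                       "deciding_quantity")],
    rejected_path, row.names = FALSE)
  invisible(c(accepted_path, rejected_path))
}
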