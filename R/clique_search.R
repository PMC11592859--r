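#' Harvest cliques while inserting edges in descending metric order
#'
#' Deterministic heuristic: sort all variable pairs by a pairwise metric,
#' insert edges one at a time in descending order (ties broken
#' lexicographically by index pair), and after each insertion `(u, v)`
#' collect every new `set_size`-clique containing that edge. For the
#' default `set_size = 3` these are the triangles `{u, v, w}` over the
#' common neighborhood of `u` and `v`. Harvesting stops once `max_cliques`
#' cliques have been collected (a single insertion may complete several
#' cliques at once; the list is truncated to the budget) or the edges are
#' exhausted.
#'
#' Note that a pure parity (XOR-type) triplet has exactly zero pairwise
#' MI, so under the `mi` metric its edges are inserted last and the
#' triplet is found late or never: the right metric depends on the
#' synergy measure being targeted.
#'
#' @param data A [discrete_dataset()] (used only when `metric` is given by
#'   name).
#' @param metric A [pairwise_matrix()], or a metric name passed to
#'   [pairwise_matrix()].
#' @param max_cliques Clique budget (>= 1), e.g. 1000.
#' @param set_size Clique order `n >= 3`; orders above 3 grow
#'   combinatorially and trigger a warning.
#' @return Object of class `clique_list`: data frame with `rank`,
#'   `indices`, `edge_index` (insertion index of the completing edge),
#'   `edge_weight`, plus a `set` list column; attributes `metric` and
#'   `n_edges_inserted`.
#' @export
clique_scan <- function(data, metric = "mi", max_cliques = 1000,
                        set_size = 3) {
  max_cliques <- check_count(max_cliques, "max_cliques")
  set_size <- check_count(set_size, "set_size", min = 3L)
  if (set_size > 3L)
    warnf("set_size %d cliques grow combinatorially; expect slow harvests",
          set_size)
  pm <- if (inherits(metric, "pairwise_matrix")) metric
        else pairwise_matrix(data, metric)
  w <- unclass(pm)
  k <- nrow(w)
  if (any(!is.finite(w[upper.tri(w)]))) stopf("metric matrix must be finite")
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[pairs], pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]

  adj <- matrix(FALSE, k, k)
  sets <- list()
  edge_idx <- integer()
  edge_w <- numeric()
  n_inserted <- 0L
  for (e in seq_len(nrow(pairs))) {
    u <- pairs[e, 1L]; v <- pairs[e, 2L]
    adj[u, v] <- adj[v, u] <- TRUE
    n_inserted <- e
    common <- which(adj[u, ] & adj[v, ])
    common <- setdiff(common, c(u, v))
    if (length(common) >= set_size - 2L) {
      subsets <- if (set_size == 3L) as.list(common)
                 else utils::combn(common, set_size - 2L, simplify = FALSE)
      for (s in subsets) {
        if (length(s) > 1L && !all(adj[t(utils::combn(s, 2L))])) next
        sets[[length(sets) + 1L]] <- sort(c(u, v, s))
        edge_idx <- c(edge_idx, e)
        edge_w <- c(edge_w, w[u, v])
      }
    }
    if (length(sets) >= max_cliques) break
  }
  keep <- seq_len(min(length(sets), max_cliques))
  df <- data.frame(
    rank = keep,
    indices = vapply(sets[keep], function(s) paste(s, collapse = ";"), ""),
    edge_index = edge_idx[keep],
    edge_weight = edge_w[keep],
    stringsAsFactors = FALSE
  )
  df$set <- I(sets[keep])
  structure(df, metric = attr(pm, "metric"), n_edges_inserted = n_inserted,
            class = c("clique_list", "data.frame"))
}

#' Score harvested cliques with a synergy measure
#'
#' Each clique becomes a synergy record; records are returned both in
#' clique-formation order (`formation`) and sorted by canonical score
#' (`ranked`).
#'
#' @param data A [discrete_dataset()].
#' @param cliques A `clique_list` from [clique_scan()].
#' @param measure A [synergy_measure()].
#' @return List with elements `formation` and `ranked`, both
#'   `synergy_records` data frames (the formation-order copy keeps the
#'   clique rank and creating-edge columns).
#' @export
score_cliques <- function(data, cliques, measure = synergy_measure()) {
  stopifnot(inherits(data, "discrete_dataset"),
            inherits(cliques, "clique_list"))
  sets <- cliques$set
  if (length(sets) == 0L) {
    empty <- new_records(list(), numeric(), numeric(), measure$name,
                         data$names)
    return(list(formation = cbind(as.data.frame(cliques),
                                  raw_value = numeric(0),
                                  canonical_score = numeric(0)),
                ranked = empty))
  }
  raw <- vapply(sets, function(s) measure$raw_fun(data, s), 0)
  canonical <- measure$canonical(raw)
  formation <- as.data.frame(cliques)
  formation$raw_value <- raw
  formation$canonical_score <- canonical
  ranked <- new_records(sets, raw, canonical, measure$name, data$names)
  list(formation = formation, ranked = ranked)
}
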