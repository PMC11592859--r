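#' Specification of a synthetic benchmark dataset
#'
#' Describes a discrete dataset with planted ground truth: modular-parity
#' (XOR-type) synergistic triplets, redundant groups (noisy copies of one
#' latent variable), echo partner variables (noisy copies of a member of a
#' planted triplet), and independent uniform background variables. Noise
#' is a symmetric state flip: with the stated probability a value is
#' replaced by a uniform draw over the other states, which keeps
#' closed-form expectations available (for binary variables a flip
#' probability `q` gives the binary-symmetric-channel mutual information
#' `1 - h2(q)` between a variable and its noisy copy).
#'
#' @param n_samples Number of samples to draw.
#' @param n_background Number of i.i.d. uniform background variables.
#' @param planted_xor List of triplet specs, each a list with `noise`
#'   (flip probability in `[0, 0.5)`, default 0) and `n_states` (>= 2,
#'   default 2): two uniform variables X, Y plus `Z = (X + Y) mod
#'   n_states` with flip noise on Z.
#' @param redundant_groups List of group specs, each a list with `size`
#'   (>= 2) and `noise` (copy flip probability): noisy copies of one
#'   uniform latent.
#' @param echo_pairs List of echo specs, each a list with `triplet` (which
#'   planted triplet, default 1), `member` (which of its three variables
#'   to copy, default 3) and `noise` (copy flip probability).
#' @param n_states_background States per background variable (default 2).
#' @param seed Integer seed; generation is bit-reproducible from it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 2000, n_background = 9,
                       planted_xor = list(), redundant_groups = list(),
                       echo_pairs = list(), n_states_background = 2,
                       seed = 1) {
  n_samples <- check_count(n_samples, "n_samples")
  n_background <- check_count(n_background, "n_background", min = 0L)
  norm_xor <- lapply(planted_xor, function(p) {
    p <- as.list(p)
    p$noise <- p$noise %||% 0
    p$n_states <- check_count(p$n_states %||% 2L, "n_states", min = 2L)
    if (p$noise < 0 || p$noise >= 0.5) stopf("noise must lie in [0, 0.5)")
    p
  })
  norm_red <- lapply(redundant_groups, function(g) {
    g <- as.list(g)
    g$size <- check_count(g$size %||% 3L, "size", min = 2L)
    g$noise <- g$noise %||% 0
    g$n_states <- check_count(g$n_states %||% 2L, "n_states", min = 2L)
    if (g$noise < 0 || g$noise >= 0.5) stopf("noise must lie in [0, 0.5)")
    g
  })
  norm_echo <- lapply(echo_pairs, function(e) {
    e <- as.list(e)
    e$triplet <- check_count(e$triplet %||% 1L, "triplet")
    e$member <- check_count(e$member %||% 3L, "member")
    if (e$member > 3L) stopf("`member` must be 1, 2 or 3")
    e$noise <- e$noise %||% 0.05
    if (e$noise < 0 || e$noise >= 0.5) stopf("noise must lie in [0, 0.5)")
    if (e$triplet > length(norm_xor))
      stopf("echo pair references planted triplet %d of %d", e$triplet,
            length(norm_xor))
    e
  })
  structure(list(n_samples = n_samples, n_background = n_background,
                 planted_xor = norm_xor, redundant_groups = norm_red,
                 echo_pairs = norm_echo,
                 n_states_background = check_count(n_states_background,
                                                   "n_states_background",
                                                   min = 2L),
                 seed = seed),
            class = "synth_spec")
}

# Symmetric state flip: with prob q replace by a uniform draw over the
# other K-1 states.
flip_states <- function(x, k, q) {
  if (q <= 0 || k < 2L) return(x)
  hit <- stats::runif(length(x)) < q
  if (any(hit)) {
    shift <- sample.int(k - 1L, sum(hit), replace = TRUE)
    x[hit] <- (x[hit] + shift) %% k
  }
  x
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Draws the dataset described by a [synth_spec()]. Column layout (and the
#' returned truth registry): planted triplets first, then redundant
#' groups, then echo partners, then background variables. With zero noise
#' a binary planted triplet attains O-information exactly -1 bit on a full
#' factorial design and approximately -1 bit under uniform sampling; a
#' group of exact copies attains `+H(latent)`.
#'
#' @param spec A [synth_spec()].
#' @return List with `data` (a [discrete_dataset()]) and `truth` (class
#'   `planted_truth`: `synergistic_sets`, `redundant_groups`,
#'   `echo_pairs` as index vectors/pairs, and the generating `spec`).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  cols <- list()
  names <- character()
  ks <- integer()
  syn_sets <- list()
  red_groups <- list()
  echo_idx <- list()

  for (i in seq_along(spec$planted_xor)) {
    p <- spec$planted_xor[[i]]
    x <- sample.int(p$n_states, n, replace = TRUE) - 1L
    y <- sample.int(p$n_states, n, replace = TRUE) - 1L
    z <- flip_states((x + y) %% p$n_states, p$n_states, p$noise)
    at <- length(cols)
    cols <- c(cols, list(x, y, z))
    names <- c(names, sprintf("xor%d_%s", i, c("a", "b", "c")))
    ks <- c(ks, rep(p$n_states, 3L))
    syn_sets[[i]] <- at + 1:3
  }
  for (g in seq_along(spec$redundant_groups)) {
    gg <- spec$redundant_groups[[g]]
    latent <- sample.int(gg$n_states, n, replace = TRUE) - 1L
    at <- length(cols)
    for (m in seq_len(gg$size)) {
      cols <- c(cols, list(flip_states(latent, gg$n_states, gg$noise)))
      names <- c(names, sprintf("red%d_%d", g, m))
      ks <- c(ks, gg$n_states)
    }
    red_groups[[g]] <- at + seq_len(gg$size)
  }
  for (e in seq_along(spec$echo_pairs)) {
    ee <- spec$echo_pairs[[e]]
    src <- syn_sets[[ee$triplet]][ee$member]
    kk <- ks[src]
    cols <- c(cols, list(flip_states(cols[[src]], kk, ee$noise)))
    names <- c(names, sprintf("echo%d", e))
    ks <- c(ks, kk)
    echo_idx[[e]] <- c(source = src, echo = length(cols))
  }
  for (b in seq_len(spec$n_background)) {
    cols <- c(cols, list(sample.int(spec$n_states_background, n,
                                    replace = TRUE) - 1L))
    names <- c(names, sprintf("bg%d", b))
    ks <- c(ks, spec$n_states_background)
  }
  if (length(cols) == 0L) stopf("spec generates no variables")
  states <- do.call(cbind, cols)
  data <- discrete_dataset(states, names = names, n_states = ks)
  truth <- structure(list(synergistic_sets = syn_sets,
                          redundant_groups = red_groups,
                          echo_pairs = echo_idx, spec = spec),
                     class = "planted_truth")
  list(data = data, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d synergistic sets, %d redundant groups, %d echo pairs\n",
              length(x$synergistic_sets), length(x$redundant_groups),
              length(x$echo_pairs)))
  invisible(x)
}

#' Evaluate search and filter results against the planted truth
#'
#' Measures how well search results recovered the planted structure: the
#' fraction of runs whose best set is a planted synergistic set (hit
#' rate), the ranks of the planted sets in a brute-force record list, and
#' a confusion count of an echo filter against the planted echoes.
#'
#' @param results List of search results ([anneal()] / [pso_optimize()]
#'   outputs, or bare integer index vectors of best sets). May be empty
#'   (hit rate 0 with a warning).
#' @param truth A `planted_truth` from [synth_generate()].
#' @param brute_records Optional `synergy_records` from
#'   [brute_force_scan()] on the same dataset, for planted-set ranks.
#' @param filter_result Optional `filter_result` whose rejected records
#'   are checked against the planted echo pairs: a rejection is counted
#'   correct when the rejected set contains an echo variable whose source
#'   completes an accepted partner set.
#' @param top_m Hits are also counted within the strongest `top_m`
#'   brute-force records (default 1, i.e. exact optimum).
#' @return List with `hit_rate`, per-run `hits`, `planted_ranks` (or
#'   `NULL`), and `filter_confusion` (or `NULL`).
#' @export
evaluate_recovery <- function(results, truth, brute_records = NULL,
                              filter_result = NULL, top_m = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  planted_keys <- vapply(truth$synergistic_sets, set_key, "")
  best_of <- function(r) {
    if (is.numeric(r)) sort(as.integer(r)) else r$best_set
  }
  if (length(results) == 0L) {
    warnf("no search results supplied; hit rate 0")
    hits <- logical(0)
  } else {
    hits <- vapply(results, function(r)
      set_key(best_of(r)) %in% planted_keys, TRUE)
  }
  planted_ranks <- NULL
  if (!is.null(brute_records)) {
    planted_ranks <- vapply(planted_keys, function(k) {
      hit <- which(vapply(brute_records$set, set_key, "") == k)
      if (length(hit)) brute_records$rank[hit[1L]] else NA_integer_
    }, 0L)
  }
  filter_confusion <- NULL
  if (!is.null(filter_result)) {
    echo_vars <- vapply(truth$echo_pairs, `[[`, 0L, "echo")
    rej_sets <- filter_result$rejected$set
    is_echo_rec <- function(s) any(echo_vars %in% s)
    acc_sets <- filter_result$accepted$set
    filter_confusion <- c(
      echo_rejected = sum(vapply(rej_sets, is_echo_rec, TRUE)),
      genuine_rejected = sum(!vapply(rej_sets, is_echo_rec, TRUE)),
      echo_accepted = sum(vapply(acc_sets, is_echo_rec, TRUE)),
      genuine_accepted = sum(!vapply(acc_sets, is_echo_rec, TRUE))
    )
  }
  list(hit_rate = if (length(hits)) mean(hits) else 0,
       hits = hits, planted_ranks = planted_ranks,
       filter_confusion = filter_confusion)
}
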