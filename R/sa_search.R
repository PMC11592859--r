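#' Simulated-annealing configuration
#'
#' Bundles the tunables of [anneal()]: set size, temperature schedule,
#' replacement weighting and synergy measure.
#'
#' The geometric cooling factor `gamma` defaults to the value that brings
#' the temperature to 1% of `t0` at the final step, `0.01^(1/steps)`. The
#' swap-count probability is `p = (T/T0)^p_exponent` clamped to
#' `(eps_p, 1]`; as printed this makes multi-variable moves more likely as
#' the system cools, which is unconventional for annealing, so
#' `invert_swap_schedule = TRUE` offers the conventional reading
#' (`p = (1 - T/T0)^p_exponent`, large moves while hot).
#'
#' @param n Set size (>= 3).
#' @param t0 Initial temperature (> 0).
#' @param cooling `"geometric"` (`T_t = t0 * gamma^t`) or `"boltzmann"`
#'   (`T_t = t0 / ln(t + 2)`).
#' @param gamma Geometric cooling factor in (0, 1); default reaches
#'   `0.01 * t0` at the last step.
#' @param steps Number of iterations (>= 1).
#' @param weight_scheme Replacement weighting: `"no_weight"`,
#'   `"inverse_mi"`, `"mi"` or `"mi_ent"`.
#' @param seed Optional integer seed.
#' @param measure A [synergy_measure()].
#' @param p_exponent Exponent of the swap-count probability (default 0.1).
#' @param eps_p Lower clamp for the geometric probability (default 1e-3).
#' @param invert_swap_schedule Use the conventional hot-moves-big reading?
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(n = 3, t0 = 1, cooling = c("geometric", "boltzmann"),
                      gamma = NULL, steps = 1000,
                      weight_scheme = c("no_weight", "inverse_mi", "mi",
                                        "mi_ent"),
                      seed = NULL, measure = synergy_measure(),
                      p_exponent = 0.1, eps_p = 1e-3,
                      invert_swap_schedule = FALSE) {
  n <- check_count(n, "n", min = 3L)
  steps <- check_count(steps, "steps")
  cooling <- match.arg(cooling)
  weight_scheme <- match.arg(weight_scheme)
  if (t0 <= 0) stopf("`t0` must be positive")
  if (is.null(gamma)) gamma <- 0.01^(1 / steps)
  if (gamma <= 0 || gamma >= 1) stopf("`gamma` must lie in (0, 1)")
  structure(list(n = n, t0 = t0, cooling = cooling, gamma = gamma,
                 steps = steps, weight_scheme = weight_scheme, seed = seed,
                 measure = measure, p_exponent = p_exponent, eps_p = eps_p,
                 invert_swap_schedule = invert_swap_schedule),
            class = "sa_config")
}

#' Temperature-dependent geometric swap count
#'
#' Number of set members to exchange at temperature `t`: a draw from a
#' geometric distribution with support starting at 1 and success
#' probability `p = (t/t0)^p_exponent` (clamped to `(eps_p, 1]`),
#' truncated at the set size `n`. At `t = t0` the probability is 1 and
#' exactly one member is swapped.
#'
#' @param t Current temperature, `0 < t <= t0` (values above `t0` clamp to
#'   a single swap with a warning).
#' @param t0 Initial temperature.
#' @param n Set size (upper truncation).
#' @param p_exponent,eps_p,invert See [sa_config()].
#' @return Integer swap count in `[1, n]`.
#' @export
swap_count <- function(t, t0, n, p_exponent = 0.1, eps_p = 1e-3,
                       invert = FALSE) {
  if (t <= 0 || t0 <= 0) stopf("temperatures must be positive")
  if (t > t0) {
    warnf("temperature %.3g above t0 = %.3g; clamping to a single swap", t, t0)
    return(1L)
  }
  ratio <- if (invert) 1 - t / t0 else t / t0
  p <- min(max(ratio^p_exponent, eps_p), 1)
  k <- stats::rgeom(1L, p) + 1L
  min(k, as.integer(n))
}

# Weight of candidate c against member m under a scheme, as a members x
# candidates matrix. `weights` is a pairwise_matrix of the scheme's metric
# ("mi_ent" stores exp(I/2) with entropies attached).
scheme_weight_matrix <- function(weights, members, candidates) {
  w <- unclass(weights)[members, candidates, drop = FALSE]
  if (identical(attr(weights, "metric"), "mi_ent")) {
    H <- attr(weights, "entropies")
    w <- sweep(w, 2L, H[candidates], `*`)
  }
  w
}

#' Propose a neighbouring variable set
#'
#' Exchanges `k_swaps` members of `current` for variables outside it.
#' Members to remove are chosen with probability proportional to their
#' summed scheme weight against the candidate pool; replacements are drawn
#' without replacement from the pool with probability proportional to
#' their scheme weight against the retained members (`inverse_mi`:
#' `1 - I/max(I)`; `mi`: `I`; `mi_ent`: `H(c) * mean_m exp(I(m,c)/2)`;
#' `no_weight`: uniform). Degenerate all-zero weight vectors fall back to
#' uniform.
#'
#' @param current Sorted integer vector of distinct variable indices.
#' @param n_vars Total number of variables in the dataset.
#' @param weights A [pairwise_matrix()] matching the scheme, or `NULL` for
#'   `"no_weight"`.
#' @param k_swaps Number of members to exchange, in `[1, length(current)]`.
#' @param scheme Weight scheme name (see [sa_config()]).
#' @return Sorted integer vector of the same size as `current`.
#' @export
propose <- function(current, n_vars, weights = NULL, k_swaps = 1,
                    scheme = c("no_weight", "inverse_mi", "mi", "mi_ent")) {
  scheme <- match.arg(scheme)
  current <- sort(as.integer(current))
  k_swaps <- check_count(k_swaps, "k_swaps")
  n <- length(current)
  if (k_swaps > n) stopf("`k_swaps` exceeds the set size")
  candidates <- setdiff(seq_len(n_vars), current)
  if (length(candidates) < k_swaps)
    stopf("candidate pool (%d) smaller than k_swaps (%d)",
          length(candidates), k_swaps)
  if (scheme == "no_weight" || is.null(weights)) {
    removed <- sample_vec(current, k_swaps)
    added <- sample_vec(candidates, k_swaps)
  } else {
    wm <- scheme_weight_matrix(weights, current, candidates)
    removed <- sample_weighted(current, k_swaps, rowSums(wm, na.rm = TRUE))
    retained <- setdiff(current, removed)
    cand_w <- if (length(retained)) {
      colMeans(scheme_weight_matrix(weights, retained, candidates),
               na.rm = TRUE)
    } else NULL
    added <- sample_weighted(candidates, k_swaps, cand_w)
  }
  sort(c(setdiff(current, removed), added))
}

#' Metropolis acceptance
#'
#' Accepts an improvement (or tie) of the canonical score always, and a
#' worsening with probability `exp((score_new - score_old)/t)`.
#'
#' @param score_new,score_old Canonical scores (higher = more synergistic).
#' @param t Temperature (> 0).
#' @return Logical: accept the candidate?
#' @export
accept <- function(score_new, score_old, t) {
  if (t <= 0) stopf("`t` must be positive")
  if (score_new >= score_old) return(TRUE)
  stats::runif(1L) < exp((score_new - score_old) / t)
}

#' Simulated annealing over fixed-cardinality variable sets
#'
#' Starts from a random set of `config$n` variables and iterates: draw a
#' swap count from the temperature-dependent geometric schedule, propose a
#' weighted replacement, score it (one oracle call), and accept by the
#' Metropolis criterion on the canonical score. Fully reproducible from
#' `config$seed`; oracle calls total `steps + 1`.
#'
#' @param data A [discrete_dataset()] with more than `config$n` variables.
#' @param config An [sa_config()].
#' @return Object of class `sa_trace`: a `trace` data frame (`t`,
#'   `temperature`, `set`, `score`, `accepted`, `swaps`), `best_set`,
#'   `best_score` (canonical), `oracle_calls`, `seed`, `config`.
#' @examples
#' \donttest{
#' d <- synth_generate(synth_spec(n_samples = 500, n_background = 9,
#'                                planted_xor = list(list(noise = 0.05)),
#'                                seed = 1))$data
#' res <- anneal(d, sa_config(steps = 300, weight_scheme = "inverse_mi",
#'                            seed = 7))
#' res$best_set
#' }
#' @export
anneal <- function(data, config = sa_config()) {
  stopifnot(inherits(data, "discrete_dataset"), inherits(config, "sa_config"))
  k <- n_vars(data)
  if (k <= config$n) stopf("need more than %d variables", config$n)
  if (!is.null(config$seed)) set.seed(config$seed)
  weights <- if (config$weight_scheme == "no_weight") NULL else
    pairwise_matrix(data, config$weight_scheme)
  scorer <- make_scorer(data, config$measure)

  current <- sort(sample.int(k, config$n))
  cur_score <- scorer$score(current)
  best_set <- current
  best_score <- cur_score

  steps <- config$steps
  tr_t <- integer(steps); tr_temp <- numeric(steps); tr_set <- character(steps)
  tr_score <- numeric(steps); tr_acc <- logical(steps); tr_sw <- integer(steps)

  for (t in seq_len(steps)) {
    temp <- switch(config$cooling,
                   geometric = config$t0 * config$gamma^(t - 1L),
                   boltzmann = config$t0 / log(t + 1))
    ks <- swap_count(temp, config$t0, config$n, config$p_exponent,
                     config$eps_p, config$invert_swap_schedule)
    cand <- propose(current, k, weights, ks, config$weight_scheme)
    cand_score <- scorer$score(cand)
    acc <- accept(cand_score, cur_score, temp)
    if (acc) {
      current <- cand
      cur_score <- cand_score
      if (cur_score > best_score) {
        best_score <- cur_score
        best_set <- current
      }
    }
    tr_t[t] <- t; tr_temp[t] <- temp; tr_set[t] <- set_key(current)
    tr_score[t] <- cur_score; tr_acc[t] <- acc; tr_sw[t] <- ks
  }
  structure(list(
    trace = data.frame(t = tr_t, temperature = tr_temp, set = tr_set,
                       score = tr_score, accepted = tr_acc, swaps = tr_sw,
                       stringsAsFactors = FALSE),
    best_set = best_set, best_score = best_score,
    oracle_calls = scorer$calls(), seed = config$seed, config = config
  ), class = "sa_trace")
}

#' @export
print.sa_trace <- function(x, ...) {
  cat(sprintf("<sa_trace> %d steps, best {%s} score %.4f (%d oracle calls)\n",
              nrow(x$trace), set_key(x$best_set), x$best_score,
              x$oracle_calls))
  invisible(x)
}

#' Repeated annealing runs with summary statistics
#'
#' Executes [anneal()] `n_runs` times with per-run seeds derived from a
#' master seed by a counter scheme (`master + run`), and summarizes the
#' per-run best canonical scores: mean, median, standard deviation, IQR,
#' and how many runs reached `threshold`.
#'
#' @param data A [discrete_dataset()].
#' @param config An [sa_config()]; its `seed` is the master seed (drawn
#'   randomly when `NULL`).
#' @param n_runs Number of independent runs.
#' @param threshold Optional canonical-score threshold; the summary counts
#'   runs whose best reaches it.
#' @return List with `runs` (per-run data frame: run, seed, best set,
#'   best score) and `summary`.
#' @export
sa_multi_run <- function(data, config = sa_config(), n_runs = 100,
                         threshold = NULL) {
  n_runs <- check_count(n_runs, "n_runs")
  master <- config$seed %||% sample.int(2^30, 1L)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- child_seed(master, r)
    res <- anneal(data, cfg)
    runs[[r]] <- data.frame(run = r, seed = cfg$seed,
                            best_set = set_key(res$best_set),
                            best_score = res$best_score,
                            oracle_calls = res$oracle_calls,
                            stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, runs)
  s <- runs$best_score
  summary <- list(mean = mean(s), median = stats::median(s),
                  sd = stats::sd(s), iqr = stats::IQR(s),
                  n_at_threshold = if (is.null(threshold)) NA_integer_
                                   else sum(s >= threshold),
                  threshold = threshold %||% NA_real_,
                  master_seed = master)
  list(runs = runs, summary = summary)
}
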