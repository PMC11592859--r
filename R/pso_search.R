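#' Particle swarm configuration
#'
#' Tunables of the discrete set-based particle swarm in [pso_optimize()].
#'
#' Movement strategies weight replacement candidates before nudging:
#' `"uniform"`; `"mi_removed"` / `"inverse_mi_removed"` use the (inverse)
#' MI between the candidate and the removed member; `"mean_mi_remaining"`
#' / `"mean_inverse_mi_remaining"` average over the retained members;
#' `"mi_ent"` uses `H(c) * mean_m exp(I(m,c)/2)`.
#'
#' Nudge strategies set the blend strengths toward the personal and global
#' best sets: `"none"`, `"constant"` (both equal `nudge_factor`),
#' `"exp_decay"` (`nudge_factor * exp(-t/max_steps)`), or `"adaptive"`
#' (sigmoid of elapsed time plus score gaps; see [nudge_schedule()]).
#'
#' @param n Set size (>= 3).
#' @param n_particles Number of particles `P >= 1`.
#' @param max_steps Number of swarm iterations.
#' @param movement Movement strategy (see Details).
#' @param nudge Nudge strategy (see Details).
#' @param nudge_factor Base nudge strength in `[0, 1]` (default 0.2, also
#'   the constant-nudge magnitude).
#' @param alpha,beta Scale of the local / global score-gap terms in the
#'   adaptive schedule, and the blend coefficients' carriers elsewhere.
#' @param k Sigmoid steepness of the adaptive schedule.
#' @param seed Optional integer seed.
#' @param measure A [synergy_measure()].
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(n = 3, n_particles = 10, max_steps = 200,
                       movement = c("uniform", "mi_removed",
                                    "inverse_mi_removed", "mean_mi_remaining",
                                    "mean_inverse_mi_remaining", "mi_ent"),
                       nudge = c("none", "constant", "exp_decay", "adaptive"),
                       nudge_factor = 0.2, alpha = 0.5, beta = 0.5, k = 1,
                       seed = NULL, measure = synergy_measure()) {
  n <- check_count(n, "n", min = 3L)
  n_particles <- check_count(n_particles, "n_particles")
  max_steps <- check_count(max_steps, "max_steps")
  if (nudge_factor < 0 || nudge_factor > 1)
    stopf("`nudge_factor` must lie in [0, 1]")
  structure(list(n = n, n_particles = n_particles, max_steps = max_steps,
                 movement = match.arg(movement), nudge = match.arg(nudge),
                 nudge_factor = nudge_factor, alpha = alpha, beta = beta,
                 k = k, seed = seed, measure = measure),
            class = "pso_config")
}

#' Normal-deviate swap count
#'
#' Draws `z ~ N(0,1)` and converts distance from the mean into a swap
#' count: within one standard deviation a single variable is replaced,
#' within two standard deviations two, beyond that three; capped at the
#' set size. About 68.27% of steps therefore swap one variable.
#'
#' @param n_max Cap (set size); default uncapped.
#' @return Integer swap count >= 1.
#' @export
swap_count_normal <- function(n_max = Inf) {
  z <- abs(stats::rnorm(1L))
  k <- if (z <= 1) 1L else if (z <= 2) 2L else 3L
  min(k, n_max)
}

#' Blend a candidate distribution with nudge distributions
#'
#' `blended = (1 - nudge_factor) * P + alpha * d_local + beta * d_global`,
#' renormalized to sum 1. An all-zero blend falls back to uniform with a
#' warning.
#'
#' @param p Base probability vector over candidates (sums to 1).
#' @param d_local,d_global Non-negative nudge vectors (typically uniform
#'   mass on best-set members absent from the current position).
#' @param nudge_factor Weight removed from the base distribution.
#' @param alpha,beta Weights of the local / global nudges.
#' @return Probability vector of the same length.
#' @export
blend_weights <- function(p, d_local, d_global, nudge_factor = 0,
                          alpha = 0, beta = 0) {
  if (any(p < 0) || any(d_local < 0) || any(d_global < 0))
    stopf("inputs must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stopf("`p` must sum to 1")
  blended <- (1 - nudge_factor) * p + alpha * d_local + beta * d_global
  tot <- sum(blended)
  if (tot <= 0) {
    warnf("all-zero blended weights; falling back to uniform")
    return(rep(1 / length(p), length(p)))
  }
  blended / tot
}

#' Nudge strength schedule
#'
#' Returns the `(local, global)` nudge strengths at step `t`:
#' `"none"` gives `(0, 0)`; `"constant"` gives `(nudge_factor,
#' nudge_factor)`; `"exp_decay"` gives `nudge_factor * exp(-t/max_steps)`
#' for both; `"adaptive"` gives
#' `local = sigmoid(t/max_steps + alpha * |cost - global_best|)` and
#' `global = sigmoid(t/max_steps + beta * |cost - particle_best|)` with
#' `sigmoid(x) = 1 / (1 + exp(-k x))`.
#'
#' @param strategy Nudge strategy name.
#' @param t Current step, `0 <= t <= max_steps`.
#' @param max_steps Total steps.
#' @param cost Particle's current canonical score (adaptive only).
#' @param global_best,particle_best Best canonical scores (adaptive only).
#' @param alpha,beta,k Adaptive-schedule scale factors.
#' @param nudge_factor Base strength for constant / exponential decay.
#' @return Numeric `c(local, global)`.
#' @export
nudge_schedule <- function(strategy = c("none", "constant", "exp_decay",
                                        "adaptive"),
                           t = 0, max_steps = 1, cost = NULL,
                           global_best = NULL, particle_best = NULL,
                           alpha = 0.5, beta = 0.5, k = 1,
                           nudge_factor = 0.2) {
  strategy <- match.arg(strategy)
  if (t < 0 || t > max_steps) stopf("`t` must lie in [0, max_steps]")
  switch(strategy,
    none = c(local = 0, global = 0),
    constant = c(local = nudge_factor, global = nudge_factor),
    exp_decay = {
      v <- nudge_factor * exp(-t / max_steps)
      c(local = v, global = v)
    },
    adaptive = {
      sig <- function(x) 1 / (1 + exp(-k * x))
      c(local = sig(t / max_steps + alpha * abs(cost - global_best)),
        global = sig(t / max_steps + beta * abs(cost - particle_best)))
    }
  )
}

# Base movement weights for candidates given the removed member and the
# retained members. `mats` holds mi, inv (1 - I/max I), entropies.
movement_weights <- function(movement, mats, removed, retained, candidates) {
  switch(movement,
    uniform = rep(1, length(candidates)),
    mi_removed = mats$mi[removed, candidates],
    inverse_mi_removed = mats$inv[removed, candidates],
    mean_mi_remaining =
      if (length(retained)) colMeans(mats$mi[retained, candidates, drop = FALSE])
      else rep(1, length(candidates)),
    mean_inverse_mi_remaining =
      if (length(retained)) colMeans(mats$inv[retained, candidates, drop = FALSE])
      else rep(1, length(candidates)),
    mi_ent = {
      base <- if (length(retained))
        colMeans(exp(mats$mi[retained, candidates, drop = FALSE] / 2))
      else rep(1, length(candidates))
      mats$entropies[candidates] * base
    }
  )
}

normalize_prob <- function(w) {
  w[!is.finite(w) | w < 0] <- 0
  tot <- sum(w)
  if (tot <= 0) rep(1 / length(w), length(w)) else w / tot
}

#' Advance one particle by one step
#'
#' Draws a swap count from [swap_count_normal()], removes that many
#' members uniformly, and refills the position one slot at a time: base
#' candidate weights come from the movement strategy, are blended with
#' nudge distributions placing uniform mass on personal-best / global-best
#' members missing from the current position, and a candidate is sampled
#' from the blended distribution. The new position is scored (one oracle
#' call) and the personal best updated.
#'
#' @param particle List with `position`, `score`, `best_position`,
#'   `best_score` (canonical orientation).
#' @param global_best_position,global_best_score Swarm best.
#' @param scorer Internal scorer closure (from the optimizer).
#' @param mats Precomputed pairwise matrices (internal).
#' @param config A [pso_config()].
#' @param t Current step (for the nudge schedule).
#' @return The updated particle list.
#' @keywords internal
#' @export
particle_step <- function(particle, global_best_position, global_best_score,
                          scorer, mats, config, t) {
  pos <- particle$position
  n <- length(pos)
  n_all <- length(mats$entropies)
  kk <- swap_count_normal(n)
  removed <- sample_vec(pos, kk)
  newpos <- setdiff(pos, removed)
  candidates <- setdiff(seq_len(n_all), pos)
  if (length(candidates) < kk) stopf("candidate pool exhausted")
  ng <- nudge_schedule(config$nudge, t, config$max_steps,
                       cost = particle$score,
                       global_best = global_best_score,
                       particle_best = particle$best_score,
                       alpha = config$alpha, beta = config$beta,
                       k = config$k, nudge_factor = config$nudge_factor)
  for (r in removed) {
    p <- normalize_prob(movement_weights(config$movement, mats, r,
                                         newpos, candidates))
    d_local <- normalize_prob_or_zero(
      as.numeric(candidates %in% setdiff(particle$best_position, newpos)))
    d_global <- normalize_prob_or_zero(
      as.numeric(candidates %in% setdiff(global_best_position, newpos)))
    blended <- blend_weights(p, d_local, d_global,
                             nudge_factor = min(1, ng[["local"]] + ng[["global"]]),
                             alpha = ng[["local"]], beta = ng[["global"]])
    pick <- sample_vec(candidates, 1L, prob = blended)
    newpos <- c(newpos, pick)
    candidates <- setdiff(candidates, pick)
  }
  newpos <- sort(newpos)
  sc <- scorer$score(newpos)
  particle$position <- newpos
  particle$score <- sc
  if (sc > particle$best_score) {
    particle$best_score <- sc
    particle$best_position <- newpos
  }
  particle
}

# Normalize to a probability vector, or all zeros when empty of mass
# (a zero nudge direction must not steal probability in the blend).
normalize_prob_or_zero <- function(w) {
  tot <- sum(w)
  if (tot <= 0) w else w / tot
}

#' Discrete particle swarm optimization over variable sets
#'
#' `P` particles hold fixed-size variable sets and move by probabilistic
#' replacement: the number of members changed per step follows the
#' distance of a standard-normal draw from its mean, replacement
#' candidates are weighted by the movement strategy and nudged toward
#' each particle's personal best and the swarm's global best. Personal
#' and global bests update whenever a better canonical score is found, so
#' the global-best history is non-decreasing. Oracle calls total
#' `P * (max_steps + 1)`; fully reproducible from `config$seed`.
#'
#' @param data A [discrete_dataset()] with more than `config$n` variables.
#' @param config A [pso_config()].
#' @return Object of class `pso_result`: `particles`, `best_set`,
#'   `best_score`, `history` (global best per step), `oracle_calls`,
#'   `seed`, `config`.
#' @export
pso_optimize <- function(data, config = pso_config()) {
  stopifnot(inherits(data, "discrete_dataset"), inherits(config, "pso_config"))
  k <- n_vars(data)
  if (k <= config$n) stopf("need more than %d variables", config$n)
  if (!is.null(config$seed)) set.seed(config$seed)
  mi_pm <- pairwise_matrix(data, "mi")
  mi <- unclass(mi_pm)
  mx <- max(mi, na.rm = TRUE)
  inv <- if (mx <= 0) ifelse(is.na(mi), NA_real_, 1) else 1 - mi / mx
  mats <- list(mi = mi, inv = inv, entropies = attr(mi_pm, "entropies"))
  scorer <- make_scorer(data, config$measure)

  particles <- lapply(seq_len(config$n_particles), function(i) {
    pos <- sort(sample.int(k, config$n))
    sc <- scorer$score(pos)
    list(position = pos, score = sc, best_position = pos, best_score = sc)
  })
  gb <- which.max(vapply(particles, `[[`, 0, "best_score"))
  global_best_position <- particles[[gb]]$best_position
  global_best_score <- particles[[gb]]$best_score

  history <- numeric(config$max_steps)
  for (t in seq_len(config$max_steps)) {
    for (i in seq_along(particles)) {
      particles[[i]] <- particle_step(particles[[i]], global_best_position,
                                      global_best_score, scorer, mats,
                                      config, t)
      if (particles[[i]]$best_score > global_best_score) {
        global_best_score <- particles[[i]]$best_score
        global_best_position <- particles[[i]]$best_position
      }
    }
    history[t] <- global_best_score
  }
  structure(list(particles = particles, best_set = global_best_position,
                 best_score = global_best_score, history = history,
                 oracle_calls = scorer$calls(), seed = config$seed,
                 config = config),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf(
    "<pso_result> %d particles, %d steps, best {%s} score %.4f (%d oracle calls)\n",
    x$config$n_particles, length(x$history), set_key(x$best_set),
    x$best_score, x$oracle_calls))
  invisible(x)
}
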