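# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Key used for score caches and set comparisons.
set_key <- function(idx) paste(idx, collapse = ",")

# Child seed for run r under a master seed: a simple counter scheme so that
# multi-run summaries are reproducible run-by-run. Kept within 32-bit range.
child_seed <- function(master, r) {
  as.integer((as.numeric(master) + as.numeric(r)) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. With seed = NULL the current stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() treats a length-1 numeric x as 1:x; this version never does.
sample_vec <- function(x, size, prob = NULL) {
  if (length(x) == 1L && size == 1L) return(x)
  x[sample.int(length(x), size, replace = FALSE, prob = prob)]
}

# Weighted draw of `size` distinct elements; falls back to uniform when the
# weight vector is degenerate (all zero / non-finite).
sample_weighted <- function(x, size, w) {
  if (is.null(w)) return(sample_vec(x, size))
  w[!is.finite(w) | w < 0] <- 0
  if (sum(w) <= 0) return(sample_vec(x, size))
  sample_vec(x, size, prob = w)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}
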