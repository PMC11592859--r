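# Fixtures and independent oracles used across the suite. Oracles are
# deliberately written with different machinery (table()/data frames,
# explicit double sums) than the package internals they check.

# Full-factorial parity design: each (x, y) combination `reps` times,
# z = x XOR y. 4*reps rows.
xor_design <- function(reps = 2L) {
  g <- expand.grid(x = 0:1, y = 0:1)
  g <- g[rep(seq_len(4L), each = reps), ]
  discrete_dataset(cbind(x = g$x, y = g$y, z = (g$x + g$y) %% 2L))
}

# Independent uniform binary columns.
independent_data <- function(n, k, seed) {
  set.seed(seed)
  discrete_dataset(matrix(sample(0:1, n * k, TRUE), n, k))
}

# Noisy planted-XOR benchmark via the generator.
planted_fixture <- function(n = 2000, flip = 0.05, n_background = 9,
                            echo_noise = NULL, seed = 1) {
  synth_generate(synth_spec(
    n_samples = n, n_background = n_background,
    planted_xor = list(list(noise = flip)),
    echo_pairs = if (is.null(echo_noise)) list()
                 else list(list(triplet = 1, member = 3, noise = echo_noise)),
    seed = seed
  ))
}

# Entropy oracle from table() counts.
oracle_entropy <- function(...) {
  p <- as.vector(table(...))
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# MI oracle: explicit double sum over the joint table.
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / n
      if (p > 0) s <- s + p * log2(p / (px[i] * py[j]))
    }
  }
  unname(s)
}

# O-information oracle: entropy sums computed through table().
oracle_o_information <- function(data, vars) {
  cols <- lapply(vars, function(j) data$states[, j])
  n <- length(vars)
  h_all <- do.call(oracle_entropy, cols)
  acc <- (n - 2) * h_all
  for (m in seq_len(n)) {
    acc <- acc + oracle_entropy(cols[[m]]) -
      do.call(oracle_entropy, cols[-m])
  }
  acc
}

# Brute-force triangle enumeration of a graph given its adjacency matrix.
oracle_triangles <- function(adj) {
  k <- nrow(adj)
  out <- character()
  for (i in seq_len(k - 2L)) {
    for (j in (i + 1L):(k - 1L)) {
      if (!adj[i, j]) next
      for (l in (j + 1L):k) {
        if (adj[i, l] && adj[j, l])
          out <- c(out, paste(i, j, l, sep = ";"))
      }
    }
  }
  sort(out)
}

# Binary entropy in bits.
h2 <- function(q) -q * log2(q) - (1 - q) * log2(1 - q)
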