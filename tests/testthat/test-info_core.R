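test_that("plug-in entropy matches closed forms", {
  expect_equal(entropy(c(50, 50)), 1.0)
  expect_equal(entropy(c(100, 0)), 0.0)
  expect_equal(entropy(c(75, 25)), 0.8112781, tolerance = 1e-6)
  expect_error(entropy(c(0, 0)), "all-zero")
  expect_error(entropy(c(-1, 2)), "non-negative")
})

test_that("joint entropy handles copies, factorials and parity designs", {
  b <- rep(0:1, each = 4)
  d <- discrete_dataset(cbind(a = b, b = b))
  expect_equal(joint_entropy(d, 1:2), joint_entropy(d, 1))
  ff <- discrete_dataset(as.matrix(expand.grid(x = 0:1, y = 0:1)))
  expect_equal(joint_entropy(ff, 1:2), 2.0)
  expect_equal(joint_entropy(xor_design(2L), 1:3), 2.0)
  expect_error(joint_entropy(ff, integer()), "at least 1")
})

test_that("mutual information agrees with the double-sum oracle", {
  b <- rep(0:1, each = 4)
  d <- discrete_dataset(cbind(a = b, b = b))
  expect_equal(mutual_information(d, 1, 2), joint_entropy(d, 1))
  ff <- discrete_dataset(as.matrix(expand.grid(x = 0:1, y = 0:1)))
  expect_equal(mutual_information(ff, 1, 2), 0.0)
  # 2x2 contingency table [[40,10],[10,40]]
  x <- rep(c(0, 0, 1, 1), times = c(40, 10, 10, 40))
  y <- rep(c(0, 1, 0, 1), times = c(40, 10, 10, 40))
  d2 <- discrete_dataset(cbind(x = x, y = y))
  expect_equal(mutual_information(d2, 1, 2), oracle_mi(x, y), tolerance = 1e-12)
  expect_equal(mutual_information(d2, 2, 1), mutual_information(d2, 1, 2))
  expect_error(mutual_information(d2, 1, 1), "distinct")
})

test_that("O-information separates synergy from redundancy analytically", {
  expect_equal(o_information(xor_design(2L), 1:3), -1.0)
  b <- rep(0:1, each = 4)
  copies <- discrete_dataset(cbind(a = b, b = b, c = b))
  expect_equal(o_information(copies, 1:3), 1.0)
  expect_error(o_information(xor_design(), 1:2), "at least 3")
})

test_that("O-information equals the entropy-sum oracle on a 4-variable mix", {
  g <- expand.grid(x = 0:1, y = 0:1)
  d <- discrete_dataset(cbind(x = g$x, y = g$y, z = (g$x + g$y) %% 2,
                              w = g$x))
  expect_equal(o_information(d, 1:4), oracle_o_information(d, 1:4),
               tolerance = 1e-12)
})

test_that("O-information is permutation- and relabeling-invariant, and equals
           co-information at order 3", {
  set.seed(7)
  for (rep in 1:5) {
    d <- discrete_dataset(matrix(sample(0:2, 60 * 4, TRUE), 60, 4))
    base <- o_information(d, c(1, 2, 3))
    expect_equal(o_information(d, c(3, 1, 2)), base, tolerance = 1e-12)
    # relabel states of variable 2
    st <- d$states
    st[, 2] <- 2L - st[, 2]
    expect_equal(o_information(discrete_dataset(st), 1:3), base,
                 tolerance = 1e-12)
    # inclusion-exclusion co-information identity
    coinfo <- sum(vapply(1:3, function(j) joint_entropy(d, j), 0)) -
      joint_entropy(d, c(1, 2)) - joint_entropy(d, c(1, 3)) -
      joint_entropy(d, c(2, 3)) + joint_entropy(d, 1:3)
    expect_equal(base, coinfo, tolerance = 1e-12)
  }
})

test_that("bias correction recentres the null and keeps strong synergy", {
  d <- independent_data(1000, 3, seed = 11)
  corrected <- bias_corrected_o_information(d, 1:3, n_perm = 100, seed = 1)
  expect_lt(abs(corrected), 0.05)
  gen <- planted_fixture(n = 4096, flip = 0, n_background = 0, seed = 2)
  raw <- o_information(gen$data, 1:3)
  corrected <- bias_corrected_o_information(gen$data, 1:3, n_perm = 50,
                                            seed = 1)
  expect_equal(raw, -1.0, tolerance = 0.02)
  expect_equal(corrected, raw, tolerance = 0.05)
  # seed-reproducible to the bit
  a <- bias_corrected_o_information(d, 1:3, n_perm = 100, seed = 99)
  b <- bias_corrected_o_information(d, 1:3, n_perm = 100, seed = 99)
  expect_identical(a, b)
})

test_that("MMI-PID synergy matches analytic and enumerated values", {
  d <- xor_design(2L)
  expect_equal(mmi_pid_synergy(d, c(1, 2), 3), 1.0)
  b <- rep(0:1, each = 4)
  dc <- discrete_dataset(cbind(s1 = b, s2 = rep(0:1, 4), t = b))
  expect_equal(mmi_pid_synergy(dc, c(1, 2), 3), 0.0, tolerance = 1e-12)
  expect_error(mmi_pid_synergy(d, c(1, 1), 3), "distinct")
  # noisy XOR against an exhaustive joint-table oracle
  gen <- planted_fixture(n = 4096, flip = 0.1, n_background = 0, seed = 5)
  x <- gen$data$states
  i_joint <- oracle_entropy(x[, 3]) +
    oracle_entropy(paste(x[, 1], x[, 2])) -
    oracle_entropy(paste(x[, 1], x[, 2], x[, 3]))
  oracle <- i_joint - max(oracle_mi(x[, 1], x[, 3]), oracle_mi(x[, 2], x[, 3]))
  expect_equal(mmi_pid_synergy(gen$data, c(1, 2), 3), oracle,
               tolerance = 1e-10)
})

test_that("improvement factor flags super-additive information", {
  b <- rep(0:1, each = 8)
  dup <- discrete_dataset(cbind(a = b, b = b, t = b))
  expect_equal(improvement_factor(dup, c(1, 2), 3), 0.5)
  expect_error(improvement_factor(xor_design(2L), c(1, 2), 3),
               "undefined improvement factor")
  gen <- planted_fixture(n = 4096, flip = 0.1, n_background = 0, seed = 5)
  x <- gen$data$states
  i_joint <- oracle_entropy(x[, 3]) +
    oracle_entropy(paste(x[, 1], x[, 2])) -
    oracle_entropy(paste(x[, 1], x[, 2], x[, 3]))
  oracle <- i_joint / (oracle_mi(x[, 1], x[, 3]) + oracle_mi(x[, 2], x[, 3]))
  expect_equal(improvement_factor(gen$data, c(1, 2), 3), oracle,
               tolerance = 1e-10)
  all3 <- improvement_factor_all(gen$data, 1:3)
  expect_identical(nrow(all3), 3L)
  expect_equal(all3$factor[all3$target == 3], oracle, tolerance = 1e-10)
})

test_that("search space size is exact", {
  expect_equal(search_space_size(400, 3), 10586800)
  expect_equal(search_space_size(400, 4), 1050739900)
  expect_equal(search_space_size(3, 3), 1)
  expect_equal(search_space_size(5, 0), 1)
  expect_error(search_space_size(3, 4), "exceed")
})

test_that("brute force ranks the planted triplet first and orders correctly", {
  gen <- planted_fixture(n = 1000, flip = 0, n_background = 2, seed = 9)
  rec <- brute_force_scan(gen$data, 3)
  expect_identical(rec$indices[1], "1;2;3")
  expect_identical(nrow(rec), as.integer(choose(5, 3)))
  # canonical ordering is the exact reverse of raw-Omega ordering
  expect_identical(order(-rec$canonical_score), order(rec$raw_value))
  # independent re-sort reproduces the ranking
  expect_identical(rec$canonical_score, sort(rec$canonical_score,
                                             decreasing = TRUE))
  d10 <- independent_data(400, 10, seed = 13)
  rec10 <- brute_force_scan(d10, 3)
  expect_identical(nrow(rec10), 120L)
  expect_lt(max(abs(rec10$canonical_score)), 0.1)
  expect_error(brute_force_scan(d10, 3, cap = 50), "cap")
})

test_that("bootstrap significance detects strong synergy and is reproducible", {
  gen <- planted_fixture(n = 2000, flip = 0, n_background = 0, seed = 21)
  bs <- bootstrap_significance(gen$data, 1:3, n_boot = 200, seed = 4)
  expect_true(bs$significant)
  expect_lt(bs$ci[2], 0)  # raw Omega CI entirely below zero
  bs2 <- bootstrap_significance(gen$data, 1:3, n_boot = 200, seed = 4)
  expect_identical(bs$ci, bs2$ci)
  expect_identical(bs$p_value, bs2$p_value)
})
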