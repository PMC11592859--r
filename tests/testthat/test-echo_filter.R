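# Shared fixture: one planted triplet {1,2,3}, an echo partner 4 copying
# variable 3 with 5% flip noise, and independent background.
echo_fixture <- function(seed = 1, n = 2000) {
  planted_fixture(n = n, flip = 0.05, n_background = 4,
                  echo_noise = 0.05, seed = seed)
}

test_that("the MI-threshold filter rejects the echo and keeps the source", {
  gen <- echo_fixture(seed = 61)
  rec <- brute_force_scan(gen$data, 3)
  mi <- pairwise_matrix(gen$data, "mi")
  expect_gt(mi[3, 4], 0.6)  # noisy copy: MI near 1 - h2(0.05) = 0.71
  fr <- mi_threshold_filter(rec, mi, threshold = 0.6, top_n = 10)
  expect_true("1;2;3" %in% fr$accepted$indices)
  expect_true("1;2;4" %in% fr$rejected$indices)
  rej <- fr$rejected[fr$rejected$indices == "1;2;4", ]
  expect_identical(rej$partner_indices, "1;2;3")
  expect_equal(rej$deciding_quantity, mi[3, 4])
  # accepted + rejected partition the filtered slice
  expect_identical(nrow(fr$accepted) + nrow(fr$rejected), 10L)
})

test_that("a threshold above every MI accepts everything", {
  gen <- echo_fixture(seed = 62)
  rec <- brute_force_scan(gen$data, 3, top_m = 15)
  mi <- pairwise_matrix(gen$data, "mi")
  fr <- mi_threshold_filter(rec, mi, threshold = 2)
  expect_identical(nrow(fr$rejected), 0L)
  expect_identical(fr$accepted$indices, rec$indices)
})

test_that("disjoint records pass any threshold; the top record always survives", {
  gen <- echo_fixture(seed = 63)
  rec <- brute_force_scan(gen$data, 3)
  mi <- pairwise_matrix(gen$data, "mi")
  two <- rec[vapply(rec$set, function(s)
    all(s %in% c(1, 2, 3)) || all(s %in% c(5, 6, 7)), TRUE), ]
  fr <- mi_threshold_filter(two, mi, threshold = 0)
  expect_identical(nrow(fr$rejected), 0L)
  full <- mi_threshold_filter(rec, mi, threshold = 0, top_n = 50)
  expect_identical(full$accepted$indices[1], rec$indices[1])
})

test_that("unsorted records are re-sorted with a warning", {
  gen <- echo_fixture(seed = 64)
  rec <- brute_force_scan(gen$data, 3, top_m = 8)
  shuffled <- rec[rev(seq_len(nrow(rec))), ]
  mi <- pairwise_matrix(gen$data, "mi")
  expect_warning(fr <- mi_threshold_filter(shuffled, mi, threshold = 2),
                 "re-sorting")
  expect_identical(fr$accepted$indices, rec$indices)
})

test_that("the merged-set filter rejects the echo via the union's synergy", {
  gen <- echo_fixture(seed = 65)
  rec <- brute_force_scan(gen$data, 3, top_m = 10)
  fr <- merged_set_filter(rec, gen$data)
  expect_true("1;2;3" %in% fr$accepted$indices)
  expect_true("1;2;4" %in% fr$rejected$indices)
  # deciding quantity is the union's canonical score, below the echo's own
  rej <- fr$rejected[fr$rejected$indices == "1;2;4", ]
  union_score <- -o_information(gen$data, 1:4)
  expect_equal(rej$deciding_quantity, union_score, tolerance = 1e-12)
  echo_rec <- rec[rec$indices == "1;2;4", ]
  expect_lt(union_score, echo_rec$canonical_score)
})

test_that("mutually disjoint or singleton record lists are accepted as-is", {
  gen <- echo_fixture(seed = 66)
  rec <- brute_force_scan(gen$data, 3)
  two <- rec[vapply(rec$set, function(s)
    all(s %in% c(1, 2, 3)) || all(s %in% c(5, 6, 7)), TRUE), ]
  fr <- merged_set_filter(two, gen$data)
  expect_identical(nrow(fr$rejected), 0L)
  expect_identical(fr$accepted$indices, two$indices)
  one <- merged_set_filter(rec[1, ], gen$data)
  expect_identical(nrow(one$accepted), 1L)
})

test_that("echo-free data passes the MI-threshold filter untouched", {
  gen <- planted_fixture(n = 1500, flip = 0.05, n_background = 6, seed = 67)
  rec <- brute_force_scan(gen$data, 3)
  mi <- pairwise_matrix(gen$data, "mi")
  for (thr in c(0.2, 0.5, 0.8)) {
    fr <- mi_threshold_filter(rec, mi, threshold = thr, top_n = 30)
    expect_identical(nrow(fr$rejected), 0L)
  }
})

test_that("the grid scan reproduces single filter calls and sums to one", {
  gen <- echo_fixture(seed = 68)
  rec <- brute_force_scan(gen$data, 3)
  mi <- pairwise_matrix(gen$data, "mi")
  grid <- echo_grid_scan(rec, mi, top_n_grid = c(5, 20, 50),
                         threshold_grid = c(0, 0.6, 1.5))
  expect_true(all(grid$accepted + grid$rejected == 1))
  single <- mi_threshold_filter(rec, mi, threshold = 0.6, top_n = 20)
  expect_equal(grid$accepted["20", "0.6"],
               nrow(single$accepted) / 20)
  # threshold 0 rejects every two-node-overlap partner it inspects
  expect_true(all(grid$rejected[, "0"] >= grid$rejected[, "1.5"]))
})

test_that("substitution robustness measures interchangeability", {
  gen <- echo_fixture(seed = 69)
  rec <- brute_force_scan(gen$data, 3)
  cutoff <- 0.5  # canonical scale; the planted triplet scores ~0.7
  # echo partner 4 is a noisy copy of 3: substituting it should retain
  # high synergy; substituting independent background should not
  sub <- substitution_robustness(gen$data, rec,
                                 correlated_pairs = list(c(3L, 4L)),
                                 synergy_cutoff = cutoff)
  fwd <- sub[sub$from == 3 & sub$to == 4, ]
  expect_identical(fwd$n_eligible, 1L)
  expect_equal(fwd$percentage, 100)
  # an exact copy gives identical scores in both directions
  st <- gen$data$states
  st <- cbind(st, st[, 3])
  d2 <- discrete_dataset(st, names = c(gen$data$names, "copy3"))
  rec2 <- brute_force_scan(d2, 3)
  sub2 <- substitution_robustness(d2, rec2,
                                  correlated_pairs = list(c(3L, 9L)),
                                  synergy_cutoff = cutoff)
  expect_true(all(sub2$percentage[sub2$n_eligible > 0] == 100))
  # independent partner: the substituted triplet loses its synergy
  sub3 <- substitution_robustness(gen$data, rec,
                                  correlated_pairs = list(c(3L, 6L)),
                                  synergy_cutoff = cutoff)
  fwd3 <- sub3[sub3$from == 3 & sub3$to == 6, ]
  expect_equal(fwd3$percentage, 0)
})

test_that("substitution percentages follow k/N * 100", {
  # arithmetic contract on a hand-built record list
  gen <- echo_fixture(seed = 70)
  rec <- brute_force_scan(gen$data, 3)
  sub <- substitution_robustness(gen$data, rec,
                                 correlated_pairs = list(c(3L, 4L)),
                                 synergy_cutoff = 0.5)
  with_n <- sub[sub$n_eligible > 0, ]
  expect_equal(with_n$percentage,
               100 * with_n$n_retained / with_n$n_eligible)
})

test_that("filter results serialize to paired CSVs", {
  gen <- echo_fixture(seed = 71)
  rec <- brute_force_scan(gen$data, 3, top_m = 10)
  fr <- mi_threshold_filter(rec, pairwise_matrix(gen$data, "mi"), 0.6)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_filter_result(fr, fa, fb)
  acc <- utils::read.csv(fa)
  rej <- utils::read.csv(fb)
  expect_identical(nrow(acc), nrow(fr$accepted))
  expect_true("deciding_quantity" %in% names(rej))
})
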