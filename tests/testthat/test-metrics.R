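table2 <- function() fig1_count_table()

test_that("TP/FN/FP on the published toy table match worked values", {
  ct <- table2()
  tp <- count_tp(ct); fn <- count_fn(ct); fp <- count_fp(ct)
  expect_equal(tp$by_neuron[["green"]], 1)  # choose(2,2) + choose(1,2)
  expect_equal(fn$by_neuron[["green"]], 2)  # 2 * 1 cross-column pairs
  expect_equal(fp$global, 2)                # green x orange pairs in column 1
  expect_equal(fp$incident_by_neuron[["green"]], 2)
  expect_equal(fp$by_neuron[["green"]], 1)  # halved merge attribution
  expect_equal(sum(fp$by_neuron), fp$global)
})

test_that("single-row tallies match direct pair enumeration", {
  ct <- count_table(matrix(c(3, 2), 1, 2))
  expect_equal(count_tp(ct)$global, 4)   # choose(3,2) + choose(2,2)
  expect_equal(count_fn(ct)$global, 6)   # 3 * 2 cross pairs
  # deletion-heavy neuron: 200 deleted of 1000 terminals
  M <- matrix(c(200, 800), 1, 2, dimnames = list("g1", c("del", "s1")))
  ct2 <- count_table(rbind(ins = c(0, 0), M))
  expect_equal(count_fn(ct2)$global, choose(200, 2) + 200 * 800)  # 179900
  expect_equal(count_tp(ct2)$global + count_fn(ct2)$global, choose(1000, 2))
})

test_that("insertion and merge false positives attribute per the halving rule", {
  # column with 3 inserted terminals and 2 neuron terminals
  M <- matrix(c(0, 0, 3, 2), 2, 2,
              dimnames = list(c("ins", "g1"), c("del", "s1")))
  ct <- count_table(M)
  fp <- count_fp(ct)
  expect_equal(fp$by_neuron[["ins"]], 3)  # choose(3,2)
  expect_equal(fp$by_neuron[["g1"]], 6)   # 2 * 3 full weight
  expect_equal(fp$global, 9)
  # two merged neurons with m terminals each
  m <- 7
  ct2 <- count_table(matrix(c(m, m), 2, 1))
  fp2 <- count_fp(ct2)
  expect_equal(fp2$global, m^2)
  expect_equal(unname(fp2$by_neuron[-1]), c(m^2 / 2, m^2 / 2))
})

test_that("f-beta conventions handle zero tallies as specified", {
  expect_equal(round(nri_from_counts(1, 2, 2)$score, 3), 0.333)
  expect_equal(nri_from_counts(5, 0, 0)$score, 1)
  expect_equal(nri_from_counts(0, 1, 1)$score, 0)
  expect_equal(nri_from_counts(0, 0, 3)$score, 0)
  expect_equal(nri_from_counts(0, 0, 0)$score, 1)
  # beta weighting: recall dominates for beta > 1
  r <- nri_from_counts(10, 0, 10, beta = 2)
  expect_equal(r$score, 5 * 0.5 * 1 / (4 * 1 + 0.5))
})

test_that("per-neuron scores match the two attribution conventions", {
  ct <- table2()
  expect_equal(round(neuron_nri(ct, "green", "incident")$score, 3), 0.333)
  expect_equal(neuron_nri(ct, "green", "attributed")$score, 0.4)
  expect_equal(neuron_nri(ct, "blue")$score, 1)
  expect_error(neuron_nri(ct, "purple"), "unknown")
})

test_that("tallies agree with brute-force pair enumeration on random tables", {
  set.seed(99)
  for (rep in 1:200) {
    ct <- random_count_table()
    oracle <- pair_oracle(ct)
    expect_equal(count_tp(ct)$global, oracle$tp)
    expect_equal(count_fn(ct)$global, oracle$fn)
    fp <- count_fp(ct)
    expect_equal(fp$global, oracle$fp)
    expect_equal(sum(fp$by_neuron), fp$global)
    if (length(oracle$fp_by_neuron) > 0) {
      expect_equal(unname(fp$by_neuron[names(oracle$fp_by_neuron)]),
                   unname(oracle$fp_by_neuron))
    }
    # conservation: per-neuron TP + FN = choose(row total, 2)
    rs <- rowSums(unclass(ct)[-1, , drop = FALSE])
    expect_equal(count_tp(ct)$by_neuron + count_fn(ct)$by_neuron,
                 choose(rs, 2))
  }
})

test_that("adapted Rand equals pair-enumeration Rand and is 1 when perfect", {
  perfect <- count_table(diag(c(4, 6, 3)))
  expect_equal(adapted_rand(perfect)$score, 1)
  set.seed(123)
  for (rep in 1:50) {
    ct <- random_count_table(4, 4)
    o <- pair_oracle(ct)
    r <- adapted_rand(ct)
    total_pairs <- choose(sum(unclass(ct)), 2)
    expect_equal(r$tn, o$tn)
    expect_equal(r$tp + r$tn + r$fp + r$fn, total_pairs)
    # oracle Rand on the full partition pair classification
    M <- unclass(ct)
    tp_full <- sum(choose(M, 2))
    expect_equal(r$score, (tp_full + o$tn) / total_pairs)
  }
  # the as-printed TN variant never exceeds the pair-consistent one
  set.seed(321)
  for (rep in 1:20) {
    ct <- random_count_table(4, 4)
    expect_lte(adapted_rand(ct, tn_mode = "half_quadrant")$tn,
               adapted_rand(ct)$tn)
  }
})

test_that("extreme splitting keeps the adapted Rand near 1", {
  # 50 neurons, every terminal its own fragment
  M <- matrix(0, 50, 500)
  for (i in 1:50) M[i, ((i - 1) * 10 + 1):(i * 10)] <- 1
  ct <- count_table(M)
  expect_gt(adapted_rand(ct)$score, 0.97)
  expect_lt(global_nri(ct)$score, 0.05)
})

test_that("normalized VI is 0 iff perfect, in [0,1], and base-free", {
  perfect <- count_table(diag(c(5, 2, 9)))
  expect_equal(normalized_vi(perfect)$score, 0)
  single <- count_table(matrix(10, 1, 1))
  expect_equal(normalized_vi(single)$score, 0)
  set.seed(55)
  for (rep in 1:50) {
    ct <- random_count_table()
    if (sum(unclass(ct)) == 0) next
    v <- normalized_vi(ct)
    expect_gte(v$score, 0)
    expect_lte(v$score, 1 + 1e-12)
    M <- unclass(ct)
    imperfect <- any((rowSums(M > 0) > 1)[-1]) || any((colSums(M > 0) > 1)[-1]) ||
      sum(M[1, ]) > 0 || sum(M[, 1]) > 0
    if (!imperfect) expect_equal(v$score, 0)
    else expect_gt(v$score, 0)
  }
  # hand-computed 2x2 example: joint {2,1;1,2}/6
  ct2 <- count_table(matrix(c(2, 1, 1, 2), 2, 2))
  p <- c(2, 1, 1, 2) / 6
  hj <- -sum(p * log(p))
  hm <- -sum(rep(0.5, 2) * log(0.5))
  expect_equal(normalized_vi(ct2)$score, (2 * (hj - hm)) / hj)
  expect_error(normalized_vi(count_table(matrix(0, 2, 2))), "all-zero")
})

test_that("degradation is strictly monotone in extra errors", {
  # deleting one more synapse from a neuron with >= 2 remaining
  base <- global_nri(count_table(matrix(c(0, 0, 0, 10), 2, 2,
                                        dimnames = list(c("ins", "g"),
                                                        c("del", "s")))))
  worse <- global_nri(count_table(matrix(c(0, 2, 0, 8), 2, 2,
                                         dimnames = list(c("ins", "g"),
                                                         c("del", "s")))))
  expect_lt(worse$score, base$score)
  # merging two fragments strictly decreases precision
  split2 <- count_table(matrix(c(6, 0, 0, 6), 2, 2))
  merged <- count_table(matrix(c(6, 6), 2, 1))
  expect_lt(global_nri(merged)$precision, global_nri(split2)$precision)
})

test_that("per-neuron report covers every ground-truth neuron", {
  ct <- table2()
  rep <- nri_by_neuron(ct, attribution = "incident")
  expect_setequal(rep$neuron, c("blue", "green", "orange", "red"))
  expect_equal(round(rep$nri[rep$neuron == "green"], 3), 0.333)
  expect_equal(rep$nri[rep$neuron == "blue"], 1)
})
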