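test_that("overlap score matches its defining arithmetic", {
  expect_equal(overlap_score(letters[1:10], letters[6:15]), 0.25)
  expect_equal(overlap_score(letters[1:4], letters[1:4]), 1)
  expect_equal(overlap_score(c("a", "b", "c", "d"), c("a", "b", "c", "e")),
               0.5625)
  expect_equal(overlap_score(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_score(c("a", "b"), c("b", "a")), 1)  # order-free
  expect_error(overlap_score(character(), "a"), "empty")
})

test_that("matched fraction counts predictions with omega >= cutoff (inclusive)", {
  ref <- complex_set(list(r1 = letters[1:4], r2 = letters[10:13]))
  expect_equal(fraction_matched(ref, ref),
               list(n_clusters = 2L, n_matched = 2L))
  far <- complex_set(list(p1 = c("x", "y"), p2 = c("z", "w"), p3 = c("q", "v")))
  expect_equal(fraction_matched(far, ref)$n_matched, 0L)

  # one of three predictions overlaps a reference at exactly omega = 0.25
  pred <- complex_set(list(p1 = c("a", "b", "x", "y"), p2 = c("q", "v"),
                           p3 = c("m", "n")))
  expect_equal(oracle_omega(pred$p1, ref$r1), 0.25)
  expect_equal(fraction_matched(pred, ref, 0.25)$n_matched, 1L)
})

test_that("confusion matrix counts shared proteins per (reference, prediction)", {
  one <- complex_set(list(k = c("A", "B", "C")))
  cm1 <- confusion_matrix(one, one)
  expect_equal(unname(cm1[1, 1]), 3L)
  expect_equal(unname(attr(cm1, "ref_sizes")), 3L)

  ref <- complex_set(list(r1 = c("A", "B", "C"), r2 = c("D", "E", "F")))
  pred <- complex_set(list(p1 = c("A", "B", "D"), p2 = c("D", "E", "F")))
  cm <- confusion_matrix(ref, pred)
  expect_equal(matrix(as.integer(cm), 2, 2), matrix(c(2L, 1L, 0L, 3L), 2, 2))
  expect_equal(unname(colSums(cm)), c(3, 3))

  disj <- complex_set(list(p = c("x", "y")))
  expect_true(all(confusion_matrix(ref, disj) == 0))
})

test_that("Sn, PPV and Acc follow the confusion-matrix formulas", {
  ref <- complex_set(list(r1 = c("A", "B", "C"), r2 = c("D", "E", "F")))
  pred <- complex_set(list(p1 = c("A", "B", "D"), p2 = c("D", "E", "F")))
  cm <- confusion_matrix(ref, pred)
  expect_equal(clustering_wise_sn(cm), 5 / 6)
  expect_equal(clustering_wise_ppv(cm), 5 / 6)
  expect_equal(geometric_accuracy(5 / 6, 5 / 6), 5 / 6)
  expect_equal(geometric_accuracy(0.5, 0.125), 0.25)
  expect_equal(geometric_accuracy(0, 0.7), 0)

  perfect <- confusion_matrix(ref, ref)
  expect_equal(clustering_wise_sn(perfect), 1)
  expect_equal(clustering_wise_ppv(perfect), 1)

  # a single prediction split 2/1 across two references: PPV = 2/3
  split <- confusion_matrix(ref, complex_set(list(p = c("A", "B", "D"))))
  expect_equal(clustering_wise_ppv(split), 2 / 3)

  disj <- confusion_matrix(ref, complex_set(list(p = c("x", "y"))))
  expect_equal(clustering_wise_sn(disj), 0)
  expect_warning(ppv0 <- clustering_wise_ppv(disj), "disjoint")
  expect_equal(ppv0, 0)
})

test_that("MMR uses a one-to-one matching, not the row-max upper bound", {
  ref <- complex_set(list(r1 = letters[1:10], r2 = letters[11:20]))
  # one prediction overlapping both references; only one pairing may count
  pred <- complex_set(list(p1 = c(letters[1:9], letters[11:19])))
  om1 <- oracle_omega(pred$p1, ref$r1)
  expect_equal(max_matching_ratio(pred, ref), max(om1, om1) / 2)
  expect_equal(mmr_rowmax(pred, ref), om1)  # reuse allowed in the bound

  expect_equal(max_matching_ratio(ref, ref), 1)
  expect_equal(max_matching_ratio(complex_set(list(p = c("zz", "zx"))), ref), 0)
  expect_error(max_matching_ratio(ref, list()), "empty")
})

test_that("MMR equals brute-force enumeration on random small instances", {
  withr::with_seed(20, {
    for (rep in 1:50) {
      ref <- random_complex_set(sample(1:6, 1))
      pred <- random_complex_set(sample(1:6, 1))
      expect_equal(max_matching_ratio(pred, ref), oracle_mmr(pred, ref),
                   tolerance = 1e-9)
      expect_lte(max_matching_ratio(pred, ref),
                 mmr_rowmax(pred, ref) + 1e-12)
    }
  })
})

test_that("metrics are invariant under complex order and protein relabeling", {
  withr::with_seed(31, {
    ref <- random_complex_set(4)
    pred <- random_complex_set(5)
    e1 <- suppressWarnings(evaluate_all(pred, ref))
    perm <- suppressWarnings(evaluate_all(pred[sample(5)], ref[sample(4)]))
    expect_equal(perm[c("sn", "ppv", "acc", "mmr", "n_matched")],
                 e1[c("sn", "ppv", "acc", "mmr", "n_matched")])
    map <- stats::setNames(sprintf("Q%02d", 1:12), LETTERS[1:12])
    rel <- suppressWarnings(evaluate_all(
      lapply(pred, function(m) unname(map[m])),
      lapply(ref, function(m) unname(map[m]))))
    expect_equal(rel[c("sn", "ppv", "acc", "mmr", "n_matched")],
                 e1[c("sn", "ppv", "acc", "mmr", "n_matched")])
  })
})

test_that("matching an unmatched reference never lowers MMR or Sn", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      ref <- random_complex_set(4, universe = LETTERS[1:20])
      pred <- random_complex_set(3, universe = LETTERS[1:10])
      base_mmr <- max_matching_ratio(pred, ref)
      base_sn <- clustering_wise_sn(confusion_matrix(ref, pred))
      pred2 <- complex_set(c(pred, ref[4]))
      expect_gte(max_matching_ratio(pred2, ref), base_mmr - 1e-12)
      expect_gte(clustering_wise_sn(confusion_matrix(ref, pred2)),
                 base_sn - 1e-12)
    }
  })
})

test_that("evaluate_all composes the individual metrics", {
  ref <- complex_set(list(r1 = c("A", "B", "C"), r2 = c("D", "E", "F")))
  perfect <- evaluate_all(ref, ref)
  expect_equal(perfect[c("sn", "ppv", "acc", "mmr")],
               list(sn = 1, ppv = 1, acc = 1, mmr = 1))
  expect_equal(perfect$n_matched, 2L)

  expect_warning(none <- evaluate_all(complex_set(list()), ref), "disjoint")
  expect_equal(none[c("sn", "ppv", "acc", "mmr", "n_clusters", "n_matched")],
               list(sn = 0, ppv = 0, acc = 0, mmr = 0,
                    n_clusters = 0L, n_matched = 0L))

  pred <- complex_set(list(p1 = c("A", "B", "D"), p2 = c("D", "E", "F")))
  ev <- evaluate_all(pred, ref)
  expect_equal(ev$sn, 5 / 6)
  expect_equal(ev$ppv, 5 / 6)
  expect_equal(ev$acc, 5 / 6)
  expect_equal(ev$mmr, oracle_mmr(pred, ref))
  expect_error(evaluate_all(pred, list()), "empty")
})
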