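test_that("cohesiveness trades internal against boundary weight plus penalty", {
  tripen <- make_net(c("A-B", "B-C", "A-C", "C-D"))
  expect_equal(cohesiveness(tripen, c("A", "B", "C"), penalty = 0), 0.75)

  clique <- ppi_network(clique_edges(paste0("P", 1:4)))
  expect_equal(cohesiveness(clique, paste0("P", 1:4), penalty = 0), 1)

  expect_equal(cohesiveness(tripen, "D", penalty = 0), 0)  # no internal edge
  expect_error(cohesiveness(tripen, character()), "empty")

  # penalty enters the denominator per member
  expect_equal(cohesiveness(tripen, c("A", "B", "C"), penalty = 2),
               3 / (3 + 1 + 6))
})

test_that("greedy growth finds the expected local optima", {
  cl5 <- ppi_network(clique_edges(paste0("P", 1:5)))
  g <- grow_from_seed(cl5, "P3")
  expect_equal(g$members, paste0("P", 1:5))

  star <- make_net(c("H-A", "H-B", "H-C", "H-D"))
  g2 <- grow_from_seed(star, "H", detection_params(penalty = 0))
  expect_equal(g2$members, sort(c("H", "A", "B", "C", "D")))

  # two 4-cliques joined by a single bridge: growth stays in the seed's clique
  bar <- ppi_network(rbind(clique_edges(paste0("A", 1:4)),
                           clique_edges(paste0("B", 1:4)),
                           data.frame(a = "A1", b = "B1")))
  expect_equal(grow_from_seed(bar, "A2")$members, paste0("A", 1:4))
  expect_equal(grow_from_seed(bar, "B3")$members, paste0("B", 1:4))

  expect_error(grow_from_seed(cl5, "ZZ"), "unknown seed")
})

test_that("merging collapses overlapping groups above the threshold", {
  expect_equal(merge_overlapping(list(c("A", "B", "C"), c("A", "B", "C"))),
               list(c("A", "B", "C")))
  disj <- list(c("A", "B"), c("C", "D"))
  expect_equal(merge_overlapping(disj), disj)
  # omega = 3^2 / (4 * 4) = 0.5625 >= 0.5 -> single union
  out <- merge_overlapping(list(c("A", "B", "C", "D"), c("A", "B", "C", "E")),
                           merge_overlap = 0.5)
  expect_equal(out, list(c("A", "B", "C", "D", "E")))
  # ... but not at the default 0.8
  expect_length(merge_overlapping(list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "E"))), 2L)
})

test_that("detection returns planted cliques and respects its own filters", {
  net <- ppi_network(rbind(clique_edges(paste0("A", 1:5)),
                           clique_edges(paste0("B", 1:5)),
                           data.frame(a = c("X1", "Y1"), b = c("X2", "Y2"))))
  found <- detect_complexes(net)
  expect_length(found, 2L)
  expect_equal(sort(unname(vapply(found, paste, "", collapse = " "))),
               sort(c(paste(paste0("A", 1:5), collapse = " "),
                      paste(paste0("B", 1:5), collapse = " "))))

  empty <- detect_complexes(ppi_network())
  expect_length(empty, 0L)
})

test_that("the density filter discards a 4-star at 0.6 but keeps it after one extra edge", {
  params <- detection_params(density_threshold = 0.6, penalty = 0,
                             min_size = 3)
  star <- make_net(c("H-A", "H-B", "H-C"))
  found <- detect_complexes(star, params)
  expect_false(any(vapply(found, function(m) setequal(m, c("H", "A", "B", "C")),
                          logical(1))))
  star2 <- make_net(c("H-A", "H-B", "H-C", "A-C"))
  found2 <- detect_complexes(star2, params)
  expect_true(any(vapply(found2, function(m) setequal(m, c("H", "A", "B", "C")),
                         logical(1))))
})

test_that("every reported complex meets the size and density constraints", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      truth <- generate_synthetic(synthetic_config(
        n_complexes = 6, size_range = c(4, 9), p_in = 0.85, p_noise = 0.03,
        holdout_fraction = 0, n_false_lit = 0, seed = sample(1e6, 1)))
      net <- filter_self_and_isolated(truth$network)
      params <- detection_params()
      found <- detect_complexes(net, params)
      dthr <- attr(found, "density_threshold")
      for (m in found) {
        expect_gte(length(m), params$min_size)
        expect_gte(complex_density(net, m), dthr - 1e-12)
      }
    }
  })
})

test_that("detection is invariant under protein relabeling", {
  # tie-breaking is lexicographic by id, so label invariance is only promised
  # where no growth decision rests on a tie between isomorphic alternatives;
  # disjoint structures of distinct sizes make every decision tie-free
  net <- ppi_network(rbind(clique_edges(paste0("A", 1:4)),
                           clique_edges(paste0("B", 1:5)),
                           data.frame(a = c("P1", "P2"), b = c("P2", "P3"))))
  relabel <- stats::setNames(sprintf("Z%02d", seq_along(net$proteins)),
                             rev(net$proteins))
  net2 <- ppi_network(data.frame(a = relabel[net$edges$a],
                                 b = relabel[net$edges$b]))
  f1 <- detect_complexes(net)
  f2 <- detect_complexes(net2)
  canon1 <- sort(unname(vapply(f1, function(m) paste(sort(unname(relabel[m])),
                                                     collapse = " "), "")))
  canon2 <- sort(unname(vapply(f2, function(m) paste(m, collapse = " "), "")))
  expect_equal(canon1, canon2)
})

test_that("adding leaf-leaf edges to stars increases the number of retained complexes", {
  # two hubs with 3 leaves each; at threshold 0.6 nothing passes, and closing
  # one leaf pair per star retains both stars
  stars <- make_net(c("H1-A1", "H1-A2", "H1-A3", "H2-B1", "H2-B2", "H2-B3"))
  params <- detection_params(density_threshold = 0.6)
  n_before <- length(detect_complexes(stars, params))
  closed <- make_net(c("H1-A1", "H1-A2", "H1-A3", "A1-A2",
                       "H2-B1", "H2-B2", "H2-B3", "B1-B2"))
  n_after <- length(detect_complexes(closed, params))
  expect_gt(n_after, n_before)
})

test_that("the detector registry dispatches and placeholder slots stay unimplemented", {
  expect_true(all(c("cluster_one", "cmc", "coach", "rrw") %in% list_detectors()))
  expect_identical(get_detector("cluster_one"), detect_complexes)
  expect_error(get_detector("cmc")(ppi_network(), detection_params()),
               "not implemented")
  expect_error(get_detector("nope"), "unknown detector")
  register_detector("constant", function(net, params) complex_set(list(c("A", "B", "C"))))
  expect_equal(get_detector("constant")(ppi_network(), NULL)$C1, c("A", "B", "C"))
})
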