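#' Configuration for the planted-complex simulator
#'
#' The simulator emulates the inputs of the integration experiment: a PPI
#' network with planted, possibly overlapping complexes; a held-out stream of
#' literature interactions whose confidence score correlates with edge truth;
#' an alias table mapping common names to systematic-style ids; and a
#' (possibly incomplete) gold standard.
#'
#' Defaults describe a mid-sized TAP-style study: 15 planted complexes of
#' 5 to 12 proteins (curated catalogs average roughly 5 to 12 members per
#' complex), intra-complex pairs wired with probability 0.9, background noise
#' edges at probability 0.01 over all remaining pairs, 10% of complexes
#' sharing a protein with another complex, 20% of true edges withheld from
#' the network and emitted as literature records, and 200 spurious literature
#' pairs.  Literature scores follow the two-component model
#' `N(0.8, 0.1)` for true edges and `N(-0.8, 0.1)` for spurious ones, an
#' unbounded real scale spanning roughly \[-1, 1\] that matches confidence
#' cutoffs between 0 and -0.9.
#'
#' @param n_complexes number of planted complexes.
#' @param size_range integer `(min, max)` complex sizes, `min >= 3`.
#' @param p_in probability that an intra-complex pair is wired.
#' @param p_noise probability that a background (non-intra-complex) pair is
#'   wired.
#' @param overlap_fraction fraction of complexes seeded with one or two
#'   proteins borrowed from another complex.
#' @param holdout_fraction fraction of true (wired intra-complex) edges
#'   withheld from the network and emitted as literature records.
#' @param n_false_lit number of spurious literature pairs (non-edges).
#' @param true_score_mean,true_score_sd,false_score_mean,false_score_sd the
#'   literature confidence score model.
#' @param weighted generate a weighted network?
#' @param intra_weight,noise_weight base edge weights before noise (weighted
#'   networks only).
#' @param weight_noise_sd standard deviation of the Gaussian weight noise;
#'   weights are clamped to \[0, 1\].
#' @param n_extra_proteins proteins outside any planted complex (background
#'   substrate).
#' @param gold_drop_fraction fraction of planted complexes removed from the
#'   emitted gold standard (gold standards are typically incomplete).
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_complexes = 15L,
                             size_range = c(5L, 12L),
                             p_in = 0.9,
                             p_noise = 0.01,
                             overlap_fraction = 0.1,
                             holdout_fraction = 0.2,
                             n_false_lit = 200L,
                             true_score_mean = 0.8,
                             true_score_sd = 0.1,
                             false_score_mean = -0.8,
                             false_score_sd = 0.1,
                             weighted = TRUE,
                             intra_weight = 0.8,
                             noise_weight = 0.3,
                             weight_noise_sd = 0.1,
                             n_extra_proteins = 20L,
                             gold_drop_fraction = 0,
                             seed = 1L) {
  size_range <- as.integer(size_range)
  stopifnot(n_complexes >= 1L,
            length(size_range) == 2L,
            size_range[1] >= 3L, size_range[2] >= size_range[1],
            is_probability(p_in), is_probability(p_noise),
            is_probability(overlap_fraction), is_probability(holdout_fraction),
            n_false_lit >= 0,
            is.finite(true_score_mean), true_score_sd >= 0,
            is.finite(false_score_mean), false_score_sd >= 0,
            is.logical(weighted),
            weight_noise_sd >= 0,
            n_extra_proteins >= 0,
            is_probability(gold_drop_fraction), gold_drop_fraction < 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(as.list(environment()), class = "synthetic_config")
}

# systematic-ORF-style identifiers: YAL001W, YAL002C, ...
make_systematic_ids <- function(n) {
  if (n > 6000) stop("id scheme supports at most 6000 proteins", call. = FALSE)
  i <- seq_len(n) - 1L
  sprintf("Y%s%s%03d%s",
          LETTERS[(i %/% 396L) %% 16L + 1L],
          c("L", "R")[(i %/% 198L) %% 2L + 1L],
          i %% 198L + 1L,
          c("W", "C")[i %% 2L + 1L])
}

all_pairs <- function(ids) {
  if (length(ids) < 2L) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  cmb <- utils::combn(sort(ids), 2L)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

generate_impl <- function(config) {
  cf <- config
  sizes <- sample(seq.int(cf$size_range[1], cf$size_range[2]),
                  cf$n_complexes, replace = TRUE)
  n_core <- sum(sizes)
  ids <- make_systematic_ids(n_core + cf$n_extra_proteins)
  core_ids <- ids[seq_len(n_core)]

  blocks <- split(core_ids, rep(seq_along(sizes), sizes))
  complexes <- lapply(blocks, identity)

  n_ov <- round(cf$overlap_fraction * cf$n_complexes)
  if (n_ov > 0 && cf$n_complexes >= 2L) {
    targets <- sample(seq_len(cf$n_complexes), n_ov)
    for (k in targets) {
      donor <- sample(setdiff(seq_len(cf$n_complexes), k), 1L)
      take <- min(sample(1:2, 1L), length(complexes[[donor]]))
      complexes[[k]] <- unique(c(complexes[[k]],
                                 sample(complexes[[donor]], take)))
    }
  }
  complexes <- lapply(complexes, sort)
  names(complexes) <- sprintf("K%02d", seq_along(complexes))

  # candidate intra-complex pairs (union over complexes), wired w.p. p_in
  intra <- unique(do.call(rbind, lapply(complexes, all_pairs)))
  true_edges <- intra[stats::runif(nrow(intra)) < cf$p_in, , drop = FALSE]
  rownames(true_edges) <- NULL

  universe <- all_pairs(ids)
  intra_key <- pair_key(intra$a, intra$b)
  background <- universe[!(pair_key(universe$a, universe$b) %in% intra_key), ,
                         drop = FALSE]
  noise_edges <- background[stats::runif(nrow(background)) < cf$p_noise, ,
                            drop = FALSE]

  n_true <- nrow(true_edges)
  n_hold <- floor(cf$holdout_fraction * n_true)
  hold_idx <- if (n_hold > 0) sort(sample(n_true, n_hold)) else integer()
  held_out <- true_edges[hold_idx, , drop = FALSE]
  net_true <- true_edges[setdiff(seq_len(n_true), hold_idx), , drop = FALSE]

  net_edges <- rbind(net_true, noise_edges)
  if (cf$weighted) {
    base <- c(rep(cf$intra_weight, nrow(net_true)),
              rep(cf$noise_weight, nrow(noise_edges)))
    net_edges$weight <- clamp01(base + stats::rnorm(length(base), 0,
                                                    cf$weight_noise_sd))
  }
  network <- ppi_network(net_edges, proteins = ids, weighted = cf$weighted)

  # aliases: gene-like common names, one per protein
  stems <- c("cdc", "cln", "rpl", "rps", "act", "tub", "sec", "pre",
             "nup", "mcm", "orc", "taf")
  common <- paste0(stems[(seq_along(ids) - 1L) %% length(stems) + 1L],
                   seq_along(ids))
  aliases <- alias_table(common, ids)
  to_common <- stats::setNames(common, ids)

  # literature stream: held-out true edges + spurious pairs, in common names
  # with mixed case, scored by the two-component confidence model
  used_key <- pair_key(c(true_edges$a, noise_edges$a),
                       c(true_edges$b, noise_edges$b))
  free <- background[!(pair_key(background$a, background$b) %in% used_key), ,
                     drop = FALSE]
  n_false <- min(cf$n_false_lit, nrow(free))
  false_pairs <- free[sample(nrow(free), n_false), , drop = FALSE]

  mixcase <- function(x) {
    up <- stats::runif(length(x)) < 0.5
    ifelse(up, toupper(x), x)
  }
  lit <- data.frame(
    name_a = mixcase(to_common[c(held_out$a, false_pairs$a)]),
    name_b = mixcase(to_common[c(held_out$b, false_pairs$b)]),
    score = c(stats::rnorm(nrow(held_out), cf$true_score_mean,
                           cf$true_score_sd),
              stats::rnorm(n_false, cf$false_score_mean, cf$false_score_sd)),
    is_true = rep(c(TRUE, FALSE), c(nrow(held_out), n_false)),
    stringsAsFactors = FALSE
  )
  if (nrow(lit)) lit <- lit[sample(nrow(lit)), , drop = FALSE]
  rownames(lit) <- NULL

  gold <- complexes
  if (cf$gold_drop_fraction > 0) {
    n_drop <- floor(cf$gold_drop_fraction * length(gold))
    if (n_drop > 0) gold <- gold[sort(sample(length(gold),
                                             length(gold) - n_drop))]
  }

  structure(
    list(network = network,
         complexes = complex_set(complexes),
         literature = lit,
         aliases = aliases,
         gold = complex_set(gold),
         true_edges = true_edges,
         held_out = held_out,
         config = cf),
    class = "synthetic_truth"
  )
}

#' Generate a planted-complex benchmark
#'
#' Draws complex sizes uniformly in `size_range`, wires intra-complex pairs
#' with probability `p_in` and background pairs with `p_noise`, withholds
#' `holdout_fraction` of the true edges as confidence-scored literature
#' records (plus `n_false_lit` spurious pairs), and emits the planted
#' complexes as ground truth together with an alias table and a gold standard.
#' All randomness flows from `config$seed` through an isolated RNG stream, so
#' a fixed seed reproduces the output exactly without touching the global
#' random state.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_truth`: a list with `network`
#'   (a [ppi_network()]), `complexes` (planted truth, a [complex_set()]),
#'   `literature` (records with columns `name_a`, `name_b`, `score`,
#'   `is_true`; names are common-name aliases), `aliases`
#'   (an [alias_table()]), `gold` (the emitted gold standard), `true_edges`,
#'   `held_out` and `config`.
#' @export
#' @examples
#' truth <- generate_synthetic(synthetic_config(n_complexes = 4, seed = 7))
#' truth$network
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(as.integer(config$seed), generate_impl(config))
}

#' Randomly drop complexes from a gold standard
#'
#' Emulates gold-standard incompleteness by removing a fixed fraction of
#' complexes, deterministically per seed.
#'
#' @param complexes a complex set.
#' @param drop_fraction fraction in \[0, 1) of complexes to remove
#'   (`floor(drop_fraction * n)` of them).
#' @param seed integer seed.
#' @return the reduced complex set.
#' @export
perturb_gold <- function(complexes, drop_fraction, seed = 1L) {
  stopifnot(is_probability(drop_fraction), drop_fraction < 1)
  n <- length(complexes)
  n_drop <- floor(drop_fraction * n)
  if (n_drop == 0L) return(complexes)
  withr::with_seed(as.integer(seed), {
    complexes[sort(sample(n, n - n_drop))]
  })
}
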