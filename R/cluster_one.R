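#' Detection parameters for cohesiveness-based complex detection
#'
#' @param penalty non-negative per-member boundary penalty in the
#'   cohesiveness score.  It models unobserved interactions: every member is
#'   charged as if it had this much additional boundary weight, which stops
#'   growth from swallowing weakly attached proteins.  Default 2.
#' @param density_threshold minimum density of a reported complex, or
#'   `"auto"`: weighted networks use 0.5; unweighted networks use 0.6 when the
#'   global transitivity falls below `transitivity_cutoff` (sparse, star-heavy
#'   topologies) and 0.5 otherwise.
#' @param min_size minimum complex size; candidates with fewer members are
#'   discarded.  Default 3.
#' @param merge_overlap overlap score at or above which two locally optimal
#'   groups are merged.  Default 0.8.
#' @param transitivity_cutoff transitivity below which the automatic density
#'   threshold resolves to 0.6 on unweighted networks.  Default 0.3.
#' @param max_iter_factor growth is hard-capped at
#'   `max_iter_factor * |proteins|` moves per seed to force termination.
#' @param seed_order seed selection rule; only `"degree"` (decreasing degree,
#'   ties broken lexicographically) is implemented.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(penalty = 2,
                             density_threshold = "auto",
                             min_size = 3L,
                             merge_overlap = 0.8,
                             transitivity_cutoff = 0.3,
                             max_iter_factor = 10L,
                             seed_order = "degree") {
  stopifnot(is.numeric(penalty), length(penalty) == 1L, penalty >= 0)
  if (!identical(density_threshold, "auto")) {
    stopifnot(is.numeric(density_threshold), length(density_threshold) == 1L,
              density_threshold >= 0, density_threshold <= 1)
  }
  min_size <- as.integer(min_size)
  stopifnot(min_size >= 1L,
            is_probability(merge_overlap), merge_overlap > 0,
            is_probability(transitivity_cutoff),
            max_iter_factor >= 1,
            identical(seed_order, "degree"))
  structure(
    list(penalty = penalty, density_threshold = density_threshold,
         min_size = min_size, merge_overlap = merge_overlap,
         transitivity_cutoff = transitivity_cutoff,
         max_iter_factor = max_iter_factor, seed_order = seed_order),
    class = "detection_params"
  )
}

# adjacency lists (self-loops excluded): per protein a named numeric vector of
# incident edge weights, names = neighbours; plus weighted degrees
build_adjacency <- function(net) {
  e <- net$edges[net$edges$a != net$edges$b, , drop = FALSE]
  w <- if (net$weighted) e$weight else rep(1, nrow(e))
  ends <- factor(c(e$a, e$b), levels = net$proteins)
  adj <- split(stats::setNames(c(w, w), c(e$b, e$a)), ends)
  list(adj = adj,
       deg = vapply(adj, sum, numeric(1)),
       n_nbr = lengths(adj))
}

coh_value <- function(w_in, w_bound, pen_total) {
  w_in <- max(w_in, 0)
  den <- w_in + max(w_bound, 0) + pen_total
  if (w_in <= 0 || den <= 0) 0 else w_in / den
}

#' Cohesiveness of a protein group
#'
#' The cohesiveness of a member set `V` is
#' `w_in / (w_in + w_bound + penalty * |V|)`, where `w_in` is the total weight
#' of edges with both endpoints in `V` and `w_bound` the total weight of edges
#' with exactly one endpoint in `V`.  It is 1 only for an isolated group with
#' internal edges and zero penalty, and 0 for any group without internal
#' edges.  Greedy maximization of this score drives [grow_from_seed()].
#'
#' @param net a [ppi_network()].
#' @param members non-empty character vector of member protein ids.
#' @param penalty per-member boundary penalty (see [detection_params()]).
#' @return a real in \[0, 1\].
#' @export
#' @examples
#' tri <- ppi_network(data.frame(a = c("A", "A", "B", "C"),
#'                               b = c("B", "C", "C", "D")))
#' cohesiveness(tri, c("A", "B", "C"), penalty = 0)  # 3 / (3 + 1)
cohesiveness <- function(net, members, penalty = 2) {
  stopifnot(inherits(net, "ppi_network"))
  members <- unique(as.character(members))
  if (!length(members)) stop("member set is empty", call. = FALSE)
  missing <- setdiff(members, net$proteins)
  if (length(missing)) {
    stop("member(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e <- net$edges[net$edges$a != net$edges$b, , drop = FALSE]
  w <- if (net$weighted) e$weight else rep(1, nrow(e))
  ain <- e$a %in% members
  bin <- e$b %in% members
  coh_value(sum(w[ain & bin]), sum(w[xor(ain, bin)]),
            penalty * length(members))
}

# greedy steepest-ascent growth on prebuilt adjacency
grow_impl <- function(ad, seed, params, n_proteins) {
  adj <- ad$adj
  deg <- ad$deg
  pen <- params$penalty
  tol <- 1e-12

  members <- seed
  in_set <- stats::setNames(TRUE, seed)
  w_in <- 0
  w_bound <- deg[[seed]]
  f_cur <- coh_value(w_in, w_bound, pen)
  max_iter <- ceiling(params$max_iter_factor * max(n_proteins, 1))

  weight_into <- function(v) {
    nb <- adj[[v]]
    sum(nb[names(nb) %in% members])
  }

  for (iter in seq_len(max_iter)) {
    best_f <- f_cur
    best_id <- NULL
    best_type <- NULL

    consider <- function(id, f_new, type) {
      if (f_new > best_f + tol ||
          (abs(f_new - best_f) <= tol && !is.null(best_id) && id < best_id)) {
        best_f <<- f_new
        best_id <<- id
        best_type <<- type
      }
    }

    ext <- setdiff(unique(unlist(lapply(adj[members], names),
                                 use.names = FALSE)), members)
    for (v in sort(ext)) {
      wv <- weight_into(v)
      f_new <- coh_value(w_in + wv, w_bound + deg[[v]] - 2 * wv,
                         pen * (length(members) + 1))
      consider(v, f_new, "add")
    }
    if (length(members) > 1L) {
      for (u in sort(setdiff(members, seed))) {
        wu <- weight_into(u)
        f_new <- coh_value(w_in - wu, w_bound - deg[[u]] + 2 * wu,
                           pen * (length(members) - 1))
        consider(u, f_new, "remove")
      }
    }

    if (is.null(best_id) || best_f <= f_cur + tol) break
    if (best_type == "add") {
      wv <- weight_into(best_id)
      w_in <- w_in + wv
      w_bound <- w_bound + deg[[best_id]] - 2 * wv
      members <- c(members, best_id)
    } else {
      wu <- weight_into(best_id)
      w_in <- w_in - wu
      w_bound <- w_bound - deg[[best_id]] + 2 * wu
      members <- setdiff(members, best_id)
    }
    f_cur <- best_f
  }

  list(members = sort(members), cohesiveness = f_cur)
}

#' Grow a cohesive group from a seed protein
#'
#' Greedy local search: starting from the singleton seed, repeatedly apply the
#' single best move -- adding an external neighbour or removing a member other
#' than the seed -- that strictly increases the group's [cohesiveness()];
#' stop at a local optimum.  Ties are broken towards the lexicographically
#' smallest protein id, making growth deterministic.
#'
#' @param net a [ppi_network()].
#' @param seed a protein id present in `net`.
#' @param params a [detection_params()] object.
#' @return a list with `members` (sorted character vector) and `cohesiveness`
#'   at the local optimum.
#' @export
grow_from_seed <- function(net, seed, params = detection_params()) {
  stopifnot(inherits(net, "ppi_network"), inherits(params, "detection_params"))
  seed <- as.character(seed)
  if (!seed %in% net$proteins) {
    stop("unknown seed protein: ", seed, call. = FALSE)
  }
  grow_impl(build_adjacency(net), seed, params, length(net$proteins))
}

#' Merge highly overlapping groups
#'
#' While any pair of groups has overlap score ([overlap_score()]) at or above
#' `merge_overlap`, the highest-scoring pair is replaced by its union; ties
#' are broken towards the pair whose sorted member lists are
#' lexicographically smallest.  On return all pairwise overlap scores are
#' below `merge_overlap`; exact duplicate groups (overlap 1) always collapse.
#'
#' @param groups a list of member-id character vectors, or of groups as
#'   returned by [grow_from_seed()].
#' @param merge_overlap overlap-score threshold in (0, 1\].
#' @return a list of merged member-id vectors.
#' @export
merge_overlapping <- function(groups, merge_overlap = 0.8) {
  stopifnot(is_probability(merge_overlap), merge_overlap > 0)
  sets <- lapply(groups, function(g) {
    sort(unique(as.character(if (is.list(g)) g$members else g)))
  })
  sets <- sets[lengths(sets) > 0]

  repeat {
    n <- length(sets)
    if (n < 2L) break
    keys <- vapply(sets, paste, character(1), collapse = " ")
    best <- NULL
    best_om <- -Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        om <- overlap_score(sets[[i]], sets[[j]])
        cand_key <- sort(c(keys[i], keys[j]))
        if (om > best_om + 1e-12 ||
            (abs(om - best_om) <= 1e-12 && !is.null(best) &&
             (cand_key[1] < best$key[1] ||
              (cand_key[1] == best$key[1] && cand_key[2] < best$key[2])))) {
          best_om <- om
          best <- list(i = i, j = j, key = cand_key)
        }
      }
    }
    if (best_om < merge_overlap) break
    sets[[best$i]] <- sort(union(sets[[best$i]], sets[[best$j]]))
    sets[[best$j]] <- NULL
  }
  sets
}

resolve_density_threshold <- function(net, params) {
  if (!identical(params$density_threshold, "auto")) {
    return(params$density_threshold)
  }
  if (net$weighted) return(0.5)
  t <- suppressWarnings(network_transitivity(net))
  if (t < params$transitivity_cutoff) 0.6 else 0.5
}

#' Detect potentially overlapping protein complexes
#'
#' Cohesiveness-based detection in three steps: (1) grow locally optimal
#' cohesive groups ([grow_from_seed()]) from seed proteins taken in decreasing
#' degree order, skipping proteins already covered by a grown group; (2) merge
#' highly overlapping groups ([merge_overlapping()]); (3) discard candidates
#' with fewer than `min_size` members or with [complex_density()] below the
#' resolved density threshold (see [detection_params()] for the automatic
#' rule).  Returned complexes may overlap.
#'
#' @param net a [ppi_network()]; self-loops are ignored.
#' @param params a [detection_params()] object.
#' @return a named list of sorted member-id vectors (a complex set), ordered
#'   by decreasing size then lexicographically, with attribute
#'   `density_threshold` recording the resolved threshold.
#' @export
detect_complexes <- function(net, params = detection_params()) {
  stopifnot(inherits(net, "ppi_network"), inherits(params, "detection_params"))
  net <- filter_self_and_isolated(net)
  if (!length(net$proteins) || !nrow(net$edges)) {
    return(structure(stats::setNames(list(), character()),
                     density_threshold = NA_real_))
  }
  dthr <- resolve_density_threshold(net, params)
  ad <- build_adjacency(net)

  seeds <- net$proteins[order(-ad$n_nbr, net$proteins)]
  covered <- character()
  groups <- list()
  for (s in seeds) {
    if (s %in% covered) next
    g <- grow_impl(ad, s, params, length(net$proteins))
    groups[[length(groups) + 1L]] <- g$members
    covered <- unique(c(covered, g$members))
  }

  merged <- merge_overlapping(groups, params$merge_overlap)
  keep <- vapply(merged, function(m) {
    length(m) >= params$min_size &&
      complex_density(net, m) >= dthr - 1e-12
  }, logical(1))
  res <- merged[keep]

  ord <- order(-lengths(res),
               vapply(res, paste, character(1), collapse = " "))
  res <- res[ord]
  names(res) <- if (length(res)) sprintf("C%d", seq_along(res)) else character()
  attr(res, "density_threshold") <- dthr
  res
}

# --- pluggable detector registry ------------------------------------------

.detectors <- new.env(parent = emptyenv())

#' Register or look up a complex detector
#'
#' Any function with signature `(net, params) -> complex set` can be
#' registered under a name and retrieved later, so alternative detectors can
#' be swapped into the sweep pipeline.  `"cluster_one"` is registered at load
#' time; `"cmc"`, `"coach"` and `"rrw"` exist as named slots but are
#' unimplemented placeholders that error when called.
#'
#' @param name detector name.
#' @param fun detector function `(net, params)`.
#' @return `register_detector()` returns `name` invisibly; `get_detector()`
#'   the registered function; `list_detectors()` the sorted names.
#' @export
register_detector <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .detectors)
  invisible(name)
}

#' @rdname register_detector
#' @export
get_detector <- function(name) {
  if (!exists(name, envir = .detectors, inherits = FALSE)) {
    stop("unknown detector: ", name, call. = FALSE)
  }
  get(name, envir = .detectors, inherits = FALSE)
}

#' @rdname register_detector
#' @export
list_detectors <- function() sort(ls(.detectors))

unimplemented_detector <- function(name) {
  force(name)
  function(net, params) {
    stop("detector '", name, "' is a registered slot but not implemented; ",
         "register your own with register_detector()", call. = FALSE)
  }
}
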