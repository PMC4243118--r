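#' Construct a PPI network
#'
#' A `ppi_network` is an undirected graph over protein identifiers, stored as
#' a canonicalized edge list.  Protein identifiers are arbitrary whitespace-free
#' tokens; by yeast convention they are systematic ORF names (e.g. `"YAL001C"`),
#' but the convention is not enforced.  Edges are unordered pairs, kept as
#' `(min, max)` in lexicographic order; duplicate pairs are collapsed keeping
#' the first occurrence (with a warning).  Self-loops are retained at
#' construction time and removed by [filter_self_and_isolated()], mirroring the
#' usual hygiene step applied to experimental interaction datasets.
#'
#' @param edges a data frame with character columns `a` and `b` and, for
#'   weighted networks, a numeric column `weight`.  `NULL` means no edges.
#' @param proteins additional protein identifiers to include even when they
#'   have no incident edge (isolated proteins survive until hygiene filtering).
#' @param weighted logical flag; when `FALSE` no edge carries a weight.
#'
#' @return an object of class `ppi_network`: a list with elements `edges`
#'   (data frame `a`, `b`\[, `weight`\]), `proteins` (sorted character vector)
#'   and `weighted`.
#' @seealso [read_ppi_network()], [filter_self_and_isolated()],
#'   [complex_density()], [network_transitivity()]
#' @export
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' net
ppi_network <- function(edges = NULL, proteins = character(), weighted = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
    if (weighted) edges$weight <- numeric()
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("a", "b") %in% names(edges))) {
    stop("`edges` needs columns `a` and `b`", call. = FALSE)
  }
  a <- check_protein_ids(edges$a)
  b <- check_protein_ids(edges$b)
  proteins <- check_protein_ids(as.character(proteins))

  cp <- canonicalize_pairs(a, b)
  out <- data.frame(a = cp$a, b = cp$b, stringsAsFactors = FALSE)
  if (weighted) {
    if (!("weight" %in% names(edges))) {
      stop("weighted network requires a `weight` column", call. = FALSE)
    }
    w <- as.numeric(edges$weight)
    if (length(w) && any(!is.finite(w))) {
      stop("edge weights must be finite", call. = FALSE)
    }
    out$weight <- w
  }

  dup <- duplicated(pair_key(out$a, out$b))
  if (any(dup)) {
    warning(sum(dup), " duplicate interaction pair(s) dropped; ",
            "first occurrence kept", call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL

  structure(
    list(edges = out,
         proteins = sort(unique(c(proteins, out$a, out$b))),
         weighted = isTRUE(weighted)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions (%s)\n",
              length(x$proteins), nrow(x$edges),
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

edge_weights <- function(net) {
  if (net$weighted) net$edges$weight else rep(1, nrow(net$edges))
}

#' Read a PPI network from a tab-separated edge list
#'
#' The file carries one interaction per line: `protein_a<TAB>protein_b` for
#' unweighted networks, plus a third numeric column for weighted ones.  Lines
#' starting with `#` and blank lines are ignored.  Duplicate unordered pairs
#' are collapsed first-wins with a warning.  Self-interactions are read as-is;
#' apply [filter_self_and_isolated()] afterwards for the usual hygiene.
#'
#' @param path path to the edge-list file.
#' @param weighted expect (and require) a third weight column?
#' @return a [ppi_network()].
#' @export
read_ppi_network <- function(path, weighted = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(ppi_network(weighted = weighted))

  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  need <- if (weighted) 3L else 2L
  short <- which(lengths(parts) < need)
  if (length(short)) {
    stop("malformed line ", idx[short[1]], " in ", path,
         ": expected at least ", need, " tab-separated fields", call. = FALSE)
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
    bad <- which(!is.finite(w))
    if (length(bad)) {
      stop("malformed line ", idx[bad[1]], " in ", path,
           ": weight is not a finite number", call. = FALSE)
    }
    ppi_network(data.frame(a = a, b = b, weight = w,
                           stringsAsFactors = FALSE), weighted = TRUE)
  } else {
    ppi_network(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  }
}

#' Write a PPI network as a tab-separated edge list
#'
#' Emits a `# weighted=<true|false>` header comment followed by one canonical
#' `(min, max)` pair per line.  Isolated proteins are not representable in an
#' edge list and are dropped with a warning; round-tripping is the identity on
#' hygiene-filtered networks.
#'
#' @param net a [ppi_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppi_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  iso <- setdiff(net$proteins, c(net$edges$a, net$edges$b))
  if (length(iso)) {
    warning(length(iso), " isolated protein(s) not representable in an ",
            "edge list were dropped on write", call. = FALSE)
  }
  header <- sprintf("# weighted=%s", tolower(as.character(net$weighted)))
  body <- if (net$weighted) {
    sprintf("%s\t%s\t%.17g", net$edges$a, net$edges$b, net$edges$weight)
  } else {
    paste(net$edges$a, net$edges$b, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Remove self-interactions and isolated proteins
#'
#' Standard hygiene applied to interaction datasets before complex detection:
#' self-loops are deleted, and proteins left without any incident edge are
#' dropped from the protein set.  The operation is idempotent.
#'
#' @param net a [ppi_network()].
#' @return the filtered [ppi_network()].
#' @export
filter_self_and_isolated <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  e <- net$edges[net$edges$a != net$edges$b, , drop = FALSE]
  rownames(e) <- NULL
  structure(
    list(edges = e,
         proteins = sort(unique(c(e$a, e$b))),
         weighted = net$weighted),
    class = "ppi_network"
  )
}

#' Density of a candidate complex
#'
#' The density of a member set with `n` proteins is the total weight of its
#' internal edges divided by `n * (n - 1) / 2`, the number of possible pairs.
#' In an unweighted network every internal edge contributes 1, so the value
#' lies in \[0, 1\]; with edge weights above 1 the value can exceed 1 and is
#' deliberately not clamped.
#'
#' @param net a [ppi_network()].
#' @param members character vector of at least two member protein ids, all
#'   present in `net`.
#' @return the density, a non-negative real.
#' @export
#' @examples
#' star <- ppi_network(data.frame(a = c("H", "H", "H"), b = c("A", "B", "C")))
#' complex_density(star, c("H", "A", "B", "C"))  # 3 / 6 = 0.5
complex_density <- function(net, members) {
  stopifnot(inherits(net, "ppi_network"))
  members <- unique(as.character(members))
  n <- length(members)
  if (n < 2L) {
    stop("density is undefined for member sets of size < 2", call. = FALSE)
  }
  missing <- setdiff(members, net$proteins)
  if (length(missing)) {
    stop("member(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  internal <- net$edges$a %in% members & net$edges$b %in% members &
    net$edges$a != net$edges$b
  sum(edge_weights(net)[internal]) / (n * (n - 1) / 2)
}

#' Global transitivity (clustering coefficient) of a network
#'
#' Computed on the unweighted topology as 3 times the number of triangles over
#' the number of connected triples.  Used by [detect_complexes()] to resolve
#' the automatic density threshold: sparse, star-heavy networks have low
#' transitivity and get the stricter threshold.
#'
#' @param net a [ppi_network()].
#' @return a real in \[0, 1\]; networks without any connected triple yield 0
#'   with a warning.
#' @export
network_transitivity <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- as_igraph(filter_self_and_isolated(net))
  t <- igraph::transitivity(g, type = "global")
  if (is.nan(t) || is.na(t)) {
    warning("network has no connected triple; transitivity reported as 0",
            call. = FALSE)
    t <- 0
  }
  t
}

#' Convert a PPI network to an igraph graph
#'
#' @param net a [ppi_network()].
#' @return an undirected [igraph::graph]; edge attribute `weight` is set for
#'   weighted networks.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  d <- net$edges
  names(d)[1:2] <- c("from", "to")
  igraph::graph_from_data_frame(d, directed = FALSE, vertices = net$proteins)
}
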