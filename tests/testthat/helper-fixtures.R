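# fixture builders and independent oracles used across test files

# edge list from "A-B" strings; weights optional, parallel vector
make_net <- function(pairs, weights = NULL, proteins = character()) {
  sp <- strsplit(pairs, "-", fixed = TRUE)
  e <- data.frame(a = vapply(sp, `[[`, "", 1L),
                  b = vapply(sp, `[[`, "", 2L),
                  stringsAsFactors = FALSE)
  if (!is.null(weights)) {
    e$weight <- weights
    ppi_network(e, proteins = proteins, weighted = TRUE)
  } else {
    ppi_network(e, proteins = proteins)
  }
}

clique_edges <- function(ids) {
  cmb <- utils::combn(ids, 2L)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

# independent overlap score (set arithmetic written out, not the package's)
oracle_omega <- function(a, b) {
  a <- unique(a); b <- unique(b)
  sum(a %in% b)^2 / (length(a) * length(b))
}

# brute-force maximum-weight one-to-one matching over all assignments:
# recursion over reference complexes, each either unmatched or paired with an
# unused prediction.  Exponential; only for small |ref|, |pred|.
oracle_mmr <- function(pred, ref) {
  n <- length(ref)
  m <- length(pred)
  if (n == 0L) stop("empty reference")
  if (m == 0L) return(0)
  om <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    om[i, j] <- oracle_omega(ref[[i]], pred[[j]])
  }
  best <- function(i, used) {
    if (i > n) return(0)
    res <- best(i + 1L, used)  # leave ref i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && om[i, j] > 0) {
        used[j] <- TRUE
        res <- max(res, om[i, j] + best(i + 1L, used))
        used[j] <- FALSE
      }
    }
    res
  }
  best(1L, rep(FALSE, m)) / n
}

# random complex set over a small protein universe
random_complex_set <- function(n_complexes, universe = LETTERS[1:12]) {
  complex_set(lapply(seq_len(n_complexes), function(i) {
    sample(universe, sample(2:5, 1))
  }))
}
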