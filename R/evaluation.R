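#' Complex sets
#'
#' Throughout the package a *complex set* -- a collection of predicted or
#' reference complexes -- is a named list of character vectors of protein ids.
#' `complex_set()` validates and canonicalizes such a list: members are
#' deduplicated and sorted, empty complexes are rejected, and missing names
#' are filled in as `C1, C2, ...`.
#'
#' @param x a list of character vectors.
#' @return a named list of sorted, unique member-id vectors.
#' @export
complex_set <- function(x) {
  stopifnot(is.list(x))
  out <- lapply(x, function(m) sort(unique(check_protein_ids(m))))
  if (any(lengths(out) == 0L)) {
    stop("complexes must be non-empty", call. = FALSE)
  }
  nm <- names(out)
  if (is.null(nm)) nm <- rep("", length(out))
  nm[!nzchar(nm)] <- sprintf("C%d", which(!nzchar(nm)))
  if (anyDuplicated(nm)) stop("complex ids must be unique", call. = FALSE)
  names(out) <- nm
  out
}

#' Read and write complex sets as cluster files
#'
#' The common "cluster file" convention: one complex per line, members
#' tab-separated.  Lines starting with `#` are ignored on read; complexes are
#' named `C1, C2, ...` in file order.
#'
#' @param path file path.
#' @return `read_complexes()` returns a [complex_set()];
#'   `write_complexes()` returns `path` invisibly.
#' @export
read_complexes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  complex_set(lapply(strsplit(lines, "\t", fixed = TRUE), unique))
}

#' @rdname read_complexes
#' @param complexes a complex set.
#' @export
write_complexes <- function(complexes, path) {
  writeLines(vapply(complexes, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Overlap score between two protein sets
#'
#' `omega(A, B) = |A  intersect  B|^2 / (|A| * |B|)`, also called the
#' neighborhood affinity score.  It is symmetric, 1 exactly when the sets are
#' equal and 0 exactly when they are disjoint.  The conventional match cutoff
#' 0.25 corresponds to two equally sized sets sharing half their members.
#'
#' @param a,b non-empty character vectors of protein ids (duplicates ignored).
#' @return a real in \[0, 1\].
#' @export
#' @examples
#' overlap_score(letters[1:10], letters[6:15])  # 25 / 100
overlap_score <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (!length(a) || !length(b)) {
    stop("overlap score is undefined for empty sets", call. = FALSE)
  }
  length(intersect(a, b))^2 / (length(a) * length(b))
}

# |ref| x |pred| matrix of pairwise overlap scores
omega_matrix <- function(ref, pred) {
  m <- matrix(0, nrow = length(ref), ncol = length(pred),
              dimnames = list(names(ref), names(pred)))
  for (i in seq_along(ref)) {
    for (j in seq_along(pred)) {
      m[i, j] <- overlap_score(ref[[i]], pred[[j]])
    }
  }
  m
}

#' Fraction of predicted complexes matching a reference
#'
#' A predicted complex counts as matched when its [overlap_score()] with at
#' least one reference complex reaches `omega_min` (inclusive, default 0.25).
#'
#' @param pred,ref complex sets (named lists of member-id vectors).
#' @param omega_min inclusive overlap-score cutoff.
#' @return a list with `n_clusters` (number of predictions) and `n_matched`.
#' @export
fraction_matched <- function(pred, ref, omega_min = 0.25) {
  stopifnot(is_probability(omega_min))
  if (!length(pred) || !length(ref)) {
    return(list(n_clusters = length(pred), n_matched = 0L))
  }
  om <- omega_matrix(ref, pred)
  list(n_clusters = length(pred),
       n_matched = sum(apply(om, 2, max) >= omega_min))
}

#' Reference-by-prediction confusion matrix
#'
#' Entry `T[i, j]` counts the proteins found in both reference complex `i` and
#' predicted complex `j`.  The attribute `ref_sizes` carries `N_i`, the size
#' of each reference complex, needed by [clustering_wise_sn()].
#'
#' @param ref,pred complex sets.
#' @return an integer matrix with attribute `ref_sizes`.
#' @export
confusion_matrix <- function(ref, pred) {
  Tm <- matrix(0L, nrow = length(ref), ncol = length(pred),
               dimnames = list(names(ref), names(pred)))
  for (i in seq_along(ref)) {
    ri <- unique(ref[[i]])
    for (j in seq_along(pred)) {
      Tm[i, j] <- length(intersect(ri, pred[[j]]))
    }
  }
  attr(Tm, "ref_sizes") <- vapply(ref, function(m) length(unique(m)),
                                  integer(1))
  Tm
}

#' Clustering-wise sensitivity, PPV and geometric accuracy
#'
#' From a confusion matrix `T` with reference sizes `N_i`:
#' `Sn = sum_i max_j T_ij / sum_i N_i` measures how well reference complexes
#' are covered by single predictions, and
#' `PPV = sum_j max_i T_ij / sum_j T.j` (column sums `T.j = sum_i T_ij`)
#' measures how specifically predictions hit single references.  The geometric
#' accuracy `Acc = sqrt(Sn * PPV)` balances the two.
#'
#' @param cm a [confusion_matrix()].
#' @return a real in \[0, 1\].  `clustering_wise_ppv()` returns 0 with a
#'   warning when every prediction is disjoint from every reference (zero
#'   denominator).
#' @export
clustering_wise_sn <- function(cm) {
  N <- attr(cm, "ref_sizes")
  if (is.null(N)) stop("`cm` must come from confusion_matrix()", call. = FALSE)
  if (!length(N) || sum(N) <= 0) {
    stop("no reference complexes: Sn undefined", call. = FALSE)
  }
  rowmax <- if (ncol(cm)) apply(cm, 1, max) else rep(0, nrow(cm))
  sum(rowmax) / sum(N)
}

#' @rdname clustering_wise_sn
#' @export
clustering_wise_ppv <- function(cm) {
  total <- sum(cm)
  if (total <= 0) {
    warning("every prediction is disjoint from every reference; ",
            "PPV defined as 0", call. = FALSE)
    return(0)
  }
  colmax <- apply(cm, 2, max)
  sum(colmax) / total
}

#' @rdname clustering_wise_sn
#' @param sn,ppv clustering-wise sensitivity and positive predictive value.
#' @export
geometric_accuracy <- function(sn, ppv) {
  stopifnot(is_probability(sn), is_probability(ppv))
  sqrt(sn * ppv)
}

#' Maximum matching ratio
#'
#' Build a bipartite graph between reference and predicted complexes with an
#' edge of weight [overlap_score()] wherever the score is positive; the MMR is
#' the total weight of the maximum-weight one-to-one matching divided by the
#' number of reference complexes.  Unlike the geometric accuracy it does not
#' penalize extra predictions that match nothing, which matters because gold
#' standards are incomplete.
#'
#' `mmr_rowmax()` is a diagnostic variant without the one-to-one constraint
#' (each reference takes its best-overlapping prediction, with reuse); it is
#' an upper bound on the MMR, attained when row maxima fall in distinct
#' columns.
#'
#' @param pred,ref complex sets; `ref` must be non-empty.
#' @return a real in \[0, 1\].
#' @export
max_matching_ratio <- function(pred, ref) {
  if (!length(ref)) stop("reference complex set is empty", call. = FALSE)
  if (!length(pred)) return(0)
  om <- omega_matrix(ref, pred)
  hit <- which(om > 0, arr.ind = TRUE)
  if (!nrow(hit)) return(0)
  el <- cbind(sprintf("r%d", hit[, 1]), sprintf("p%d", hit[, 2]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "p")
  m <- igraph::max_bipartite_match(g, weights = om[hit], eps = 1e-9)
  m$matching_weight / length(ref)
}

#' @rdname max_matching_ratio
#' @export
mmr_rowmax <- function(pred, ref) {
  if (!length(ref)) stop("reference complex set is empty", call. = FALSE)
  if (!length(pred)) return(0)
  om <- omega_matrix(ref, pred)
  sum(apply(om, 1, max)) / length(ref)
}

#' Score a prediction against a reference with all metrics
#'
#' Bundles [fraction_matched()], the confusion-matrix measures
#' ([clustering_wise_sn()], [clustering_wise_ppv()], [geometric_accuracy()])
#' and [max_matching_ratio()] into one result.  Predictions of any size are
#' scored as-is; size filtering belongs to the detection stage.
#'
#' @param pred,ref complex sets; `ref` must be non-empty.
#' @param omega_min inclusive overlap cutoff for the matched fraction.
#' @return an object of class `evaluation_result`: a list with `sn`, `ppv`,
#'   `acc`, `mmr`, `n_clusters`, `n_matched` and `omega_min`.
#' @export
evaluate_all <- function(pred, ref, omega_min = 0.25) {
  if (!length(ref)) stop("reference complex set is empty", call. = FALSE)
  cm <- confusion_matrix(ref, pred)
  sn <- clustering_wise_sn(cm)
  ppv <- clustering_wise_ppv(cm)
  fm <- fraction_matched(pred, ref, omega_min)
  structure(
    list(sn = sn, ppv = ppv, acc = geometric_accuracy(sn, ppv),
         mmr = max_matching_ratio(pred, ref),
         n_clusters = fm$n_clusters, n_matched = fm$n_matched,
         omega_min = omega_min),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> Sn=%.4f PPV=%.4f Acc=%.4f MMR=%.4f  %d/%d matched (omega >= %g)\n",
    x$sn, x$ppv, x$acc, x$mmr, x$n_matched, x$n_clusters, x$omega_min))
  invisible(x)
}
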