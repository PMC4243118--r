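#' Literature-extracted PPI records
#'
#' A literature PPI is a candidate interaction mined from text: two protein
#' names (as they appear in abstracts, not necessarily systematic ORF names)
#' and a real-valued confidence score produced by the extraction system.
#' Scores are on an arbitrary finite scale; confidence cutoffs of 0 down to
#' -0.9 are typical, so negative scores are expected.
#'
#' @param name_a,name_b character vectors of protein names.
#' @param score numeric vector of finite confidence scores.
#' @return a data frame with columns `name_a`, `name_b`, `score`.
#' @export
literature_ppis <- function(name_a, name_b, score) {
  name_a <- as.character(name_a)
  name_b <- as.character(name_b)
  score <- as.numeric(score)
  stopifnot(length(name_a) == length(name_b),
            length(name_a) == length(score))
  if (any(!nzchar(name_a)) || any(!nzchar(name_b))) {
    stop("protein names must be non-empty", call. = FALSE)
  }
  if (length(score) && any(!is.finite(score))) {
    stop("confidence scores must be finite", call. = FALSE)
  }
  data.frame(name_a = name_a, name_b = name_b, score = score,
             stringsAsFactors = FALSE)
}

#' Read literature PPI records from a TSV file
#'
#' Expects three tab-separated columns: `name_a`, `name_b`, `score`.
#' Lines starting with `#` are ignored.
#'
#' @param path input file path.
#' @return a data frame as returned by [literature_ppis()].
#' @export
read_literature_ppis <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("expected 3 tab-separated columns in ", path,
                         call. = FALSE)
  literature_ppis(d[[1]], d[[2]], d[[3]])
}

#' Build or read a protein alias table
#'
#' An alias table maps common protein names, as used in abstracts, to
#' systematic ORF names.  Lookup is case-insensitive after trimming and each
#' alias maps to exactly one systematic name; conflicting duplicate aliases
#' are an error.
#'
#' @param alias character vector of alias names.
#' @param systematic character vector of systematic ids, same length.
#' @return a named character vector: `tolower(alias) -> systematic`.
#' @export
alias_table <- function(alias, systematic) {
  alias <- tolower(trimws(as.character(alias)))
  systematic <- check_protein_ids(as.character(systematic), "systematic name")
  stopifnot(length(alias) == length(systematic))
  if (any(!nzchar(alias))) stop("aliases must be non-empty", call. = FALSE)
  first <- !duplicated(alias)
  if (any(tapply(systematic, alias, function(x) length(unique(x))) > 1)) {
    stop("alias table maps some alias to more than one systematic name",
         call. = FALSE)
  }
  stats::setNames(systematic[first], alias[first])
}

#' @rdname alias_table
#' @param path two-column TSV file (`alias`, `systematic_name`).
#' @export
read_alias_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expected 2 tab-separated columns in ", path,
                         call. = FALSE)
  alias_table(d[[1]], d[[2]])
}

#' Normalize literature protein names to systematic ids
#'
#' Each name is replaced by its alias-table target when present (matching is
#' case-insensitive after trimming) and left unchanged otherwise.  Unmatched
#' names are not an error -- the endpoint-exists rule of
#' [integrate_literature()] filters them later -- but their count is recorded
#' in the `n_unmatched` attribute of the result.
#'
#' @param records literature PPI records ([literature_ppis()]).
#' @param aliases an [alias_table()].
#' @return the records with normalized names; attribute `n_unmatched` carries
#'   the number of name occurrences that had no alias entry.
#' @export
normalize_names <- function(records, aliases) {
  lookup <- function(x) {
    key <- tolower(trimws(x))
    hit <- match(key, names(aliases))
    out <- ifelse(is.na(hit), x, unname(aliases[hit]))
    list(name = out, unmatched = sum(is.na(hit)))
  }
  a <- lookup(records$name_a)
  b <- lookup(records$name_b)
  out <- records
  out$name_a <- a$name
  out$name_b <- b$name
  attr(out, "n_unmatched") <- a$unmatched + b$unmatched
  out
}

#' Keep literature records at or above a confidence threshold
#'
#' The comparison is inclusive: a record with score equal to the threshold is
#' integrated.  Input order is preserved.
#'
#' @param records literature PPI records.
#' @param threshold confidence cutoff.
#' @return the filtered records.
#' @export
filter_by_threshold <- function(records, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  out <- records[records$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescale literature confidence scores onto a network's weight range
#'
#' Literature confidence scores live on the extractor's own scale, while
#' native network weights are reliability estimates (typically in \[0, 1\]).
#' Before attaching literature edges to a weighted network their scores are
#' adjusted proportionately: the default `minmax` strategy maps
#' `[min(score), max(score)]` affinely onto `[min(weight), max(weight)]` of
#' the target network, preserving score order.  If all record scores are equal
#' (degenerate range), or with strategy `"mean"`, every record receives the
#' mean native edge weight.
#'
#' @param records literature PPI records.
#' @param net a weighted [ppi_network()] with at least one edge.
#' @param strategy `"minmax"` (affine map) or `"mean"` (constant mean weight).
#' @return the records with rescaled `score`.
#' @export
rescale_weights <- function(records, net, strategy = c("minmax", "mean")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(net, "ppi_network"))
  if (!net$weighted) {
    stop("rescaling requires a weighted network; unweighted networks discard ",
         "literature weights", call. = FALSE)
  }
  if (!nrow(net$edges)) stop("network has no edges to rescale against",
                             call. = FALSE)
  if (!nrow(records)) return(records)
  w <- net$edges$weight
  s <- records$score
  if (strategy == "mean" || max(s) == min(s)) {
    records$score <- rep(mean(w), length(s))
  } else {
    records$score <- min(w) + (s - min(s)) / (max(s) - min(s)) * (max(w) - min(w))
  }
  records
}

#' Integrate literature PPIs into a PPI network
#'
#' Applies the integration rules in order: (1) keep records with score at or
#' above `threshold`; (2) drop records with either endpoint absent from the
#' network's protein set (no protein is ever added); (3) drop records whose
#' unordered pair already exists in the network -- the native edge and its
#' weight are always kept -- as well as within-batch duplicates and
#' self-pairs; (4) on weighted networks, rescale the surviving records'
#' scores with [rescale_weights()] and attach them as edge weights; on
#' unweighted networks the scores are discarded.  Records must already be
#' normalized to the network's identifier space (see [normalize_names()]).
#'
#' @param net a [ppi_network()].
#' @param records normalized literature PPI records.
#' @param threshold confidence cutoff (inclusive).
#' @param rescale weight-adjustment strategy for weighted networks:
#'   `"minmax"`, `"mean"` or `"none"` (attach raw scores).
#' @return a list with elements `network` (the augmented [ppi_network()]) and
#'   `report` (one-row data frame: `threshold`, `n_candidates`,
#'   `n_pass_threshold`, `n_added`, `n_skipped_unknown_protein`,
#'   `n_skipped_duplicate`).
#' @export
integrate_literature <- function(net, records, threshold,
                                 rescale = c("minmax", "mean", "none")) {
  rescale <- match.arg(rescale)
  stopifnot(inherits(net, "ppi_network"))
  n_candidates <- nrow(records)

  kept <- filter_by_threshold(records, threshold)
  n_pass <- nrow(kept)

  cp <- canonicalize_pairs(kept$name_a, kept$name_b)
  kept$name_a <- cp$a
  kept$name_b <- cp$b
  known <- kept$name_a %in% net$proteins & kept$name_b %in% net$proteins
  n_unknown <- sum(!known)
  kept <- kept[known, , drop = FALSE]

  kept <- kept[kept$name_a != kept$name_b, , drop = FALSE]  # no self-loops
  keys <- pair_key(kept$name_a, kept$name_b)
  existing <- pair_key(net$edges$a, net$edges$b)
  dup <- keys %in% existing | duplicated(keys)
  n_dup <- sum(dup)
  kept <- kept[!dup, , drop = FALSE]

  new_edges <- data.frame(a = kept$name_a, b = kept$name_b,
                          stringsAsFactors = FALSE)
  if (net$weighted) {
    if (rescale != "none" && nrow(kept)) {
      kept <- rescale_weights(kept, net,
                              strategy = if (rescale == "mean") "mean" else "minmax")
    }
    new_edges$weight <- kept$score
  }

  out <- ppi_network(rbind(net$edges, new_edges), proteins = net$proteins,
                     weighted = net$weighted)
  report <- data.frame(
    threshold = threshold,
    n_candidates = n_candidates,
    n_pass_threshold = n_pass,
    n_added = nrow(new_edges),
    n_skipped_unknown_protein = n_unknown,
    n_skipped_duplicate = n_dup
  )
  list(network = out, report = report)
}

#' Integration counts over a grid of confidence thresholds
#'
#' Runs [integrate_literature()] independently from the original network at
#' each threshold and collects the integration reports, reproducing the
#' "edges added per threshold" bookkeeping of a threshold sweep.
#'
#' @inheritParams integrate_literature
#' @param thresholds non-empty numeric vector of cutoffs.
#' @return a data frame with one report row per threshold.
#' @export
sweep_counts <- function(net, records, thresholds,
                         rescale = c("minmax", "mean", "none")) {
  rescale <- match.arg(rescale)
  stopifnot(length(thresholds) > 0)
  do.call(rbind, lapply(thresholds, function(t) {
    integrate_literature(net, records, t, rescale = rescale)$report
  }))
}
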