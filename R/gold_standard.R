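#' Read a complex catalog (category membership table)
#'
#' MIPS-style catalogs list one membership per row: a dotted category code
#' (e.g. `510.190.10`) and a protein id, tab-separated.
#'
#' @param path two-column TSV file.
#' @return a data frame with columns `category` and `protein`.
#' @export
read_complex_catalog <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) < 2L) stop("expected 2 tab-separated columns in ", path,
                         call. = FALSE)
  data.frame(category = d[[1]], protein = d[[2]], stringsAsFactors = FALSE)
}

#' Filter a MIPS-style catalog into a gold-standard complex set
#'
#' Keeps categories with at least 3 and at most 100 member proteins, and
#' excludes category 550 together with all its descendants -- the
#' computationally predicted, unconfirmed complexes.  Descent is tested on the
#' dotted category code component-wise: `"550"` and codes starting `"550."`
#' are excluded, while e.g. `"5500"` is kept.
#'
#' @param catalog a data frame with columns `category` and `protein`
#'   (see [read_complex_catalog()]), or a named list of member vectors.
#' @param min_size,max_size inclusive size bounds (defaults 3 and 100).
#' @param exclude_category root category whose subtree is dropped
#'   (default `"550"`).
#' @return a [complex_set()] named by category code.
#' @export
filter_mips <- function(catalog, min_size = 3L, max_size = 100L,
                        exclude_category = "550") {
  if (is.data.frame(catalog)) {
    members <- lapply(split(catalog$protein, catalog$category), unique)
  } else {
    members <- lapply(catalog, unique)
  }
  sizes <- lengths(members)
  cats <- names(members)
  excluded <- cats == exclude_category |
    startsWith(cats, paste0(exclude_category, "."))
  keep <- sizes >= min_size & sizes <= max_size & !excluded
  complex_set(members[keep])
}

#' GO annotations
#'
#' @param protein,term,qualifier,evidence equal-length character vectors; GO
#'   terms must match `GO:` followed by seven digits; `qualifier` may be empty
#'   or a `|`-separated list of modifiers.
#' @return a data frame with the four columns.
#' @export
go_annotations <- function(protein, term, qualifier = "", evidence = "ND") {
  n <- max(length(protein), length(term))
  d <- data.frame(protein = check_protein_ids(protein),
                  term = as.character(term),
                  qualifier = rep_len(as.character(qualifier), n),
                  evidence = rep_len(as.character(evidence), n),
                  stringsAsFactors = FALSE)
  bad <- !grepl("^GO:\\d{7}$", d$term)
  if (any(bad)) {
    stop("malformed GO term id: ", d$term[bad][1], call. = FALSE)
  }
  d
}

#' @rdname go_annotations
#' @param path GAF-inspired 4-column TSV: protein, GO id, qualifier, evidence.
#' @export
read_go_annotations <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character", fill = TRUE)
  if (ncol(d) < 4L) stop("expected 4 tab-separated columns in ", path,
                         call. = FALSE)
  go_annotations(d[[1]], d[[2]], d[[3]], d[[4]])
}

#' Read a term hierarchy (minimal OBO or child-parent TSV)
#'
#' Two input dialects are accepted: a minimal OBO file, from which only the
#' `id:`, `is_a:` and `relationship: part_of` fields of `[Term]` stanzas are
#' taken, or a precomputed two-column TSV of `(child, parent)` pairs.  Both
#' yield the same edge table; "descendant" downstream means reachable via
#' `is_a` or `part_of`.  Full OBO semantics are deliberately out of scope.
#'
#' @param path input file path.
#' @return a data frame with columns `child` and `parent`.
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\[Term\\]", lines))) {
    d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
    if (ncol(d) < 2L) stop("expected 2 tab-separated columns in ", path,
                           call. = FALSE)
    return(data.frame(child = d[[1]], parent = d[[2]],
                      stringsAsFactors = FALSE))
  }
  child <- character()
  parent <- character()
  cur <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "is_a:") && !is.na(cur)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      child <- c(child, cur); parent <- c(parent, p)
    } else if (grepl("^relationship:\\s*part_of\\b", ln) && !is.na(cur)) {
      p <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      child <- c(child, cur); parent <- c(parent, p)
    }
  }
  data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
}

#' Descendant terms of an ontology term
#'
#' @param ontology a `(child, parent)` edge table ([read_ontology()]).
#' @param term a term id.
#' @return character vector of strict descendants (the term itself excluded).
#' @export
ontology_descendants <- function(ontology, term) {
  out <- character()
  frontier <- term
  while (length(frontier)) {
    kids <- unique(ontology$child[ontology$parent %in% frontier])
    kids <- setdiff(kids, c(out, term))
    out <- c(out, kids)
    frontier <- kids
  }
  sort(out)
}

#' Derive GO-based gold-standard complexes
#'
#' One complex per strict descendant term of `root` (by convention
#' `GO:0043234`, "protein complex"), with members the proteins annotated to
#' that term after two filters: annotations carrying a `NOT` or
#' `colocalizes_with` qualifier are dropped, and a protein-term pair supported
#' *only* by `IEA` evidence is dropped (pairs with IEA plus another code
#' survive).  Terms left without members are omitted.  No minimum size is
#' applied: GO-derived gold standards legitimately contain singleton
#' complexes.  The same protein may appear in many complexes.
#'
#' @param annotations a [go_annotations()] data frame.
#' @param ontology a `(child, parent)` edge table containing `root`.
#' @param root the ancestor term defining the complex subtree.
#' @param closure when `TRUE`, a term's complex also includes the proteins
#'   annotated to its own descendants (term closure); default `FALSE`,
#'   per-term annotation only.
#' @return a [complex_set()] named by GO term.
#' @export
filter_sgd <- function(annotations, ontology, root = "GO:0043234",
                       closure = FALSE) {
  if (!(root %in% c(ontology$child, ontology$parent))) {
    stop("root term ", root, " absent from ontology", call. = FALSE)
  }
  desc <- ontology_descendants(ontology, root)

  quals <- strsplit(tolower(annotations$qualifier), "|", fixed = TRUE)
  drop_qual <- vapply(quals, function(q) {
    any(trimws(q) %in% c("not", "colocalizes_with"))
  }, logical(1))
  ann <- annotations[!drop_qual, , drop = FALSE]

  # per protein-term pair: keep unless all supporting evidence is IEA
  key <- paste(ann$protein, ann$term, sep = "\r")
  only_iea <- !(key %in% key[ann$evidence != "IEA"])
  ann <- ann[!only_iea, , drop = FALSE]

  members_of <- function(term) unique(ann$protein[ann$term == term])
  complexes <- lapply(desc, function(term) {
    m <- members_of(term)
    if (closure) {
      m <- unique(c(m, unlist(lapply(ontology_descendants(ontology, term),
                                     members_of))))
    }
    sort(m)
  })
  names(complexes) <- desc
  complex_set(complexes[lengths(complexes) > 0])
}

#' Summarize a gold-standard complex set
#'
#' @param gold a non-empty complex set.
#' @return a list with `n_complexes`, `max_size`, `min_size` and `mean_size`
#'   (mean reported to 1 decimal).
#' @export
summarize_gold <- function(gold) {
  if (!length(gold)) stop("gold standard is empty", call. = FALSE)
  sizes <- vapply(gold, function(m) length(unique(m)), integer(1))
  list(n_complexes = length(sizes),
       max_size = max(sizes),
       min_size = min(sizes),
       mean_size = round(mean(sizes), 1))
}
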