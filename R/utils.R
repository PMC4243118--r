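# internal helpers shared across modules

# canonical unordered pair: (min, max) lexicographically
canonicalize_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  list(a = a, b = b)
}

# key for set membership tests on canonical pairs; "\r" cannot occur in ids
pair_key <- function(a, b) paste(a, b, sep = "\r")

clamp01 <- function(x) pmin(1, pmax(0, x))

check_protein_ids <- function(x, what = "protein id") {
  x <- as.character(x)
  bad <- !nzchar(x) | grepl("[[:space:]]", x)
  if (any(bad)) {
    stop(what, " must be a non-empty token without whitespace (offender: ",
         deparse(x[bad][1]), ")", call. = FALSE)
  }
  x
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
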