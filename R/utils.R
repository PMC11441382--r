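#' @importFrom Biostrings DNAStringSet reverseComplement writeXStringSet
#' @importFrom stats setNames rexp runif
#' @importFrom utils write.table
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. IUPAC
#' ambiguity codes (including N) are complemented by Biostrings rules.
#'
#' @param x character vector of DNA sequences over the IUPAC alphabet.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Canonical form of a k-mer: the lexicographically smaller of the k-mer and
## its reverse complement. A/C/G/T/N order is locale-stable for this alphabet.
canonical_kmers <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

## All k-mers of each sequence, as a list parallel to `seqs`.
enumerate_kmers <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  })
}

#' N50 of a set of sequence lengths
#'
#' Length L such that sequences of length >= L cover at least half of the
#' total length.
#'
#' @param lengths integer vector of sequence lengths.
#' @return the N50 value (0 for an empty set).
#' @export
n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (length(lengths) == 0L || sum(lengths) == 0) return(0)
  idx <- which(cumsum(lengths) >= sum(lengths) / 2)[1L]
  lengths[idx]
}

## Locale-independent (byte-order) sorting and comparison. All ordering that
## can reach an output file goes through these, so results do not depend on
## the session collation.
sort_c <- function(x) sort(x, method = "radix")

## elementwise a <= b in byte order
le_c <- function(a, b) {
  vapply(seq_along(a), function(i) {
    a[i] == b[i] || sort(c(a[i], b[i]), method = "radix")[1L] == a[i]
  }, logical(1))
}

## Simple union-find with path compression; elements are 1..n.
uf_new <- function(n) seq_len(n)

## Non-recursive find returning both root and compressed parent vector.
uf_find2 <- function(parent, i) {
  root <- i
  while (parent[root] != root) root <- parent[root]
  while (parent[i] != root) {
    nxt <- parent[i]
    parent[i] <- root
    i <- nxt
  }
  list(root = root, parent = parent)
}

uf_union <- function(parent, i, j) {
  a <- uf_find2(parent, i); parent <- a$parent
  b <- uf_find2(parent, j); parent <- b$parent
  if (a$root != b$root) parent[b$root] <- a$root
  parent
}

## Component labels 1..k for a union-find parent vector.
uf_components <- function(parent) {
  roots <- vapply(seq_along(parent),
                  function(i) uf_find2(parent, i)$root, integer(1))
  match(roots, unique(roots))
}

## Write sequences as wrapped FASTA (60 columns).
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  xs <- Biostrings::DNAStringSet(unlist(seqs))
  names(xs) <- names(seqs)
  Biostrings::writeXStringSet(xs, filepath = path, width = width)
  invisible(path)
}
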