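## Linked-read ingestion and compression.
##
## Homopolymer-compressed assembly graphs (LJA-style) require the reads to be
## compressed the same way before k-mer matching: homopolymer runs collapse to
## a single base and long alternating dimer runs are truncated.

#' Collapse homopolymer runs
#'
#' Every run of identical characters X...X collapses to a single X. 'N'
#' participates in runs like any other symbol.
#'
#' @param seq character vector of DNA strings.
#' @return character vector with no two equal adjacent characters.
#' @export
compress_homopolymers <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) <= 1L) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rle(ch)$values, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Truncate long alternating dimer runs
#'
#' A maximal alternating run XYXY... (X != Y) of length `min_len` or more is
#' truncated to its first `min_len` characters; shorter runs are untouched.
#' Input is expected to be homopolymer-compressed already.
#'
#' @param seq character vector of DNA strings.
#' @param min_len minimum run length (bp) that triggers truncation; default 16.
#' @return character vector.
#' @export
compress_dimers <- function(seq, min_len = 16L) {
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < min_len) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ## period-2 continuation flags: ch[i] == ch[i-2]
    cont <- c(FALSE, FALSE, ch[3:n] == ch[1:(n - 2L)])
    keep <- rep(TRUE, n)
    i <- 1L
    while (i <= n - 1L) {
      j <- i + 1L
      while (j + 1L <= n && cont[j + 1L]) j <- j + 1L
      run_len <- j - i + 1L
      if (run_len >= min_len) keep[(i + min_len):j] <- FALSE
      i <- j  # next run may start at the last character of this one
    }
    paste(ch[keep], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Compress reads to match a homopolymer-compressed graph
#'
#' @param seq character vector of DNA strings.
#' @param dimer_min_len dimer-run truncation threshold (bp).
#' @return compressed sequences.
#' @export
compress_reads <- function(seq, dimer_min_len = 16L) {
  compress_dimers(compress_homopolymers(seq), min_len = dimer_min_len)
}

## Barcode extraction from a FASTQ read name. Sources:
##   "BX-tag":           whitespace-delimited BX:Z:<barcode> field
##   "read-name-suffix": trailing "#<barcode>"
extract_barcode <- function(names, barcode_source = c("BX-tag", "read-name-suffix")) {
  barcode_source <- match.arg(barcode_source)
  if (barcode_source == "BX-tag") {
    m <- regmatches(names, regexec("BX:Z:(\\S+)", names))
    vapply(m, function(x) if (length(x) == 2L) x[2] else "", character(1))
  } else {
    m <- regmatches(names, regexec("#([^#[:space:]]+)\\s*$", names))
    vapply(m, function(x) if (length(x) == 2L) x[2] else "", character(1))
  }
}

## Read id without barcode tag, pair suffix or comment, for sync checking.
core_read_id <- function(names) {
  id <- sub("\\s.*$", "", names)
  id <- sub("#[^#]*$", "", id)
  sub("/[12]$", "", id)
}

#' Read a barcoded paired-end FASTQ library
#'
#' Loads two synchronised FASTQ files (optionally gzip-compressed) and
#' extracts the barcode of each pair from the read names. Pairs with a
#' missing or empty barcode are dropped with a message.
#'
#' @param fq1,fq2 paths to the mate-1 and mate-2 FASTQ files.
#' @param barcode_source `"BX-tag"` (a `BX:Z:<barcode>` name field) or
#'   `"read-name-suffix"` (a trailing `#<barcode>`).
#' @return data.frame with columns `read1`, `read2`, `barcode`.
#' @export
read_linked_fastq <- function(fq1, fq2,
                              barcode_source = c("BX-tag", "read-name-suffix")) {
  barcode_source <- match.arg(barcode_source)
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq")
  if (length(r1) != length(r2))
    stop("desynchronised FASTQ files: ", length(r1), " vs ", length(r2),
         " records")
  if (length(r1) == 0)
    return(data.frame(read1 = character(0), read2 = character(0),
                      barcode = character(0), stringsAsFactors = FALSE))
  id1 <- core_read_id(names(r1))
  id2 <- core_read_id(names(r2))
  bad <- which(id1 != id2)
  if (length(bad) > 0)
    stop("desynchronised FASTQ files at record ", bad[1L], ": '",
         id1[bad[1L]], "' vs '", id2[bad[1L]], "'")
  bc <- extract_barcode(names(r1), barcode_source)
  bc2 <- extract_barcode(names(r2), barcode_source)
  bc[bc == ""] <- bc2[bc == ""]
  keep <- bc != ""
  if (any(!keep))
    message("read_linked_fastq: dropped ", sum(!keep),
            " pair(s) without a barcode")
  data.frame(read1 = as.character(r1)[keep],
             read2 = as.character(r2)[keep],
             barcode = bc[keep], stringsAsFactors = FALSE)
}
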