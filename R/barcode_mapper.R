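## Unique k-mer indexing and barcoded read mapping.
##
## Reads are mapped to contracted-graph edges through k-mers that occur
## exactly once in the edge set. K-mers are canonicalised (a k-mer and its
## reverse complement are identified, keyed by the lexicographic minimum) and
## uniqueness is assessed over one strand representative per rc edge pair --
## otherwise every k-mer would trivially occur twice, once per strand.

#' Build a unique k-mer index over a contracted graph
#'
#' Collects all k-mers of one strand representative per reverse-complement
#' edge pair, canonicalises them, and keeps exactly those occurring once in
#' total. K-mers containing 'N' are never indexed. Edges shorter than `k`
#' contribute nothing (reported via a message).
#'
#' @param cg a contracted `dbg_graph`.
#' @param k k-mer size in bp (default 31).
#' @return an object of class `ukmer_index` with fields `k`, `kmers`
#'   (canonical k-mer strings), `edge`, `pos` (0-based offset on the
#'   representative edge), `strand` (`"+"` if the canonical form matches the
#'   edge forward strand).
#' @export
build_unique_kmer_index <- function(cg, k = 31L) {
  stopifnot(inherits(cg, "dbg_graph"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  rep_edges <- representative_edges(cg)
  short <- rep_edges[nchar(cg$seq[rep_edges]) < k]
  if (length(short) > 0)
    message("build_unique_kmer_index: ", length(short),
            " edge pair(s) shorter than k contribute no k-mers")
  km_list <- enumerate_kmers(unname(cg$seq[rep_edges]), k)
  nk <- lengths(km_list)
  kmers <- unlist(km_list, use.names = FALSE)
  if (is.null(kmers)) kmers <- character(0)
  edge <- rep(rep_edges, nk)
  pos <- unlist(lapply(nk, function(n) seq_len(n) - 1L), use.names = FALSE)
  if (is.null(pos)) pos <- integer(0)
  has_n <- grepl("N", kmers, fixed = TRUE)
  kmers <- kmers[!has_n]; edge <- edge[!has_n]; pos <- pos[!has_n]
  canon <- canonical_kmers(kmers)
  counts <- table(canon)
  uniq <- canon %in% names(counts)[counts == 1L]
  structure(list(
    k = k,
    kmers = canon[uniq],
    edge = edge[uniq],
    pos = pos[uniq],
    strand = ifelse(canon[uniq] == kmers[uniq], "+", "-")),
    class = "ukmer_index")
}

## One strand representative per rc edge pair: the forward (non-rc) edge.
representative_edges <- function(cg) {
  sort_c(cg$edges[!cg$is_rc[cg$edges]])
}

## Map an edge id to its pair representative.
rep_of <- function(cg, e) {
  ifelse(cg$is_rc[e], unname(cg$rc[e]), e)
}

#' @export
print.ukmer_index <- function(x, ...) {
  cat("ukmer_index: k =", x$k, ",", length(x$kmers), "unique k-mers over",
      length(unique(x$edge)), "edges\n")
  invisible(x)
}

## Indexed edges hit by one read (representative edge ids, unique, sorted).
edges_hit_by_read <- function(read, idx) {
  n <- nchar(read)
  if (n < idx$k) return(character(0))
  km <- substring(read, 1:(n - idx$k + 1L), idx$k:n)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0) return(character(0))
  hit <- match(canonical_kmers(km), idx$kmers)
  sort_c(unique(idx$edge[hit[!is.na(hit)]]))
}

## Batched mapping of all pairs: one canonicalisation pass over every k-mer
## of every read, then per-read and per-pair aggregation. Semantically
## identical to calling map_read_pair() per row.
map_pairs_batch <- function(pairs, idx, mode) {
  npairs <- nrow(pairs)
  if (npairs == 0) return(list())
  reads <- c(pairs$read1, pairs$read2)
  km_list <- enumerate_kmers(reads, idx$k)
  nk <- lengths(km_list)
  km <- unlist(km_list, use.names = FALSE)
  read_of <- rep(seq_along(reads), nk)
  has_n <- grepl("N", km, fixed = TRUE)
  km <- km[!has_n]; read_of <- read_of[!has_n]
  hit <- match(canonical_kmers(km), idx$kmers)
  ok <- !is.na(hit)
  edge_hits <- idx$edge[hit[ok]]
  read_hits <- read_of[ok]
  per_read <- lapply(split(edge_hits, factor(read_hits, levels = seq_along(reads))),
                     unique)
  lapply(seq_len(npairs), function(i) {
    h1 <- per_read[[i]]
    h2 <- per_read[[i + npairs]]
    if (mode == "metagenomic") sort_c(intersect(h1, h2)) else sort_c(unique(c(h1, h2)))
  })
}

#' Map a barcoded read pair to graph edges
#'
#' In metagenomic mode a pair maps to an edge only when both reads contain at
#' least one unique k-mer of that edge; in diploid mode a single unique k-mer
#' anywhere in the pair suffices (most k-mers of a phased assembly graph are
#' repetitive, so the requirement is relaxed). K-mers are matched on both read
#' strands via canonicalisation. An unmapped pair yields an empty set.
#'
#' @param read1,read2 DNA strings of the two mates.
#' @param idx a `ukmer_index`.
#' @param mode `"diploid"` or `"metagenomic"`.
#' @return sorted character vector of representative edge ids.
#' @export
map_read_pair <- function(read1, read2, idx, mode = c("diploid", "metagenomic")) {
  mode <- match.arg(mode)
  h1 <- edges_hit_by_read(read1, idx)
  h2 <- edges_hit_by_read(read2, idx)
  if (mode == "metagenomic") sort_c(intersect(h1, h2)) else sort_c(union(h1, h2))
}

#' Collect per-edge barcode sets from a linked-read library
#'
#' Maps every read pair and accumulates, for each edge `e`, the set
#' `barcodes(e)` of barcodes of all pairs mapped to `e`. Strand symmetry
#' `barcodes(e) == barcodes(rc(e))` is guaranteed by construction: sets are
#' stored per rc edge pair.
#'
#' @param pairs data.frame with columns `read1`, `read2`, `barcode`
#'   (as from [read_linked_fastq()]).
#' @param cg the contracted `dbg_graph` the index was built over.
#' @param idx a `ukmer_index`.
#' @param mode `"diploid"` or `"metagenomic"`.
#' @param verbose log a mapping summary.
#' @return an object of class `edge_barcodes`: list with `sets` (named list,
#'   representative edge id -> character vector of barcodes), `mode`, and
#'   mapping statistics `stats`.
#' @export
collect_edge_barcodes <- function(pairs, cg, idx,
                                  mode = c("diploid", "metagenomic"),
                                  verbose = FALSE) {
  mode <- match.arg(mode)
  npairs <- nrow(pairs)
  acc_edge <- map_pairs_batch(pairs, idx, mode)
  n_mapped <- sum(lengths(acc_edge) > 0)
  n_multi <- sum(lengths(acc_edge) > 1)
  nh <- lengths(acc_edge)
  edge_vec <- unlist(acc_edge, use.names = FALSE)
  bc_vec <- rep(pairs$barcode, nh)
  sets <- lapply(split(bc_vec, edge_vec), function(b) sort_c(unique(b)))
  stats <- c(pairs = npairs, mapped = n_mapped,
             unmapped = npairs - n_mapped, multi_edge = n_multi)
  if (verbose)
    message("collect_edge_barcodes: ", n_mapped, "/", npairs,
            " pairs mapped (", n_multi, " to multiple edges)")
  structure(list(sets = sets, mode = mode, stats = stats, graph_rc = cg$rc,
                 graph_is_rc = cg$is_rc),
            class = "edge_barcodes")
}

#' Construct per-edge barcode sets directly
#'
#' Programmatic constructor for an `edge_barcodes` object (the result type of
#' [collect_edge_barcodes()]), useful for supplying externally derived or
#' synthetic barcode assignments. Sets may be keyed by either orientation of
#' an edge; they are merged onto the pair representative, which enforces
#' `barcodes(e) == barcodes(rc(e))`.
#'
#' @param cg the contracted `dbg_graph` the sets refer to.
#' @param sets named list: edge id -> character vector of barcodes.
#' @param mode `"diploid"` or `"metagenomic"` (annotation only).
#' @return an `edge_barcodes` object.
#' @export
edge_barcode_sets <- function(cg, sets, mode = "diploid") {
  stopifnot(inherits(cg, "dbg_graph"))
  unknown <- setdiff(names(sets), cg$edges)
  if (length(unknown) > 0)
    stop("unknown edge(s): ", paste(unknown, collapse = ", "))
  merged <- list()
  for (e in names(sets)) {
    key <- unname(rep_of(cg, e))
    merged[[key]] <- sort_c(unique(c(merged[[key]], sets[[e]])))
  }
  structure(list(sets = merged, mode = mode,
                 stats = c(pairs = NA, mapped = NA, unmapped = NA,
                           multi_edge = NA),
                 graph_rc = cg$rc, graph_is_rc = cg$is_rc),
            class = "edge_barcodes")
}

#' Barcode set of an edge
#'
#' Accessor honouring strand symmetry: `edge_barcode_set(sets, e)` equals
#' `edge_barcode_set(sets, rc(e))`.
#'
#' @param sets an `edge_barcodes` object.
#' @param e directed edge id.
#' @return character vector of barcodes (possibly empty).
#' @export
edge_barcode_set <- function(sets, e) {
  stopifnot(inherits(sets, "edge_barcodes"))
  if (!e %in% names(sets$graph_rc)) stop("unknown edge: ", e)
  key <- if (isTRUE(sets$graph_is_rc[[e]])) sets$graph_rc[[e]] else e
  b <- sets$sets[[key]]
  if (is.null(b)) character(0) else b
}

#' Write per-edge barcode counts as TSV
#'
#' @param sets an `edge_barcodes` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_barcode_counts <- function(sets, path) {
  df <- data.frame(edge_id = names(sets$sets),
                   n_barcodes = lengths(sets$sets),
                   stringsAsFactors = FALSE)
  df <- df[order(df$edge_id, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict barcode sets to a subset of barcodes
#'
#' Used for coverage-downsampling analyses: keeps only barcodes in `keep`.
#'
#' @param sets an `edge_barcodes` object.
#' @param keep character vector of barcodes to retain.
#' @return a filtered `edge_barcodes` object.
#' @export
subset_barcodes <- function(sets, keep) {
  stopifnot(inherits(sets, "edge_barcodes"))
  out <- sets
  out$sets <- lapply(sets$sets, function(b) b[b %in% keep])
  out
}
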