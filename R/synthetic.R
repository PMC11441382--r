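## Ground-truthed synthetic diploid linked-read data.
##
## The generator emulates the situation the resolver targets: a diploid
## genome as a chain of heterozygous bubbles separated by long shared
## (homozygous) repeat segments, long barcoded fragments sampled per
## haplotype, and several short read pairs per fragment sharing the
## fragment's barcode.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

## Substitute each base with probability `rate` (always to a different base).
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe a small diploid genome with 20 heterozygous bubbles
#' separated by homozygous repeat blocks, TELL-Seq-like long fragments
#' (exponential length, mean 30 kb) and 2 x 150 bp read pairs.
#'
#' @param n_blocks number of alternating blocks; odd positions are
#'   homozygous, so `n_blocks = 41` gives 20 bubbles flanked by homozygous
#'   blocks.
#' @param homo_len,het_len block lengths in bp.
#' @param snp_rate per-base divergence between haplotypes inside
#'   heterozygous blocks, in (0, 1].
#' @param fragment_len_mean mean barcoded-fragment length in bp.
#' @param reads_per_fragment read pairs sampled per fragment.
#' @param read_len read length in bp.
#' @param insert_len read-pair insert length in bp.
#' @param coverage expected number of fragments covering a genome position,
#'   per haplotype.
#' @param error_rate per-base substitution error rate in reads (default 0,
#'   error-free).
#' @param barcode_collision_rate fraction of fragments that reuse the
#'   barcode of another fragment (default 0).
#' @param seed RNG seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 41L, homo_len = 10000L, het_len = 10000L,
                       snp_rate = 0.02, fragment_len_mean = 30000L,
                       reads_per_fragment = 20L, read_len = 150L,
                       insert_len = 400L, coverage = 25,
                       error_rate = 0, barcode_collision_rate = 0,
                       seed = 1L) {
  stopifnot(n_blocks >= 1, homo_len > 0, het_len > 0,
            snp_rate > 0, snp_rate <= 1, fragment_len_mean > 0,
            reads_per_fragment >= 0, read_len > 0,
            insert_len >= 2 * read_len || reads_per_fragment == 0,
            coverage > 0, error_rate >= 0, error_rate < 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 homo_len = as.integer(homo_len),
                 het_len = as.integer(het_len),
                 snp_rate = snp_rate,
                 fragment_len_mean = as.integer(fragment_len_mean),
                 reads_per_fragment = as.integer(reads_per_fragment),
                 read_len = as.integer(read_len),
                 insert_len = as.integer(insert_len),
                 coverage = coverage,
                 error_rate = error_rate,
                 barcode_collision_rate = barcode_collision_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a diploid genome of alternating homozygous/heterozygous blocks
#'
#' Odd blocks are homozygous (shared exactly between haplotypes); even blocks
#' are heterozygous, with haplotype 2 diverging from haplotype 1 at
#' `snp_rate` per base.
#'
#' @param cfg a [sim_config].
#' @return list with `hap1`, `hap2` (DNA strings), and `blocks` (data.frame:
#'   `block`, `type`, `len`, `start`, `end`; coordinates are 1-based and
#'   identical on both haplotypes since block lengths match).
#' @export
simulate_diploid <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  types <- ifelse(seq_len(cfg$n_blocks) %% 2L == 1L, "homo", "het")
  lens <- ifelse(types == "homo", cfg$homo_len, cfg$het_len)
  seq1 <- character(cfg$n_blocks)
  seq2 <- character(cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    s <- random_dna(lens[i])
    seq1[i] <- s
    seq2[i] <- if (types[i] == "homo") s else mutate_seq(s, cfg$snp_rate)
  }
  ends <- cumsum(lens)
  blocks <- data.frame(block = seq_len(cfg$n_blocks), type = types,
                       len = lens, start = ends - lens + 1L, end = ends,
                       stringsAsFactors = FALSE)
  list(hap1 = paste(seq1, collapse = ""), hap2 = paste(seq2, collapse = ""),
       blocks = blocks, cfg = cfg)
}

#' Build the bubble-chain assembly graph of a simulated diploid genome
#'
#' One segment per homozygous block, two (one per haplotype) per heterozygous
#' block, linked into a chain of bubbles. Homozygous segments are the shared
#' repeats; contracting them (see [contract_repeat_edges()]) turns every
#' internal junction into a branching 2-in/2-out vertex.
#'
#' @param sim output of [simulate_diploid()].
#' @return list with `gfa` (a [gfa_graph]), `edge_haplotype` (named character:
#'   segment name -> `"hap1"`/`"hap2"`/`"homozygous"`), `repeat_segments`
#'   (homozygous segment names), `true_links` (data.frame of in/out directed
#'   edge ids that follow each other on a haplotype across each homozygous
#'   block), and `hap_paths` (list of the two segment-name paths).
#' @export
build_bubble_graph <- function(sim) {
  blocks <- sim$blocks
  seg_names <- list(); seg_seqs <- list()
  hap_label <- character(0)
  node_sets <- vector("list", nrow(blocks))  # segment names per block
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    s1 <- substr(sim$hap1, b$start, b$end)
    if (b$type == "homo") {
      nm <- sprintf("H%03d", i)
      seg_names[[i]] <- nm
      seg_seqs[[nm]] <- s1
      hap_label[nm] <- "homozygous"
      node_sets[[i]] <- nm
    } else {
      s2 <- substr(sim$hap2, b$start, b$end)
      nma <- sprintf("A%03d", i); nmb <- sprintf("B%03d", i)
      seg_names[[i]] <- c(nma, nmb)
      seg_seqs[[nma]] <- s1
      seg_seqs[[nmb]] <- s2
      hap_label[nma] <- "hap1"
      hap_label[nmb] <- "hap2"
      node_sets[[i]] <- c(nma, nmb)
    }
  }
  lf <- character(0); lt <- character(0)
  for (i in seq_len(nrow(blocks) - 1L)) {
    for (a in node_sets[[i]]) for (b in node_sets[[i + 1L]]) {
      ## haplotype-pure adjacencies only: hap1 segments join hap1/homozygous
      la <- hap_label[[a]]; lb <- hap_label[[b]]
      if (la != "homozygous" && lb != "homozygous" && la != lb) next
      lf <- c(lf, a); lt <- c(lt, b)
    }
  }
  gfa <- gfa_graph(
    segments = data.frame(name = names(seg_seqs),
                          sequence = unlist(seg_seqs),
                          stringsAsFactors = FALSE),
    links = data.frame(from = lf, from_orient = "+", to = lt,
                       to_orient = "+", overlap = 0L,
                       stringsAsFactors = FALSE))
  ## true follow-up links across each homozygous block (het -> het)
  tl_in <- character(0); tl_out <- character(0); tl_hap <- character(0)
  het_idx <- which(blocks$type == "het")
  for (j in seq_along(het_idx)[-1]) {
    prev <- het_idx[j - 1L]; cur <- het_idx[j]
    if (cur - prev != 2L) next  # only adjacent bubbles separated by one repeat
    tl_in <- c(tl_in, paste0(node_sets[[prev]][1L], "+"),
               paste0(node_sets[[prev]][2L], "+"))
    tl_out <- c(tl_out, paste0(node_sets[[cur]][1L], "+"),
                paste0(node_sets[[cur]][2L], "+"))
    tl_hap <- c(tl_hap, "hap1", "hap2")
  }
  hap_paths <- list(
    hap1 = vapply(node_sets, `[`, character(1), 1L),
    hap2 = vapply(node_sets, function(s) s[length(s)], character(1)))
  list(gfa = gfa, edge_haplotype = hap_label,
       repeat_segments = names(hap_label)[hap_label == "homozygous"],
       true_links = data.frame(in_edge = tl_in, out_edge = tl_out,
                               haplotype = tl_hap, stringsAsFactors = FALSE),
       hap_paths = hap_paths)
}

#' Simulate a barcoded linked-read library from a diploid genome
#'
#' Fragments are dropped per haplotype with exponential lengths (mean
#' `fragment_len_mean`, truncated to [1 kb, 5 x mean]); each fragment gets a
#' fresh barcode and `reads_per_fragment` read pairs sampled uniformly along
#' it. Pairs are emitted strand-randomised; errors are off by default.
#'
#' @param sim output of [simulate_diploid()].
#' @param cfg a [sim_config]; defaults to `sim$cfg`.
#' @return list with `pairs` (data.frame `read1`, `read2`, `barcode`),
#'   `fragments` (truth table: `barcode`, `haplotype`, `start`, `end`), and
#'   `cfg`.
#' @export
simulate_linked_reads <- function(sim, cfg = sim$cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  glen <- nchar(sim$hap1)
  n_frag <- max(1L, as.integer(round(cfg$coverage * glen / cfg$fragment_len_mean)))
  haps <- c(sim$hap1, sim$hap2)
  frag <- list()
  pairs <- list()
  idx <- 0L
  for (h in 1:2) {
    for (i in seq_len(n_frag)) {
      idx <- idx + 1L
      flen <- round(rexp(1L, rate = 1 / cfg$fragment_len_mean))
      flen <- min(max(flen, 1000L), 5L * cfg$fragment_len_mean)
      start <- sample.int(glen, 1L)
      end <- min(start + flen - 1L, glen)
      bc <- sprintf("BC%06d", idx)
      if (cfg$barcode_collision_rate > 0 && idx > 1L &&
          runif(1L) < cfg$barcode_collision_rate)
        bc <- sprintf("BC%06d", sample.int(idx - 1L, 1L))
      frag[[idx]] <- data.frame(barcode = bc, haplotype = paste0("hap", h),
                                start = start, end = end,
                                stringsAsFactors = FALSE)
      if (cfg$reads_per_fragment > 0L && end - start + 1L >= cfg$insert_len) {
        p <- sample.int(end - start + 2L - cfg$insert_len,
                        cfg$reads_per_fragment, replace = TRUE) + start - 1L
        tmpl <- substring(haps[h], p, p + cfg$insert_len - 1L)
        r1 <- substring(tmpl, 1L, cfg$read_len)
        r2 <- revcomp(substring(tmpl, cfg$insert_len - cfg$read_len + 1L,
                                cfg$insert_len))
        flipped <- runif(cfg$reads_per_fragment) < 0.5
        tmp <- r1[flipped]; r1[flipped] <- r2[flipped]; r2[flipped] <- tmp
        if (cfg$error_rate > 0) {
          r1 <- vapply(r1, mutate_seq, character(1), rate = cfg$error_rate,
                       USE.NAMES = FALSE)
          r2 <- vapply(r2, mutate_seq, character(1), rate = cfg$error_rate,
                       USE.NAMES = FALSE)
        }
        pairs[[idx]] <- data.frame(read1 = r1, read2 = r2, barcode = bc,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  list(pairs = if (length(pairs) > 0) do.call(rbind, c(pairs, make.row.names = FALSE))
       else data.frame(read1 = character(0), read2 = character(0),
                       barcode = character(0), stringsAsFactors = FALSE),
       fragments = do.call(rbind, c(frag, make.row.names = FALSE)),
       cfg = cfg)
}

#' Write a linked-read library as paired FASTQ with BX tags
#'
#' @param pairs data.frame with `read1`, `read2`, `barcode`.
#' @param fq1,fq2 output FASTQ paths.
#' @return c(fq1, fq2), invisibly.
#' @export
write_linked_fastq <- function(pairs, fq1, fq2) {
  nm <- sprintf("pair%06d BX:Z:%s", seq_len(nrow(pairs)), pairs$barcode)
  fq_record <- function(name, seq)
    paste0("@", name, "\n", seq, "\n+\n", strrep("I", nchar(seq)))
  writeLines(fq_record(nm, pairs$read1), fq1)
  writeLines(fq_record(nm, pairs$read2), fq2)
  invisible(c(fq1, fq2))
}

#' Hand-built toy fixture: one branching vertex, barcoded read pairs, k = 3
#'
#' A four-segment graph whose single (per-strand) branching vertex has
#' in-edges s1, s2 and out-edges s3, s4. Two barcodes support the link
#' s1 -> s3, two support s2 -> s4, and one barcode ("YEL") consists of reads
#' whose 3-mers all occur in several segments, so it maps nowhere. Segment
#' sequences were chosen so that every segment carries unique 3-mers while
#' the shared motif occurs in both s1 and s2.
#'
#' @return list with `gfa`, `pairs` (data.frame `read1`, `read2`, `barcode`),
#'   `k`, `yellow_barcode`, and `true_links` (data.frame `in_edge`,
#'   `out_edge`).
#' @export
fig1_fixture <- function() {
  segs <- c(
    s1 = "ATAACCTCCGACGTACGTGCCTTTTTTC",
    s2 = "TGGCGCTATTACGTACGTATAAGTCGGT",
    s3 = "GTCACTAGTCAGGAATCATGTGTG",
    s4 = "TGATTCCATAGACACATGGCGCGG")
  gfa <- gfa_graph(
    segments = data.frame(name = names(segs), sequence = unname(segs),
                          stringsAsFactors = FALSE),
    links = data.frame(from = c("s1", "s1", "s2", "s2"),
                       from_orient = "+",
                       to = c("s3", "s4", "s3", "s4"),
                       to_orient = "+", overlap = 0L,
                       stringsAsFactors = FALSE))
  sub_of <- function(nm, from, to) substr(segs[[nm]], from, to)
  pairs <- data.frame(
    read1 = c(sub_of("s1", 1, 12), sub_of("s1", 5, 16),
              sub_of("s2", 1, 12), sub_of("s2", 5, 16),
              "ACGTACGTACGT"),
    read2 = c(sub_of("s3", 1, 12), sub_of("s3", 5, 16),
              sub_of("s4", 1, 12), sub_of("s4", 5, 16),
              "CGTACGTACGTA"),
    barcode = c("BLU", "RED", "GRN", "PUR", "YEL"),
    stringsAsFactors = FALSE)
  list(gfa = gfa, pairs = pairs, k = 3L, yellow_barcode = "YEL",
       true_links = data.frame(in_edge = c("s1+", "s2+"),
                               out_edge = c("s3+", "s4+"),
                               stringsAsFactors = FALSE))
}
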