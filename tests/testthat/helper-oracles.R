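## Shared fixtures and independent brute-force oracles.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

tempfile_empty <- function() {
  f <- tempfile(fileext = ".fastq")
  file.create(f)
  f
}

## reverse complement computed independently of the package (chartr + rev)
rc_oracle <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## random valid GFA graph
random_gfa <- function(n_seg = 20, n_link = 25, seed = NULL,
                       min_len = 20, max_len = 60) {
  if (!is.null(seed)) set.seed(seed)
  nm <- sprintf("seg%03d", seq_len(n_seg))
  seqs <- vapply(sample(min_len:max_len, n_seg, TRUE), rand_dna, character(1))
  links <- data.frame(from = sample(nm, n_link, TRUE),
                      from_orient = sample(c("+", "-"), n_link, TRUE),
                      to = sample(nm, n_link, TRUE),
                      to_orient = sample(c("+", "-"), n_link, TRUE),
                      overlap = rep(0L, n_link), stringsAsFactors = FALSE)
  gfa_graph(
    segments = data.frame(name = nm, sequence = seqs,
                          stringsAsFactors = FALSE),
    links = links)
}

## star graph: n_in in-edges and n_out out-edges around one branching vertex
## (per strand); returns the contracted graph and the forward-strand vertex
star_graph <- function(n_in, n_out, seg_len = 30) {
  ins <- sprintf("i%d", seq_len(n_in))
  outs <- sprintf("o%d", seq_len(n_out))
  nm <- c(ins, outs)
  pairs <- expand.grid(from = ins, to = outs, stringsAsFactors = FALSE)
  g <- gfa_graph(
    segments = data.frame(name = nm,
                          sequence = vapply(rep(seg_len, length(nm)),
                                            rand_dna, character(1)),
                          stringsAsFactors = FALSE),
    links = data.frame(from = pairs$from, from_orient = "+",
                       to = pairs$to, to_orient = "+", overlap = 0L,
                       stringsAsFactors = FALSE))
  cg <- contract_link_edges(build_raw_dbg(g))
  v <- unname(cg$to[[paste0(ins[1], "+")]])
  list(gfa = g, cg = cg, v = v,
       ins = paste0(ins, "+"), outs = paste0(outs, "+"))
}

## literal application of the selection rule + matching test, independent of
## the package implementation
oracle_resolve <- function(in_sets, out_sets, abs_thr = 2, rel_thr = 2) {
  ins <- sort(names(in_sets)); outs <- sort(names(out_sets))
  ovm <- matrix(0L, length(ins), length(outs), dimnames = list(ins, outs))
  for (e in ins) for (f in outs)
    ovm[e, f] <- length(intersect(in_sets[[e]], out_sets[[f]]))
  if (!any(ovm >= abs_thr)) return(list(status = "UNCOVERED",
                                        matching = NULL))
  cand_in <- character(0); cand_out <- character(0)
  for (e in ins) {
    o <- ovm[e, ]
    o1 <- max(o)
    o2 <- if (length(o) >= 2) sort(o, decreasing = TRUE)[2] else 0
    if (o1 >= abs_thr && o1 >= rel_thr * o2) {
      cand_in <- c(cand_in, e)
      cand_out <- c(cand_out, sort(outs[o == o1])[1])
    }
  }
  if (length(cand_in) == 0 || anyDuplicated(cand_out) > 0)
    return(list(status = "AMBIGUOUS", matching = NULL))
  status <- if (length(cand_in) == length(ins) &&
                length(cand_in) == length(outs))
    "COMPLETELY_RESOLVED" else "PARTIALLY_RESOLVED"
  list(status = status,
       matching = data.frame(in_edge = cand_in, out_edge = cand_out,
                             stringsAsFactors = FALSE))
}

## random barcode sets for the edges of a star graph
random_star_sets <- function(st, pool_size = 12, max_set = 8) {
  pool <- sprintf("b%02d", seq_len(pool_size))
  sets <- lapply(c(st$ins, st$outs), function(e)
    sort(sample(pool, sample(0:max_set, 1))))
  names(sets) <- c(st$ins, st$outs)
  sets
}

## number of edges after merging maximal unbranched runs, counted on the
## vertex degree sequence alone (independent of condense_paths internals)
oracle_condensed_edge_count <- function(g) {
  indeg <- table(g$to); outdeg <- table(g$from)
  passthrough <- 0L
  for (v in unique(c(g$from, g$to))) {
    if (!is.na(indeg[v]) && indeg[v] == 1 &&
        !is.na(outdeg[v]) && outdeg[v] == 1) {
      e <- names(g$to)[g$to == v]
      f <- names(g$from)[g$from == v]
      if (f != e && f != g$rc[[e]]) passthrough <- passthrough + 1L
    }
  }
  ## each pass-through vertex merges two edges into one (cycles of
  ## pass-through vertices collapse to a single loop edge: k vertices on a
  ## cycle remove k - 1 edges, handled by the caller where cycles exist)
  length(g$edges) - passthrough
}

## total sequence multiset (for conservation checks)
seq_multiset <- function(g) sort(unname(g$seq))

expect_same_graph <- function(a, b) {
  expect_setequal(a$edges, b$edges)
  expect_identical(a$seq[sort(a$edges)], b$seq[sort(b$edges)])
  ## vertex identity up to relabelling: adjacency partition must agree
  part <- function(g) {
    key <- function(v) paste(sort(names(g$to)[g$to == v]),
                             sort(names(g$from)[g$from == v]),
                             collapse = "|")
    sort(vapply(unique(c(g$from, g$to)), key, character(1), USE.NAMES = FALSE))
  }
  expect_identical(part(a), part(b))
}
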