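## bubble-free chain GFA with given overlaps between consecutive segments
chain_gfa <- function(seqs, overlaps) {
  nm <- sprintf("e%d", seq_along(seqs))
  gfa_graph(
    segments = data.frame(name = nm, sequence = seqs,
                          stringsAsFactors = FALSE),
    links = data.frame(from = nm[-length(nm)], from_orient = "+",
                       to = nm[-1], to_orient = "+",
                       overlap = as.integer(overlaps),
                       stringsAsFactors = FALSE))
}

test_that("split_vertex reroutes matched links through fresh 1-in/1-out vertices", {
  st <- star_graph(2, 2)
  n_edges_before <- length(st$cg$edges)
  perfect <- data.frame(in_edge = c("i1+", "i2+"), out_edge = c("o1+", "o2+"),
                        stringsAsFactors = FALSE)
  out <- split_vertex(st$cg, st$v, perfect)
  g <- out$graph
  ## the original vertex is gone on both strands; each new vertex is 1-in/1-out
  expect_false(st$v %in% c(g$from, g$to))
  for (nv in out$events$new_vertex) {
    expect_equal(sum(g$to == nv), 1)
    expect_equal(sum(g$from == nv), 1)
  }
  expect_identical(unname(g$from[["o1+"]]), unname(g$to[["i1+"]]))
  expect_identical(unname(g$from[["o2+"]]), unname(g$to[["i2+"]]))
  ## sequence edges unchanged; skew symmetry preserved
  expect_equal(length(g$edges), n_edges_before)
  expect_identical(seq_multiset(g), seq_multiset(st$cg))
  check_skew_symmetry(g)

  ## partial matching keeps the residual vertex with the unmatched edges
  st3 <- star_graph(3, 3)
  single <- data.frame(in_edge = "i1+", out_edge = "o2+",
                       stringsAsFactors = FALSE)
  g3 <- split_vertex(st3$cg, st3$v, single)$graph
  expect_true(st3$v %in% g3$from)
  expect_setequal(names(g3$to)[g3$to == st3$v], c("i2+", "i3+"))
  expect_setequal(names(g3$from)[g3$from == st3$v], c("o1+", "o3+"))
  check_skew_symmetry(g3)

  ## empty matching is the identity; invalid matchings are rejected
  expect_identical(split_vertex(st$cg, st$v,
                                perfect[0, ])$graph, st$cg)
  expect_error(split_vertex(st$cg, st$v,
                            data.frame(in_edge = c("i1+", "i2+"),
                                       out_edge = c("o1+", "o1+"))),
               "shared endpoint")
  expect_error(split_vertex(st$cg, st$v,
                            data.frame(in_edge = "o1+", out_edge = "o2+")),
               "not incident")
})

test_that("splitting preserves exactly the matched traversals", {
  st <- star_graph(2, 2)
  matching <- data.frame(in_edge = c("i1+", "i2+"), out_edge = c("o2+", "o1+"),
                         stringsAsFactors = FALSE)
  g <- split_vertex(st$cg, st$v, matching)$graph
  walks <- function(gr) {
    w <- character(0)
    for (e in gr$edges) for (f in names(gr$from)[gr$from == gr$to[[e]]])
      w <- c(w, paste(e, f))
    sort(w)
  }
  ## post-split two-edge walks = exactly the matching (and its mirror image)
  expect_setequal(walks(g),
                  c("i1+ o2+", "i2+ o1+", "o1- i2-", "o2- i1-"))
})

test_that("condense_paths merges non-branching runs with overlap trimming", {
  ## three-edge chain, zero overlaps: single edge, length = sum
  g <- contract_link_edges(build_raw_dbg(
    chain_gfa(c("AACCG", "TTGGA", "CATCA"), c(0, 0))))
  cgc <- condense_paths(g)
  expect_equal(length(cgc$edges), 2)  # one merged edge per strand
  reps <- cgc$edges[!cgc$is_rc[cgc$edges]]
  expect_identical(unname(cgc$seq[[reps]]), "AACCGTTGGACATCA")
  check_skew_symmetry(cgc)

  ## overlap-aware: suffix/prefix overlap is trimmed once per join
  g2 <- contract_link_edges(build_raw_dbg(
    chain_gfa(c("AACCGTT", "GTTCATC", "TCGGA"), c(3, 2))))
  cgc2 <- condense_paths(g2)
  reps2 <- cgc2$edges[!cgc2$is_rc[cgc2$edges]]
  expect_identical(unname(cgc2$seq[[reps2]]), "AACCGTTCATCGGA")

  ## inconsistent overlap (larger than a joined edge) is an error
  g3 <- contract_link_edges(build_raw_dbg(chain_gfa(c("AACG", "CGTT"), 1)))
  g3$links$overlap <- 6L
  expect_error(condense_paths(g3), "overlap")

  ## an already-condensed graph is unchanged (idempotence)
  expect_same_graph(condense_paths(cgc2), cgc2)
})

test_that("condensed edge count matches the path-decomposition oracle", {
  set.seed(81)
  for (rep in 1:15) {
    ## random DAG-ish GFA: forward-only links between distinct ranks
    n <- 10
    nm <- sprintf("n%02d", 1:n)
    pairs <- expand.grid(a = 1:n, b = 1:n)
    pairs <- pairs[pairs$a < pairs$b, ]
    pick <- pairs[sample(nrow(pairs), 12), ]
    g <- gfa_graph(
      segments = data.frame(name = nm,
                            sequence = vapply(rep(20, n), rand_dna,
                                              character(1)),
                            stringsAsFactors = FALSE),
      links = data.frame(from = nm[pick$a], from_orient = "+",
                         to = nm[pick$b], to_orient = "+", overlap = 0L,
                         stringsAsFactors = FALSE))
    cg <- contract_link_edges(build_raw_dbg(g))
    cgc <- condense_paths(cg)
    expect_equal(length(cgc$edges), oracle_condensed_edge_count(cg))
    check_skew_symmetry(cgc)
    ## no internal 1-in/1-out vertex survives
    for (v in unique(c(cgc$from, cgc$to))) {
      if (sum(cgc$to == v) == 1 && sum(cgc$from == v) == 1) {
        e <- names(cgc$to)[cgc$to == v]
        f <- names(cgc$from)[cgc$from == v]
        expect_true(f == e || f == cgc$rc[[e]])
      }
    }
    ## idempotent
    expect_same_graph(condense_paths(cgc), cgc)
  }
})

test_that("fill_gap distinguishes unique paths, ambiguous paths, and dead ends", {
  ## single intermediate edge of length 100: literal fill
  g <- contract_link_edges(build_raw_dbg(
    chain_gfa(c(rand_dna(50), rand_dna(100), rand_dna(50)), c(0, 0))))
  fg <- fill_gap(g, "e1+", "e3+")
  expect_equal(fg$type, "fill")
  expect_identical(fg$sequence, unname(g$seq[["e2+"]]))
  expect_equal(fg$trail_overlap, 0)

  ## two parallel equal-length alternatives: N-gap of the path length
  nm <- c("a", "p", "q", "b")
  g2 <- gfa_graph(
    segments = data.frame(name = nm,
                          sequence = c(rand_dna(40), rand_dna(80),
                                       rand_dna(80), rand_dna(40)),
                          stringsAsFactors = FALSE),
    links = data.frame(from = c("a", "a", "p", "q"), from_orient = "+",
                       to = c("p", "q", "b", "b"), to_orient = "+",
                       overlap = 0L, stringsAsFactors = FALSE))
  dg2 <- contract_link_edges(build_raw_dbg(g2))
  fg2 <- fill_gap(dg2, "a+", "b+")
  expect_equal(fg2$type, "gap")
  expect_equal(fg2$gap_len, 80L)

  ## unreachable: default gap
  g3 <- gfa_graph(segments = data.frame(name = c("x", "y"),
                                        sequence = c(rand_dna(30),
                                                     rand_dna(30))))
  dg3 <- contract_link_edges(build_raw_dbg(g3))
  fg3 <- fill_gap(dg3, "x+", "y+", default_gap = 42L)
  expect_equal(fg3$type, "gap")
  expect_equal(fg3$gap_len, 42L)
})

test_that("scaffolds account for every base of their edges", {
  ## unresolved graph: one scaffold per input edge pair
  set.seed(82)
  g <- gfa_graph(segments = data.frame(
    name = c("u", "w"), sequence = c(rand_dna(25), rand_dna(35)),
    stringsAsFactors = FALSE))
  dg <- contract_link_edges(build_raw_dbg(g))
  sc <- build_scaffolds(dg, dg)
  expect_length(sc, 2)
  expect_setequal(vapply(sc, function(s) nchar(s$sequence), numeric(1)),
                  c(25, 35))

  ## chain with literal fill: total non-N equals edge + fill sequence
  g2 <- contract_link_edges(build_raw_dbg(
    chain_gfa(c(rand_dna(50), rand_dna(100), rand_dna(50)), c(0, 0))))
  split_cg <- contract_repeat_edges(g2, c("e2+", "e2-"))
  sc2 <- build_scaffolds(split_cg, g2)
  expect_length(sc2, 1)
  expect_equal(nchar(sc2[[1]]$sequence), 200)
  expect_false(grepl("N", sc2[[1]]$sequence, fixed = TRUE))

  ## one strand representative per rc pair: re-emitting the mirror strand
  ## and deduplicating canonically changes nothing
  seqs <- vapply(sc2, `[[`, character(1), "sequence")
  both <- unique(c(seqs, rc_oracle(seqs)))
  canon <- unique(pmin(both, rc_oracle(both)))
  expect_length(canon, length(seqs))
})

test_that("graph export writes valid GFA that round-trips the adjacency", {
  st <- star_graph(2, 2)
  gf <- gfa_from_dbg(st$cg)
  f <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(gf, f)
  back <- contract_link_edges(build_raw_dbg(parse_gfa(f)))
  expect_setequal(back$edges, st$cg$edges)
  expect_equal(length(unique(c(back$from, back$to))),
               length(unique(c(st$cg$from, st$cg$to))))
  expect_identical(seq_multiset(back), seq_multiset(st$cg))
})
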