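## barcode sets giving a prescribed overlap matrix on a star graph: in-edge i
## shares `ovm[i, j]` dedicated barcodes with out-edge j
sets_from_matrix <- function(st, ovm) {
  ins <- st$ins; outs <- st$outs
  sets <- setNames(vector("list", length(ins) + length(outs)),
                   c(ins, outs))
  for (i in seq_along(ins)) for (j in seq_along(outs)) {
    if (ovm[i, j] > 0) {
      bcs <- sprintf("b_%d_%d_%d", i, j, seq_len(ovm[i, j]))
      sets[[ins[i]]] <- c(sets[[ins[i]]], bcs)
      sets[[outs[j]]] <- c(sets[[outs[j]]], bcs)
    }
  }
  edge_barcode_sets(st$cg, Filter(Negate(is.null), sets))
}

test_that("barcode_overlap is the intersection size", {
  st <- star_graph(2, 2)
  sets <- edge_barcode_sets(st$cg, list(
    `i1+` = c("b1", "b2", "b3"), `o1+` = c("b2", "b3", "b4"),
    `i2+` = character(0)))
  expect_equal(barcode_overlap("i1+", "o1+", sets), 2)
  expect_equal(barcode_overlap("i2+", "o1+", sets), 0)
  expect_equal(barcode_overlap("i1+", "o2+", sets), 0)
  expect_error(barcode_overlap("zz+", "o1+", sets), "unknown edge")

  ## set oracle on random barcode collections
  set.seed(51)
  for (i in 1:200) {
    a <- sample(sprintf("b%02d", 1:30), sample(0:15, 1))
    b <- sample(sprintf("b%02d", 1:30), sample(0:15, 1))
    sets2 <- edge_barcode_sets(st$cg, list(`i1+` = a, `o1+` = b))
    expect_equal(barcode_overlap("i1+", "o1+", sets2),
                 length(intersect(a, b)))
  }
})

test_that("select_candidate applies absolute and relative thresholds", {
  st <- star_graph(1, 2)
  ## overlaps (10, 4): 10 >= 2*4 and 10 >= 2 -> candidate with count 10
  s <- sets_from_matrix(st, matrix(c(10, 4), 1))
  cand <- select_candidate("i1+", st$v, st$cg, s)
  expect_equal(cand$overlap_count, 10)
  expect_equal(cand$out_edge, "o1+")
  ## overlaps (3, 2): fails the relative test
  s <- sets_from_matrix(st, matrix(c(3, 2), 1))
  expect_null(select_candidate("i1+", st$v, st$cg, s))
  ## overlaps (1, 0): fails abs_thr
  s <- sets_from_matrix(st, matrix(c(1, 0), 1))
  expect_null(select_candidate("i1+", st$v, st$cg, s))

  ## single out-edge: overlap2 is defined as 0
  st1 <- star_graph(1, 1)
  s1 <- sets_from_matrix(st1, matrix(2, 1))
  cand1 <- select_candidate("i1+", st1$v, st1$cg, s1)
  expect_equal(cand1$overlap_count, 2)

  ## tie at the maximum: unreachable with rel_thr = 2, lexicographic with 1
  st2 <- star_graph(1, 2)
  s2 <- sets_from_matrix(st2, matrix(c(5, 5), 1))
  expect_null(select_candidate("i1+", st2$v, st2$cg, s2))
  cand2 <- select_candidate("i1+", st2$v, st2$cg, s2,
                            resolver_params(rel_thr = 1))
  expect_equal(cand2$out_edge, "o1+")
})

test_that("resolve_vertex classifies by matching structure", {
  st <- star_graph(2, 2)
  ## diagonal support: completely resolved with the two true links
  r <- resolve_vertex(st$v, st$cg,
                      sets_from_matrix(st, rbind(c(5, 0), c(0, 6))))
  expect_equal(r$status, "COMPLETELY_RESOLVED")
  expect_setequal(paste(r$matching$in_edge, r$matching$out_edge),
                  c("i1+ o1+", "i2+ o2+"))
  ## no support at all: uncovered
  r0 <- resolve_vertex(st$v, st$cg, sets_from_matrix(st, rbind(c(0, 0), c(0, 0))))
  expect_equal(r0$status, "UNCOVERED")
  expect_equal(nrow(r0$matching), 0)
  ## both in-edges select the same out-edge: ambiguous, links discarded
  ra <- resolve_vertex(st$v, st$cg, sets_from_matrix(st, rbind(c(5, 1), c(4, 1))))
  expect_equal(ra$status, "AMBIGUOUS")
  expect_equal(nrow(ra$matching), 0)
  ## one candidate survives: partially resolved
  rp <- resolve_vertex(st$v, st$cg, sets_from_matrix(st, rbind(c(5, 1), c(2, 2))))
  expect_equal(rp$status, "PARTIALLY_RESOLVED")
  expect_identical(rp$matching$in_edge, "i1+")
  ## coverage present but no candidate survives the relative test: ambiguous
  rb <- resolve_vertex(st$v, st$cg, sets_from_matrix(st, rbind(c(3, 2), c(3, 2))))
  expect_equal(rb$status, "AMBIGUOUS")
})

test_that("elimination completes n-1 matchings in diploid mode only", {
  st <- star_graph(2, 2)
  rp <- resolve_vertex(st$v, st$cg, sets_from_matrix(st, rbind(c(5, 1), c(2, 2))))
  done <- complete_by_elimination(rp, st$cg)
  expect_equal(done$status, "PARTIALLY_RESOLVED")  # label kept for reporting
  expect_true(done$eliminated)
  expect_setequal(paste(done$matching$in_edge, done$matching$out_edge),
                  c("i1+ o1+", "i2+ o2+"))
  ## already-perfect matching unchanged
  rc <- resolve_vertex(st$v, st$cg, sets_from_matrix(st, rbind(c(5, 0), c(0, 6))))
  expect_identical(complete_by_elimination(rc, st$cg), rc)
  ## 3x3 with a single link: more than one pair remains, unchanged
  st3 <- star_graph(3, 3)
  ovm <- matrix(0, 3, 3); ovm[1, 1] <- 5
  r3 <- resolve_vertex(st3$v, st3$cg, sets_from_matrix(st3, ovm))
  expect_equal(r3$status, "PARTIALLY_RESOLVED")
  expect_identical(complete_by_elimination(r3, st3$cg)$matching, r3$matching)
})

test_that("resolve_vertex agrees with the literal brute-force oracle", {
  set.seed(61)
  shapes <- expand.grid(n_in = 2:5, n_out = 2:5)
  stars <- lapply(seq_len(nrow(shapes)), function(i)
    star_graph(shapes$n_in[i], shapes$n_out[i]))
  for (iter in 1:300) {
    st <- stars[[sample(length(stars), 1)]]
    raw <- random_star_sets(st)
    sets <- edge_barcode_sets(st$cg, raw)
    got <- resolve_vertex(st$v, st$cg, sets)
    exp <- oracle_resolve(raw[st$ins], raw[st$outs])
    expect_equal(got$status, exp$status)
    if (!is.null(exp$matching)) {
      expect_setequal(paste(got$matching$in_edge, got$matching$out_edge),
                      paste(exp$matching$in_edge, exp$matching$out_edge))
    } else {
      expect_equal(nrow(got$matching), 0)
    }
  }
})

test_that("classify_graph partitions branching vertices and is deterministic", {
  ## graph with no branching vertices
  g <- gfa_graph(segments = data.frame(name = "a", sequence = "ACGTACGT"))
  cg <- contract_link_edges(build_raw_dbg(g))
  rep0 <- classify_graph(cg, edge_barcode_sets(cg, list()), mode = "diploid")
  expect_equal(sum(rep0$counts), 0)

  ## random sets on a star: counts sum to the branching vertex count
  set.seed(62)
  st <- star_graph(3, 3)
  sets <- edge_barcode_sets(st$cg, random_star_sets(st))
  rep1 <- classify_graph(st$cg, sets, mode = "metagenomic")
  expect_equal(sum(rep1$counts), length(branching_vertices(st$cg)))
  ## determinism
  rep2 <- classify_graph(st$cg, sets, mode = "metagenomic")
  expect_identical(resolution_table(rep1), resolution_table(rep2))
  ## table column contract
  tab <- resolution_table(rep1)
  expect_named(tab, c("vertex_id", "status", "in_degree", "out_degree", "links"))
})

test_that("growing barcode sets never un-cover a vertex (downsampling monotonicity)", {
  set.seed(63)
  st <- star_graph(2, 2)
  pool <- sprintf("b%02d", 1:40)
  full <- random_star_sets(st, pool_size = 40, max_set = 20)
  sets_full <- edge_barcode_sets(st$cg, full)
  uncovered_at <- function(keep) {
    sub <- subset_barcodes(sets_full, keep)
    r <- classify_graph(st$cg, sub, mode = "diploid")
    sum(r$counts["UNCOVERED"])
  }
  shuffled <- sample(pool)
  fracs <- seq(0.1, 1, by = 0.1)
  unc <- vapply(fracs, function(f)
    uncovered_at(shuffled[seq_len(ceiling(f * length(shuffled)))]), numeric(1))
  expect_true(all(diff(unc) <= 0))
})

test_that("noiseless diploid data yields no cross-haplotype links", {
  cfg <- sim_config(n_blocks = 9, homo_len = 2000, het_len = 2000,
                    snp_rate = 0.03, fragment_len_mean = 8000,
                    coverage = 12, reads_per_fragment = 10, seed = 71)
  sim <- simulate_diploid(cfg)
  bg <- build_bubble_graph(sim)
  lib <- simulate_linked_reads(sim)
  cg <- contract_link_edges(build_raw_dbg(bg$gfa))
  cg <- contract_repeat_edges(
    cg, c(paste0(bg$repeat_segments, "+"), paste0(bg$repeat_segments, "-")))
  idx <- build_unique_kmer_index(cg, k = 31)
  sets <- collect_edge_barcodes(lib$pairs, cg, idx, mode = "diploid")
  report <- classify_graph(cg, sets, mode = "diploid")
  ev <- evaluate_links(report, cg, bg$edge_haplotype)
  expect_equal(unname(ev$link_counts["incorrect"]), 0)
})
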