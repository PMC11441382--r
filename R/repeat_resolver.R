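## Repeat resolution at branching vertices.
##
## The working assumption: consecutive edges of the genomic traversal share
## many barcodes, because fragments spanning the repeat carry reads on both
## the in-edge suffix and the out-edge prefix. For each in-edge e of a
## branching vertex, the out-edge with the largest barcode-set overlap is a
## candidate follow-up when the overlap clears an absolute threshold and
## dominates the runner-up by a relative threshold.

#' Resolver parameters
#'
#' @param abs_thr minimum number of shared barcodes between an in-edge and
#'   its selected out-edge (default 2).
#' @param rel_thr the largest overlap must be at least `rel_thr` times the
#'   second largest (default 2).
#' @param uncovered_def which definition of an uncovered vertex to use:
#'   `"pairwise"` (no in/out edge pair shares `abs_thr` barcodes; default) or
#'   `"edge-size"` (every incident edge has fewer than `abs_thr` barcodes).
#' @return an object of class `resolver_params`.
#' @export
resolver_params <- function(abs_thr = 2L, rel_thr = 2,
                            uncovered_def = c("pairwise", "edge-size")) {
  abs_thr <- as.integer(abs_thr)
  if (is.na(abs_thr) || abs_thr < 1L) stop("abs_thr must be >= 1")
  if (!is.numeric(rel_thr) || rel_thr < 1) stop("rel_thr must be >= 1")
  structure(list(abs_thr = abs_thr, rel_thr = rel_thr,
                 uncovered_def = match.arg(uncovered_def)),
            class = "resolver_params")
}

#' Barcode-set overlap of two edges
#'
#' Size of the intersection of `barcodes(e)` and `barcodes(e2)`.
#'
#' @param e,e2 directed edge ids.
#' @param sets an `edge_barcodes` object.
#' @return integer overlap count.
#' @export
barcode_overlap <- function(e, e2, sets) {
  length(intersect(edge_barcode_set(sets, e), edge_barcode_set(sets, e2)))
}

## Overlap counts of one in-edge against a vector of out-edges.
overlap_row <- function(e, outs, sets) {
  b <- edge_barcode_set(sets, e)
  vapply(outs, function(o) length(intersect(b, edge_barcode_set(sets, o))),
         integer(1))
}

#' Select the candidate follow-up edge for one in-edge
#'
#' Computes `overlap(e, e')` for every out-edge `e'` of `v`; with `overlap1`
#' the largest and `overlap2` the second largest (0 when there is a single
#' out-edge), the best out-edge `e*` is selected iff
#' `overlap1 >= rel_thr * overlap2` and `overlap1 >= abs_thr`. With
#' `rel_thr > 1` a tie for the maximum necessarily fails the relative test;
#' when `rel_thr == 1` makes a tie selectable, the lexicographically smallest
#' out-edge id wins.
#'
#' @param e an in-edge of `v`.
#' @param v vertex id.
#' @param cg a contracted `dbg_graph`.
#' @param sets an `edge_barcodes` object.
#' @param params a [resolver_params] object.
#' @return a one-row data.frame (`in_edge`, `out_edge`, `overlap_count`) or
#'   NULL when no out-edge qualifies.
#' @export
select_candidate <- function(e, v, cg, sets, params = resolver_params()) {
  outs <- out_edges(cg, v)
  if (length(outs) == 0) return(NULL)
  ov <- overlap_row(e, outs, sets)
  o1 <- max(ov)
  o2 <- if (length(ov) >= 2) sort(ov, decreasing = TRUE)[2L] else 0L
  if (o1 < params$abs_thr || o1 < params$rel_thr * o2) return(NULL)
  best <- outs[ov == o1]
  data.frame(in_edge = e, out_edge = sort_c(best)[1L], overlap_count = o1,
             stringsAsFactors = FALSE)
}

#' Resolve one branching vertex
#'
#' Computes candidate links for every in-edge and classifies the vertex:
#' `UNCOVERED` when no barcode support exists at all (see
#' [resolver_params()] for the two definitions), `COMPLETELY_RESOLVED` /
#' `PARTIALLY_RESOLVED` when the candidate links form a perfect / non-empty
#' matching, and `AMBIGUOUS` otherwise (either no candidate survived the
#' thresholds despite coverage, or two in-edges claimed the same out-edge, in
#' which case all links are discarded).
#'
#' @param v vertex id (must be branching).
#' @param cg a contracted `dbg_graph`.
#' @param sets an `edge_barcodes` object.
#' @param params a [resolver_params] object.
#' @return an object of class `vertex_resolution`: list with `vertex_id`,
#'   `status`, `matching` (data.frame of links), `in_degree`, `out_degree`,
#'   `eliminated` (logical, see [complete_by_elimination()]).
#' @export
resolve_vertex <- function(v, cg, sets, params = resolver_params()) {
  ins <- in_edges(cg, v)
  outs <- out_edges(cg, v)
  ovm <- do.call(rbind, lapply(ins, overlap_row, outs = outs, sets = sets))
  covered <- if (params$uncovered_def == "pairwise") {
    any(ovm >= params$abs_thr)
  } else {
    any(vapply(c(ins, outs),
               function(e) length(edge_barcode_set(sets, e)), integer(1)) >=
        params$abs_thr)
  }
  empty <- data.frame(in_edge = character(0), out_edge = character(0),
                      overlap_count = integer(0), stringsAsFactors = FALSE)
  res <- list(vertex_id = v, status = "AMBIGUOUS", matching = empty,
              in_degree = length(ins), out_degree = length(outs),
              eliminated = FALSE)
  class(res) <- "vertex_resolution"
  if (!covered) {
    res$status <- "UNCOVERED"
    return(res)
  }
  cand <- do.call(rbind, lapply(ins, select_candidate, v = v, cg = cg,
                                sets = sets, params = params))
  if (is.null(cand) || nrow(cand) == 0) return(res)  # AMBIGUOUS
  if (anyDuplicated(cand$out_edge) > 0) return(res)  # conflict -> AMBIGUOUS
  res$matching <- cand
  res$status <- if (nrow(cand) == length(ins) && nrow(cand) == length(outs))
    "COMPLETELY_RESOLVED" else "PARTIALLY_RESOLVED"
  res
}

#' Complete an almost-perfect matching by elimination
#'
#' In diploid mode, when a vertex has equal in- and out-degree n and the
#' matching covers exactly n-1 in-edges and n-1 out-edges, the remaining
#' in/out pair is forced and added to the matching. The status stays
#' `PARTIALLY_RESOLVED` for reporting (only one haplotype was recovered from
#' barcodes; the other by elimination), but the matching becomes perfect for
#' splitting purposes.
#'
#' @param res a `vertex_resolution`.
#' @param cg a contracted `dbg_graph`.
#' @return a `vertex_resolution`, possibly with the forced link added and
#'   `eliminated = TRUE`; unchanged when the precondition is unmet.
#' @export
complete_by_elimination <- function(res, cg) {
  stopifnot(inherits(res, "vertex_resolution"))
  if (res$status != "PARTIALLY_RESOLVED") return(res)
  ins <- in_edges(cg, res$vertex_id)
  outs <- out_edges(cg, res$vertex_id)
  n <- length(ins)
  if (length(outs) != n || nrow(res$matching) != n - 1L) return(res)
  rem_in <- setdiff(ins, res$matching$in_edge)
  rem_out <- setdiff(outs, res$matching$out_edge)
  if (length(rem_in) != 1L || length(rem_out) != 1L) return(res)
  forced <- data.frame(in_edge = rem_in, out_edge = rem_out,
                       overlap_count = NA_integer_, stringsAsFactors = FALSE)
  res$matching <- rbind(res$matching, forced)
  res$eliminated <- TRUE
  res
}

#' @export
print.vertex_resolution <- function(x, ...) {
  cat("vertex", x$vertex_id, ":", x$status,
      sprintf("(%d-in/%d-out, %d link(s)%s)\n", x$in_degree, x$out_degree,
              nrow(x$matching), if (x$eliminated) ", 1 by elimination" else ""))
  invisible(x)
}

## Mirror image of a resolution at the reverse-complement vertex: every link
## (e, f) becomes (rc(f), rc(e)); status and provenance carry over.
mirror_resolution <- function(res, cg, mv) {
  m <- res$matching
  out <- res
  out$vertex_id <- mv
  out$in_degree <- res$out_degree
  out$out_degree <- res$in_degree
  if (nrow(m) > 0) {
    mm <- data.frame(in_edge = unname(cg$rc[m$out_edge]),
                     out_edge = unname(cg$rc[m$in_edge]),
                     overlap_count = m$overlap_count,
                     stringsAsFactors = FALSE)
    mm <- mm[order(mm$in_edge, method = "radix"), , drop = FALSE]
    rownames(mm) <- NULL
    out$matching <- mm
  }
  out
}

#' Classify every branching vertex of a graph
#'
#' Runs [resolve_vertex()] (plus [complete_by_elimination()] in diploid mode)
#' on one strand representative of every branching vertex pair; candidate
#' links are computed on the in-edge side only, and the mirror vertex
#' inherits the mirrored matching, keeping the report strand-symmetric by
#' construction.
#'
#' @param cg a contracted `dbg_graph`.
#' @param sets an `edge_barcodes` object.
#' @param params a [resolver_params] object.
#' @param mode `"diploid"` (enables elimination) or `"metagenomic"`.
#' @return an object of class `resolution_report`: list with `resolutions`
#'   (named list of `vertex_resolution`), `counts` (named integer vector over
#'   the four statuses), `mode`, `params`.
#' @export
classify_graph <- function(cg, sets, params = resolver_params(),
                           mode = c("diploid", "metagenomic")) {
  mode <- match.arg(mode)
  bv <- branching_vertices(cg)
  resolutions <- vector("list", length(bv))
  names(resolutions) <- bv
  for (v in bv) {
    if (!is.null(resolutions[[v]])) next
    r <- resolve_vertex(v, cg, sets, params)
    if (mode == "diploid") r <- complete_by_elimination(r, cg)
    resolutions[[v]] <- r
    mv <- mirror_vertex(cg, v)
    if (mv != v && mv %in% bv && is.null(resolutions[[mv]]))
      resolutions[[mv]] <- mirror_resolution(r, cg, mv)
  }
  statuses <- vapply(resolutions, `[[`, character(1), "status")
  lv <- c("COMPLETELY_RESOLVED", "PARTIALLY_RESOLVED", "UNCOVERED", "AMBIGUOUS")
  counts <- table(factor(statuses, levels = lv))
  structure(list(resolutions = resolutions,
                 counts = setNames(as.integer(counts), lv),
                 mode = mode, params = params),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("resolution_report (", x$mode, " mode): ",
      sum(x$counts), " branching vertices\n", sep = "")
  for (s in names(x$counts)) cat(sprintf("  %-20s %d\n", s, x$counts[[s]]))
  invisible(x)
}

#' Resolution report as a data.frame / TSV
#'
#' One row per branching vertex: `vertex_id`, `status`, `in_degree`,
#' `out_degree`, `links` (semicolon-separated `in>out` pairs).
#'
#' @param report a `resolution_report`.
#' @param path optional TSV output path.
#' @return the data.frame, invisibly when `path` is given.
#' @export
resolution_table <- function(report, path = NULL) {
  stopifnot(inherits(report, "resolution_report"))
  rows <- lapply(report$resolutions, function(r) {
    data.frame(vertex_id = r$vertex_id, status = r$status,
               in_degree = r$in_degree, out_degree = r$out_degree,
               links = paste(sprintf("%s>%s", r$matching$in_edge,
                                     r$matching$out_edge), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(vertex_id = character(0), status = character(0),
               in_degree = integer(0), out_degree = integer(0),
               links = character(0), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
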