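## DBG-like graph model.
##
## An arbitrary GFA assembly graph is turned into a directed, strand-symmetric
## graph in which every segment becomes a pair of directed edges (forward and
## reverse complement) and GFA links become "link edges" between private
## endpoint vertices. Contracting all link edges yields the graph on which
## repeat resolution operates: segments are edges, clusters of contracted
## links are vertices ("unresolved repeats"). For repeat-annotated graphs
## (metaFlye-style) the labelled repeat edges themselves can be contracted
## further.
##
## Internal representation of a `dbg_graph`:
##   stage       "RAW" or "CONTRACTED"
##   edges       character vector of directed edge ids
##   seq         named character, edge id -> sequence
##   segment     named character, edge id -> originating segment name
##   is_rc       named logical
##   rc          named character, edge id -> id of reverse-complement edge
##   from, to    named character, edge id -> vertex id (start/end vertex)
##   links       data.frame(in_edge, out_edge, overlap): oriented adjacency
##               pairs carried over from GFA links (mirrors included)
##   link_edges  (RAW only) data.frame(from_vertex, to_vertex)
## Vertices exist implicitly as the values of `from`/`to`.

#' Expand GFA segments into a strand-doubled directed edge set
#'
#' Every segment yields two directed edges: the forward orientation and its
#' reverse complement. The pairing is an involution with no fixed points; even
#' for palindromic sequences the two orientations are distinct edges.
#'
#' @param g a [gfa_graph].
#' @return data.frame with columns `edge_id`, `segment`, `is_rc`, `sequence`,
#'   `length`, `rc_id`.
#' @export
expand_edges <- function(g) {
  stopifnot(inherits(g, "gfa_graph"))
  nm <- g$segments$name
  if (any(g$segments$sequence %in% c("", "*")))
    stop("all segments must carry sequences")
  fwd_id <- paste0(nm, "+")
  rc_id <- paste0(nm, "-")
  data.frame(
    edge_id = c(fwd_id, rc_id),
    segment = c(nm, nm),
    is_rc = rep(c(FALSE, TRUE), each = length(nm)),
    sequence = c(g$segments$sequence, revcomp(g$segments$sequence)),
    length = rep(nchar(g$segments$sequence), 2L),
    rc_id = c(rc_id, fwd_id),
    stringsAsFactors = FALSE)
}

## Directed edge id for a (segment, orientation) pair.
oriented_id <- function(segment, orient) {
  paste0(segment, ifelse(orient == "+", "+", "-"))
}

flip_id <- function(edge_id) {
  n <- nchar(edge_id)
  sgn <- substr(edge_id, n, n)
  paste0(substr(edge_id, 1L, n - 1L), ifelse(sgn == "+", "-", "+"))
}

#' Build the raw DBG-like graph
#'
#' Each directed edge gets private endpoint vertices; each GFA link
#' \eqn{(e_1, e_2)} (orientation-resolved) contributes a link edge from
#' \eqn{end(e_1)} to \eqn{start(e_2)} plus the mirror link edge from
#' \eqn{end(rc(e_2))} to \eqn{start(rc(e_1))}.
#'
#' @param g a [gfa_graph].
#' @return a `dbg_graph` at stage `"RAW"`.
#' @export
build_raw_dbg <- function(g) {
  ed <- expand_edges(g)
  ids <- ed$edge_id
  gr <- list(
    stage = "RAW",
    edges = ids,
    seq = setNames(ed$sequence, ids),
    segment = setNames(ed$segment, ids),
    is_rc = setNames(ed$is_rc, ids),
    rc = setNames(ed$rc_id, ids),
    from = setNames(paste0("S:", ids), ids),
    to = setNames(paste0("E:", ids), ids))
  lk <- g$links
  if (nrow(lk) > 0) {
    e1 <- oriented_id(lk$from, lk$from_orient)
    e2 <- oriented_id(lk$to, lk$to_orient)
    in_edge <- c(e1, flip_id(e2))
    out_edge <- c(e2, flip_id(e1))
    ov <- c(lk$overlap, lk$overlap)
    key <- paste(in_edge, out_edge)
    keep <- !duplicated(key)
    links <- data.frame(in_edge = in_edge[keep], out_edge = out_edge[keep],
                        overlap = ov[keep], stringsAsFactors = FALSE)
  } else {
    links <- data.frame(in_edge = character(0), out_edge = character(0),
                        overlap = integer(0), stringsAsFactors = FALSE)
  }
  links <- links[order(links$in_edge, links$out_edge, method = "radix"), , drop = FALSE]
  rownames(links) <- NULL
  gr$links <- links
  gr$link_edges <- if (nrow(links) > 0)
    data.frame(from_vertex = paste0("E:", links$in_edge),
               to_vertex = paste0("S:", links$out_edge),
               stringsAsFactors = FALSE)
  else data.frame(from_vertex = character(0), to_vertex = character(0),
                  stringsAsFactors = FALSE)
  structure(gr, class = "dbg_graph")
}

## Deterministic relabelling: component containing the smallest vertex name
## gets the smallest number.
relabel_vertices <- function(vertex_names, comp) {
  mins <- tapply(vertex_names, comp, min)
  lab <- rank(mins, ties.method = "first")
  setNames(paste0("v", lab[as.character(comp)]), vertex_names)
}

#' Contract all link edges
#'
#' Merges the endpoint vertices joined by link edges (contraction = merge the
#' two endpoints, drop the resulting loop), producing the DBG-like graph on
#' which resolution operates. The GFA links contracted into each vertex stay
#' available through [vertex_links()].
#'
#' @param rdg a `dbg_graph` at stage `"RAW"`.
#' @return a `dbg_graph` at stage `"CONTRACTED"`.
#' @export
contract_link_edges <- function(rdg) {
  stopifnot(inherits(rdg, "dbg_graph"))
  if (rdg$stage == "CONTRACTED") return(rdg)  # no link edges left: identity
  verts <- sort_c(unique(c(rdg$from, rdg$to,
                         rdg$link_edges$from_vertex, rdg$link_edges$to_vertex)))
  parent <- uf_new(length(verts))
  vi <- setNames(seq_along(verts), verts)
  le <- rdg$link_edges
  for (i in seq_len(nrow(le)))
    parent <- uf_union(parent, vi[[le$from_vertex[i]]], vi[[le$to_vertex[i]]])
  comp <- uf_components(parent)
  vmap <- relabel_vertices(verts, comp)
  out <- rdg
  out$stage <- "CONTRACTED"
  out$from <- setNames(unname(vmap[rdg$from]), names(rdg$from))
  out$to <- setNames(unname(vmap[rdg$to]), names(rdg$to))
  out$link_edges <- NULL
  structure(out, class = "dbg_graph")
}

#' Contract repeat-labelled edges
#'
#' For assembly graphs whose producer labels repetitive edges (metaFlye-style),
#' contracts every labelled edge: its two endpoint vertices merge and the edge
#' is removed, so the resulting vertex represents the unresolved (possibly
#' inexact) repeat. The label set must be closed under reverse complement.
#'
#' @param cg a contracted `dbg_graph`.
#' @param repeat_edges character vector of directed edge ids to contract.
#' @return a `dbg_graph` at stage `"CONTRACTED"` without the repeat edges.
#' @export
contract_repeat_edges <- function(cg, repeat_edges) {
  stopifnot(inherits(cg, "dbg_graph"))
  if (cg$stage != "CONTRACTED") stop("expects a CONTRACTED graph")
  repeat_edges <- unique(as.character(repeat_edges))
  if (length(repeat_edges) == 0) return(cg)
  unknown <- setdiff(repeat_edges, cg$edges)
  if (length(unknown) > 0)
    stop("unknown repeat edge(s): ", paste(unknown, collapse = ", "))
  if (!setequal(repeat_edges, unname(cg$rc[repeat_edges])))
    stop("repeat edge set is not closed under reverse complement")
  verts <- sort_c(unique(c(cg$from, cg$to)))
  parent <- uf_new(length(verts))
  vi <- setNames(seq_along(verts), verts)
  for (e in repeat_edges)
    parent <- uf_union(parent, vi[[cg$from[[e]]]], vi[[cg$to[[e]]]])
  vmap <- relabel_vertices(verts, uf_components(parent))
  keep <- setdiff(cg$edges, repeat_edges)
  out <- cg
  out$edges <- keep
  out$seq <- cg$seq[keep]
  out$segment <- cg$segment[keep]
  out$is_rc <- cg$is_rc[keep]
  out$rc <- cg$rc[keep]
  out$from <- setNames(unname(vmap[cg$from[keep]]), keep)
  out$to <- setNames(unname(vmap[cg$to[keep]]), keep)
  lk <- cg$links
  lk <- lk[lk$in_edge %in% keep & lk$out_edge %in% keep, , drop = FALSE]
  rownames(lk) <- NULL
  out$links <- lk
  structure(out, class = "dbg_graph")
}

#' Repeat labels from a plain-text file of segment names
#'
#' One GFA segment name per line; both orientations of each named segment are
#' returned (reverse-complement closure is applied automatically).
#'
#' @param path text file of segment names.
#' @param cg the contracted graph the labels refer to.
#' @return character vector of directed edge ids.
#' @export
read_repeat_labels <- function(path, cg) {
  nm <- trimws(readLines(path, warn = FALSE))
  nm <- nm[nzchar(nm)]
  ids <- c(paste0(nm, "+"), paste0(nm, "-"))
  ids[ids %in% cg$edges]
}

## Vertex accessors ----------------------------------------------------------

vertex_ids <- function(g) sort_c(unique(c(g$from, g$to)))

in_edges <- function(g, v) sort_c(names(g$to)[g$to == v])

out_edges <- function(g, v) sort_c(names(g$from)[g$from == v])

in_degree <- function(g, v) sum(g$to == v)

out_degree <- function(g, v) sum(g$from == v)

## Mirror (reverse-complement) vertex of v.
mirror_vertex <- function(g, v) {
  e <- names(g$to)[g$to == v]
  if (length(e) > 0) return(unname(g$from[[g$rc[[e[1]]]]]))
  e <- names(g$from)[g$from == v]
  if (length(e) > 0) return(unname(g$to[[g$rc[[e[1]]]]]))
  stop("vertex has no incident edges: ", v)
}

#' GFA links contracted into a vertex
#'
#' @param g a contracted `dbg_graph`.
#' @param v vertex id.
#' @return data.frame of oriented links (in_edge, out_edge, overlap) whose
#'   contact point lies in `v`.
#' @export
vertex_links <- function(g, v) {
  lk <- g$links
  lk[lk$in_edge %in% names(g$to)[g$to == v], , drop = FALSE]
}

## Overlap to trim when joining e -> f at a shared vertex: the recorded link
## overlap if a direct link exists, else a single overlap value shared by all
## links at the vertex, else 0 (with a warning).
join_overlap <- function(g, e, f) {
  lk <- g$links
  hit <- which(lk$in_edge == e & lk$out_edge == f)
  if (length(hit) > 0) return(lk$overlap[hit[1L]])
  v <- g$to[[e]]
  vl <- vertex_links(g, v)
  if (nrow(vl) > 0 && length(unique(vl$overlap)) == 1L)
    return(vl$overlap[1L])
  if (nrow(vl) > 0)
    warning("no direct link and conflicting overlaps at vertex ", v,
            "; joining ", e, " -> ", f, " without trimming")
  0L
}

#' Branching vertices of a contracted graph
#'
#' A vertex is branching when both its in-degree and out-degree are at least
#' two; such vertices represent unresolved genomic repeats. A loop edge
#' contributes one to both degrees.
#'
#' @param cg a contracted `dbg_graph`.
#' @return sorted character vector of vertex ids.
#' @export
branching_vertices <- function(cg) {
  stopifnot(inherits(cg, "dbg_graph"))
  if (cg$stage != "CONTRACTED") stop("expects a CONTRACTED graph")
  indeg <- table(cg$to)
  outdeg <- table(cg$from)
  v <- intersect(names(indeg)[indeg >= 2], names(outdeg)[outdeg >= 2])
  sort_c(v)
}

#' Check strand (skew) symmetry of a DBG-like graph
#'
#' Verifies that reverse complementation is a fixed-point-free involution on
#' edges, that rc sequences match, and that the vertex mirror map is
#' well-defined: whenever edge `e` ends where `f` starts, `rc(f)` ends where
#' `rc(e)` starts.
#'
#' @param g a `dbg_graph`.
#' @return TRUE invisibly; stops with a message on violation.
#' @export
check_skew_symmetry <- function(g) {
  stopifnot(inherits(g, "dbg_graph"))
  if (!identical(sort(unname(g$rc[g$rc])), sort(g$edges)) ||
      any(g$rc[g$edges] == g$edges))
    stop("rc is not a fixed-point-free involution")
  if (!identical(unname(g$seq[g$rc[g$edges]]), revcomp(unname(g$seq[g$edges]))))
    stop("rc sequences are not reverse complements")
  ## mirror map from 'to' side and 'from' side must agree
  m1 <- tapply(unname(g$from[g$rc[names(g$to)]]), unname(g$to), unique)
  m2 <- tapply(unname(g$to[g$rc[names(g$from)]]), unname(g$from), unique)
  if (any(lengths(m1) != 1L) || any(lengths(m2) != 1L))
    stop("vertex mirror map is not well-defined")
  common <- intersect(names(m1), names(m2))
  if (!identical(unlist(m1[common]), unlist(m2[common])))
    stop("vertex mirror maps from in- and out-sides disagree")
  invisible(TRUE)
}

#' @export
print.dbg_graph <- function(x, ...) {
  nv <- length(unique(c(x$from, x$to)))
  cat("dbg_graph (", x$stage, "): ", length(x$edges), " directed edges, ",
      nv, " vertices\n", sep = "")
  if (x$stage == "CONTRACTED")
    cat("  branching vertices:", length(branching_vertices(x)), "\n")
  invisible(x)
}
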