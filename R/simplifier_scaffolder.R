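## Graph simplification and scaffolding.
##
## Resolved branching vertices are split: every matched (in-edge, out-edge)
## link is rerouted through a fresh 1-in/1-out vertex, the residual vertex
## keeping any unmatched edges (and disappearing when the matching was
## perfect). Non-branching paths are then condensed into single edges
## (LJA-style graphs) or emitted as scaffolds with literal-path or N-gap
## fills looked up in the original graph (all other producers).

#' Split a resolved vertex
#'
#' For every link `(e, f)` of the matching a new vertex is created with `e`
#' as its only in-edge and `f` as its only out-edge; the mirror vertex is
#' split identically. Unmatched edges stay on the residual vertex, which
#' ceases to exist exactly when the matching was perfect. Sequence edges are
#' never created or removed.
#'
#' @param cg a contracted `dbg_graph`.
#' @param v vertex id.
#' @param matching data.frame with columns `in_edge`, `out_edge`.
#' @return list with `graph` (the modified `dbg_graph`) and `events`
#'   (data.frame: `original_vertex`, `new_vertex`, `in_edge`, `out_edge`).
#' @export
split_vertex <- function(cg, v, matching) {
  stopifnot(inherits(cg, "dbg_graph"))
  if (nrow(matching) == 0)
    return(list(graph = cg, events = data.frame(
      original_vertex = character(0), new_vertex = character(0),
      in_edge = character(0), out_edge = character(0),
      stringsAsFactors = FALSE)))
  ins <- in_edges(cg, v); outs <- out_edges(cg, v)
  if (!all(matching$in_edge %in% ins) || !all(matching$out_edge %in% outs))
    stop("matching references edges not incident to vertex ", v)
  if (anyDuplicated(matching$in_edge) > 0 || anyDuplicated(matching$out_edge) > 0)
    stop("invalid matching: shared endpoint at vertex ", v)
  m <- mirror_vertex(cg, v)
  g <- cg
  ev <- vector("list", nrow(matching))
  for (i in seq_len(nrow(matching))) {
    e <- matching$in_edge[i]; f <- matching$out_edge[i]
    nv <- paste0(v, "|", e)
    g$to[[e]] <- nv
    g$from[[f]] <- nv
    ## mirror split: link (rc(f), rc(e)) at the mirror vertex
    nm <- paste0(m, "|", g$rc[[f]])
    g$to[[g$rc[[f]]]] <- nm
    g$from[[g$rc[[e]]]] <- nm
    ev[[i]] <- data.frame(original_vertex = v, new_vertex = nv,
                          in_edge = e, out_edge = f, stringsAsFactors = FALSE)
  }
  list(graph = g, events = do.call(rbind, ev))
}

#' Split every resolved vertex of a classified graph
#'
#' Applies [split_vertex()] to each completely or partially resolved vertex
#' (each vertex/mirror pair once; the mirror is split alongside its partner).
#'
#' @param cg a contracted `dbg_graph`.
#' @param report a `resolution_report` from [classify_graph()].
#' @return list with `graph` and `events` (row-bound split events).
#' @export
split_resolved <- function(cg, report) {
  stopifnot(inherits(report, "resolution_report"))
  g <- cg
  events <- list()
  done <- character(0)
  for (v in names(report$resolutions)) {
    if (v %in% done) next
    res <- report$resolutions[[v]]
    if (!res$status %in% c("COMPLETELY_RESOLVED", "PARTIALLY_RESOLVED")) next
    if (nrow(res$matching) == 0) next
    mv <- mirror_vertex(g, v)
    out <- split_vertex(g, v, res$matching)
    g <- out$graph
    events[[v]] <- out$events
    done <- c(done, v, mv)
  }
  list(graph = g,
       events = if (length(events) > 0) do.call(rbind, c(events, make.row.names = FALSE))
       else data.frame(original_vertex = character(0), new_vertex = character(0),
                       in_edge = character(0), out_edge = character(0),
                       stringsAsFactors = FALSE))
}

## Maximal non-branching chains of edges. A vertex is a pass-through when it
## has exactly one in-edge e and one out-edge f with f != e (loop) and
## f != rc(e) (hairpin). Returns a list of character vectors (ordered edge
## ids), one chain per rc pair of chains, chosen canonically; every edge of
## the graph occurs in exactly one returned chain or its mirror.
nonbranching_chains <- function(g) {
  indeg <- table(g$to); outdeg <- table(g$from)
  verts <- unique(c(g$from, g$to))
  succ <- character(0)
  for (v in verts) {
    if (!is.na(indeg[v]) && indeg[v] == 1 && !is.na(outdeg[v]) && outdeg[v] == 1) {
      e <- names(g$to)[g$to == v]
      f <- names(g$from)[g$from == v]
      if (f != e && f != g$rc[[e]]) succ[e] <- f
    }
  }
  pred <- if (length(succ) > 0) setNames(names(succ), unname(succ))
          else character(0)
  chains <- list()
  visited <- character(0)
  walk <- function(start) {
    chain <- start
    while (!is.na(succ[chain[length(chain)]]) &&
           !(succ[[chain[length(chain)]]] %in% chain)) {
      chain <- c(chain, succ[[chain[length(chain)]]])
    }
    chain
  }
  starts <- sort_c(g$edges[!(g$edges %in% names(pred))])
  for (s in starts) {
    if (s %in% visited) next
    ch <- walk(s)
    visited <- c(visited, ch)
    chains[[length(chains) + 1L]] <- ch
  }
  ## remaining edges belong to fully condensable cycles
  left <- sort_c(setdiff(g$edges, visited))
  while (length(left) > 0) {
    ch <- walk(left[1L])
    visited <- c(visited, ch)
    chains[[length(chains) + 1L]] <- ch
    left <- sort_c(setdiff(left, ch))
  }
  ## keep one chain per mirror pair (the one with the smaller key)
  keys <- vapply(chains, function(ch) ch[1L], character(1))
  mirror_keys <- vapply(chains, function(ch) g$rc[[ch[length(ch)]]], character(1))
  if (any(keys == mirror_keys))
    stop("self-mirror chain encountered; cannot condense")
  keep <- le_c(keys, mirror_keys)
  chains[keep]
}

#' Condense non-branching paths
#'
#' Merges every maximal path through 1-in/1-out vertices into a single edge
#' whose sequence is the overlap-aware concatenation of the constituent edge
#' sequences (each join trims the recorded link overlap from the successor's
#' prefix). Strand symmetry is preserved; the operation is idempotent.
#'
#' @param cg a contracted `dbg_graph`.
#' @return a condensed `dbg_graph`.
#' @export
condense_paths <- function(cg) {
  stopifnot(inherits(cg, "dbg_graph"))
  if (cg$stage != "CONTRACTED") stop("expects a CONTRACTED graph")
  chains <- nonbranching_chains(cg)
  g <- cg
  counter <- 0L
  for (ch in chains) {
    if (length(ch) == 1L) next
    counter <- counter + 1L
    new_fwd <- sprintf("c%d+", counter)
    new_rev <- sprintf("c%d-", counter)
    while (new_fwd %in% g$edges) {  # avoid collisions with existing names
      counter <- counter + 1L
      new_fwd <- sprintf("c%d+", counter)
      new_rev <- sprintf("c%d-", counter)
    }
    seqs <- g$seq[ch]
    merged <- seqs[[1L]]
    for (i in 2L:length(ch)) {
      ov <- join_overlap(g, ch[i - 1L], ch[i])
      if (ov > nchar(seqs[[i - 1L]]) || ov > nchar(seqs[[i]]))
        stop("inconsistent overlap (", ov, " bp) joining ", ch[i - 1L],
             " -> ", ch[i])
      merged <- paste0(merged, substring(seqs[[i]], ov + 1L))
    }
    mirror_ch <- unname(rev(g$rc[ch]))
    from_v <- g$from[[ch[1L]]]
    to_v <- g$to[[ch[length(ch)]]]
    from_v_rc <- g$from[[mirror_ch[1L]]]
    to_v_rc <- g$to[[mirror_ch[length(mirror_ch)]]]
    drop <- c(ch, mirror_ch)
    keep <- setdiff(g$edges, drop)
    ## rewire boundary links to the new edge ids: drop rows touching chain
    ## interiors (only the chain tail may appear as in_edge, only the chain
    ## head as out_edge), then rename the surviving boundary references
    lk <- g$links
    interior_in <- setdiff(drop, c(ch[length(ch)], mirror_ch[length(mirror_ch)]))
    interior_out <- setdiff(drop, c(ch[1L], mirror_ch[1L]))
    lk <- lk[!(lk$in_edge %in% interior_in) & !(lk$out_edge %in% interior_out), ,
             drop = FALSE]
    lk$in_edge[lk$in_edge == ch[length(ch)]] <- new_fwd
    lk$in_edge[lk$in_edge == mirror_ch[length(mirror_ch)]] <- new_rev
    lk$out_edge[lk$out_edge == ch[1L]] <- new_fwd
    lk$out_edge[lk$out_edge == mirror_ch[1L]] <- new_rev
    rownames(lk) <- NULL
    g$edges <- c(keep, new_fwd, new_rev)
    g$seq <- c(g$seq[keep], setNames(c(merged, revcomp(merged)),
                                     c(new_fwd, new_rev)))
    g$segment <- c(g$segment[keep],
                   setNames(c(sub(".$", "", new_fwd), sub(".$", "", new_fwd)),
                            c(new_fwd, new_rev)))
    g$is_rc <- c(g$is_rc[keep], setNames(c(FALSE, TRUE), c(new_fwd, new_rev)))
    g$rc <- c(g$rc[keep], setNames(c(new_rev, new_fwd), c(new_fwd, new_rev)))
    g$from <- c(g$from[keep], setNames(c(from_v, from_v_rc), c(new_fwd, new_rev)))
    g$to <- c(g$to[keep], setNames(c(to_v, to_v_rc), c(new_fwd, new_rev)))
    g$links <- lk
  }
  g
}

#' Fill between two scaffolded edges using the original graph
#'
#' Searches the original (link-contracted, repeat edges intact) graph for
#' simple paths from `end(e)` to `start(next_e)`, up to `max_edges`
#' intermediate edges and `max_bp` of fill sequence. Exactly one path: its
#' overlap-trimmed sequence is the literal fill. Several paths, or none within
#' the enumeration bound but the target reachable: an N-gap of the
#' shortest-path distance in bp. Unreachable: an N-gap of `default_gap`.
#'
#' @param dg the original contracted `dbg_graph` (before repeat contraction).
#' @param e,next_e directed edge ids (scaffolded neighbours).
#' @param max_edges,max_bp path-enumeration bounds.
#' @param default_gap N-gap length used when no connecting path exists.
#' @return list with `type` (`"fill"` or `"gap"`), `sequence` (fill only),
#'   `gap_len` (gap only), `trail_overlap` (bp to trim from the start of
#'   `next_e` when joining literally), `path` (edge ids of the unique path).
#' @export
fill_gap <- function(dg, e, next_e, max_edges = 10L, max_bp = 1e6,
                     default_gap = 100L) {
  stopifnot(inherits(dg, "dbg_graph"))
  src <- dg$to[[e]]
  dst <- dg$from[[next_e]]
  paths <- list()
  ## bounded DFS over simple edge paths; the empty path covers direct adjacency
  if (src == dst) paths[[length(paths) + 1L]] <- character(0)
  dfs <- function(path, v, used_bp) {
    if (length(paths) >= 2L) return()  # only need to know if > 1
    if (length(path) >= max_edges || used_bp > max_bp) return()
    for (gph in sort_c(names(dg$from)[dg$from == v])) {
      if (gph %in% path || gph == e || gph == next_e) next
      prev <- if (length(path) == 0) e else path[length(path)]
      add <- nchar(dg$seq[[gph]]) - join_overlap(dg, prev, gph)
      np <- c(path, gph)
      if (dg$to[[gph]] == dst) paths[[length(paths) + 1L]] <<- np
      if (length(paths) >= 2L) return()
      dfs(np, dg$to[[gph]], used_bp + add)
    }
  }
  dfs(character(0), src, 0)
  if (length(paths) == 1L) {
    p <- paths[[1L]]
    fill <- ""
    prev <- e
    for (gph in p) {
      ov <- join_overlap(dg, prev, gph)
      fill <- paste0(fill, substring(dg$seq[[gph]], ov + 1L))
      prev <- gph
    }
    return(list(type = "fill", sequence = fill,
                trail_overlap = join_overlap(dg, prev, next_e), path = p))
  }
  d <- shortest_fill_distance(dg, e, next_e)
  if (is.finite(d)) {
    if (d == 0) return(list(type = "fill", sequence = "",
                            trail_overlap = join_overlap(dg, e, next_e),
                            path = character(0)))
    return(list(type = "gap", gap_len = as.integer(round(d))))
  }
  list(type = "gap", gap_len = as.integer(default_gap))
}

## Dijkstra over edges: distance = fill bp accumulated through intermediate
## edges (each trimmed by the overlap with its predecessor).
shortest_fill_distance <- function(dg, e, next_e) {
  src <- dg$to[[e]]
  dst <- dg$from[[next_e]]
  if (src == dst) return(0)
  dist <- setNames(rep(Inf, length(dg$edges)), dg$edges)
  for (gph in names(dg$from)[dg$from == src]) {
    if (gph == next_e) next
    dist[[gph]] <- nchar(dg$seq[[gph]]) - join_overlap(dg, e, gph)
  }
  done <- setNames(rep(FALSE, length(dg$edges)), dg$edges)
  best <- Inf
  repeat {
    cand <- dist[!done]
    if (length(cand) == 0 || min(cand) == Inf) break
    u <- names(cand)[which.min(cand)]
    done[[u]] <- TRUE
    if (dg$to[[u]] == dst) best <- min(best, dist[[u]])
    if (dist[[u]] >= best) next
    for (w in names(dg$from)[dg$from == dg$to[[u]]]) {
      if (w == next_e) next
      nd <- dist[[u]] + nchar(dg$seq[[w]]) - join_overlap(dg, u, w)
      if (nd < dist[[w]]) dist[[w]] <- nd
    }
  }
  best
}

#' Build scaffolds from a resolved graph
#'
#' Seeds scaffolds from the maximal non-branching chains of the post-split
#' contracted graph (one strand representative per chain) and joins
#' consecutive edges with [fill_gap()] look-ups in the original graph. The
#' original graph is never mutated.
#'
#' @param split_cg the contracted graph after [split_resolved()].
#' @param dg the original contracted `dbg_graph` (repeat edges intact).
#' @param max_edges,max_bp,default_gap passed to [fill_gap()].
#' @return list of scaffolds; each scaffold is a list with `name`, `sequence`,
#'   `edges`, and `parts` (per-junction fill/gap descriptors).
#' @export
build_scaffolds <- function(split_cg, dg, max_edges = 10L, max_bp = 1e6,
                            default_gap = 100L) {
  chains <- nonbranching_chains(split_cg)
  ord <- order(vapply(chains, `[`, character(1), 1L), method = "radix")
  chains <- chains[ord]
  scaffolds <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    seq <- split_cg$seq[[ch[1L]]]
    parts <- list()
    if (length(ch) > 1) {
      for (j in 2L:length(ch)) {
        fg <- fill_gap(dg, ch[j - 1L], ch[j], max_edges = max_edges,
                       max_bp = max_bp, default_gap = default_gap)
        parts[[j - 1L]] <- fg
        if (fg$type == "fill") {
          seq <- paste0(seq, fg$sequence,
                        substring(split_cg$seq[[ch[j]]], fg$trail_overlap + 1L))
        } else {
          seq <- paste0(seq, strrep("N", fg$gap_len), split_cg$seq[[ch[j]]])
        }
      }
    }
    scaffolds[[i]] <- list(name = sprintf("scaffold_%d", i), sequence = seq,
                           edges = ch, parts = parts)
  }
  scaffolds
}

#' Export a DBG-like graph as a GFA graph
#'
#' One segment per reverse-complement edge pair; one link per (in-edge,
#' out-edge) adjacency at each vertex, carrying the join overlap. Parsing the
#' output and contracting its link edges reconstructs the graph's adjacency.
#'
#' @param g a contracted `dbg_graph`.
#' @return a [gfa_graph].
#' @export
gfa_from_dbg <- function(g) {
  reps <- representative_edges(g)
  base <- function(id) substr(id, 1L, nchar(id) - 1L)
  sign_of <- function(id) substr(id, nchar(id), nchar(id))
  segs <- data.frame(name = vapply(reps, base, character(1)),
                     sequence = unname(g$seq[reps]),
                     stringsAsFactors = FALSE)
  lf <- character(0); lfo <- character(0); lt <- character(0)
  lto <- character(0); lov <- integer(0)
  for (v in vertex_ids(g)) {
    for (e in in_edges(g, v)) for (f in out_edges(g, v)) {
      lf <- c(lf, base(e)); lfo <- c(lfo, sign_of(e))
      lt <- c(lt, base(f)); lto <- c(lto, sign_of(f))
      lov <- c(lov, join_overlap(g, e, f))
    }
  }
  gfa_graph(segments = segs,
            links = data.frame(from = lf, from_orient = lfo, to = lt,
                               to_orient = lto, overlap = lov,
                               stringsAsFactors = FALSE))
}

#' Write scaffolds as FASTA
#'
#' @param scaffolds list from [build_scaffolds()].
#' @param path output FASTA path (60-column wrapped).
#' @return the path, invisibly.
#' @export
write_scaffolds <- function(scaffolds, path) {
  seqs <- setNames(vapply(scaffolds, `[[`, character(1), "sequence"),
                   vapply(scaffolds, `[[`, character(1), "name"))
  write_fasta(seqs, path)
}
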