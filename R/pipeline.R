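## End-to-end pipeline: graph load -> DBG-like transform -> read prep ->
## barcode mapping -> repeat resolution -> simplification / scaffolding.

#' Run the repeat-resolution pipeline
#'
#' Loads an assembly graph, transforms it into the contracted DBG-like graph,
#' maps barcoded read pairs via unique k-mers, resolves branching vertices by
#' barcode-set overlaps, and emits either a simplified graph (`"lja"` flavour:
#' vertices are split and non-branching paths condensed) or FASTA scaffolds
#' with literal-path / N-gap fills while leaving the input graph untouched
#' (`"metaflye-like"` flavour). Outputs land in `out_dir` under fixed names:
#' `graph.simplified.gfa`, `scaffolds.fasta`, `resolution.tsv`, `run.log`.
#'
#' @param gfa path to a GFA file or a [gfa_graph] object.
#' @param reads1,reads2 paired FASTQ paths (alternative to `pairs`).
#' @param pairs data.frame `read1`/`read2`/`barcode` (alternative to FASTQ).
#' @param out_dir output directory (created if missing); NULL disables file
#'   output.
#' @param mode `"diploid"` or `"metagenomic"` mapping/resolution mode.
#' @param flavor `"lja"` (split + condense, homopolymer-compressed input) or
#'   `"metaflye-like"` (scaffold-only output).
#' @param k unique k-mer size (default 31).
#' @param abs_thr,rel_thr resolver thresholds (defaults 2 and 2).
#' @param uncovered_def see [resolver_params()].
#' @param repeats repeat labels: path to a text file of segment names, or a
#'   character vector of segment names, or NULL.
#' @param hpc_reads apply homopolymer + dimer compression to reads; default
#'   TRUE for `"lja"` flavour, FALSE otherwise.
#' @param dimer_min_len dimer-run truncation threshold (bp).
#' @param barcode_source see [read_linked_fastq()].
#' @param max_fill_edges,default_gap scaffolding parameters, see [fill_gap()].
#' @param verbose log progress messages.
#' @return (invisibly) list with `dg` (contracted graph of the input), `cg`
#'   (after repeat contraction), `index`, `barcodes`, `report`,
#'   `split` (graph + events), and `simplified` graph or `scaffolds`.
#' @export
run_pipeline <- function(gfa, reads1 = NULL, reads2 = NULL, pairs = NULL,
                         out_dir = NULL,
                         mode = c("diploid", "metagenomic"),
                         flavor = c("lja", "metaflye-like"),
                         k = 31L, abs_thr = 2L, rel_thr = 2,
                         uncovered_def = "pairwise",
                         repeats = NULL, hpc_reads = NULL,
                         dimer_min_len = 16L,
                         barcode_source = "BX-tag",
                         max_fill_edges = 10L, default_gap = 100L,
                         verbose = TRUE) {
  mode <- match.arg(mode)
  flavor <- match.arg(flavor)
  if (is.null(hpc_reads)) hpc_reads <- flavor == "lja"
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }

  g <- if (inherits(gfa, "gfa_graph")) gfa else parse_gfa(gfa)
  say("[graph] ", nrow(g$segments), " segments, ", nrow(g$links), " links")
  dg <- contract_link_edges(build_raw_dbg(g))
  cg <- dg
  if (!is.null(repeats)) {
    seg_names <- if (length(repeats) == 1 && file.exists(repeats)) {
      nm <- trimws(readLines(repeats, warn = FALSE)); nm[nzchar(nm)]
    } else as.character(repeats)
    ids <- c(paste0(seg_names, "+"), paste0(seg_names, "-"))
    ids <- ids[ids %in% cg$edges]
    cg <- contract_repeat_edges(cg, ids)
    say("[graph] contracted ", length(ids), " repeat edge(s)")
  }
  say("[graph] contracted graph: ", length(cg$edges), " directed edges, ",
      length(branching_vertices(cg)), " branching vertices")

  if (is.null(pairs)) {
    if (is.null(reads1) || is.null(reads2))
      stop("provide either `pairs` or both `reads1` and `reads2`")
    pairs <- read_linked_fastq(reads1, reads2, barcode_source = barcode_source)
  }
  if (hpc_reads) {
    pairs$read1 <- compress_reads(pairs$read1, dimer_min_len)
    pairs$read2 <- compress_reads(pairs$read2, dimer_min_len)
    say("[reads] homopolymer + dimer compression applied")
  }
  say("[reads] ", nrow(pairs), " pairs, ",
      length(unique(pairs$barcode)), " barcodes")

  idx <- build_unique_kmer_index(cg, k = k)
  say("[index] k = ", k, ": ", length(idx$kmers), " unique k-mers")
  sets <- collect_edge_barcodes(pairs, cg, idx, mode = mode)
  say("[map] ", sets$stats[["mapped"]], "/", sets$stats[["pairs"]],
      " pairs mapped (", sets$stats[["multi_edge"]], " to multiple edges)")

  params <- resolver_params(abs_thr = abs_thr, rel_thr = rel_thr,
                            uncovered_def = uncovered_def)
  report <- classify_graph(cg, sets, params = params, mode = mode)
  for (s in names(report$counts))
    say("[resolve] ", s, ": ", report$counts[[s]])

  sp <- split_resolved(cg, report)
  say("[split] ", nrow(sp$events), " vertex split event(s)")

  result <- list(dg = dg, cg = cg, index = idx, barcodes = sets,
                 report = report, split = sp, mode = mode, flavor = flavor,
                 params = params)
  if (flavor == "lja") {
    simplified <- condense_paths(sp$graph)
    say("[condense] ", length(simplified$edges), " directed edges after ",
        "condensation (from ", length(cg$edges), ")")
    result$simplified <- simplified
  } else {
    scaffolds <- build_scaffolds(sp$graph, dg, max_edges = max_fill_edges,
                                 default_gap = default_gap)
    say("[scaffold] ", length(scaffolds), " scaffold(s), N50 ",
        n50(vapply(scaffolds, function(s) nchar(s$sequence), numeric(1))))
    result$scaffolds <- scaffolds
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    resolution_table(report, file.path(out_dir, "resolution.tsv"))
    if (flavor == "lja") {
      write_gfa(gfa_from_dbg(result$simplified),
                file.path(out_dir, "graph.simplified.gfa"))
      reps <- representative_edges(result$simplified)
      write_fasta(setNames(unname(result$simplified$seq[reps]),
                           sub(".$", "", reps)),
                  file.path(out_dir, "scaffolds.fasta"))
    } else {
      write_scaffolds(result$scaffolds, file.path(out_dir, "scaffolds.fasta"))
    }
    if (nrow(sp$events) > 0)
      utils::write.table(sp$events, file.path(out_dir, "split_events.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(result)
}

#' Evaluate resolved links against truth haplotype labels
#'
#' Mirrors trio-binning-style validation on simulated truth: a resolved link
#' is `correct` when both edges carry the same haplotype label, `incorrect`
#' when the labels are the two different haplotypes, and `unbinned` when
#' either edge is homozygous/unlabelled. A vertex is `correct` if all its
#' links are correct or unbinned (with at least one correct), `unbinned` if
#' all links are unbinned, `incorrect` otherwise.
#'
#' @param report a `resolution_report`.
#' @param cg the contracted `dbg_graph` the report refers to.
#' @param edge_haplotype named character vector, segment name ->
#'   `"hap1"`/`"hap2"`/`"homozygous"` (as from [build_bubble_graph()]).
#' @return list with `links` (data.frame: vertex, in_edge, out_edge, class)
#'   and `vertex_counts` / `link_counts` (named integer vectors).
#' @export
evaluate_links <- function(report, cg, edge_haplotype) {
  stopifnot(inherits(report, "resolution_report"))
  lab_of <- function(e) {
    seg <- cg$segment[[e]]
    if (seg %in% names(edge_haplotype)) edge_haplotype[[seg]] else "unlabelled"
  }
  rows <- list()
  vclass <- character(0)
  for (r in report$resolutions) {
    if (nrow(r$matching) == 0) next
    cls <- character(nrow(r$matching))
    for (i in seq_len(nrow(r$matching))) {
      l1 <- lab_of(r$matching$in_edge[i])
      l2 <- lab_of(r$matching$out_edge[i])
      cls[i] <- if (l1 %in% c("hap1", "hap2") && l2 %in% c("hap1", "hap2")) {
        if (l1 == l2) "correct" else "incorrect"
      } else "unbinned"
    }
    rows[[r$vertex_id]] <- data.frame(
      vertex = r$vertex_id, in_edge = r$matching$in_edge,
      out_edge = r$matching$out_edge, class = cls, stringsAsFactors = FALSE)
    vclass[r$vertex_id] <- if (any(cls == "incorrect")) "incorrect"
      else if (all(cls == "unbinned")) "unbinned" else "correct"
  }
  links <- if (length(rows) > 0) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(vertex = character(0), in_edge = character(0),
                    out_edge = character(0), class = character(0),
                    stringsAsFactors = FALSE)
  lv <- c("correct", "incorrect", "unbinned")
  list(links = links,
       link_counts = setNames(as.integer(table(factor(links$class, lv))), lv),
       vertex_counts = setNames(as.integer(table(factor(vclass, lv))), lv))
}
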