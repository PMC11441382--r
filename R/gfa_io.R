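## GFA 1.x input/output.
##
## Only S (segment) and L (link) records take part in downstream analysis.
## Overlaps must be '*' (treated as 0 bp) or a single-match CIGAR "<n>M";
## assembler GFAs (LJA, metaFlye, Verkko) use match-only overlaps.

#' Construct an assembly graph object
#'
#' A `gfa_graph` holds GFA segments (name, sequence, optional raw tags) and
#' links (oriented segment pairs with a match-overlap length in bp). Links are
#' canonicalised: a record and its reverse-complement mirror describe the same
#' link, and duplicates are removed.
#'
#' @param segments data.frame with columns `name`, `sequence`.
#' @param links data.frame with columns `from`, `from_orient`, `to`,
#'   `to_orient`, `overlap` (integer bp).
#' @param tags named list of character vectors of raw GFA tag strings,
#'   keyed by segment name.
#' @return an object of class `gfa_graph`.
#' @export
gfa_graph <- function(segments = data.frame(name = character(0),
                                            sequence = character(0),
                                            stringsAsFactors = FALSE),
                      links = data.frame(from = character(0),
                                         from_orient = character(0),
                                         to = character(0),
                                         to_orient = character(0),
                                         overlap = integer(0),
                                         stringsAsFactors = FALSE),
                      tags = list()) {
  segments$name <- as.character(segments$name)
  segments$sequence <- toupper(as.character(segments$sequence))
  if (anyDuplicated(segments$name))
    stop("duplicate segment names: ",
         paste(unique(segments$name[duplicated(segments$name)]), collapse = ", "))
  if (any(segments$name == "")) stop("empty segment name")
  links <- canonicalize_links(links)
  missing_ref <- setdiff(c(links$from, links$to), segments$name)
  if (length(missing_ref) > 0)
    stop("link references missing segment(s): ",
         paste(missing_ref, collapse = ", "))
  seg_len <- setNames(nchar(segments$sequence), segments$name)
  bad <- links$overlap > pmin(seg_len[links$from], seg_len[links$to])
  if (any(bad))
    stop("link overlap exceeds segment length at link ",
         which(bad)[1L])
  structure(list(segments = segments, links = links, tags = tags),
            class = "gfa_graph")
}

## Canonical representative of each link: a link (f,fo,t,to) and its mirror
## (t,flip(to),f,flip(fo)) are the same adjacency; keep the lexicographically
## smaller record and drop duplicates.
canonicalize_links <- function(links) {
  if (nrow(links) == 0) {
    links$overlap <- as.integer(links$overlap)
    return(links)
  }
  links$from <- as.character(links$from)
  links$to <- as.character(links$to)
  links$from_orient <- as.character(links$from_orient)
  links$to_orient <- as.character(links$to_orient)
  links$overlap <- as.integer(links$overlap)
  if (!all(links$from_orient %in% c("+", "-")) ||
      !all(links$to_orient %in% c("+", "-")))
    stop("link orientation must be '+' or '-'")
  flip <- function(o) ifelse(o == "+", "-", "+")
  fwd <- paste(links$from, links$from_orient, links$to, links$to_orient)
  mir <- paste(links$to, flip(links$to_orient), links$from, flip(links$from_orient))
  use_mirror <- !le_c(fwd, mir)
  res <- links
  res$from[use_mirror] <- links$to[use_mirror]
  res$from_orient[use_mirror] <- flip(links$to_orient[use_mirror])
  res$to[use_mirror] <- links$from[use_mirror]
  res$to_orient[use_mirror] <- flip(links$from_orient[use_mirror])
  key <- paste(res$from, res$from_orient, res$to, res$to_orient)
  res <- res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$from, res$from_orient, res$to, res$to_orient,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Parse an assembly graph from a GFA 1.x file
#'
#' Reads S and L records. Link overlaps must be `*` (stored as 0 bp) or a
#' single-match CIGAR such as `55M`; any other CIGAR is rejected. Records of
#' other types (H, P, W, ...) are skipped with a message.
#'
#' @param path path to a GFA file.
#' @return a [gfa_graph] object.
#' @export
parse_gfa <- function(path) {
  if (!file.exists(path)) stop("GFA file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  seg_names <- character(0); seg_seqs <- character(0)
  tags <- list()
  lf <- character(0); lfo <- character(0); lt <- character(0)
  lto <- character(0); lov <- integer(0)
  skipped <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rec <- f[1]
    if (rec == "S") {
      if (length(f) < 3) stop("malformed S record at line ", i)
      if (f[3] == "*")
        stop("segment '", f[2], "' has no sequence (line ", i,
             "); sequences are required")
      seg_names <- c(seg_names, f[2])
      seg_seqs <- c(seg_seqs, f[3])
      if (length(f) > 3) tags[[f[2]]] <- f[-(1:3)]
    } else if (rec == "L") {
      if (length(f) < 6) stop("malformed L record at line ", i)
      ov <- parse_overlap_cigar(f[6], i)
      lf <- c(lf, f[2]); lfo <- c(lfo, f[3])
      lt <- c(lt, f[4]); lto <- c(lto, f[5]); lov <- c(lov, ov)
    } else {
      skipped <- c(skipped, rec)
    }
  }
  if (length(skipped) > 0) {
    tab <- table(skipped)
    message("parse_gfa: skipped record types: ",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "))
  }
  gfa_graph(
    segments = data.frame(name = seg_names, sequence = seg_seqs,
                          stringsAsFactors = FALSE),
    links = data.frame(from = lf, from_orient = lfo, to = lt,
                       to_orient = lto, overlap = lov,
                       stringsAsFactors = FALSE),
    tags = tags)
}

parse_overlap_cigar <- function(cigar, line = NA) {
  if (cigar == "*") return(0L)
  m <- regmatches(cigar, regexec("^([0-9]+)M$", cigar))[[1]]
  if (length(m) == 0)
    stop("unsupported overlap CIGAR '", cigar, "'",
         if (!is.na(line)) paste0(" at line ", line),
         "; only '*' and '<n>M' are supported")
  as.integer(m[2])
}

#' Write an assembly graph to a GFA 1.x file
#'
#' Emits a header, then S records sorted by segment name, then canonicalised L
#' records in sorted order, so two writes of the same graph are byte-identical.
#'
#' @param graph a [gfa_graph].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "gfa_graph"))
  segs <- graph$segments[order(graph$segments$name, method = "radix"), ,
                         drop = FALSE]
  out <- "H\tVN:Z:1.0"
  if (nrow(segs) > 0) {
    tagstr <- vapply(segs$name, function(nm) {
      tg <- graph$tags[[nm]]
      if (is.null(tg) || length(tg) == 0) "" else paste0("\t", paste(tg, collapse = "\t"))
    }, character(1))
    out <- c(out, paste0("S\t", segs$name, "\t", segs$sequence, tagstr))
  }
  lk <- graph$links
  if (nrow(lk) > 0) {
    out <- c(out, paste0("L\t", lk$from, "\t", lk$from_orient, "\t",
                         lk$to, "\t", lk$to_orient, "\t", lk$overlap, "M"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con = con, sep = "\n")
  invisible(path)
}

#' @export
print.gfa_graph <- function(x, ...) {
  cat("gfa_graph:", nrow(x$segments), "segments,", nrow(x$links), "links\n")
  cat("  total sequence:", sum(nchar(x$segments$sequence)), "bp\n")
  invisible(x)
}
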