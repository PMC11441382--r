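---
title: "Resolving assembly-graph repeats with barcoded linked-reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving assembly-graph repeats with barcoded linked-reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrresolve)
```

## The problem

Long-read assemblers leave repeats longer than the read length unresolved. In
an assembly graph these repeats appear as *branching vertices*: vertices with
at least two in-edges and at least two out-edges, where the assembler could
not decide which in-edge continues into which out-edge. In a diploid genome
the commonest case is a long homozygous segment flanked by heterozygous
sequence: both haplotypes enter and leave the shared repeat, and the assembly
remains unphased across it.

Barcoded linked-reads (TELL-Seq-style libraries) offer long-range evidence at
short-read cost: long DNA fragments (tens of kb) are partitioned into
barcoded containers and sequenced as short read pairs, so all reads carrying
one barcode derive from the same long fragment. A fragment that spans a
repeat deposits reads — and hence its barcode — on the flanking sequence of
*one* haplotype on both sides. Edges that follow each other in the genome
therefore share many barcodes; edges from different haplotypes share few.
`lrresolve` turns that signal into explicit repeat resolution, graph
simplification and scaffolds.

## Graph model

An arbitrary GFA 1.x assembly graph is first transformed into a
*DBG-like* representation on which the method operates:

1. **Strand doubling.** Every segment becomes two directed edges, the
   forward sequence and its reverse complement. Reverse complementation is a
   fixed-point-free involution: even a palindromic sequence yields two
   distinct edge objects.
2. **Raw graph.** Each directed edge receives private endpoint vertices.
   Every GFA link $(e_1, e_2)$ (orientation-resolved) contributes a *link
   edge* $end(e_1) \to start(e_2)$ together with its mirror
   $end(rc(e_2)) \to start(rc(e_1))$.
3. **Contraction.** All link edges are contracted (endpoints merged, the loop
   discarded), computed as connected components of the link-edge subgraph.
   Segments are now edges; clusters of former links are vertices. Each vertex
   retains the links contracted into it, including their overlap lengths.
4. **Repeat contraction (optional).** For producers that label repetitive
   segments (metaFlye-style), the labelled edges are contracted too, so each
   resulting vertex stands for one unresolved — possibly inexact — repeat.
   The label set must be closed under reverse complement; closure is applied
   automatically when labels are given as segment names.

Every transformation preserves *skew symmetry*: whenever edge $e$ ends where
$f$ starts, $rc(f)$ ends where $rc(e)$ starts. `check_skew_symmetry()`
verifies this and is exercised after every stage in the test suite.

Link overlap lengths are carried along but play no role in resolution; they
are used only when sequences are joined (condensation and scaffold fills).
When a contracted vertex holds links with conflicting overlap values, each
join uses its own original link's overlap; a pair made adjacent by
contraction without a direct link falls back to the single shared overlap at
the vertex, or 0 with a warning.

## Read preparation

Homopolymer-compressed assemblies (LJA-style graphs) require reads in the
same coordinate space. `compress_homopolymers()` collapses each run of equal
bases to one base; `compress_dimers()` truncates each maximal alternating
two-base run of at least `min_len` bp (default 16) to its first `min_len`
characters. The truncation form of the dimer rule is this package's choice —
the upstream convention is threshold-16 but the exact normal form is not
published; `min_len` is exposed as a knob. 'N' takes part in runs like any
other symbol. Compression is applied to reads only (never to the graph) and
is on by default in `"lja"` flavour, off in `"metaflye-like"` flavour.

## Mapping by unique k-mers

Reads are aligned to edges only through *unique* k-mers (default
$k = 31$). The index collects all k-mers of one strand representative per
reverse-complement edge pair, identifies each k-mer with its reverse
complement (canonical form = lexicographic minimum, byte order), and keeps
exactly those canonical k-mers whose total count is 1. Uniqueness over one
representative per pair is the only self-consistent reading: counted over
both strands, every k-mer would occur at least twice. K-mers containing 'N'
are never indexed.

A read pair maps to an edge under one of two rules:

* **metagenomic mode** — both mates must contain a unique k-mer of the edge;
* **diploid mode** — one unique k-mer anywhere in the pair suffices, because
  in a phased diploid graph most k-mers are shared between haplotypes and
  per-mate evidence is too sparse.

Diploid-mode hits therefore always contain the metagenomic-mode hits — a
property test in the suite. A pair may map to several edges; it contributes
its barcode to each. For every edge the barcode set $barcodes(e)$ is the
union over mapped pairs, stored once per edge pair so that
$barcodes(e) = barcodes(rc(e))$ holds by construction.

## Repeat resolution

For an in-edge $e$ of a branching vertex $v$ and out-edge $e'$, let
$overlap(e, e') = |barcodes(e) \cap barcodes(e')|$. With $overlap_1(e)$ the
largest and $overlap_2(e)$ the second largest value over all out-edges of
$v$, the best out-edge $e^{*}$ becomes the *candidate link* of $e$ iff

$$ overlap_1(e) \ge \texttt{abs\_thr} \quad\text{and}\quad
   overlap_1(e) \ge \texttt{rel\_thr} \cdot overlap_2(e), $$

with `abs_thr = 2` shared barcodes and `rel_thr = 2` by default. A tie for
the maximum cannot pass the relative test when `rel_thr > 1`; with
`rel_thr = 1` the smallest out-edge id (byte order) is selected, keeping
results deterministic.

The vertex is then classified:

* **uncovered** — no in/out pair shares `abs_thr` barcodes (no usable
  coverage at all);
* **completely resolved** — the candidate links form a perfect matching
  between in- and out-edges;
* **partially resolved** — they form a non-empty matching;
* **ambiguous** — otherwise: either two in-edges claimed the same out-edge
  (all links are discarded rather than greedily pruned — resolution is
  defined only when the candidates *are* a matching), or coverage exists but
  no candidate survived the thresholds.

Two non-equivalent definitions of "uncovered" circulate: the pairwise
shared-barcode form above and a per-edge form (every incident edge has fewer
than `abs_thr` barcodes). The pairwise form is the default because it is what
the overlap-based selection actually measures; the per-edge form is available
via `resolver_params(uncovered_def = "edge-size")`.

In diploid mode, a vertex with equal in- and out-degree $n$ whose matching
covers exactly $n-1$ pairs has its last link forced *by elimination*: with
one in-edge and one out-edge left, the continuation is determined. The vertex
stays labelled partially resolved in reports — only one haplotype was
recovered from barcodes — but the completed matching is used for splitting.

**Strand symmetry of resolutions.** Candidate links are computed on the
in-edge side of one strand representative per vertex pair, and the mirror
vertex inherits the mirrored matching. Recomputing the mirror independently
can genuinely disagree: for the overlap matrix
$\left(\begin{smallmatrix}5&0\\4&4\end{smallmatrix}\right)$ the forward
vertex selects only $(i_1, o_1)$ while the mirror's in-edge-side selection
finds only the image of $(i_2, o_2)$. Imposing the mirror keeps the report
consistent and the split graph skew-symmetric.

## Simplification and scaffolding

For every completely or partially resolved vertex, each matched link
$(e, next(e))$ is rerouted through a fresh vertex with $e$ as its only
in-edge and $next(e)$ as its only out-edge; the mirror vertex is split
identically. Unmatched edges stay on the residual vertex, which disappears
exactly when the matching was perfect. Splitting never creates or removes
sequence edges.

* **`"lja"` flavour** — after splitting, maximal non-branching paths are
  condensed into single edges (overlap-trimmed concatenation; loops and
  hairpins, where the out-edge is the in-edge or its reverse complement, are
  never condensed through). The simplified graph is written as GFA plus a
  FASTA of its edges.
* **`"metaflye-like"` flavour** — the input graph is never mutated. The
  non-branching chains of the post-split contracted graph seed scaffolds;
  for each consecutive pair the original graph (repeat edges intact) is
  searched for connecting paths. Exactly one simple path within the bounds
  (`max_fill_edges = 10` intermediate edges, 1 Mb of fill): its
  overlap-trimmed sequence is inserted literally. Several paths, or none
  within the bound but a finite shortest-path distance: an N-gap of that
  distance in bp (Dijkstra over trimmed intermediate-edge lengths; a
  0-length gap becomes a direct join). Unreachable: an N-gap of
  `default_gap = 100` bp. The enumeration bound exists because simple-path
  enumeration is exponential; the distance-based fallback keeps gap sizes
  honest where enumeration gives out.

One strand representative is emitted per reverse-complement pair, with
deterministic `scaffold_<n>` naming; all ordering that reaches an output file
uses byte order, so identical inputs give byte-identical outputs regardless
of locale.

## The synthetic study design

The generator (`sim_config()`, `simulate_diploid()`, `build_bubble_graph()`,
`simulate_linked_reads()`) emulates the situation the resolver exists for: a
diploid genome as alternating homozygous and heterozygous blocks. Defaults —
chosen once as the package's study conditions — are 41 blocks (20
heterozygous bubbles flanked by homozygous repeats), 10 kb per block, 2%
haplotype divergence in bubbles, fragments with exponential lengths of mean
30 kb clamped to [1 kb, 150 kb], 20 read pairs of 2 × 150 bp per fragment,
one fresh barcode per fragment, and error-free reads. Fragment coverage is
25 fragments per position per haplotype, set so that every junction is
bridged by at least 4 fragments per haplotype with large margin (the
expected count is ≈ 18; at materially lower coverage the realized minimum
across 38 junction/haplotype cells can dip below 4). Divergence of 2% gives
roughly 200 SNPs per bubble, ample unique 31-mers — the regime the method
assumes; heterozygosity far below $1/k$ would starve the index.

The graph writes one segment per homozygous block and two per bubble, with
haplotype-pure links; contracting the homozygous (repeat) edges turns every
internal junction into a 2-in/2-out branching vertex, mirroring how long
shared repeats appear as vertices in compressed de Bruijn representations. A
truth table records each fragment's haplotype and span and each junction's
true link, so tests can count phase errors exactly.

What the simulation does *not* model: sequencing errors beyond a uniform
substitution option (off by default), barcode collisions (off by default,
available via `barcode_collision_rate`), chimeric fragments, coverage bias,
and inexact repeats. Passing tests therefore demonstrate the graph-and-
barcode logic, not robustness to real library artefacts.

Problem sizes in the tests and the acceptance script (a 410 kb diploid
genome, ~14,000 read pairs; toy graphs elsewhere) were chosen so the whole
suite completes in a couple of minutes while every junction still carries
deep fragment support.

## Numerical and design choices

* Coordinates are 0-based half-open internally; k-mer index offsets are
  0-based.
* Only match-CIGAR overlaps (`*`, `<n>M`) are accepted in GFA links — the
  target producers emit nothing else; anything else is a hard error naming
  the line.
* Canonical k-mers, link canonicalisation, tie-breaks and all output
  ordering use byte (radix) order, never locale collation.
* `contract_link_edges()` is idempotent; contracting an already-contracted
  graph is the identity. Condensation is idempotent and refuses self-mirror
  chains (impossible without a hairpin, which is never condensed through).
* The downsampling property — the uncovered-vertex count is non-increasing
  under nested barcode subsets — holds exactly, not statistically: barcode
  sets only grow, so overlaps only grow.

## Known limitations

* Exact k-mer matching only: a sequencing error in every unique k-mer of a
  read leaves it unmapped; there is no mismatch tolerance.
* Whole-edge barcode sets: for edges much longer than a fragment, barcodes
  near the far end dilute the overlap signal; windowed sets near the
  relevant edge end are not implemented.
* Single resolution pass: no iterative re-resolution after simplification.
* Scaffolding quality depends on the input graph's connectivity; a graph
  with few branching vertices gives the method little to do.
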