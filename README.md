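# lrresolve

Repeat resolution, phasing and scaffolding of long-read assembly graphs using
barcoded linked-reads.

## The problem

Even accurate long reads leave repeats longer than the read length
unresolved. In an assembly graph such a repeat is a **branching vertex** — a
vertex with two or more in-edges and two or more out-edges, where the
assembler could not decide which in-edge continues into which out-edge. For
diploid genomes these vertices are exactly the places where phasing breaks:
both haplotypes run through a long shared (homozygous) segment.

Barcoded linked-read libraries (TELL-Seq-style) tag all short reads derived
from one long DNA fragment (~30 kb) with a shared barcode. A fragment
spanning a repeat leaves its barcode on the flanking sequence of *one*
haplotype on both sides, so consecutive edges of the genomic traversal share
barcodes while edges of different haplotypes do not. `lrresolve` exploits
this to resolve branching vertices, simplify the graph, and emit scaffolds.

## Method in brief

Given a GFA assembly graph and a barcoded paired-end library:

1. **Graph transform** — segments are doubled with their reverse complements
   and GFA links are contracted, giving a strand-symmetric DBG-like graph
   whose edges are segments and whose vertices are unresolved repeats
   (repeat-labelled edges can be contracted as well, for metaFlye-style
   inputs).
2. **Mapping** — reads are mapped to edges via *unique* k-mers (default
   k = 31; canonical over reverse complement, occurring exactly once in the
   edge set). For each edge `e` the barcode set `barcodes(e)` collects the
   barcodes of all mapped pairs; `barcodes(e) = barcodes(rc(e))` always. A
   diploid mode (one unique k-mer per pair suffices) and a metagenomic mode
   (both mates must match) are available.
3. **Resolution** — for an in-edge `e` of a branching vertex, with
   `overlap(e, e') = |barcodes(e) ∩ barcodes(e')|` over the out-edges, the
   best out-edge is selected iff `overlap1 ≥ abs_thr` (default 2) and
   `overlap1 ≥ rel_thr · overlap2` (default 2). Candidate links that form a
   perfect / non-empty matching make the vertex completely / partially
   resolved; vertices with no pair sharing `abs_thr` barcodes are uncovered;
   everything else is ambiguous. In diploid mode an `(n-1)`-of-`n` matching
   is completed by elimination.
4. **Simplification / scaffolding** — matched links are split into
   1-in/1-out vertices. For LJA-style graphs, non-branching paths are then
   condensed and a simplified GFA is written. For other graphs the input is
   left untouched and scaffolds are emitted, joining consecutive edges with
   the sequence of the unique connecting path in the original graph, or an
   N-gap of the shortest-path distance when the path is not unique.

A fully ground-truthed synthetic generator (diploid genome with heterozygous
bubbles separated by homozygous repeats, exponential 30 kb fragments,
2 × 150 bp pairs) makes the whole pipeline testable without external data.
See `vignettes/linked-read-repeat-resolution.Rmd` for the complete model
description and design rationale.

## Worked example

The bundled toy fixture has one branching vertex (in-edges `s1`, `s2`;
out-edges `s3`, `s4`), five barcoded read pairs and k = 3; one barcode
("YEL") consists of reads whose 3-mers all occur in several segments:

```r
library(lrresolve)
fx <- fig1_fixture()
res <- run_pipeline(fx$gfa, pairs = fx$pairs, out_dir = "out",
                    flavor = "lja", hpc_reads = FALSE, k = fx$k)
```

```
[graph] 4 segments, 4 links
[graph] contracted graph: 8 directed edges, 2 branching vertices
[reads] 5 pairs, 5 barcodes
[index] k = 3: 6 unique k-mers
[map] 4/5 pairs mapped (4 to multiple edges)
[resolve] COMPLETELY_RESOLVED: 2
[resolve] PARTIALLY_RESOLVED: 0
[resolve] UNCOVERED: 0
[resolve] AMBIGUOUS: 0
[split] 2 vertex split event(s)
[condense] 4 directed edges after condensation (from 8)
```

Four of five pairs map (the unique-k-mer-free "YEL" pair stays unmapped);
the branching vertex is completely resolved on both strands (each vertex and
its reverse-complement mirror are reported), and condensation halves the
edge count — `s1` is glued to `s3` and `s2` to `s4`:

```r
res$simplified$seq[c("c1+", "c2+")]
#>                                                    c1+
#> "ATAACCTCCGACGTACGTGCCTTTTTTCGTCACTAGTCAGGAATCATGTGTG"
#>                                                    c2+
#> "TGGCGCTATTACGTACGTATAAGTCGGTTGATTCCATAGACACATGGCGCGG"
```

`out/` now holds `graph.simplified.gfa`, `scaffolds.fasta`,
`resolution.tsv`, `split_events.tsv` and `run.log`. A thin command-line
wrapper with `resolve`, `simulate` and `evaluate` subcommands is installed
at `inst/scripts/lrresolve.R`.

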