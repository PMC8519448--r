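---
title: "Methods: variant- and haplotype-aware motif scanning on variation graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant- and haplotype-aware motif scanning on variation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Classical motif scanners (FIMO, MOODS) slide a position weight matrix
(PWM) along a single linear reference genome. Genetic variants — SNPs
and indels segregating in a population — can create, destroy or
modulate transcription-factor binding sites (TFBS), and a linear scan
is blind to every binding site that exists only on a non-reference
haplotype. vgmotif scans instead over a *variation graph*: a
sequence-labelled DAG whose nodes are DNA segments, whose reference
path spells the chromosome, and in which each variant forms a bubble
anchored by shared reference sequence. Phased genotypes are threaded
through the graph as one explicit haplotype path per sample per phase,
so every k-mer window can be annotated with the number of haplotypes
that actually carry it and with a `ref`/`non.ref` flag.

## Model and procedure

1. **PWM normalization.** A count matrix $c(b,i)$ becomes a probability
   matrix with the FIMO-style pseudocount scheme
   $p(b,i) = \frac{c(b,i) + \alpha\,bg(b)}{N_i + \alpha}$, with column
   total $N_i$, background $bg$ and pseudocount $\alpha$ (default 0.1,
   spread proportionally to the background). Probability matrices are
   treated as counts with $N_i = 1$.
2. **Log-odds PSSM.** $s(b,i) = \log_2 \frac{p(b,i)}{bg(b)}$. Base 2
   follows FIMO; reported scores are these log-odds (3 decimals).
3. **Integer scaling to [0, 1000].** Each column is shifted by its
   minimum and the matrix multiplied by
   $1000 / \sum_i (\max_b s(b,i) - \min_b s(b,i))$, then rounded.
   Rounding may push the sum of columnwise maxima one or two units past
   1000; the maxima of the columns with the largest upward rounding
   error are decremented by one until the bound holds (choosing the
   largest-error columns keeps the per-cell quantization error at about
   half a unit). Every attainable k-mer total therefore lies in
   $[0, 1000]$, which caps the dynamic-programming table at 1001 cells.
4. **Exact P-values.** The total-score distribution under an i.i.d.
   background is built by convolution over columns:
   $Q_0 = \{0 \mapsto 1\}$,
   $Q_i(x) = \sum_b bg(b)\, Q_{i-1}(x - M(b,i))$. The P-value of a hit
   is the inclusive upper tail $P(\text{total} \ge s)$. One table per
   motif is built from the forward matrix; the reverse-complement
   matrix has the same attainable range and, under the default uniform
   background, the identical distribution.
5. **Enumeration.** A window of width $k$ slides along the reference
   path and every haplotype path; a window is kept when its projected
   start lies inside the queried region (it may extend up to $k-1$
   bases past the right edge, so boundary-overlapping motifs are
   found). Windows are grouped by (spelling, projected start): the
   haplotype count is the number of distinct sample haplotype paths in
   the group, and the reference path membership becomes the
   `ref`/`non.ref` flag. Each plus-strand hit is paired with a
   minus-strand hit carrying the reverse-complement spelling at the
   same coordinates. In *recombinant* mode every directed walk through
   the windowed subgraph is additionally spelled out, bounded by a
   configurable walk cap (default $10^4$) with a hard error beyond it.
6. **Multiple testing.** Per motif, the P-values of *all* scored k-mer
   hits across all scanned regions (both strands) are pooled and
   converted to q-values with the Benjamini–Hochberg step-up
   $q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, clamped at 1. Because the
   pool is global, q-values are invariant to region order and to the
   number of worker processes; the command-line driver therefore
   computes BH only after merging per-chromosome results.

## Coordinates and projections

Internally everything is 0-based half-open; reports use 1-based
inclusive coordinates (start + 1 only). K-mers starting inside an
alternative-allele node are projected to the reference coordinate of
their bubble's left anchor end — the paper-level convention for where a
variant-carrying hit "is" is not uniquely defined for insertions, so
this left-anchor rule is applied uniformly and the reported interval
always has width $k$. Identical spellings reached through different
node walks at the same projected start (e.g. around a deletion)
collapse into a single hit so haplotype counts are per-site, not
per-walk.

## Choices made where the design was open

* **Pseudocount 0.1, uniform background** by default: the upstream
  description only says scoring is done "as in FIMO", so FIMO's
  defaults are adopted; a MEME file's background line overrides the
  default and an explicit argument overrides both.
* **Scaling is per-matrix with per-column offsets** (not per-cell to an
  independent range): this reproduces the published $[0,1000]$ range
  exactly while keeping the DP table small.
* **N handling**: an N scores the columnwise minimum (0, conservative);
  windows with more than $\lfloor k/2 \rfloor$ Ns are dropped.
* **Haplotype tally excludes the reference path** — the reference is
  reported through the separate flag column, matching the two distinct
  report columns.
* **Overlapping variant records**: first record wins, later ones are
  skipped with a warning. Missing genotypes (`./.`) fall back to the
  reference allele with a warning; unphased genotypes are an error
  because haplotype threading requires phase.
* **Strict inequality** is used for significance filters (P < 1e-4
  mirrors the published selection rule).
* **Graph persistence is GFA v1 text** instead of the xg/GBWT binary
  indexes of the vg toolchain: haplotypes are materialized as explicit
  P-lines (`sample#phase`), trading compression for transparency at
  desk scale; node projections are re-derived from bubble anchors on
  read, so write/read is the identity on the data model.
* **Site classification** groups occurrences by (chrom, start, strand):
  `non-ref-only` (gained on haplotypes), `ref-only` (reference passes,
  all variant spellings fail — disrupted), `shared-modulated` (both
  pass, scores differ), `shared-equal` (otherwise, including
  variant-free sites).

## What the synthetic data emulates — and what it does not

`make_toy_dataset()` draws a uniform-random chromosome (default 600 bp),
10 diploid samples, 8 random SNPs and 2 short indels with phased
genotypes drawn at allele frequency 0.3 — values picked once to give
variant-dense, haplotype-diverse toy graphs that still scan in
milliseconds; planted sites use a width-8 consensus motif so the
exhaustive oracle can enumerate all 4^8 scores. An "alt" planting
writes the consensus with one broken mid-motif position into the
reference plus a SNP restoring the consensus, heterozygous in one
sample — the miniature version of a binding site observable only on a
non-reference haplotype. The expected-hit manifest is computed by an
independent oracle that applies variants to the reference by plain
string edits and scores k-mers with a direct log-odds sum plus
exhaustive P-value enumeration; it shares no code with the graph,
path-scan or scaled-scoring modules.

The generator does **not** emulate linkage disequilibrium, population
structure, realistic allele-frequency spectra, GC content, repeats, or
structural variants. A green planted-site test therefore establishes
the correctness of graph construction, haplotype threading, window
enumeration, scoring and flagging — not population-genetic realism,
and not the published 1000-Genomes/ENCODE percentages, which depend on
external data and are out of scope here.

## Numerical notes and limitations

* The DP P-values are exact for the *integer-scaled* matrix; the
  quantization moves scores by at most $k/(2 \cdot scale)$ log-odds
  units, so P-values extremely close to a threshold can fall on either
  side of it compared with an unscaled computation.
* BH q-values are clamped to be at least the P-value; the analytical
  identity can be violated by one ulp in floating point.
* Degenerate inputs fail loudly: uniform (zero-range) motifs, zero
  probability cells without pseudocount, symbolic alleles, unphased
  genotypes, inverted regions and recombinant walk explosions are all
  errors, not silent repairs.
* Cyclic graphs, structural variants, gapped/dinucleotide motif models
  and fuzzy matching are out of scope; chromosomes are assumed to fit
  in memory as single strings (desk-scale, not genome-scale).
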