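---
title: "Detecting prophages by phage-gene density: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting prophages by phage-gene density: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophagescan)
```

## The model and its assumptions

A prophage is a contiguous stretch of the host chromosome whose genes are,
for the most part, of phage origin. `prophagescan` turns that observation
into a detector in three stages. First, each annotated CDS is translated and
searched against a phage protein reference database; a gene with at least one
hit at e-value strictly below the cutoff is *phage-like*. Second, phage-like
genes are counted in a sliding window along each contig, windows dense enough
in phage-like genes are selected, and overlapping selections are merged into
preliminary regions. Third, region borders are refined: contracted to the
outermost phage-like genes, then snapped to nearby tRNA genes, which are the
canonical attachment sites of temperate phage integration.

The method therefore assumes:

* the user supplies a *complete* gene annotation — the detector never calls
  ORFs itself, so partial annotations depress gene density and cause missed
  prophages;
* prophages are long enough and gene-dense enough to place at least the
  minimum number of phage-like genes inside one window — short prophage
  remnants below that density are invisible by construction;
* contigs are linear. Features or prophages spanning the origin of a
  circular chromosome are not handled; a feature whose coordinates exceed
  the contig length is rejected at parse time. A prophage split across two
  contigs of a draft assembly is found only if one fragment independently
  satisfies the density criterion.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `evalue` | 1e-5 | — | strict upper bound for flagging a gene phage-like |
| `window` | 10000 | bp | sliding-window length |
| `step` | 1000 | bp | window stride |
| `min_genes` | 8 | genes | minimum phage-like genes per selected window |
| `min_span` | 5000 | bp | strict lower bound on a selected window's length |
| `trna_flank` | 3000 | bp | search distance around each trimmed border |

The window length and gene threshold are matched to the size distribution of
sequenced phage genomes: only a small minority of phages are shorter than
10 kb, and even those carry more than 8 genes, so a genuine prophage almost
always saturates at least one window. The length bound equals half the
window and, under the default interpretation (below), only bites for the
truncated windows at a contig's end. All six values are exposed as arguments
of `predict_prophages()` / `run_predict()` and as CLI flags, so sensitivity
analyses are one loop away; the defaults are the recommended operating
point.

## Coordinate and counting conventions

Internally every interval is 0-based half-open, on every type (features,
windows, predictions, truth). GFF3's 1-based inclusive coordinates are
converted once at the parse boundary, and BED output needs no conversion at
all; this keeps all interval arithmetic in a single convention. Multi-segment
CDS sharing an id are translated as the spliced concatenation in genomic
order and counted as their interval hull; unknown feature types are retained
as `other` and ignored by the scan.

Three counting rules are deliberately strict or deliberately inclusive:

* **Gene-in-window membership** is any overlap of at least 1 bp. The
  plausible alternatives (midpoint, full containment) are strictly less
  sensitive, and any overhang they would avoid is removed later by the
  trimming stage, so the inclusive rule costs nothing in precision.
* **Thresholds**: the e-value cutoff is strict (`< 1e-5`; a hit at exactly
  1e-5 does not flag), the gene count is inclusive (`>= 8`), and the length
  bound is strict (`> 5000`). A window of exactly 5,000 bp is rejected.
* **"Length" of a window instance** is read as the window's own length,
  binding only for truncated terminal windows. The alternative reading — the
  span from first to last phage-like gene within the window must exceed
  5 kb — is available as `span_rule = "genespan"` for comparison; it is more
  conservative on sparse windows and identical on saturated ones.

Flagging is per hit row with any-row-passes semantics, which for a
gene-level yes/no decision is equivalent to filtering on the best hit.

## Border refinement details

Trimming replaces a preliminary region by the hull of the phage-like genes
overlapping it, clamped to the region, so trimming never enlarges. For the
tRNA stage, each border is given a symmetric flank (`trna_flank` on both
sides, 6 kb total per border, since integration sites can sit just inside or
just outside the merged windows); among tRNAs overlapping the flank the
*most outward* one wins — minimum start on the left border, maximum end on
the right — which maximises capture of the attL/attR-bounded region and is
deterministic. tRNA strand is ignored: integration polarity does not change
which coordinate is outward. When several refined predictions come to
overlap after extension they are merged, so the BED output is always
disjoint.

A guard exists for an adjustment that would invert an interval
(`new_start >= new_end`), falling back to the trimmed borders with a
warning. Under the outermost-tRNA rule with symmetric flanks this state is
actually unreachable — any tRNA exclusive to the left flank must end before
`right_border - flank`, below every candidate right coordinate, so the
minimum left start always stays below the maximum right end — but the guard
is kept as a cheap invariant check against future rule changes.

## The reference database

`build_phage_db()` consumes local protein FASTA files plus a
`phage_id -> family` metadata table; phages absent from the table are
excluded (the family whitelist is data, not code, because phage taxonomy
moves). Records whose product annotation contains an exclusion term —
case-insensitive substring, default `"ABC transporter"` — are dropped and
logged: ABC transporters are highly conserved in non-prophage regions of
prokaryotic and eukaryotic genomes alike and would otherwise seed
false-positive islands. Every build records its date, per-family counts and
the full exclusion log, and `write_phage_db()` materialises the report next
to the FASTA so each prediction run can carry its database provenance.
Nothing is fetched from the network; reproducibility of a run reduces to the
local files plus the manifest checksums.

## What the synthetic generator emulates — and what it does not

`sim_scenario()` / `simulate_fixtures()` produce the four inputs the
pipeline consumes (FASTA, GFF3, 12-column hit table, truth BED) with the
statistical structure the detector assumes: background genes at a stated
density (default 1 gene/kb, roughly enteric-bacterium gene spacing),
implanted islands of configurable gene count, length and spacing, optional
flanking tRNAs at stated offsets, and a hit table in which island genes draw
e-values log-uniform on $[10^{-50}, 10^{-6}]$ and background genes draw
weak hits on $[10^{-4}, 10]$. The gap in that pair of supports straddles the
1e-5 cutoff so threshold behaviour is exercised from both sides;
`background_hit_rate` moves background genes into the strong class to
emulate spurious database matches, and `decoy_inject()` adds isolated
strong-hit genes below (or, if asked, at) the per-window threshold. Gene
sequences are random codon strings with forced ATG/TAA ends so translation
is well formed. The truth interval of an island is the hull of its
phage-flagged genes, extended to a flanking tRNA's outward coordinate when
that tRNA lies within the 3 kb flank of the hull border — i.e. the truth is
defined by the same geometry the refiner targets.

The generator does **not** emulate real sequence evolution: hits are
assigned, not computed by alignment, so e-value distributions, paralogy,
domain-level partial matches and database incompleteness are all absent.
Passing the synthetic end-to-end checks therefore demonstrates that the
scanning, merging and refinement geometry is correct under the model's
assumptions; it says nothing about the adequacy of any particular reference
database on real genomes, which is where real-world sensitivity is won or
lost (prophages with no database relative are invisible to any
similarity-based detector).

## Evaluation statistic

`evaluate_predictions()` measures TP/FP/FN as base-pair lengths on the
disjoint unions of predictions and gold standard — the only reading under
which the three quantities partition prediction and gold length cleanly
(`tp+fp = |pred|`, `tp+fn = |gold|`, both asserted as invariants in the test
suite against a per-base painting oracle). Ratios with zero denominator are
reported as `NA`, never 0: an empty genome with no predictions is
uninformative, not a failure. `compare_tools()` evaluates several prediction
sets against one gold standard either pooled (one TP/FP/FN pool, the shared
denominator making tools directly comparable) or per genome (unweighted mean
of per-contig ratios, undefined contigs dropped); both modes are reported
because published benchmarks are often ambiguous about which was used.

## Degenerate inputs and determinism

Empty hit tables, empty prediction sets, contigs shorter than one window
(one truncated window), predictions on contigs absent from the gold
standard (pure FP), and pseudogenes with internal stop codons (translated
with `X`, kept, flagged or not by the search) are all defined behaviour and
tested. The window grid is anchored at coordinate 0 of each contig, ties in
tRNA choice cannot occur (outermost coordinate is unique; if two tRNAs share
it the recorded anchor is the first by position, the border coordinate being
identical either way), and the run manifest contains parameters, input
checksums and package version but no timestamps — so a rerun on identical
inputs is byte-identical in BED and manifest, which the suite asserts.

## Problem sizes

The shipped checks use genomes of 30–500 kb: 100 random-genome fixtures
(20–2,000 genes) for the window-count oracle, 100 single-island scenarios of
45 kb for end-to-end recovery, 25 scenarios for exact tRNA border recovery,
and a 1,000-record proteome for the database filter. These sizes give
per-check runtimes of seconds while leaving every code path, including
terminal-window truncation and multi-contig scanning, exercised; the
detector itself scales linearly in contig length and gene count and runs
comfortably on complete bacterial genomes.

## Known limitations

* No att-site (direct repeat) detection and no integrase anchoring; borders
  are only as good as the annotation's phage-like genes and tRNAs.
* Similarity-based flagging inherits the reference database's blind spots;
  novel phage lineages are missed.
* Circular topology is not modelled.
* The original three-step density heuristic has no probabilistic score; a
  prediction is a yes/no interval with supporting gene ids, not a
  likelihood.
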