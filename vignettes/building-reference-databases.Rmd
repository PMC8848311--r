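---
title: "Building reference databases and exploring taxonomy with taxplorer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building reference databases and exploring taxonomy with taxplorer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxplorer)
options(taxplorer.quiet = TRUE)
```

## The problem

Metabarcoding and metagenomics experiments lean on reference databases:
a FASTA of marker sequences and a mapping from each accession to a
standardized taxonomy path. Public nucleotide archives hold the raw
material, but their records carry taxonomy at wildly uneven depth, marker
information only as free-form `gene` qualifiers, and geography as a mix of
decimal coordinates and country strings. `taxplorer` turns archive records
into (i) assignment-ready databases and (ii) exploration datasets that
show, before any sequencing is done, where the data gaps are.

This vignette explains the package's model of the problem, the parameters
that matter, and the design decisions taken where more than one reasonable
behaviour exists.

## Taxonomy standardization

The taxonomy store is a rooted tree in the NCBI taxdump dialect: a nodes
table (`txid | parent txid | rank`) and a names table from which only
`scientific name` entries are indexed. `load_taxdump()` enforces three
structural invariants before anything else runs — the tree is *closed*
(every parent is a node), has exactly one self-parented root, and is
acyclic. Violations are integrity errors naming the offending txids rather
than warnings, because a broken store silently corrupts every downstream
path.

`resolve_lineage()` standardizes any node to the six main ranks (phylum,
class, order, family, genus, species). For each rank it takes the nearest
ancestor-or-self carrying that rank label, matching rank strings
case-insensitively. Two genuinely open choices:

- **Fallback for missing ranks.** Real taxonomies are ragged: viruses lack
  classes, many clades sit at `no rank`. A missing rank is filled with the
  scientific name of the nearest *named* ancestor-or-self walking rootward.
  Since every taxdump node carries a scientific name, this is the queried
  node's own name; the rule is stated in terms of named ancestors so it
  degrades sensibly if names are ever optional. The practical effect is
  that serialized paths never contain empty fields — downstream
  taxonomy-assignment tools reject blanks — and that the root resolves to
  six copies of its own name. The alternative (always substituting the
  immediate parent's name) was rejected because it reports a *coarser*
  taxon than is actually known when the queried node itself is informative.
- **Homonyms.** `name_to_txids()` returns *all* matching txids in
  ascending order, and batch conversion flags ambiguous names with every
  candidate instead of picking one. Failing loudly beats resolving
  silently to the wrong kingdom.

Batch conversion (`convert_batch()`) never aborts on a bad row: unresolved
or ambiguous inputs become flagged rows in input order, so a 10,000-row
file with one typo still converts the other 9,999.

## Retrieval

Queries render deterministically from a `query_spec`: numeric organism
terms as `txidN[ORGN]`, names as `name[ORGN]`, gene terms as `g[gene]`,
joined by `AND`. Result sets are fetched in contiguous windows of at most
2,500 records — the windowing threshold the upstream endpoint tolerates
comfortably — each window to its own temporary file, merged in window
order at the end. Three behaviours are deliberate:

- **Batch invariance.** The merged file is byte-identical for any window
  size, which makes the window size a pure performance knob. This requires
  a fixed record order (the id order returned by search) and first-wins
  deduplication of accessions across pages.
- **Resume.** Temporaries are kept on failure and skipped on rerun, so a
  crash in window 37 of 40 costs one window, not forty. Each window is
  retried 3 times with exponential backoff before the run fails, naming
  the window.
- **Rate ceiling.** The live transport throttles through a token-bucket
  limiter (defaults 3 requests/s, 10 with an API key — published endpoint
  etiquette). The limiter takes an injectable clock and sleeper, so the
  ceiling is asserted in tests with a fake clock instead of wall-clock
  waits. All tests and the acceptance script use the fixture transport;
  the live transport shares every code path above it.

## Record parsing and geography

The GenBank-dialect parser extracts exactly what the pipeline consumes:
versioned accession, definition, organism, the source feature's
`taxon:` db_xref, the sequence, every feature's `gene` qualifier (not just
`gene` features — markers are routinely annotated on CDS and rRNA
features), and the `country` / `lat_lon` source qualifiers. Gene names are
deduplicated per record preserving first-appearance order.

`extract_geo()` is total: coordinates win when the `lat_lon` qualifier
parses (`"60.39 N 5.32 E"` dialect, N/E positive, S/W negative, range
checked), otherwise the country string's text before the first `:`
(region detail stripped), otherwise kind `none`. An unparseable `lat_lon`
logs a warning and falls through to the country rather than discarding the
record. No gazetteer lookup is attempted — country strings are taken as
written.

## Database outputs

The FASTA writer wraps at 70 columns with `>accession definition` headers
and deduplicates accessions first-wins. The taxonomy TSV is the
two-column `accession<TAB>six-rank-path` dialect assignment platforms
accept. Records whose txid is missing from the store fall back to an
organism-name lookup; records resolvable by neither route are *counted and
reported but not written*, keeping the mapping blank-free
(`written + unresolved` always equals the input size).

Gene frequencies count **records per gene, distinct per record,
case-insensitively** (reported under the first-seen spelling): a record
tagged `COI` twice is one COI record, and `CoI`/`COI`/`coi` merge. This
matches how marker surveys are quoted — accessions per gene. Ordering is
count descending with lexicographic tie-breaks, a total order, so outputs
are byte-stable and the top-10 cut in the bar plot is deterministic at
ties.

## Exploration datasets

- **Scatter**: per rank, counts per (taxon, parent) pair — same-named taxa
  under different parents stay separate — so each rank's counts sum to the
  corpus size.
- **Sunburst**: the six-level hierarchy with node ids equal to the full
  path prefix (disambiguating homonyms); every internal count equals the
  sum of its children.
- **World map**: coordinate points aggregated by position rounded to 4
  decimal places (~11 m — merges trivially different encodings of one
  site without merging distinct sites), country points by name; marker
  metadata records the green-cross / red-circle convention.

The frequency filter is applied at the **species level** and removals
propagate upward: "units below the threshold" most naturally means
terminal units, and a per-displayed-rank filter can be layered on later
without changing the contract. Threshold 0 is the identity and writes
nothing; any positive threshold writes the excluded units to
`filtered_out_min{threshold}.tsv` next to the plot output, so the file
name itself documents the cut that produced it.

HTML export embeds the dataset as a JSON `<script>` block and renders it
with a small inline script, so the file is self-contained, opens offline,
and the counts are machine-recoverable (`read_plot_html()`), which is also
how the export round-trip is tested. The renderer is intentionally
lightweight; the data contract, not the drawing engine, is the interface.

## The fixture generators

`make_taxonomy()` grows a ranked tree (root → phyla → … → species),
then extends every leaf to species depth, so with `rank_missing_prob = 0`
every leaf has a complete six-rank chain; positive probabilities blank
rank labels to `no rank`, exercising the fallback. `make_records()` emits
GenBank-dialect corpora whose gene tags follow either exact per-gene
counts or sampling weights, with a geography profile giving the fractions
of coordinate / country / bare records, and returns a manifest whose
marginals are recomputable from the emitted file by brute force — that
recount is a standing test. Sequences are random nucleotides of
200–1,500 bp: no tested operation depends on sequence content.
`mirror_fixture()` pins the published facts used as references — txids
8049, 8043, 7742, 2697049, the cod lineage placements, and the cod marker
survey (CYTB 985, COI 455, ND2 311 tagged records) — and leaves
everything else synthetic.

What the generators do *not* emulate: real accession semantics, synonym
name classes, multi-partition features, protein records, or the scale of
live archives (hundreds of thousands of records per query). Passing tests
show the machinery is correct on faithful miniatures, not that a live
snapshot will reproduce any historical count — those numbers move with
the archive.

## Problem sizes and numerical choices

The test suite and acceptance script run on one CPU in well under a
minute using: 100 random trees of ≤200 nodes for the lineage oracle; a
1,800-record reference corpus for the gene survey; 1,000 paths for
filter/aggregation properties; 1,000 coordinate strings for the geography
round-trip (tolerance 1e-9, against values rounded to 4 decimals);
window sizes 1 / 3 / 2,500 for batch invariance. Output files are written
with `\n` endings unconditionally, which is what makes byte-identity
assertions meaningful across platforms.

## Limitations

- Only the nucleotide database dialect is handled; no history-server
  (WebEnv) optimization and no parallel window fetching.
- Name resolution covers `scientific name` entries only — no synonyms,
  no fuzzy matching.
- The taxonomy store refreshes by explicit rebuild
  (`taxplorer build-store`), never by background download.
- Country normalization is colon-stripping and trimming; two spellings of
  one country stay two map points.
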