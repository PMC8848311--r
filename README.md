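# taxplorer

Designing a metabarcoding or metagenomics study starts with a question about
*data availability*: which sequences exist for a taxon, which marker genes
they cover, and where the samples came from. Answering it means querying a
nucleotide archive, standardizing the taxonomy of hundreds of thousands of
records, and turning the result into files that taxonomy-assignment
platforms (QIIME2-style reference FASTA + taxonomy mappings) and exploratory
plots can consume.

`taxplorer` is an R package (plus a thin command-line tool) that does this
end to end, fully offline-testable:

- **Retrieval** — builds e-utilities query strings (`txid8049[ORGN]`,
  `txid7742[ORGN] AND ACE2[gene]`), plans windowed downloads (2,500 records
  per request), fetches each window to a temporary file through a pluggable
  *transport*, and merges the windows into one GenBank-dialect flat file.
  A fixture transport replays a local corpus so the whole pipeline runs
  without network access; the live transport adds retries and a token-bucket
  rate ceiling.
- **Taxonomy standardization** — loads an NCBI taxdump-dialect store
  (`nodes.dmp` / `names.dmp`) and resolves any txid or scientific name to
  the six main ranks `phylum;class;order;family;genus;species`. A rank
  absent from a record's ancestor chain is filled with the nearest named
  ancestor-or-self, so paths never contain blanks — the ancestor (parent
  txid) substitution used for poorly described organisms.
- **Database building** — multi-FASTA (70-column wrap, `>accession
  definition` headers), the two-column `accession<TAB>path` taxonomy TSV,
  gene-frequency tables (per-record distinct, case-insensitive counting)
  and a top-10 gene bar plot (PNG).
- **Exploration** — per-rank scatter series, sunburst hierarchies (counts
  additive over the taxonomy), and world maps that split georeferenced
  records into coordinate points (`lat_lon` qualifiers, green crosses) and
  bare country names (red circles). Each dataset exports as standalone HTML
  with the data embedded as JSON, machine-recoverable via
  `read_plot_html()`. Frequency filtering at species level writes excluded
  units to an overflow TSV whose filename embeds the threshold
  (`filtered_out_min3.tsv`).
- **Fixtures** — seeded generators for synthetic taxdump trees and GenBank
  record corpora with a ground-truth manifest, including a reference corpus
  encoding the published Atlantic cod gene survey.

## Worked example

```r
library(taxplorer)

fx_dir <- file.path(tempdir(), "cod-fixture")
mirror_fixture(fx_dir, seed = 42)          # offline reference fixture
store <- load_taxdump(file.path(fx_dir, "nodes.dmp"),
                      file.path(fx_dir, "names.dmp"))

resolve_lineage(store, 8049)
#> <lineage_path> txid 8049 (species)
#>   Chordata;Actinopterygii;Gadiformes;Gadidae;Gadus;Gadus morhua

transport <- fixture_transport(file.path(fx_dir, "records.gb"), store)
raw <- run_download(transport, query_spec(organism = 8049),
                    file.path(fx_dir, "dl"))
records <- parse_records(raw)

gene_frequency(records)
#> <freq_table> 3 gene(s); 1751 of 1800 records tagged
#>   gene count
#> 1 CYTB   985
#> 2  COI   455
#> 3  ND2   311

write_taxonomy_tsv(records, store, file.path(fx_dir, "taxonomy.tsv"))
#>    written unresolved
#>       1800          0

build_worldmap(lapply(records, extract_geo),
               vapply(records, function(r) r$organism, ""))
#> <geo_arrays> 586 coordinate point(s), 8 country point(s), 696 record(s) without geography
```

The lineage line is the standardized six-rank path of the Atlantic cod
(txid 8049). The frequency table says that of 1,800 retrieved records 1,751
carry a `gene` qualifier, dominated by the mitochondrial barcoding markers
CYTB (985 records), COI (455) and ND2 (311) — the marker ranking a gene
survey reports for this species. Every record's txid resolved against the
store (`unresolved 0`), and the world map split the georeferenced subset
into 586 distinct coordinate sites and 8 countries.

The same pipeline is scriptable from a shell:

```sh
inst/cli/taxplorer fixtures --out fx
inst/cli/taxplorer database --txid 8049 --fixture fx --out db
inst/cli/taxplorer viz --type sunburst --input db/taxonomy.tsv \
    --filter 3 --out sunburst.html
inst/cli/taxplorer convert --txid 8049 --store fx
```

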