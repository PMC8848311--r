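# Shared helpers: independent brute-force oracles and memoized fixtures.

options(taxplorer.quiet = TRUE)
options(taxplorer.backoff_base = 0.001)  # keep retry tests fast

ranks6 <- c("phylum", "class", "order", "family", "genus", "species")

# Brute-force lineage oracle: repeated parent lookups on the raw node table,
# nearest rank-labelled ancestor-or-self per rank, self name as fallback.
# Deliberately independent of the package's index structures.
oracle_lineage <- function(nodes, txid) {
  chain <- integer(0)
  cur <- txid
  repeat {
    chain <- c(chain, cur)
    p <- nodes$parent_txid[match(cur, nodes$txid)]
    if (p == cur) break
    cur <- p
  }
  nm <- nodes$scientific_name[match(chain, nodes$txid)]
  rk <- tolower(nodes$rank[match(chain, nodes$txid)])
  vapply(ranks6, function(r) {
    hit <- which(rk == r)
    if (length(hit)) nm[hit[1]] else nm[1]
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force gene recount: per-record set union, case-insensitive.
oracle_gene_counts <- function(records) {
  genes <- unlist(lapply(records, function(r) unique(tolower(r$gene_names))))
  if (!length(genes)) return(table(character(0)))
  table(genes)
}

# Memoized shared fixtures (generated once per test run).
.fixture_cache <- new.env()

shared_mirror_fixture <- function() {
  if (is.null(.fixture_cache$mirror)) {
    dir <- file.path(tempdir(), "taxplorer-mirror-fixture")
    .fixture_cache$mirror <- mirror_fixture(dir, seed = 20260101L)
  }
  .fixture_cache$mirror
}

shared_mirror_store <- function() {
  if (is.null(.fixture_cache$store)) {
    fx <- shared_mirror_fixture()
    .fixture_cache$store <- load_taxdump(file.path(fx$dir, "nodes.dmp"),
                                         file.path(fx$dir, "names.dmp"))
  }
  .fixture_cache$store
}

# Small synthetic taxonomy + corpus shared by parser/builder/viz tests.
shared_synthetic <- function() {
  if (is.null(.fixture_cache$synth)) {
    taxo <- make_taxonomy(101L, n_nodes = 40L, rank_missing_prob = 0,
                          dir = file.path(tempdir(), "taxplorer-synth-taxdump"))
    recs <- make_records(
      202L, taxo, n_records = 200L,
      gene_pool = data.frame(gene = c("COI", "CYTB", "ND2", "rbcL"),
                             weight = c(4, 3, 2, 1)),
      geo_profile = c(0.35, 0.35, 0.30),
      file = file.path(tempdir(), "taxplorer-synth-records.gb"))
    .fixture_cache$synth <- list(
      taxonomy = taxo,
      records = recs,
      table = load_taxdump(taxo$nodes_file, taxo$names_file),
      parsed = parse_records(recs$file))
  }
  .fixture_cache$synth
}

# Random lineage set built by resolving sampled species txids of a synthetic
# tree (fast path to many taxonomy paths).
random_lineage_set <- function(n, seed) {
  synth <- shared_synthetic()
  species <- synth$taxonomy$nodes$txid[synth$taxonomy$nodes$rank == "species"]
  set.seed(seed)
  picks <- sample(species, n, replace = TRUE)
  as_lineage_set(lapply(picks, function(tx) resolve_lineage(synth$table, tx)))
}
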