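# Reference fixture: a small taxonomy and record corpus encoding the
# published placements and survey counts used throughout the tests (Atlantic
# cod and its order, the vertebrate ACE2 survey, SARS-CoV-2). Only publicly
# stated txids (8049, 8043, 7742, 2697049) and placements are fixed; every
# other txid and all sequences are synthetic.

#' The reference taxonomy fixture
#'
#' A fixed tree placing *Gadus morhua* (txid 8049) under genus Gadus, family
#' Gadidae, order Gadiformes (txid 8043), class Actinopterygii, phylum
#' Chordata, with the Vertebrata clade (txid 7742, rank-less) on the chain to
#' exercise rank skipping; sibling Gadiformes families Merlucciidae and
#' Macrouridae; and SARS-CoV-2 (txid 2697049) on a sparsely ranked viral
#' lineage to exercise the ancestor fallback.
#'
#' @param dir Directory to write `nodes.dmp` / `names.dmp` into.
#' @return Manifest list (`nodes`, `nodes_file`, `names_file`, `root_txid`),
#'   same shape as [make_taxonomy()].
#' @export
mirror_taxonomy <- function(dir = tempfile("mirror_taxdump")) {
  n <- function(txid, parent, rank, name) {
    data.frame(txid = txid, parent_txid = parent, rank = rank,
               scientific_name = name, stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    n(1L,       1L,       "no rank", "root"),
    n(101L,     1L,       "phylum",  "Chordata"),
    n(7742L,    101L,     "no rank", "Vertebrata"),
    n(102L,     7742L,    "class",   "Actinopterygii"),
    n(8043L,    102L,     "order",   "Gadiformes"),
    n(103L,     8043L,    "family",  "Gadidae"),
    n(104L,     103L,     "genus",   "Gadus"),
    n(8049L,    104L,     "species", "Gadus morhua"),
    n(105L,     8043L,    "family",  "Merlucciidae"),
    n(106L,     105L,     "genus",   "Merluccius"),
    n(107L,     106L,     "species", "Merluccius merluccius"),
    n(108L,     8043L,    "family",  "Macrouridae"),
    n(109L,     108L,     "genus",   "Coryphaenoides"),
    n(110L,     109L,     "species", "Coryphaenoides rupestris"),
    # sparsely ranked viral lineage: no class/order on the chain
    n(200L,     1L,       "no rank", "Viruses"),
    n(201L,     200L,     "phylum",  "Pisuviricota"),
    n(202L,     201L,     "family",  "Coronaviridae"),
    n(203L,     202L,     "genus",   "Betacoronavirus"),
    n(2697049L, 203L,     "species",
      "Severe acute respiratory syndrome coronavirus 2"))
  nodes$true_depth <- NA_integer_
  files <- write_taxdump(nodes, dir)
  list(nodes = nodes, nodes_file = files$nodes, names_file = files$names,
       root_txid = 1L)
}

#' The reference record corpus: the Atlantic cod gene survey
#'
#' Generates a corpus of *Gadus morhua* (txid 8049) records whose gene-tag
#' marginals equal the published survey for that species: 985 records tagged
#' CYTB, 455 COI and 311 ND2, plus `n_untagged` records without a gene tag.
#' Geography is mixed (coordinates / bare country / none) so the world-map
#' path is exercised on the same corpus.
#'
#' @param seed Integer seed.
#' @param dir Directory for the flat file.
#' @param n_untagged Untagged records appended after the tagged ones.
#' @return Record manifest, same shape as [make_records()].
#' @export
mirror_records <- function(seed = 20260101L, dir = tempfile("mirror_corpus"),
                           n_untagged = 49L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  taxo <- mirror_taxonomy(file.path(dir, "taxdump"))
  cod <- taxo$nodes[taxo$nodes$txid == 8049L, , drop = FALSE]
  gene_pool <- data.frame(gene = c("CYTB", "COI", "ND2"),
                          count = c(985L, 455L, 311L),
                          stringsAsFactors = FALSE)
  make_records(seed, list(nodes = cod),
               n_records = sum(gene_pool$count) + n_untagged,
               gene_pool = gene_pool,
               geo_profile = c(0.3, 0.3, 0.4),
               file = file.path(dir, "records.gb"))
}

#' Write the full reference fixture directory
#'
#' Assembles `nodes.dmp`, `names.dmp` and `records.gb` in one directory —
#' the layout the CLI's `--fixture` flag expects.
#'
#' @param dir Target directory.
#' @param seed Seed for the record corpus.
#' @return List with `dir`, `taxonomy` and `records` manifests.
#' @export
mirror_fixture <- function(dir = tempfile("mirror_fixture"),
                           seed = 20260101L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  taxo <- mirror_taxonomy(dir)
  recs <- mirror_records(seed = seed, dir = dir)
  unlink(file.path(dir, "taxdump"), recursive = TRUE)
  list(dir = dir, taxonomy = taxo, records = recs)
}
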