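# Taxonomy store: taxdump loading, lineage resolution, name lookup,
# batch conversion.

write_tiny_taxdump <- function(dir = tempfile("tiny")) {
  dir.create(dir)
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "10\t|\t1\t|\tphylum\t|",
               "100\t|\t10\t|\tspecies\t|"),
             file.path(dir, "nodes.dmp"))
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "10\t|\tProteozoa\t|\t\t|\tscientific name\t|",
               "10\t|\tproto things\t|\t\t|\tcommon name\t|",
               "100\t|\tProteozoa minima\t|\t\t|\tscientific name\t|"),
             file.path(dir, "names.dmp"))
  dir
}

test_that("minimal taxdump loads with root detection and scientific names only", {
  d <- write_tiny_taxdump()
  tab <- load_taxdump(file.path(d, "nodes.dmp"), file.path(d, "names.dmp"))
  expect_equal(nrow(tab$nodes), 3L)
  expect_equal(tab$root_txid, 1L)
  expect_equal(sort(names(tab$name_index)),
               sort(c("root", "proteozoa", "proteozoa minima")))
  # common-name entries are not indexed
  expect_length(name_to_txids(tab, "proto things"), 0L)
})

test_that("malformed and inconsistent taxdump input raises informative errors", {
  d <- write_tiny_taxdump()
  nodes <- file.path(d, "nodes.dmp")
  bad <- file.path(d, "bad_nodes.dmp")
  writeLines(c("1\t|\t1\t|\tno rank\t|", "10\t|\t1\t|"), bad)  # rank missing
  expect_error(load_taxdump(bad, file.path(d, "names.dmp")),
               "line 2")
  orphan <- file.path(d, "orphan_nodes.dmp")
  writeLines(c("1\t|\t1\t|\tno rank\t|", "10\t|\t99\t|\tphylum\t|"), orphan)
  expect_error(load_taxdump(orphan, file.path(d, "names.dmp")),
               "99")
  tworoot <- file.path(d, "tworoot_nodes.dmp")
  writeLines(c("1\t|\t1\t|\tno rank\t|", "10\t|\t10\t|\tphylum\t|"), tworoot)
  expect_error(load_taxdump(tworoot, file.path(d, "names.dmp")),
               "root")
  expect_error(load_taxdump(file.path(d, "nope.dmp"), file.path(d, "names.dmp")),
               "not found")
})

test_that("a 500-node synthetic tree round-trips through the taxdump dialect", {
  m <- make_taxonomy(7L, n_nodes = 500L, rank_missing_prob = 0.2,
                     dir = tempfile("big"))
  tab <- load_taxdump(m$nodes_file, m$names_file)
  got <- tab$nodes[order(tab$nodes$txid),
                   c("txid", "parent_txid", "rank", "scientific_name")]
  want <- m$nodes[order(m$nodes$txid),
                  c("txid", "parent_txid", "rank", "scientific_name")]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("the reference tree resolves the cod lineage and serializes cleanly", {
  tab <- shared_mirror_store()
  lp <- resolve_lineage(tab, 8049L)
  expect_equal(lp$ranks[["order"]], "Gadiformes")
  expect_equal(lp$ranks[["family"]], "Gadidae")
  expect_equal(lp$ranks[["species"]], "Gadus morhua")
  s <- format(lp)
  expect_identical(s, "Chordata;Actinopterygii;Gadiformes;Gadidae;Gadus;Gadus morhua")
  expect_length(strsplit(s, ";", fixed = TRUE)[[1]], 6L)
  expect_false(grepl("^\\s|\\s$", s))
})

test_that("rank-less chains fall back to ancestor-or-self names, root included", {
  tab <- shared_mirror_store()
  root <- resolve_lineage(tab, tab$root_txid)
  expect_equal(unname(root$ranks), rep("root", 6L))
  # sparsely ranked viral lineage: class and order are absent from the chain
  sars <- resolve_lineage(tab, 2697049L)
  expect_equal(sars$ranks[["phylum"]], "Pisuviricota")
  expect_equal(sars$ranks[["family"]], "Coronaviridae")
  expect_equal(sars$ranks[["class"]],
               "Severe acute respiratory syndrome coronavirus 2")
  expect_error(resolve_lineage(tab, 424242L), "424242")
})

test_that("resolve_lineage equals the brute-force parent-walk oracle", {
  for (seed in c(11L, 12L, 13L, 14L)) {
    m <- make_taxonomy(seed, n_nodes = 7L + 19L * (seed - 10L),
                       rank_missing_prob = c(0, 0.3, 0.6, 0.9)[seed - 10L])
    tab <- load_taxdump(m$nodes_file, m$names_file)
    got <- lapply(m$nodes$txid, function(tx) unname(resolve_lineage(tab, tx)$ranks))
    want <- lapply(m$nodes$txid, function(tx) oracle_lineage(m$nodes, tx))
    expect_identical(got, want, label = sprintf("tree seed %d", seed))
  }
})

test_that("name lookup is case-insensitive, ascending, and homonym-aware", {
  tab <- shared_mirror_store()
  expect_identical(name_to_txids(tab, "gadus MORHUA"), 8049L)
  expect_identical(name_to_txids(tab, "no such organism"), integer(0))

  d <- tempfile("homonym"); dir.create(d)
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "5\t|\t1\t|\tgenus\t|",
               "9\t|\t1\t|\tgenus\t|"), file.path(d, "nodes.dmp"))
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "9\t|\tMorus\t|\t\t|\tscientific name\t|",
               "5\t|\tMorus\t|\t\t|\tscientific name\t|"),
             file.path(d, "names.dmp"))
  hom <- load_taxdump(file.path(d, "nodes.dmp"), file.path(d, "names.dmp"))
  expect_identical(name_to_txids(hom, "Morus"), c(5L, 9L))
})

test_that("six-rank names round-trip through lookup and resolution", {
  tab <- shared_synthetic()$table
  ranked <- tab$nodes[tolower(tab$nodes$rank) %in% ranks6, ]
  for (i in seq_len(nrow(ranked))) {
    tx <- ranked$txid[i]
    expect_true(tx %in% name_to_txids(tab, ranked$scientific_name[i]))
    lp <- resolve_lineage(tab, tx)
    expect_equal(lp$ranks[[tolower(ranked$rank[i])]], ranked$scientific_name[i])
  }
})

test_that("batch conversion preserves order, flags failures, equals single calls", {
  tab <- shared_mirror_store()
  f <- tempfile(fileext = ".tsv")
  writeLines(c("8049\textra", "8043\textra", "1\textra"), f)
  rows <- convert_batch(tab, f, "txid_to_ranks")
  expect_equal(rows$input, c("8049", "8043", "1"))
  expect_equal(rows$status, rep("resolved", 3L))
  expect_equal(rows$lineage[1],
               "Chordata;Actinopterygii;Gadiformes;Gadidae;Gadus;Gadus morhua")

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("8049", "999999", "8043", "7742", "2697049"), f2)
  rows2 <- convert_batch(tab, f2, "txid_to_ranks")
  expect_equal(nrow(rows2), 5L)
  expect_equal(sum(rows2$status == "unresolved"), 1L)
  expect_equal(rows2$status[2], "unresolved")

  # 200-row batch equals the concatenation of 200 single-input conversions
  synth <- shared_synthetic()
  set.seed(33)
  txids <- sample(synth$taxonomy$nodes$txid, 200L, replace = TRUE)
  f3 <- tempfile(fileext = ".csv")
  writeLines(sprintf("%d,x", txids), f3)
  batch <- convert_batch(synth$table, f3, "txid_to_ranks")
  singles <- do.call(rbind, lapply(as.character(txids), function(tx)
    taxplorer:::convert_one(synth$table, tx, "txid_to_ranks")))
  expect_identical(batch, singles)

  # name direction, ambiguity flagged with all candidates
  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("Gadus morhua", "nobody knows"), f4)
  rows4 <- convert_batch(tab, f4, "name_to_txid")
  expect_equal(rows4$txid[1], "8049")
  expect_equal(rows4$status, c("resolved", "unresolved"))

  empty <- tempfile(fileext = ".tsv"); file.create(empty)
  expect_equal(nrow(convert_batch(tab, empty, "txid_to_ranks")), 0L)
  expect_error(convert_batch(tab, tempfile(), "txid_to_ranks"), "cannot read")
})

test_that("resolution is deterministic across repeated calls", {
  tab <- shared_mirror_store()
  a <- vapply(tab$nodes$txid, function(tx) format(resolve_lineage(tab, tx)), "")
  b <- vapply(tab$nodes$txid, function(tx) format(resolve_lineage(tab, tx)), "")
  expect_identical(a, b)
})
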