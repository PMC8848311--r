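# Visualization datasets: taxonomy-file loading, frequency filtering,
# scatter/sunburst/worldmap aggregation, HTML export.

path_row <- function(...) {
  x <- c(...)
  as_lineage_set(list(structure(list(txid = 0L, source_rank = "species",
                                     scientific_name = x[6],
                                     ranks = stats::setNames(x, ranks6)),
                                class = "lineage_path")))
}

rep_paths <- function(path, n) {
  ls <- path_row(path)[rep(1L, n), , drop = FALSE]
  class(ls) <- c("lineage_set", "data.frame")
  rownames(ls) <- NULL
  ls
}

bind_paths <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("lineage_set", "data.frame")
  out
}

test_that("taxonomy files load in both two-column and bare-path dialects", {
  f <- tempfile(fileext = ".tsv")
  writeLines("X1\tChordata;Actinopterygii;Gadiformes;Gadidae;Gadus;Gadus morhua", f)
  ls <- load_taxonomy_file(f)
  expect_equal(nrow(ls), 1L)
  expect_identical(ls$accession, "X1")
  expect_identical(ls$species, "Gadus morhua")
  expect_identical(ls$phylum, "Chordata")

  bare <- tempfile(fileext = ".tsv")
  writeLines(c("Chordata;Actinopterygii;Gadiformes;Gadidae;Gadus;Gadus morhua",
               "Chordata;Actinopterygii;Gadiformes;Gadidae;Gadus;Gadus chalcogrammus"),
             bare)
  ls2 <- load_taxonomy_file(bare)
  expect_equal(nrow(ls2), 2L)
  expect_identical(ls2$accession, c("", ""))

  # ragged short path: right-padded by repeating the last name
  short <- tempfile(fileext = ".tsv")
  writeLines("Y1\tChordata;Actinopterygii;Gadiformes", short)
  ls3 <- load_taxonomy_file(short)
  expect_identical(unname(unlist(ls3[1, ranks6])),
                   c("Chordata", "Actinopterygii", rep("Gadiformes", 4L)))

  long <- tempfile(fileext = ".tsv")
  writeLines(c("ok;ok;ok;ok;ok;ok", "a;b;c;d;e;f;g"), long)
  expect_error(load_taxonomy_file(long), "line 2")
})

test_that("database output reloads to the identical lineage set", {
  synth <- shared_synthetic()
  f <- tempfile(fileext = ".tsv")
  write_taxonomy_tsv(synth$parsed, synth$table, f)
  reloaded <- load_taxonomy_file(f)
  direct <- as_lineage_set(
    lapply(synth$records$records$txid,
           function(tx) resolve_lineage(synth$table, tx)),
    accessions = synth$records$records$accession)
  expect_identical(as.data.frame(reloaded), as.data.frame(direct))
})

test_that("threshold 0 keeps everything and writes no overflow file", {
  ls <- random_lineage_set(50L, seed = 5L)
  wd <- tempfile("filter0"); dir.create(wd)
  res <- apply_filter(ls, 0L, wd)
  expect_identical(as.data.frame(res$kept), as.data.frame(ls))
  expect_equal(nrow(res$discarded), 0L)
  expect_null(res$overflow_file)
  expect_length(list.files(wd), 0L)
})

test_that("filtering partitions paths at species level with a threshold-named overflow", {
  ls <- bind_paths(rep_paths(c("P", "C", "O", "F", "G", "Species A"), 10L),
                   rep_paths(c("P", "C", "O", "F", "G", "Species B"), 2L))
  wd <- tempfile("filter3"); dir.create(wd)
  res <- apply_filter(ls, 3L, wd)
  expect_equal(nrow(res$kept), 10L)
  expect_identical(unique(res$kept$species), "Species A")
  expect_identical(res$discarded$unit, "Species B")
  expect_identical(res$discarded$count, 2L)
  expect_match(basename(res$overflow_file), "3")
  expect_identical(readLines(res$overflow_file),
                   c("taxonomic_unit\tcount", "Species B\t2"))

  # threshold larger than every count discards everything
  all_out <- apply_filter(ls, 100L, wd)
  expect_equal(nrow(all_out$kept), 0L)
  expect_equal(sum(all_out$discarded$count), 12L)
})

test_that("kept paths plus discarded counts conserve the input for any threshold", {
  ls <- random_lineage_set(300L, seed = 8L)
  wd <- tempfile("filtercons"); dir.create(wd)
  for (thr in c(0L, 1L, 3L, 10L, 50L)) {
    res <- apply_filter(ls, thr, wd)
    expect_equal(nrow(res$kept) + sum(res$discarded$count), 300L,
                 label = sprintf("threshold %d", thr))
    if (nrow(res$discarded)) expect_true(all(res$discarded$count < thr))
  }
})

test_that("scatter series carry parents and conserve totals at every rank", {
  single <- rep_paths(c("P", "C", "O", "F", "G", "S"), 1L)
  sc1 <- build_scatter(single)
  expect_equal(nrow(sc1), 6L)
  expect_true(all(sc1$count == 1L))
  expect_identical(sc1$parent[sc1$rank == "class"], "P")

  ls <- random_lineage_set(500L, seed = 21L)
  sc <- build_scatter(ls)
  sums <- tapply(sc$count, sc$rank, sum)
  expect_true(all(sums == 500L))
})

test_that("the published family-abundance ranking is reproduced from path counts", {
  ls <- bind_paths(
    rep_paths(c("Chordata", "Actinopterygii", "Gadiformes", "Gadidae",
                "Gadus", "Gadus morhua"), 381460L),
    rep_paths(c("Chordata", "Actinopterygii", "Gadiformes", "Merlucciidae",
                "Merluccius", "Merluccius merluccius"), 3252L),
    rep_paths(c("Chordata", "Actinopterygii", "Gadiformes", "Macrouridae",
                "Coryphaenoides", "Coryphaenoides rupestris"), 1673L))
  sc <- build_scatter(ls)
  fam <- sc[sc$rank == "family", ]
  expect_identical(fam$taxon, c("Gadidae", "Merlucciidae", "Macrouridae"))
  expect_identical(fam$count, c(381460L, 3252L, 1673L))
  expect_true(all(fam$parent == "Gadiformes"))
})

test_that("sunburst nodes are additive and homonyms stay distinct", {
  two <- bind_paths(rep_paths(c("P", "C1", "O", "F", "G", "S1"), 1L),
                    rep_paths(c("P", "C2", "O", "F", "G", "S2"), 1L))
  tree <- build_sunburst(two)
  expect_equal(tree$count[tree$level == 1L], 2L)
  expect_equal(sum(tree$level == 2L), 2L)
  expect_true(all(tree$count[tree$level == 2L] == 1L))

  # one genus name under two families -> two distinct nodes
  hom <- bind_paths(rep_paths(c("P", "C", "O", "F1", "Gadus", "S1"), 3L),
                    rep_paths(c("P", "C", "O", "F2", "Gadus", "S2"), 2L))
  treeh <- build_sunburst(hom)
  gadus <- treeh[treeh$label == "Gadus", ]
  expect_equal(nrow(gadus), 2L)
  expect_setequal(gadus$count, c(3L, 2L))
})

test_that("every internal sunburst count equals the sum of its children", {
  ls <- random_lineage_set(400L, seed = 31L)
  tree <- build_sunburst(ls)
  expect_equal(sum(tree$count[tree$level == 1L]), 400L)
  for (lvl in 1:5) {
    parents <- tree[tree$level == lvl, ]
    kids <- tree[tree$level == lvl + 1L, ]
    kid_sum <- tapply(kids$count, kids$parent_id, sum)
    expect_equal(as.vector(kid_sum[parents$id]), parents$count,
                 label = sprintf("level %d", lvl))
  }
})

test_that("world-map arrays aggregate by site and country with marker metadata", {
  geo <- function(kind, lat = NULL, lon = NULL, country = NULL) {
    structure(list(kind = kind, lat = lat, lon = lon, country_name = country),
              class = "geo_ref")
  }
  refs <- list(geo("coordinates", 60.39, 5.32), geo("coordinates", 60.39, 5.32),
               geo("coordinates", 60.39001, 5.32004),  # same site after rounding
               geo("country", country = "Norway"),
               geo("country", country = "Norway"),
               geo("none"))
  wm <- build_worldmap(refs, labels = c("cod", "cod", "haddock", "cod", "cod", ""))
  expect_equal(nrow(wm$coordinates), 1L)
  expect_equal(wm$coordinates$count, 3L)
  expect_identical(wm$coordinates$marker, "green-cross")
  expect_identical(wm$coordinates$label, "cod; haddock")
  expect_equal(nrow(wm$countries), 1L)
  expect_equal(wm$countries$count, 2L)
  expect_identical(wm$countries$marker, "red-circle")
  expect_equal(wm$n_none, 1L)

  none_only <- build_worldmap(list(geo("none"), geo("none")))
  expect_equal(nrow(none_only$coordinates) + nrow(none_only$countries), 0L)
  out <- tempfile(fileext = ".html")
  export_html(none_only, out)  # empty map still exportable
  expect_true(file.exists(out))
})

test_that("world-map totals match the generator's geography manifest", {
  synth <- shared_synthetic()
  geo <- lapply(synth$parsed, extract_geo)
  wm <- build_worldmap(geo)
  man <- synth$records$marginals
  expect_equal(sum(wm$coordinates$count), man$n_coordinates)
  expect_equal(sum(wm$countries$count), man$n_country)
  expect_equal(wm$n_none, man$n_none)
  expect_equal(sum(wm$coordinates$count) + sum(wm$countries$count) + wm$n_none,
               length(synth$parsed))
})

test_that("exported HTML embeds the plot data recoverably for all plot types", {
  ls <- random_lineage_set(60L, seed = 41L)
  sc <- build_scatter(ls)
  f <- tempfile(fileext = ".html")
  export_html(sc, f)
  html <- paste(readLines(f), collapse = "\n")
  expect_true(all(vapply(unique(sc$taxon), grepl, logical(1), x = html,
                         fixed = TRUE)))
  back <- read_plot_html(f)
  expect_identical(back$type, "scatter")
  expect_equal(back$data, as.data.frame(sc), ignore_attr = TRUE)

  tree <- build_sunburst(ls)
  f2 <- tempfile(fileext = ".html")
  export_html(tree, f2)
  back2 <- read_plot_html(f2)
  expect_equal(back2$data, as.data.frame(tree), ignore_attr = TRUE)

  wm <- build_worldmap(lapply(shared_synthetic()$parsed, extract_geo))
  f3 <- tempfile(fileext = ".html")
  export_html(wm, f3)
  back3 <- read_plot_html(f3)
  expect_equal(back3$data$coordinates, wm$coordinates, ignore_attr = TRUE)
  expect_equal(back3$data$countries, wm$countries, ignore_attr = TRUE)

  # empty sunburst: valid page, data recoverable as empty
  f4 <- tempfile(fileext = ".html")
  empty <- build_sunburst(ls[0, , drop = FALSE])
  export_html(empty, f4)
  back4 <- read_plot_html(f4)
  expect_identical(back4$type, "sunburst")
  expect_equal(nrow(back4$data), 0L)
})
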