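# Synthetic-fixture generators: taxdump-dialect taxonomy trees and
# GenBank-dialect record corpora with a ground-truth manifest, so every other
# module runs and is testable offline. All generation is seeded and
# deterministic.

rank_for_depth <- function(depth) c("no rank", MAIN_RANKS)[depth + 1L]  # depth 0 = root

#' Generate a synthetic taxonomy in taxdump dialect
#'
#' Grows a random ranked tree under a single root: children of the root are
#' phyla, their children classes, and so on down to species (depth 6). Every
#' leaf is then extended to species depth, so with `rank_missing_prob = 0`
#' every leaf has a complete six-rank ancestor chain. With positive
#' `rank_missing_prob`, each non-root node's rank label is independently
#' replaced by `"no rank"` with that probability, exercising the ancestor
#' fallback.
#'
#' @param seed Integer seed; the same seed reproduces files byte-identically.
#' @param n_nodes Target node count before leaf extension (>= 7).
#' @param rank_missing_prob Probability a node's rank label is blanked.
#' @param dir Output directory for `nodes.dmp` / `names.dmp`.
#' @return Manifest list: `seed`, `nodes` (data.frame txid, parent_txid,
#'   rank, true_depth, scientific_name), `nodes_file`, `names_file`,
#'   `root_txid`.
#' @export
make_taxonomy <- function(seed, n_nodes = 50L, rank_missing_prob = 0,
                          dir = tempfile("taxdump")) {
  stopifnot(n_nodes >= 7L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rng <- local_rng(seed)

  txid <- 1L
  parent <- 1L
  depth <- 0L
  # grow: attach each new node to a random node of depth < 6
  while (length(txid) < n_nodes) {
    open <- which(depth < 6L)
    p <- open[rng$int(length(open))]
    txid <- c(txid, length(txid) + 1L)
    parent <- c(parent, txid[p])
    depth <- c(depth, depth[p] + 1L)
  }
  # extend every leaf to species depth so complete chains exist
  repeat {
    leaves <- which(depth < 6L & !(txid %in% parent[-1L]))
    if (!length(leaves)) break
    for (l in leaves) {
      txid <- c(txid, length(txid) + 1L)
      parent <- c(parent, txid[l])
      depth <- c(depth, depth[l] + 1L)
    }
  }

  rank <- rank_for_depth(depth)
  if (rank_missing_prob > 0) {
    blank <- c(FALSE, rng$unif(length(txid) - 1L) < rank_missing_prob)
    rank[blank] <- "no rank"
  }
  name <- c("root", sprintf("Taxon %s %d", rank[-1L], txid[-1L]))

  nodes <- data.frame(txid = txid, parent_txid = parent, rank = rank,
                      true_depth = depth, scientific_name = name,
                      stringsAsFactors = FALSE)
  files <- write_taxdump(nodes, dir)
  list(seed = seed, nodes = nodes, nodes_file = files$nodes,
       names_file = files$names, root_txid = 1L)
}

#' Write a node table in taxdump dialect
#'
#' @param nodes Data.frame with `txid`, `parent_txid`, `rank`,
#'   `scientific_name`.
#' @param dir Output directory.
#' @return List with `nodes` and `names` file paths.
#' @export
write_taxdump <- function(nodes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes_file <- file.path(dir, "nodes.dmp")
  names_file <- file.path(dir, "names.dmp")
  write_lines_lf(sprintf("%d\t|\t%d\t|\t%s\t|",
                         nodes$txid, nodes$parent_txid, nodes$rank),
                 nodes_file)
  write_lines_lf(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                         nodes$txid, nodes$scientific_name),
                 names_file)
  list(nodes = nodes_file, names = names_file)
}

#' Generate a synthetic GenBank-dialect record corpus
#'
#' Records reference species-level (depth-6) taxa of a [make_taxonomy()]
#' manifest. Gene qualifiers are drawn from `gene_pool`; when the pool
#' carries exact `count`s, exactly that many records are tagged with each
#' gene (in order) and the remainder stay untagged, otherwise genes are
#' sampled by `weight`. `geo_profile` gives the fractions of records with
#' coordinates, with a bare country, and with neither.
#'
#' @param seed Integer seed.
#' @param manifest Taxonomy manifest from [make_taxonomy()] (or any list with
#'   a `nodes` data.frame).
#' @param n_records Number of records.
#' @param gene_pool Data.frame with `gene` and either `count` (exact) or
#'   `weight` (sampling); `NULL` for an untagged corpus.
#' @param geo_profile Numeric length-3 vector `(coordinates, country, none)`
#'   summing to 1.
#' @param file Output flat-file path.
#' @return Manifest list: `seed`, `file`, `records` (data.frame accession,
#'   txid, organism, genes `";"`-joined, country_raw, lat_lon_raw, lat, lon,
#'   seq_length), and `marginals` (gene counts, per-kind geo totals)
#'   recomputable from `records` by brute force.
#' @export
make_records <- function(seed, manifest, n_records,
                         gene_pool = NULL,
                         geo_profile = c(0.3, 0.3, 0.4),
                         file = tempfile("records", fileext = ".gb")) {
  rng <- local_rng(seed)
  nodes <- manifest$nodes
  species <- nodes[tolower(nodes$rank) == "species", , drop = FALSE]
  if (!nrow(species)) species <- nodes[nodes$txid != nodes$parent_txid, , drop = FALSE]
  stopifnot(abs(sum(geo_profile) - 1) < 1e-9)

  pick <- species[rng$int(nrow(species), n_records), , drop = FALSE]
  accession <- sprintf("FX%06d.1", seq_len(n_records))

  genes <- replicate(n_records, character(0), simplify = FALSE)
  if (!is.null(gene_pool) && nrow(gene_pool)) {
    if ("count" %in% names(gene_pool)) {
      stopifnot(sum(gene_pool$count) <= n_records)
      at <- 1L
      for (g in seq_len(nrow(gene_pool))) {
        n_g <- gene_pool$count[g]
        if (n_g > 0L) {
          genes[at:(at + n_g - 1L)] <- list(gene_pool$gene[g])
          at <- at + n_g
        }
      }
    } else {
      w <- gene_pool$weight / sum(gene_pool$weight)
      for (i in seq_len(n_records)) {
        k <- rng$int(3L) - 1L  # 0-2 genes per record
        if (k > 0L) {
          genes[[i]] <- unique(gene_pool$gene[rng$wsample(length(w), k, w)])
        }
      }
    }
  }

  kind_pool <- c("coordinates", "country", "none")
  kinds <- kind_pool[rng$wsample(3L, n_records, geo_profile)]
  countries <- c("Norway", "Italy", "Japan", "Brazil", "Canada",
                 "South Africa", "New Zealand", "Iceland")
  regions <- c("", ": Skagerrak", ": Lofoten", ": coastal zone")

  lat <- ifelse(kinds == "coordinates",
                round(rng$unif(n_records, -89.9, 89.9), 4L), NA_real_)
  lon <- ifelse(kinds == "coordinates",
                round(rng$unif(n_records, -179.9, 179.9), 4L), NA_real_)
  lat_lon_raw <- ifelse(kinds == "coordinates", format_lat_lon(lat, lon), NA)
  country_raw <- ifelse(
    kinds == "country",
    paste0(countries[rng$int(length(countries), n_records)],
           regions[rng$int(length(regions), n_records)]),
    NA)

  seq_length <- 200L + rng$int(1301L, n_records) - 1L
  sequences <- vapply(seq_length, function(n) {
    paste(c("A", "C", "G", "T")[rng$int(4L, n)], collapse = "")
  }, character(1))

  records <- data.frame(
    accession = accession, txid = pick$txid, organism = pick$scientific_name,
    genes = vapply(genes, paste, character(1), collapse = ";"),
    country_raw = country_raw, lat_lon_raw = lat_lon_raw,
    lat = lat, lon = lon, seq_length = seq_length, stringsAsFactors = FALSE)

  write_genbank(records, sequences, file)
  list(seed = seed, file = file, records = records,
       marginals = record_marginals(records))
}

# Brute-force marginal recount from the manifest's record table.
record_marginals <- function(records) {
  gene_lists <- strsplit(records$genes, ";", fixed = TRUE)
  gene_lists <- lapply(gene_lists, function(g) unique(tolower(g[nzchar(g)])))
  genes <- unlist(gene_lists, use.names = FALSE)
  list(
    gene_counts = if (length(genes)) sort(table(genes), decreasing = TRUE)
                  else table(character(0)),
    tagged_records = sum(lengths(gene_lists) > 0L),
    n_coordinates = sum(!is.na(records$lat_lon_raw)),
    n_country = sum(!is.na(records$country_raw)),
    n_none = sum(is.na(records$lat_lon_raw) & is.na(records$country_raw)),
    per_txid = table(records$txid)
  )
}

#' Format decimal coordinates as an INSDC lat_lon string
#'
#' @param lat,lon Decimal degrees (N/E positive).
#' @return `"<deg> N|S <deg> E|W"` strings.
#' @export
format_lat_lon <- function(lat, lon) {
  sprintf("%s %s %s %s",
          format(abs(lat), trim = TRUE, scientific = FALSE),
          ifelse(lat < 0, "S", "N"),
          format(abs(lon), trim = TRUE, scientific = FALSE),
          ifelse(lon < 0, "W", "E"))
}

# Emit the GenBank flat-file dialect for a manifest record table.
write_genbank <- function(records, sequences, file) {
  blocks <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    seq <- sequences[i]
    genes <- strsplit(r$genes, ";", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes)]
    quals <- c(
      sprintf("                     /organism=\"%s\"", r$organism),
      sprintf("                     /db_xref=\"taxon:%d\"", r$txid),
      if (!is.na(r$country_raw))
        sprintf("                     /country=\"%s\"", r$country_raw),
      if (!is.na(r$lat_lon_raw))
        sprintf("                     /lat_lon=\"%s\"", r$lat_lon_raw))
    gene_feats <- unlist(lapply(genes, function(g) {
      c(sprintf("     gene            1..%d", nchar(seq)),
        sprintf("                     /gene=\"%s\"", g))
    }))
    acc_bare <- sub("\\.[0-9]+$", "", r$accession)
    starts <- seq.int(1L, nchar(seq), by = 60L)
    seq_lines <- vapply(starts, function(s) {
      chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
    }, character(1))
    paste(c(
      sprintf("LOCUS       %s              %d bp    DNA     linear   SYN 01-JAN-2026",
              acc_bare, nchar(seq)),
      sprintf("DEFINITION  %s %s sequence.", r$organism,
              if (length(genes)) paste(genes, collapse = " and ") else "genomic"),
      sprintf("ACCESSION   %s", acc_bare),
      sprintf("VERSION     %s", r$accession),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", nchar(seq)),
      quals,
      gene_feats,
      "ORIGIN",
      seq_lines,
      "//"), collapse = "\n")
  }, character(1))
  con <- file(file, open = "wb")
  writeLines(blocks, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(file)
}

# Seeded RNG helper: isolates fixture generation from the global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    int = function(n, size = 1L) with_state(function() sample.int(n, size, replace = TRUE)),
    unif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    wsample = function(n, size, w) with_state(function() sample.int(n, size, replace = TRUE, prob = w))
  )
}
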