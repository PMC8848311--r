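# Aggregation of taxonomy paths and geographic references into the three
# exploration datasets (per-rank scatter series, sunburst hierarchy, world
# map arrays), plus frequency filtering with overflow files.

#' Load taxonomy paths from a TSV/CSV file
#'
#' Accepts the two-column output of [write_taxonomy_tsv()] (accession, then a
#' six-field `";"`-joined path) as well as headerless single-column files of
#' bare paths. Short paths are right-padded by repeating the last available
#' name (mirroring the taxonomy store's ancestor fallback); rows with more
#' than six rank fields are a parse error naming the line.
#'
#' @param path Input file; delimiter sniffed from the extension.
#' @return A `lineage_set`: data.frame with `accession` (may be `""`) and the
#'   six rank columns `phylum` ... `species`.
#' @export
load_taxonomy_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  delim <- sniff_delim(path)

  acc <- character(length(lines))
  ranks <- matrix("", nrow = length(lines), ncol = 6L,
                  dimnames = list(NULL, MAIN_RANKS))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], delim, fixed = TRUE)[[1]])
    taxcol <- which(grepl(";", fields, fixed = TRUE))
    tax <- if (length(taxcol)) fields[taxcol[1L]]
           else fields[length(fields)]  # single bare name allowed
    if (length(fields) > 1L && (!length(taxcol) || taxcol[1L] > 1L)) {
      acc[i] <- fields[1L]
    }
    parts <- trimws(strsplit(tax, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) > 6L) {
      stop(sprintf("parse error in '%s' at line %d: %d rank fields (max 6)",
                   path, i, length(parts)), call. = FALSE)
    }
    if (!length(parts)) {
      stop(sprintf("parse error in '%s' at line %d: empty taxonomy path",
                   path, i), call. = FALSE)
    }
    if (length(parts) < 6L) {
      parts <- c(parts, rep(parts[length(parts)], 6L - length(parts)))
    }
    ranks[i, ] <- parts
  }
  out <- data.frame(accession = acc, ranks, stringsAsFactors = FALSE)
  class(out) <- c("lineage_set", "data.frame")
  out
}

#' Convert lineage paths to a lineage set
#'
#' @param paths List of `lineage_path` objects (or a `lineage_set`, returned
#'   unchanged).
#' @param accessions Optional accession column.
#' @return A `lineage_set` data.frame.
#' @export
as_lineage_set <- function(paths, accessions = NULL) {
  if (inherits(paths, "lineage_set")) return(paths)
  ranks <- t(vapply(paths, function(p) p$ranks, character(6)))
  colnames(ranks) <- MAIN_RANKS
  out <- data.frame(accession = accessions %||% rep("", length(paths)),
                    ranks, stringsAsFactors = FALSE)
  class(out) <- c("lineage_set", "data.frame")
  out
}

#' Filter taxonomy paths by species-level frequency
#'
#' Counts paths per terminal (species-level) taxonomic unit. Units whose
#' count falls below `threshold` are moved to `discarded` and written to an
#' overflow TSV (`filtered_out_min{threshold}.tsv` — the filename embeds the
#' threshold); the rest are kept. A threshold of 0 processes all the data:
#' nothing is discarded and no overflow file is written.
#'
#' @param paths A `lineage_set`.
#' @param threshold Minimum count (>= 0).
#' @param workdir Directory for the overflow file.
#' @return A `filter_result`: list with `kept` (lineage_set), `discarded`
#'   (data.frame `unit`, `count`), `threshold`, `overflow_file` (`NULL` when
#'   threshold is 0).
#' @export
apply_filter <- function(paths, threshold, workdir = ".") {
  stopifnot(threshold >= 0)
  threshold <- as.integer(threshold)
  if (threshold == 0L) {
    res <- list(kept = paths,
                discarded = data.frame(unit = character(0), count = integer(0),
                                       stringsAsFactors = FALSE),
                threshold = 0L, overflow_file = NULL)
    return(structure(res, class = "filter_result"))
  }
  counts <- table(paths$species)
  low <- names(counts)[as.integer(counts) < threshold]
  keep_row <- !(paths$species %in% low)
  kept <- paths[keep_row, , drop = FALSE]
  class(kept) <- class(paths)
  discarded <- data.frame(unit = low,
                          count = as.integer(counts[low]),
                          stringsAsFactors = FALSE)
  discarded <- discarded[order(-discarded$count, discarded$unit), , drop = FALSE]
  rownames(discarded) <- NULL

  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  overflow <- file.path(workdir, sprintf("filtered_out_min%d.tsv", threshold))
  write_lines_lf(c("taxonomic_unit\tcount",
                   if (nrow(discarded)) sprintf("%s\t%d", discarded$unit,
                                                discarded$count)),
                 overflow)
  structure(list(kept = kept, discarded = discarded, threshold = threshold,
                 overflow_file = overflow),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> threshold %d: kept %d path(s), discarded %d unit(s) (%d paths)\n",
              x$threshold, nrow(x$kept), nrow(x$discarded), sum(x$discarded$count)))
  invisible(x)
}

#' Per-rank count series for the taxonomy scatter plot
#'
#' For each of the six ranks, counts paths per (taxon, parent-taxon) pair —
#' same-named taxa under different parents stay separate — so every rank's
#' counts sum to the number of input paths. Rows are ordered by rank, then
#' count descending, then taxon name.
#'
#' @param paths A `lineage_set`.
#' @return A `scatter_series`: data.frame with `rank`, `taxon`, `parent`
#'   (`"total"` at phylum level), `count`.
#' @export
build_scatter <- function(paths) {
  out <- lapply(seq_along(MAIN_RANKS), function(level) {
    taxon <- paths[[MAIN_RANKS[level]]]
    parent <- if (level == 1L) rep("total", nrow(paths))
              else paths[[MAIN_RANKS[level - 1L]]]
    if (!nrow(paths)) {
      return(data.frame(rank = character(0), taxon = character(0),
                        parent = character(0), count = integer(0),
                        stringsAsFactors = FALSE))
    }
    key <- paste(taxon, parent, sep = "\r")
    agg <- table(key)
    first <- match(names(agg), key)
    d <- data.frame(rank = MAIN_RANKS[level], taxon = taxon[first],
                    parent = parent[first], count = as.integer(agg),
                    stringsAsFactors = FALSE)
    d[order(-d$count, d$taxon), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("scatter_series", "data.frame"))
}

#' Hierarchical taxon-count tree for the sunburst plot
#'
#' Builds the six-level hierarchy of the input paths. Node ids are the full
#' `";"`-joined path prefix, so same-named taxa under different parents get
#' distinct nodes. Every internal node's count equals the sum of its
#' children's counts, and the level-1 counts sum to the number of paths.
#'
#' @param paths A `lineage_set`.
#' @return A `taxon_count_tree`: data.frame with `id`, `parent_id` (`""` at
#'   level 1), `label`, `level` (1-6), `count`.
#' @export
build_sunburst <- function(paths) {
  rows <- list()
  for (level in seq_along(MAIN_RANKS)) {
    prefix <- do.call(paste, c(unname(as.list(
      paths[MAIN_RANKS[seq_len(level)]])), sep = ";"))
    parent <- if (level == 1L) rep("", nrow(paths))
              else do.call(paste, c(unname(as.list(
                paths[MAIN_RANKS[seq_len(level - 1L)]])), sep = ";"))
    if (!nrow(paths)) next
    agg <- table(prefix)
    first <- match(names(agg), prefix)
    rows[[level]] <- data.frame(
      id = names(agg), parent_id = parent[first],
      label = paths[[MAIN_RANKS[level]]][first], level = level,
      count = as.integer(agg), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), parent_id = character(0),
               label = character(0), level = integer(0), count = integer(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$level, -out$count, out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("taxon_count_tree", "data.frame"))
}

#' Two-way world-map arrays from geographic references
#'
#' Coordinate-kind references are aggregated by identical position (lat/lon
#' rounded to 4 decimal places, merging trivially different encodings of one
#' site); country-kind references by country name. Each point carries a count
#' and a label concatenating the unique record labels (taxa/genes) seen
#' there. Marker metadata follows the map convention: green crosses for
#' coordinates, red circles for countries.
#'
#' @param georefs List of `geo_ref`s from [extract_geo()].
#' @param labels Optional character vector, one label per reference.
#' @return A `geo_arrays`: list with `coordinates` (data.frame `lat`, `lon`,
#'   `count`, `label`, `marker`) and `countries` (data.frame `country`,
#'   `count`, `label`, `marker`).
#' @export
build_worldmap <- function(georefs, labels = NULL) {
  labels <- labels %||% rep("", length(georefs))
  stopifnot(length(labels) == length(georefs))
  kinds <- vapply(georefs, function(g) g$kind, character(1))

  ci <- which(kinds == "coordinates")
  if (length(ci)) {
    lat <- round(vapply(georefs[ci], function(g) g$lat, numeric(1)), 4L)
    lon <- round(vapply(georefs[ci], function(g) g$lon, numeric(1)), 4L)
    key <- sprintf("%.4f,%.4f", lat, lon)
    coords <- aggregate_points(key, labels[ci],
                               data.frame(lat = lat, lon = lon))
    coords$marker <- "green-cross"
  } else {
    coords <- data.frame(lat = numeric(0), lon = numeric(0),
                         count = integer(0), label = character(0),
                         marker = character(0), stringsAsFactors = FALSE)
  }

  ki <- which(kinds == "country")
  if (length(ki)) {
    key <- vapply(georefs[ki], function(g) g$country_name, character(1))
    countries <- aggregate_points(key, labels[ki],
                                  data.frame(country = key))
    countries$marker <- "red-circle"
  } else {
    countries <- data.frame(country = character(0), count = integer(0),
                            label = character(0), marker = character(0),
                            stringsAsFactors = FALSE)
  }
  structure(list(coordinates = coords, countries = countries,
                 n_none = sum(kinds == "none")),
            class = "geo_arrays")
}

aggregate_points <- function(key, labels, extra) {
  agg <- table(key)
  first <- match(names(agg), key)
  lab <- vapply(names(agg), function(k) {
    u <- unique(labels[key == k])
    paste(u[nzchar(u)], collapse = "; ")
  }, character(1))
  out <- extra[first, , drop = FALSE]
  out$count <- as.integer(agg)
  out$label <- unname(lab)
  ord <- order(-out$count, names(agg))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.geo_arrays <- function(x, ...) {
  cat(sprintf("<geo_arrays> %d coordinate point(s), %d country point(s), %d record(s) without geography\n",
              nrow(x$coordinates), nrow(x$countries), x$n_none))
  invisible(x)
}
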