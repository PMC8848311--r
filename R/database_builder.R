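# Turns parsed records plus the taxonomy store into the reference-database
# deliverables: multi-FASTA, accession -> six-rank taxonomy TSV, and
# gene-frequency tables with a top-n bar-plot export.

#' Write records as multi-FASTA
#'
#' Header is `>{accession} {definition}`; sequences are wrapped at 70
#' columns. Duplicate accessions are written once (first occurrence wins).
#'
#' @param records List of `seq_record`s.
#' @param out Output path.
#' @return Number of records written (after accession dedup).
#' @export
write_fasta <- function(records, out) {
  accs <- vapply(records, function(r) r$accession, character(1))
  records <- records[!duplicated(accs)]
  lines <- unlist(lapply(records, function(r) {
    header <- sprintf(">%s %s", r$accession, r$definition)
    seq <- r$sequence
    if (!nzchar(seq)) return(header)
    starts <- seq.int(1L, nchar(seq), by = 70L)
    c(header, substring(seq, starts, pmin(starts + 69L, nchar(seq))))
  }), use.names = FALSE) %||% character(0)
  write_lines_lf(lines, out)
  length(records)
}

#' Write the accession-to-taxonomy TSV
#'
#' Each row is `accession<TAB>phylum;class;order;family;genus;species` — the
#' two-column mapping dialect that taxonomy-assignment platforms accept as a
#' reference taxonomy. A record's txid is resolved against the store; records
#' whose txid is missing or unknown fall back to an organism-name lookup
#' (when it resolves to a single taxon). Records resolvable by neither route
#' are flagged unresolved: they are counted, logged and left out of the file,
#' which keeps the mapping free of blank fields.
#'
#' @param records List of `seq_record`s.
#' @param table A `taxonomy_table`.
#' @param out Output path.
#' @return Named integer vector `c(written = , unresolved = )`;
#'   `written + unresolved` equals the number of input records. Unresolved
#'   accessions are attached as attribute `"unresolved_accessions"`.
#' @export
write_taxonomy_tsv <- function(records, table, out) {
  rows <- character(0)
  unresolved <- character(0)
  known <- names(table$txid_idx)
  for (r in records) {
    txid <- r$txid
    if (is.null(txid) || !as.character(txid) %in% known) {
      hits <- if (nzchar(r$organism %||% "")) name_to_txids(table, r$organism)
              else integer(0)
      txid <- if (length(hits) == 1L) hits else NULL
    }
    if (is.null(txid)) {
      unresolved <- c(unresolved, r$accession)
      next
    }
    rows <- c(rows, sprintf("%s\t%s", r$accession,
                            format(resolve_lineage(table, txid))))
  }
  if (length(unresolved)) {
    tx_warn(length(unresolved), " record(s) unresolved: ",
            paste(utils::head(unresolved, 5L), collapse = ", "))
  }
  write_lines_lf(rows, out)
  structure(c(written = length(rows), unresolved = length(unresolved)),
            unresolved_accessions = unresolved)
}

#' Gene-frequency survey over a record corpus
#'
#' Counts, for each gene name, the number of records carrying it. Counting is
#' per-record distinct (a record tagged twice with one gene counts it once)
#' and case-insensitive, with the first-seen spelling reported. Rows are
#' ordered by count descending, ties broken lexicographically.
#'
#' @param records List of `seq_record`s.
#' @return A `freq_table`: data.frame with `gene` and `count`, plus
#'   attributes `total_records` and `tagged_records` (records with >= 1 gene
#'   tag).
#' @export
gene_frequency <- function(records) {
  per_record <- lapply(records, function(r) unique(tolower(r$gene_names)))
  tagged <- sum(lengths(per_record) > 0L)
  all_lower <- unlist(per_record, use.names = FALSE)

  first_seen <- character(0)  # lower -> first-seen spelling
  for (r in records) {
    for (g in r$gene_names) {
      lg <- tolower(g)
      if (!lg %in% names(first_seen)) first_seen[lg] <- g
    }
  }

  if (!length(all_lower)) {
    tab <- data.frame(gene = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    counts <- table(all_lower)
    tab <- data.frame(gene = unname(first_seen[names(counts)]),
                      count = as.integer(counts), stringsAsFactors = FALSE)
    tab <- tab[order(-tab$count, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, class = c("freq_table", "data.frame"),
            total_records = length(records), tagged_records = tagged)
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d gene(s); %d of %d records tagged\n",
              nrow(x), attr(x, "tagged_records"), attr(x, "total_records")))
  print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Write a frequency table as two-column TSV
#'
#' @param freq A `freq_table`.
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
write_gene_table <- function(freq, out) {
  write_lines_lf(c("gene\tfrequency",
                   if (nrow(freq)) sprintf("%s\t%d", freq$gene, freq$count)),
                 out)
  invisible(out)
}

#' Export a bar plot of the most frequent genes as PNG
#'
#' Plots the first `min(n, nrow)` table rows in table order (count
#' descending, ties lexicographic), so inclusion at the cut is deterministic.
#'
#' @param freq A `freq_table`.
#' @param n Number of top genes (default 10).
#' @param out PNG path.
#' @return Invisibly, the data.frame of plotted bars (empty table: no file is
#'   written, a warning is logged, and `NULL` is returned).
#' @export
export_top_genes <- function(freq, n = 10L, out) {
  stopifnot(n >= 1L)
  if (!nrow(freq)) {
    tx_warn("empty gene table: no plot written")
    return(invisible(NULL))
  }
  top <- utils::head(as.data.frame(freq), n)
  grDevices::png(out, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(8, 5, 3, 1))
  graphics::barplot(top$count, names.arg = top$gene, las = 2,
                    col = "steelblue", border = NA,
                    ylab = "records", main = sprintf("Top %d genes", nrow(top)))
  invisible(top)
}
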