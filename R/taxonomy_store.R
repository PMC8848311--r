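# Local taxonomy store: load taxdump-dialect files and resolve any txid or
# scientific name to a standardized six-rank lineage.

#' Load a local taxonomy database from taxdump-dialect files
#'
#' Reads the NCBI taxdump dialect: fields separated by `"\t|\t"`, records
#' terminated by `"\t|"`. The nodes table supplies `txid`, `parent_txid` and
#' `rank`; the names table supplies scientific names (only rows whose name
#' class is `"scientific name"` are indexed).
#'
#' @param nodes_file Path to the nodes table (`nodes.dmp` dialect).
#' @param names_file Path to the names table (`names.dmp` dialect).
#' @return A `taxonomy_table` object: list with a `nodes` data.frame
#'   (`txid`, `parent_txid`, `rank`, `scientific_name`), an integer index by
#'   txid, a lower-cased name index, and the root txid.
#' @details The tree must be closed: every `parent_txid` must itself be a
#'   node, exactly one node is its own parent (the root), and parent links
#'   must be acyclic. Violations raise an integrity error listing the
#'   offending txids.
#' @export
load_taxdump <- function(nodes_file, names_file) {
  nd <- parse_dmp(nodes_file, min_fields = 3L)
  nm <- parse_dmp(names_file, min_fields = 4L)

  txid <- suppressWarnings(as.integer(nd[[1L]]))
  parent <- suppressWarnings(as.integer(nd[[2L]]))
  bad <- which(is.na(txid) | is.na(parent) | txid <= 0L | parent <= 0L)
  if (length(bad)) {
    stop(sprintf("parse error in '%s': non-numeric or non-positive txid at line %d",
                 nodes_file, bad[1L]), call. = FALSE)
  }
  rank <- nd[[3L]]

  # scientific names only
  sci <- nm[[4L]] == "scientific name"
  nm_txid <- suppressWarnings(as.integer(nm[[1L]][sci]))
  nm_name <- nm[[2L]][sci]
  sci_name <- nm_name[match(txid, nm_txid)]
  if (anyNA(sci_name)) {
    missing <- txid[is.na(sci_name)]
    stop(sprintf("integrity error: no scientific name for txid(s) %s",
                 paste(utils::head(missing, 10L), collapse = ", ")), call. = FALSE)
  }

  nodes <- data.frame(txid = txid, parent_txid = parent, rank = rank,
                      scientific_name = sci_name, stringsAsFactors = FALSE)
  new_taxonomy_table(nodes)
}

# Split taxdump records: strip the "\t|" terminator, then split on "\t|\t".
parse_dmp <- function(path, min_fields) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  body <- sub("\t\\|$", "", lines)
  parts <- strsplit(body, "\t|\t", fixed = TRUE)
  n <- lengths(parts)
  short <- which(n < min_fields)
  if (length(short)) {
    stop(sprintf("parse error in '%s' at line %d: expected >= %d fields, got %d",
                 path, short[1L], min_fields, n[short[1L]]), call. = FALSE)
  }
  cols <- lapply(seq_len(min_fields), function(i) {
    vapply(parts, function(p) trimws(p[[i]]), character(1))
  })
  cols
}

# Constructor: validates tree invariants and builds lookup indexes.
new_taxonomy_table <- function(nodes) {
  if (anyDuplicated(nodes$txid)) {
    dup <- nodes$txid[duplicated(nodes$txid)]
    stop(sprintf("integrity error: duplicated txid(s) %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  idx <- match(nodes$parent_txid, nodes$txid)
  orphan <- nodes$parent_txid[is.na(idx)]
  if (length(orphan)) {
    stop(sprintf("integrity error: parent txid(s) absent from nodes table: %s",
                 paste(unique(orphan), collapse = ", ")), call. = FALSE)
  }
  roots <- nodes$txid[nodes$txid == nodes$parent_txid]
  if (length(roots) != 1L) {
    stop(sprintf("integrity error: expected exactly 1 self-parented root, found %d (%s)",
                 length(roots), paste(roots, collapse = ", ")), call. = FALSE)
  }
  # acyclicity: every node must reach the root
  check_reaches_root(nodes, idx, roots)

  name_index <- split(nodes$txid, tolower(nodes$scientific_name))
  structure(
    list(nodes = nodes,
         parent_idx = idx,                     # row index of each node's parent
         txid_idx = stats::setNames(seq_len(nrow(nodes)), nodes$txid),
         name_index = name_index,
         root_txid = roots),
    class = "taxonomy_table"
  )
}

check_reaches_root <- function(nodes, parent_idx, root_txid) {
  n <- nrow(nodes)
  reached <- nodes$txid == root_txid
  for (i in seq_len(n)) {
    if (reached[i]) next
    path <- integer(0)
    j <- i
    steps <- 0L
    while (!reached[j]) {
      path <- c(path, j)
      j <- parent_idx[j]
      steps <- steps + 1L
      if (steps > n) {
        stop(sprintf("integrity error: cycle in parent links involving txid %d",
                     nodes$txid[i]), call. = FALSE)
      }
    }
    reached[path] <- TRUE
  }
  invisible(TRUE)
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat(sprintf("<taxonomy_table> %d nodes, root txid %d\n",
              nrow(x$nodes), x$root_txid))
  rk <- sort(table(x$nodes$rank), decreasing = TRUE)
  cat("  ranks:", paste(sprintf("%s (%d)", names(rk), rk), collapse = ", "), "\n")
  invisible(x)
}

node_row <- function(table, txid) {
  i <- table$txid_idx[as.character(txid)]
  if (is.na(i)) stop(sprintf("unknown txid: %s", txid), call. = FALSE)
  unname(i)
}

# Ancestor-or-self row indices from a node up to the root (self first).
ancestor_chain <- function(table, txid) {
  i <- node_row(table, txid)
  chain <- i
  while (table$nodes$parent_txid[i] != table$nodes$txid[i]) {
    i <- table$parent_idx[i]
    chain <- c(chain, i)
  }
  chain
}

#' Resolve a txid to its standardized six-rank lineage
#'
#' Walks the ancestor-or-self chain and, for each of the six main ranks
#' (phylum, class, order, family, genus, species), takes the scientific name
#' of the nearest ancestor-or-self carrying that rank label
#' (case-insensitively). A rank absent from the chain is fallback-filled with
#' the scientific name of the nearest named ancestor-or-self — the queried
#' node itself, since every node carries a scientific name — so serialized
#' paths never contain empty fields.
#'
#' @param table A `taxonomy_table` from [load_taxdump()].
#' @param txid Integer txid present in the table.
#' @return A `lineage_path` object: list with `txid`, `source_rank`, the six
#'   rank fields, and the node's scientific name.
#' @export
resolve_lineage <- function(table, txid) {
  chain <- ancestor_chain(table, txid)
  ranks <- tolower(table$nodes$rank[chain])
  names_ <- table$nodes$scientific_name[chain]
  fallback <- names_[1L]
  vals <- vapply(MAIN_RANKS, function(r) {
    hit <- which(ranks == r)
    if (length(hit)) names_[hit[1L]] else fallback
  }, character(1))
  structure(
    list(txid = as.integer(txid),
         source_rank = table$nodes$rank[chain[1L]],
         scientific_name = names_[1L],
         ranks = vals),
    class = "lineage_path"
  )
}

#' Serialize a lineage path
#'
#' @param x A `lineage_path`.
#' @param ... Unused.
#' @return The six rank fields joined by `";"`, no surrounding whitespace.
#' @export
format.lineage_path <- function(x, ...) paste(x$ranks, collapse = ";")

#' @export
print.lineage_path <- function(x, ...) {
  cat(sprintf("<lineage_path> txid %d (%s)\n  %s\n",
              x$txid, x$source_rank, format(x)))
  invisible(x)
}

#' @export
as.character.lineage_path <- function(x, ...) format(x)

#' Look up txids by scientific name
#'
#' Case-insensitive exact match against the store's scientific names.
#' Homonyms (one name shared by several nodes) all come back.
#'
#' @param table A `taxonomy_table`.
#' @param name Scientific name to look up.
#' @return Integer vector of matching txids in ascending order; empty when
#'   unmatched (not an error).
#' @export
name_to_txids <- function(table, name) {
  hits <- table$name_index[[tolower(trimws(name))]]
  if (is.null(hits)) integer(0) else sort(as.integer(hits))
}

#' Convert a batch of txids or names from a TSV/CSV file
#'
#' The identifier is taken from the first column; the delimiter is sniffed
#' from the extension (`.csv` comma, otherwise tab). Unresolvable or
#' ambiguous inputs produce a flagged row instead of aborting the batch.
#'
#' @param table A `taxonomy_table`.
#' @param input_file Path to the TSV/CSV file.
#' @param direction `"txid_to_ranks"` or `"name_to_txid"`.
#' @return A data.frame with one row per input row, in input order:
#'   `input`, `status` (`resolved`/`unresolved`/`ambiguous`), `txid`
#'   (semicolon-joined candidates when ambiguous), `rank`, `lineage`
#'   (six-rank `";"` path).
#' @export
convert_batch <- function(table, input_file,
                          direction = c("txid_to_ranks", "name_to_txid")) {
  direction <- match.arg(direction)
  if (!file.exists(input_file)) {
    stop(sprintf("cannot read input file: '%s'", input_file), call. = FALSE)
  }
  lines <- readLines(input_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    tx_warn("empty conversion input: ", input_file)
    return(empty_conversion_df())
  }
  delim <- sniff_delim(input_file)
  inputs <- vapply(strsplit(lines, delim, fixed = TRUE),
                   function(p) trimws(p[[1L]]), character(1))
  rows <- lapply(inputs, function(inp) convert_one(table, inp, direction))
  do.call(rbind, rows)
}

empty_conversion_df <- function() {
  data.frame(input = character(0), status = character(0), txid = character(0),
             rank = character(0), lineage = character(0),
             stringsAsFactors = FALSE)
}

convert_one <- function(table, input, direction) {
  row <- function(status, txid = "", rank = "", lineage = "") {
    data.frame(input = input, status = status, txid = txid, rank = rank,
               lineage = lineage, stringsAsFactors = FALSE)
  }
  if (direction == "txid_to_ranks") {
    txid <- suppressWarnings(as.integer(input))
    if (is.na(txid) || !as.character(txid) %in% names(table$txid_idx)) {
      return(row("unresolved"))
    }
    lp <- resolve_lineage(table, txid)
    return(row("resolved", as.character(txid), lp$source_rank, format(lp)))
  }
  hits <- name_to_txids(table, input)
  if (!length(hits)) return(row("unresolved"))
  if (length(hits) > 1L) {
    return(row("ambiguous", paste(hits, collapse = ";")))
  }
  lp <- resolve_lineage(table, hits)
  row("resolved", as.character(hits), lp$source_rank, format(lp))
}

#' Write conversion rows as TSV
#'
#' @param rows Data.frame from [convert_batch()].
#' @param out Output path.
#' @return `out`, invisibly.
#' @export
write_conversion_tsv <- function(rows, out) {
  header <- paste(names(rows), collapse = "\t")
  body <- do.call(paste, c(unname(as.list(rows)), sep = "\t"))
  write_lines_lf(c(header, body), out)
  invisible(out)
}
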