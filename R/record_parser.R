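# GenBank-dialect flat-file parsing: one seq_record per "//"-terminated
# block, with accession, organism/txid, sequence, gene qualifiers and the
# source feature's geographic metadata.

# Split lines into "//"-terminated record blocks. Each returned element is a
# single string (lines rejoined with "\n", terminator included).
split_records <- function(lines) {
  lines <- lines[!(seq_along(lines) > max(which(nzchar(lines)), 0L))]
  if (!length(lines)) return(list())
  ends <- which(trimws(lines) == "//")
  if (!length(ends) || max(ends) < length(lines)) {
    tail_lines <- if (length(ends)) lines[(max(ends) + 1L):length(lines)] else lines
    acc <- grep("^ACCESSION", tail_lines, value = TRUE)
    ctx <- if (length(acc)) trimws(sub("^ACCESSION", "", acc[1L])) else "unknown accession"
    stop(sprintf("truncated record (missing '//' terminator) near %s", ctx),
         call. = FALSE)
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(s, e) paste(lines[s:e], collapse = "\n"),
         starts, ends, SIMPLIFY = FALSE)
}

# Versioned accession of one record block (string form), for merging.
record_accession <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  v <- grep("^VERSION", lines, value = TRUE)
  if (length(v)) return(strsplit(trimws(sub("^VERSION", "", v[1L])), "\\s+")[[1]][1])
  a <- grep("^ACCESSION", lines, value = TRUE)
  if (length(a)) return(strsplit(trimws(sub("^ACCESSION", "", a[1L])), "\\s+")[[1]][1])
  stop("record without ACCESSION/VERSION line", call. = FALSE)
}

#' Parse GenBank-dialect records
#'
#' @param x Path to a flat file, or a character vector of its lines.
#' @return A list of `seq_record` objects, each with `accession` (versioned),
#'   `definition`, `organism`, `txid` (from the source feature's
#'   `/db_xref="taxon:N"`, `NULL` when absent), `sequence`, `gene_names`
#'   (every feature's `/gene` qualifier, first-appearance order, no
#'   duplicates), `country_raw` and `lat_lon_raw` (`NULL` when absent).
#'   A record missing its `"//"` terminator is a parse error.
#' @export
parse_records <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  blocks <- split_records(lines)
  recs <- lapply(blocks, parse_one_record)
  accs <- vapply(recs, function(r) r$accession, character(1))
  if (anyDuplicated(accs)) {
    tx_warn("duplicate accessions in corpus: ",
            paste(unique(accs[duplicated(accs)]), collapse = ", "))
  }
  recs
}

parse_one_record <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]

  definition <- read_keyword(lines, "DEFINITION")
  accession <- record_accession(block)

  quals <- extract_qualifiers(lines)
  txid <- NULL
  taxon <- grep("^taxon:", quals$db_xref, value = TRUE)
  if (length(taxon)) txid <- as.integer(sub("^taxon:", "", taxon[1L]))

  genes <- unique(quals$gene %||% character(0))

  org_start <- grep("^ORIGIN", lines)
  sequence <- ""
  if (length(org_start)) {
    seq_lines <- lines[seq.int(org_start[1L] + 1L, length(lines))]
    seq_lines <- seq_lines[trimws(seq_lines) != "//"]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  structure(
    list(accession = accession,
         definition = definition,
         organism = if (length(quals$organism)) quals$organism[1L] else
           read_organism_line(lines),
         txid = txid,
         sequence = sequence,
         gene_names = genes,
         country_raw = if (length(quals$country)) quals$country[1L] else NULL,
         lat_lon_raw = if (length(quals$lat_lon)) quals$lat_lon[1L] else NULL),
    class = "seq_record"
  )
}

# Keyword value, joining continuation lines (10-space indent).
read_keyword <- function(lines, keyword) {
  i <- grep(paste0("^", keyword), lines)
  if (!length(i)) return("")
  vals <- trimws(sub(paste0("^", keyword), "", lines[i[1L]]))
  j <- i[1L] + 1L
  while (j <= length(lines) && grepl("^ {10,}", lines[j]) &&
         !grepl("^\\s*/", lines[j])) {
    vals <- paste(vals, trimws(lines[j]))
    j <- j + 1L
  }
  vals
}

read_organism_line <- function(lines) {
  i <- grep("^\\s+ORGANISM", lines)
  if (!length(i)) return("")
  trimws(sub("^\\s+ORGANISM", "", lines[i[1L]]))
}

# All /qualifier="value" pairs in the FEATURES section (values may span
# lines). Returned as a list of character vectors keyed by qualifier name.
extract_qualifiers <- function(lines) {
  feat <- grep("^FEATURES", lines)
  if (!length(feat)) return(list())
  end <- grep("^(ORIGIN|CONTIG)", lines)
  end <- if (length(end)) end[1L] - 1L else length(lines)
  if (end <= feat[1L]) return(list())
  flines <- lines[(feat[1L] + 1L):end]

  # join continuation lines of quoted qualifier values
  joined <- character(0)
  for (ln in flines) {
    open <- length(joined) &&
      grepl("^\\s*/[A-Za-z_]+=\"", joined[length(joined)]) &&
      !grepl("\"\\s*$", joined[length(joined)])
    if (open) {
      joined[length(joined)] <- paste0(joined[length(joined)], " ", trimws(ln))
    } else {
      joined <- c(joined, ln)
    }
  }
  qlines <- grep("^\\s*/[A-Za-z_]+=", joined, value = TRUE)
  keys <- sub("^\\s*/([A-Za-z_]+)=.*$", "\\1", qlines)
  vals <- sub("^\\s*/[A-Za-z_]+=", "", qlines)
  vals <- sub("^\"", "", sub("\"\\s*$", "", vals))
  split(vals, keys)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  %s (txid %s), %d bp, genes: %s\n",
              x$accession, x$organism %||% "?",
              x$txid %||% "?", nchar(x$sequence),
              if (length(x$gene_names)) paste(x$gene_names, collapse = ",")
              else "-"))
  invisible(x)
}

#' Parse an INSDC lat_lon qualifier string
#'
#' Accepts the `"<deg> N|S <deg> E|W"` dialect with optional decimals.
#' North/East are positive, South/West negative.
#'
#' @param s The raw string.
#' @return `c(lat, lon)` in decimal degrees, or `NULL` when unparseable.
#' @export
parse_lat_lon <- function(s) {
  if (is.null(s)) return(NULL)
  pat <- "^\\s*([0-9]+(?:\\.[0-9]+)?) ([NS]) ([0-9]+(?:\\.[0-9]+)?) ([EW])\\s*$"
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (!length(m)) return(NULL)
  lat <- as.numeric(m[2]) * if (m[3] == "S") -1 else 1
  lon <- as.numeric(m[4]) * if (m[5] == "W") -1 else 1
  if (abs(lat) > 90 || abs(lon) > 180) return(NULL)
  c(lat = lat, lon = lon)
}

#' Classify a record's geographic reference
#'
#' A parseable `lat_lon` qualifier wins; otherwise the country qualifier's
#' text before the first `":"` (region detail stripped); otherwise kind
#' `"none"`. Never raises: an unparseable `lat_lon` logs a warning and falls
#' through to the country.
#'
#' @param record A `seq_record`.
#' @return A `geo_ref`: list with `kind`
#'   (`"coordinates"`/`"country"`/`"none"`), `lat`, `lon`, `country_name`.
#' @export
extract_geo <- function(record) {
  if (!is.null(record$lat_lon_raw)) {
    ll <- parse_lat_lon(record$lat_lon_raw)
    if (!is.null(ll)) {
      return(structure(list(kind = "coordinates", lat = unname(ll["lat"]),
                            lon = unname(ll["lon"]), country_name = NULL),
                       class = "geo_ref"))
    }
    tx_warn("unparseable lat_lon '", record$lat_lon_raw, "' on ",
            record$accession)
  }
  if (!is.null(record$country_raw) && nzchar(trimws(record$country_raw))) {
    country <- trimws(strsplit(record$country_raw, ":", fixed = TRUE)[[1]][1])
    return(structure(list(kind = "country", lat = NULL, lon = NULL,
                          country_name = country), class = "geo_ref"))
  }
  structure(list(kind = "none", lat = NULL, lon = NULL, country_name = NULL),
            class = "geo_ref")
}
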