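# Query construction, batched retrieval planning, and download/merge against
# an e-utilities-style endpoint through a pluggable transport.

#' Build a query specification
#'
#' @param organism Organism term: a scientific name or a numeric txid
#'   (integer or all-digit string). Optional.
#' @param genes Character vector of gene names. Optional.
#' @param extra Raw query text appended verbatim. Optional.
#' @return A `query_spec` object. At least one component must be non-empty.
#' @export
query_spec <- function(organism = NULL, genes = character(0), extra = NULL) {
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  if (is.null(organism) && !length(genes) && is.null(extra)) {
    stop("empty query: supply an organism, gene term(s), or extra terms",
         call. = FALSE)
  }
  structure(list(organism = organism, genes = genes, extra = extra),
            class = "query_spec")
}

#' Render a query specification as an e-utilities search string
#'
#' A numeric organism term `N` renders as `txidN[ORGN]`, a name as
#' `name[ORGN]`; each gene term renders as `g[gene]`; terms are joined with
#' `" AND "`; extra terms are appended verbatim.
#'
#' @param spec A `query_spec`.
#' @return The query string.
#' @examples
#' build_query(query_spec(organism = 8049))           # "txid8049[ORGN]"
#' build_query(query_spec(organism = 7742, genes = "ACE2"))
#' @export
build_query <- function(spec) {
  stopifnot(inherits(spec, "query_spec"))
  terms <- character(0)
  if (!is.null(spec$organism)) {
    org <- trimws(as.character(spec$organism))
    terms <- if (grepl("^[0-9]+$", org)) {
      sprintf("txid%s[ORGN]", org)
    } else {
      sprintf("%s[ORGN]", org)
    }
  }
  terms <- c(terms, sprintf("%s[gene]", spec$genes))
  if (!is.null(spec$extra)) terms <- c(terms, spec$extra)
  paste(terms, collapse = " AND ")
}

#' Plan retrieval windows for a batched download
#'
#' Requests smaller than the batch size go out as a single query; larger
#' result sets are split into contiguous windows of at most `batch_size`
#' records (default 2,500).
#'
#' @param total_count Total number of matching records (>= 0).
#' @param batch_size Maximum records per window (>= 1).
#' @return A `batch_plan`: data.frame with `offset` and `size`, contiguous
#'   from 0 and covering `total_count` exactly; zero rows when
#'   `total_count == 0`.
#' @export
plan_batches <- function(total_count, batch_size = 2500L) {
  total_count <- as.integer(total_count)
  batch_size <- as.integer(batch_size)
  if (is.na(total_count) || total_count < 0L) {
    stop("total_count must be >= 0", call. = FALSE)
  }
  if (is.na(batch_size) || batch_size < 1L) {
    stop("batch_size must be >= 1", call. = FALSE)
  }
  if (total_count == 0L) {
    plan <- data.frame(offset = integer(0), size = integer(0))
  } else {
    offsets <- seq.int(0L, total_count - 1L, by = batch_size)
    sizes <- pmin(batch_size, total_count - offsets)
    plan <- data.frame(offset = offsets, size = sizes)
  }
  structure(plan, class = c("batch_plan", "data.frame"),
            total_count = total_count, batch_size = batch_size)
}

#' Download all records matching a query and merge them into one file
#'
#' Searches through the transport, plans windows with [plan_batches()],
#' fetches each window into a temporary per-window file under `workdir`, then
#' merges the temporaries in window order into `merged_records.gb`.
#' Temporaries are removed on success and retained on failure so a rerun
#' resumes from completed windows. Duplicate accessions across pages are kept
#' once (first occurrence wins), so the merged file is independent of
#' `batch_size`.
#'
#' @param transport A transport (see [fixture_transport()],
#'   [entrez_transport()]).
#' @param spec A `query_spec`.
#' @param workdir Writable directory for temporaries and the merged file.
#' @param batch_size Window size (default 2,500).
#' @param retries Attempts per window before failing (default 3).
#' @return Path of the merged raw-record file. Zero hits yield an empty file
#'   and a warning log, not an error.
#' @export
run_download <- function(transport, spec, workdir, batch_size = 2500L,
                         retries = 3L) {
  stopifnot(inherits(spec, "query_spec"))
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  query <- build_query(spec)

  first <- transport$search(query, offset = 0L, limit = 0L)
  total <- first$total_count
  out <- file.path(workdir, "merged_records.gb")
  if (total == 0L) {
    tx_warn("query matched zero records: ", query)
    write_lines_lf(character(0), out)
    return(out)
  }

  plan <- plan_batches(total, batch_size)
  tmpfiles <- file.path(workdir,
                        sprintf("window_%05d.gb.tmp", seq_len(nrow(plan))))
  for (w in seq_len(nrow(plan))) {
    if (file.exists(tmpfiles[w])) next  # resume: window already fetched
    fetch_window(transport, query, plan$offset[w], plan$size[w],
                 tmpfiles[w], retries, w)
  }

  merge_windows(tmpfiles, out)
  unlink(tmpfiles)
  out
}

fetch_window <- function(transport, query, offset, size, tmpfile, retries, w) {
  for (attempt in seq_len(retries)) {
    res <- tryCatch({
      page <- transport$search(query, offset = offset, limit = size)
      raw <- transport$fetch(page$ids)
      tmp <- paste0(tmpfile, ".part")
      write_lines_lf(strsplit(raw, "\n", fixed = TRUE)[[1]] %||% character(0),
                     tmp)
      file.rename(tmp, tmpfile)
      TRUE
    }, error = function(e) e)
    if (isTRUE(res)) return(invisible())
    if (attempt < retries) {
      backoff <- getOption("taxplorer.backoff_base", 0.1) * 2^(attempt - 1L)
      Sys.sleep(backoff)
    } else {
      stop(sprintf(
        "download failed on window %d (offset %d, size %d) after %d attempts: %s",
        w, offset, size, retries, conditionMessage(res)), call. = FALSE)
    }
  }
}

# Concatenate per-window files in order, keeping the first occurrence of each
# accession (records are "//"-terminated GenBank-dialect blocks).
merge_windows <- function(tmpfiles, out) {
  seen <- character(0)
  blocks <- character(0)
  for (f in tmpfiles) {
    lines <- readLines(f, warn = FALSE)
    if (!length(lines)) next
    recs <- split_records(lines)
    for (rec in recs) {
      acc <- record_accession(rec)
      if (acc %in% seen) next
      seen <- c(seen, acc)
      blocks <- c(blocks, rec)
    }
  }
  write_lines_lf(blocks, out)
  invisible(out)
}

#' Token-bucket rate limiter
#'
#' Returns a function that blocks (via `sleeper`) so that calls never exceed
#' `rate` per second. The clock and sleeper are injectable so the ceiling can
#' be asserted without wall-clock waits.
#'
#' @param rate Maximum requests per second (> 0).
#' @param clock Function returning the current time in seconds.
#' @param sleeper Function taking a duration in seconds.
#' @return A zero-argument function to call before each request; it returns
#'   the (possibly delayed) dispatch time.
#' @export
rate_limiter <- function(rate, clock = function() as.numeric(Sys.time()),
                         sleeper = Sys.sleep) {
  stopifnot(rate > 0)
  min_gap <- 1 / rate
  last <- -Inf
  function() {
    now <- clock()
    wait <- (last + min_gap) - now
    if (wait > 0) {
      sleeper(wait)
      now <- now + wait
    }
    last <<- now
    now
  }
}
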