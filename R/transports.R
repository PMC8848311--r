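# Transports implement the retrieval contract:
#   search(query, offset, limit) -> list(total_count, ids)
#   fetch(ids)                   -> raw GenBank-dialect text
# The fixture transport replays a local corpus deterministically; the live
# transport talks to an e-utilities endpoint under a request-rate ceiling.

#' Fixture transport over a local record corpus
#'
#' Serves canned search/fetch responses from a GenBank-dialect file so the
#' whole pipeline runs offline and deterministically. Query strings built by
#' [build_query()] are evaluated against the corpus: `txidN[ORGN]` and
#' `name[ORGN]` match a record's source taxon (by subtree when a
#' `taxonomy_table` is supplied, exactly otherwise), `g[gene]` matches the
#' record's gene qualifiers case-insensitively, and `AND`-joined terms all
#' have to hold. Ids are returned in corpus order.
#'
#' @param records_file Path to a GenBank-dialect flat file.
#' @param taxonomy Optional `taxonomy_table` enabling subtree matching of
#'   organism terms.
#' @return A transport: list with `search` and `fetch` functions.
#' @export
fixture_transport <- function(records_file, taxonomy = NULL) {
  lines <- readLines(records_file, warn = FALSE)
  blocks <- split_records(lines)
  recs <- parse_records(lines)
  ids <- vapply(recs, function(r) r$accession, character(1))
  names(blocks) <- ids

  ancestors <- NULL
  if (!is.null(taxonomy)) {
    txids <- unique(stats::na.omit(vapply(
      recs, function(r) r$txid %||% NA_integer_, integer(1))))
    txids <- txids[as.character(txids) %in% names(taxonomy$txid_idx)]
    ancestors <- lapply(stats::setNames(txids, txids), function(tx) {
      taxonomy$nodes$txid[ancestor_chain(taxonomy, tx)]
    })
  }

  match_term <- function(term, rec) {
    if (grepl("\\[ORGN\\]$", term)) {
      org <- sub("\\[ORGN\\]$", "", term)
      if (grepl("^txid[0-9]+$", org)) {
        target <- as.integer(sub("^txid", "", org))
      } else if (!is.null(taxonomy)) {
        hit <- name_to_txids(taxonomy, org)
        if (!length(hit)) return(FALSE)
        target <- hit[1L]
      } else {
        return(identical(tolower(rec$organism %||% ""), tolower(org)))
      }
      if (is.null(rec$txid)) return(FALSE)
      if (is.null(ancestors)) return(rec$txid == target)
      chain <- ancestors[[as.character(rec$txid)]] %||% rec$txid
      target %in% chain
    } else if (grepl("\\[gene\\]$", term)) {
      g <- tolower(sub("\\[gene\\]$", "", term))
      g %in% tolower(rec$gene_names)
    } else {
      # free-text terms: match against the definition line
      grepl(tolower(term), tolower(rec$definition %||% ""), fixed = TRUE)
    }
  }

  matching_ids <- function(query) {
    terms <- strsplit(query, " AND ", fixed = TRUE)[[1]]
    keep <- vapply(recs, function(r) all(vapply(terms, match_term, logical(1),
                                                rec = r)), logical(1))
    ids[keep]
  }

  list(
    search = function(query, offset = 0L, limit = 0L) {
      hits <- matching_ids(query)
      page <- if (limit > 0L && length(hits)) {
        hits[seq.int(offset + 1L, min(offset + limit, length(hits)))]
      } else {
        character(0)
      }
      list(total_count = length(hits), ids = page)
    },
    fetch = function(ids_wanted) {
      paste(unlist(blocks[ids_wanted], use.names = FALSE), collapse = "\n")
    }
  )
}

#' Wrap a transport so chosen windows fail (for failure-path testing)
#'
#' @param transport The transport to wrap.
#' @param fail_offsets Search offsets at which `search` raises.
#' @param persistent If `TRUE` the failure repeats on retries.
#' @return A transport with the same contract.
#' @export
failing_transport <- function(transport, fail_offsets, persistent = TRUE) {
  failed <- integer(0)
  list(
    search = function(query, offset = 0L, limit = 0L) {
      if (limit > 0L && offset %in% fail_offsets) {
        if (persistent || !(offset %in% failed)) {
          failed <<- c(failed, offset)
          stop(sprintf("injected transport failure at offset %d", offset),
               call. = FALSE)
        }
      }
      transport$search(query, offset, limit)
    },
    fetch = transport$fetch
  )
}

#' Live e-utilities transport
#'
#' Talks to an NCBI-style esearch/efetch endpoint over HTTP using base-R url
#' connections, under a token-bucket request-rate ceiling (published endpoint
#' etiquette: 3 requests/s without an API key, 10 with). Transient failures
#' are retried by [run_download()].
#'
#' @param email Contact e-mail (required by endpoint etiquette).
#' @param api_key Optional API key.
#' @param rate_limit Requests per second; defaults to 3, or 10 with a key.
#' @param base_url Endpoint base URL; override to point at a local stand-in.
#' @param db Target database (nucleotide).
#' @return A transport: list with `search` and `fetch`.
#' @export
entrez_transport <- function(email, api_key = NULL, rate_limit = NULL,
                             base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils",
                             db = "nuccore") {
  if (missing(email) || !nzchar(email)) {
    stop("a contact e-mail is required for the live transport", call. = FALSE)
  }
  rate_limit <- rate_limit %||% if (is.null(api_key)) 3 else 10
  throttle <- rate_limiter(rate_limit)
  common <- c(email = email, tool = "taxplorer",
              if (!is.null(api_key)) c(api_key = api_key))

  get_url <- function(path, params) {
    params <- c(params, common)
    qs <- paste(sprintf("%s=%s", names(params),
                        vapply(params, utils::URLencode, character(1),
                               reserved = TRUE)),
                collapse = "&")
    throttle()
    con <- url(sprintf("%s/%s?%s", base_url, path, qs), open = "rb")
    on.exit(close(con))
    paste(readLines(con, warn = FALSE), collapse = "\n")
  }

  list(
    search = function(query, offset = 0L, limit = 0L) {
      xml <- get_url("esearch.fcgi",
                     c(db = db, term = query, retstart = offset,
                       retmax = limit))
      total <- as.integer(sub(".*<Count>([0-9]+)</Count>.*", "\\1", xml))
      ids <- regmatches(xml, gregexpr("<Id>[0-9]+</Id>", xml))[[1]]
      list(total_count = total, ids = gsub("</?Id>", "", ids))
    },
    fetch = function(ids) {
      get_url("efetch.fcgi",
              c(db = db, id = paste(ids, collapse = ","), rettype = "gb",
                retmode = "text"))
    }
  )
}
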