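# Internal helpers shared across modules.

MAIN_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' @keywords internal
tx_log <- function(..., level = "INFO") {
  if (identical(getOption("taxplorer.quiet", FALSE), TRUE)) return(invisible())
  message(sprintf("[%s] %s", level, paste0(...)))
  invisible()
}

tx_warn <- function(...) tx_log(..., level = "WARN")

# Delimiter from file extension: ".csv" -> comma, everything else -> tab.
sniff_delim <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

# Write lines with "\n" endings regardless of platform, so outputs are
# byte-identical across runs and OSes.
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
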