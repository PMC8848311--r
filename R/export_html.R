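# Standalone HTML export: each plot dataset is embedded verbatim as a JSON
# <script> block (machine-recoverable via read_plot_html) and rendered
# offline by a small inline SVG/table script — no external assets.

#' Export a plot dataset as standalone HTML
#'
#' Writes a self-contained page: the dataset from [build_scatter()],
#' [build_sunburst()] or [build_worldmap()] is embedded as JSON inside a
#' `<script type="application/json">` block, and a small inline script
#' renders it (bar/table views) so the file opens offline. Counts remain
#' machine-recoverable from the file via [read_plot_html()].
#'
#' @param plot_data A `scatter_series`, `taxon_count_tree` or `geo_arrays`.
#' @param out Output path.
#' @param title Page title.
#' @return `out`, invisibly. Empty datasets export a valid page with an empty
#'   figure and a warning log.
#' @export
export_html <- function(plot_data, out, title = NULL) {
  type <- if (inherits(plot_data, "scatter_series")) "scatter"
          else if (inherits(plot_data, "taxon_count_tree")) "sunburst"
          else if (inherits(plot_data, "geo_arrays")) "worldmap"
          else stop("unsupported plot data of class ",
                    paste(class(plot_data), collapse = "/"), call. = FALSE)
  title <- title %||% sprintf("taxplorer %s", type)

  payload <- switch(type,
    scatter = list(type = "scatter", data = strip_df(plot_data)),
    sunburst = list(type = "sunburst", data = strip_df(plot_data)),
    worldmap = list(type = "worldmap",
                    data = list(coordinates = strip_df(plot_data$coordinates),
                                countries = strip_df(plot_data$countries),
                                n_none = plot_data$n_none)))
  empty <- switch(type,
    scatter = , sunburst = nrow(plot_data) == 0L,
    worldmap = nrow(plot_data$coordinates) + nrow(plot_data$countries) == 0L)
  if (empty) tx_warn("exporting empty ", type, " figure to ", out)

  json <- jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, null = "null")
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>body{font-family:sans-serif;margin:2em}svg{background:#fafafa}",
    "table{border-collapse:collapse}td,th{border:1px solid #ccc;padding:2px 8px}</style>",
    "</head><body>",
    sprintf("<h1>%s</h1>", html_escape(title)),
    "<div id=\"figure\"></div>",
    sprintf("<script id=\"taxplorer-data\" type=\"application/json\">%s</script>",
            json),
    inline_renderer_js(),
    "</body></html>")
  write_lines_lf(html, out)
  invisible(out)
}

strip_df <- function(d) {
  d <- as.data.frame(d)
  rownames(d) <- NULL
  d
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

inline_renderer_js <- function() {
  paste0("<script>(function(){",
    "var p=JSON.parse(document.getElementById('taxplorer-data').textContent);",
    "var el=document.getElementById('figure');",
    "function tbl(cols){var ks=Object.keys(cols);var n=ks.length?[].concat(cols[ks[0]]).length:0;",
    "var h='<table><tr>'+ks.map(function(k){return '<th>'+k+'</th>';}).join('')+'</tr>';",
    "for(var i=0;i<n;i++){h+='<tr>'+ks.map(function(k){var v=[].concat(cols[k])[i];",
    "return '<td>'+(v===null?'':v)+'</td>';}).join('')+'</tr>';}",
    "return h+'</table>';}",
    "if(p.type==='worldmap'){el.innerHTML='<h2>Coordinates (green crosses)</h2>'+tbl(p.data.coordinates)",
    "+'<h2>Countries (red circles)</h2>'+tbl(p.data.countries);}",
    "else{el.innerHTML=tbl(p.data);}",
    "})();</script>")
}

#' Recover the dataset embedded in an exported HTML file
#'
#' @param path File written by [export_html()].
#' @return List with `type` and `data` (data.frame, or list of data.frames
#'   for world maps) equal to what was exported.
#' @export
read_plot_html <- function(path) {
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(html, regexec(
    "<script id=\"taxplorer-data\" type=\"application/json\">(.*?)</script>",
    html))[[1]]
  if (length(m) < 2L) stop("no embedded plot data found in ", path, call. = FALSE)
  p <- jsonlite::fromJSON(m[2])
  rebuild <- function(cols) as.data.frame(cols, stringsAsFactors = FALSE)
  if (p$type == "worldmap") {
    p$data$coordinates <- rebuild(p$data$coordinates)
    p$data$countries <- rebuild(p$data$countries)
  } else {
    p$data <- rebuild(p$data)
  }
  p
}
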