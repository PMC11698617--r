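# Static report bundle: TSV tables plus a single self-contained HTML index.

.htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.htmlTable <- function(df, maxRows = 200) {
  if (is.null(df) || !nrow(df)) return("<p><em>empty</em></p>")
  df <- utils::head(df, maxRows)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 6, format = "g")
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  head <- paste0("<tr>", paste0("<th>", .htmlEscape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- apply(fmt, 1, function(r)
    paste0("<tr>", paste0("<td>", .htmlEscape(r), "</td>", collapse = ""),
           "</tr>"))
  paste0("<table>", head, paste(body, collapse = "\n"), "</table>")
}

#' Render the report bundle
#'
#' Writes the pipeline results as a set of TSV tables (patient overview, age
#' summary, survival listing, all evaluations, ranked candidates, per-set
#' summary, per-set overview, KM curve data), a \code{config.json} echo of
#' the run configuration with a tool-version log, and a single static
#' \code{index.html} collating all sections.  The report renders even when
#' no candidate was found.
#'
#' @param result a \code{\link{runPipeline}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
renderReport <- function(result, dir) {
  stopifnot(inherits(result, "markerPipelineResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(
    w(result$overview$composition, "patient_overview.tsv"),
    w(result$overview$ageSummary, "age_summary.tsv"),
    w(result$overview$survivalListing, "survival_listing.tsv"),
    w(result$sets, "sets.tsv"),
    w(result$evaluations, "evaluations.tsv"),
    w(result$ranked, "ranked_candidates.tsv"),
    w(result$summary, "set_summary.tsv"),
    w(result$kmCurves, "km_curves.tsv"))

  versions <- list(
    r = R.version.string,
    txmarker = as.character(utils::packageVersion("txmarker")),
    survival = as.character(utils::packageVersion("survival")))
  cfgPath <- file.path(dir, "config.json")
  jsonlite::write_json(list(config = result$config, versions = versions),
                       cfgPath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, cfgPath)

  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Treatment-success biomarker report</title>",
    "<style>body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:2px 6px;font-size:90%}h2{margin-top:1.5em}</style>",
    "</head><body>",
    "<h1>Treatment-success biomarker report</h1>",
    "<h2>Patient overview</h2>",
    .htmlTable(result$overview$composition),
    "<h2>Age distribution per set</h2>",
    .htmlTable(result$overview$ageSummary),
    "<h2>Case sets</h2>", .htmlTable(result$sets),
    "<h2>Ranked candidates (vp-product)</h2>",
    .htmlTable(result$ranked),
    "<h2>Per-set aggregation (geometric mean of vp-products)</h2>",
    .htmlTable(result$summary),
    "<h2>All evaluated features</h2>", .htmlTable(result$evaluations),
    "<h2>Run configuration and versions</h2>",
    paste0("<pre>", .htmlEscape(paste(
      readLines(cfgPath), collapse = "\n")), "</pre>"),
    "</body></html>")
  idxPath <- file.path(dir, "index.html")
  writeLines(html, idxPath)
  invisible(c(paths, idxPath))
}
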