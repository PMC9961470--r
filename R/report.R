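#' Assemble tables into a report bundle
#'
#' @param sections Named list of data.frames; names are section titles.
#' @param title Report title.
#' @param parameters Optional named list of parameters to record in the
#'   report metadata.
#' @param timestamp Include a generation timestamp? Off by default so that
#'   identical inputs render byte-identical reports.
#' @return Object of class `report_bundle`.
#' @export
report_bundle <- function(sections, title = "ctga report",
                          parameters = list(), timestamp = FALSE) {
  if (is.null(names(sections)) || any(!nzchar(names(sections)))) {
    abort("every section must be named")
  }
  ok <- vapply(sections, is.data.frame, logical(1))
  if (!all(ok)) abort("every section must be a data.frame")
  structure(list(sections = sections, title = title,
                 parameters = parameters, timestamp = timestamp,
                 version = as.character(utils::packageVersion("ctga"))),
            class = "report_bundle")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, id) {
  head <- paste0("<th>", html_escape(names(df)), "</th>", collapse = "")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(df[i, , drop = FALSE], function(v) {
      html_escape(format(v, trim = TRUE, scientific = FALSE))
    }, character(1))
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, character(1))
  paste0('<table id="', id, '" class="ctga">',
         "<thead><tr>", head, "</tr></thead><tbody>",
         paste0(body, collapse = ""), "</tbody></table>")
}

REPORT_CSS <- paste(
  "body{font-family:sans-serif;margin:2em}",
  "table.ctga{border-collapse:collapse;margin:1em 0}",
  "table.ctga th,table.ctga td{border:1px solid #999;padding:2px 8px}",
  "table.ctga th{background:#eee}",
  "input.filter{margin:4px 0;padding:2px}", sep = "\n")

REPORT_JS <- paste(
  "function filterTable(inp, id){",
  " var q = inp.value.toLowerCase();",
  " var rows = document.getElementById(id).tBodies[0].rows;",
  " for (var i = 0; i < rows.length; i++)",
  "  rows[i].style.display =",
  "   rows[i].textContent.toLowerCase().indexOf(q) >= 0 ? '' : 'none';",
  "}",
  "function exportCSV(id){",
  " var t = document.getElementById(id), lines = [];",
  " for (var i = 0; i < t.rows.length; i++){",
  "  var cells = t.rows[i].cells, vals = [];",
  "  for (var j = 0; j < cells.length; j++)",
  "   vals.push('\"' + cells[j].textContent.replace(/\"/g,'\"\"') + '\"');",
  "  lines.push(vals.join(','));",
  " }",
  " var blob = new Blob([lines.join('\\n')], {type:'text/csv'});",
  " var a = document.createElement('a');",
  " a.href = URL.createObjectURL(blob); a.download = id + '.csv';",
  " a.click();",
  "}", sep = "\n")

section_slug <- function(x) {
  gsub("[^a-z0-9]+", "_", tolower(x))
}

#' Render a report bundle to HTML, CSV or TSV
#'
#' HTML output is a single self-contained file (inline style and script,
#' no external fetches) with per-table text search and CSV export
#' controls. CSV/TSV output writes one plain data file per section,
#' named `<prefix>_<section>.csv`/`.tsv`. With timestamps disabled
#' (the default), output is byte-deterministic for identical inputs.
#'
#' @param bundle A [report_bundle()].
#' @param path Output path: the HTML file, or the directory/prefix for
#'   CSV/TSV files.
#' @param format One of `"html"`, `"csv"`, `"tsv"`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(bundle, path, format = c("html", "csv", "tsv")) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!format[1L] %in% c("html", "csv", "tsv")) {
    abort("unknown report format: ", format[1L])
  }
  format <- match.arg(format)
  if (format %in% c("csv", "tsv")) {
    files <- character(0)
    for (title in names(bundle$sections)) {
      f <- paste0(path, "_", section_slug(title), ".", format)
      df <- bundle$sections[[title]]
      if (format == "csv") {
        utils::write.csv(df, f, row.names = FALSE)
      } else {
        utils::write.table(df, f, sep = "\t", row.names = FALSE,
                           quote = FALSE)
      }
      files <- c(files, f)
    }
    return(invisible(files))
  }
  parts <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", html_escape(bundle$title), "</title>"),
    "<style>", REPORT_CSS, "</style>",
    "<script>", REPORT_JS, "</script>",
    "</head><body>",
    paste0("<h1>", html_escape(bundle$title), "</h1>"),
    paste0("<p class=\"meta\">ctga ", bundle$version,
           if (bundle$timestamp) paste0(" &mdash; ", format(Sys.time())),
           "</p>")
  )
  if (length(bundle$parameters)) {
    kv <- paste0("<li>", html_escape(names(bundle$parameters)), " = ",
                 html_escape(vapply(bundle$parameters, function(v)
                   paste(format(v), collapse = ", "), character(1))),
                 "</li>")
    parts <- c(parts, "<ul class=\"params\">", kv, "</ul>")
  }
  for (title in names(bundle$sections)) {
    id <- section_slug(title)
    parts <- c(parts,
      paste0("<h2>", html_escape(title), "</h2>"),
      paste0('<input class="filter" placeholder="filter..." ',
             'oninput="filterTable(this, \'', id, '\')"> ',
             '<button onclick="exportCSV(\'', id, '\')">',
             "export CSV</button>"),
      html_table(bundle$sections[[title]], id))
  }
  parts <- c(parts, "</body></html>")
  writeLines(parts, path)
  invisible(path)
}
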