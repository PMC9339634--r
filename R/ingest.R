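#' Read a raw clinical table
#'
#' Reads one of the delimited dialects used by the study's data sources and
#' returns a uniform raw table: every column character, every missing value
#' (`?` or an empty cell) normalized to the single canonical marker
#' `NA_character_`, which cannot collide with any category label.
#'
#' @param path file path.
#' @param dialect `"csv"` (RFC-4180 with header row), `"uci_data"`
#'   (comma-separated, no header, `?` as missing -- the UCI `.data` layout),
#'   or `"spreadsheet"` (first sheet of an xlsx file, first row as header).
#' @param col_names for `"uci_data"` only: attribute names to assign, in
#'   column order. Defaults to `V1..Vk`.
#' @param source_label free-text provenance tag attached to the result.
#'
#' @return A tibble of character columns with attribute `source_label`.
#'   No numeric coercion is performed; discretization happens later against
#'   the raw strings.
#' @export
read_table <- function(path,
                       dialect = c("csv", "uci_data", "spreadsheet"),
                       col_names = NULL,
                       source_label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read input file: ", path, call. = FALSE)

  if (dialect == "spreadsheet") {
    raw <- readxl::read_excel(path, sheet = 1, col_types = "text")
    raw[] <- lapply(raw, function(col) {
      col <- as.character(col)
      col[!is.na(col) & (trimws(col) == "" | trimws(col) == "?")] <- NA_character_
      col
    })
  } else {
    has_header <- dialect == "csv"
    raw <- readr::read_csv(
      path,
      col_names = has_header,
      col_types = readr::cols(.default = readr::col_character()),
      na = c("", "?", "NA"),
      trim_ws = TRUE,
      progress = FALSE,
      show_col_types = FALSE
    )
    probs <- readr::problems(raw)
    if (nrow(probs) > 0) {
      stop(sprintf("parse error in %s at row %d: %s", path,
                   probs$row[1], probs$expected[1]), call. = FALSE)
    }
    if (dialect == "uci_data" && !is.null(col_names)) {
      if (length(col_names) != ncol(raw)) {
        stop(sprintf("col_names has %d names but file has %d columns",
                     length(col_names), ncol(raw)), call. = FALSE)
      }
      names(raw) <- col_names
    }
  }
  attr(raw, "source_label") <- source_label
  raw
}

#' Select and rename the study's attribute subset
#'
#' Reduces a raw table to a named, ordered subset of attributes, optionally
#' renaming source columns to canonical names first. Record count is never
#' changed here.
#'
#' @param raw a raw table (tibble of character columns).
#' @param names ordered character vector of attributes to retain (canonical
#'   names, i.e. after renaming).
#' @param rename optional named character vector `c(source_name = canonical)`.
#' @return The reduced table, columns exactly `names` in order.
#' @export
select_attributes <- function(raw, names, rename = NULL) {
  stopifnot(length(names) >= 1, !anyDuplicated(names))
  if (!is.null(rename)) {
    if (anyDuplicated(unname(rename))) {
      stop("rename targets must be unique", call. = FALSE)
    }
    hit <- match(colnames(raw), base::names(rename))
    colnames(raw)[!is.na(hit)] <- unname(rename[hit[!is.na(hit)]])
  }
  missing <- setdiff(names, colnames(raw))
  if (length(missing) > 0) {
    stop("unknown attribute(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lbl <- attr(raw, "source_label")
  out <- raw[, names, drop = FALSE]
  attr(out, "source_label") <- lbl
  out
}

#' Remove incomplete records
#'
#' Drops every record holding the canonical missing marker in any retained
#' attribute, preserving the original order of the remainder. Run this after
#' attribute selection, so a record missing only an unselected attribute is
#' kept.
#'
#' @param raw a raw table with normalized missing markers.
#' @return The complete-case subset; an empty result is legal.
#' @export
drop_incomplete <- function(raw) {
  lbl <- attr(raw, "source_label")
  keep <- stats::complete.cases(raw)
  out <- raw[keep, , drop = FALSE]
  attr(out, "source_label") <- lbl
  out
}
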