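#' Transaction database
#'
#' A transaction database is an ordered collection of transactions, each a set
#' of items. Items are rendered as `"attribute=level"` strings; the rendering
#' is injective because attribute names and level labels may not contain `"="`.
#'
#' @param transactions list of character vectors, one per transaction. Each is
#'   deduplicated and stored sorted; order of transactions is preserved.
#' @param class_attr optional name of the class attribute (used by the
#'   stratified mining stage).
#' @param label free-text provenance label.
#'
#' @return An object of class `transaction_db` with fields `transactions`
#'   (list of sorted character vectors), `N` (number of transactions),
#'   `items` (sorted item universe), `class_attr`, `label`.
#' @export
transaction_db <- function(transactions, class_attr = NULL, label = NULL) {
  stopifnot(is.list(transactions))
  txns <- lapply(transactions, function(x) sort(unique(as.character(x))))
  structure(
    list(
      transactions = txns,
      N = length(txns),
      items = sort(unique(unlist(txns, use.names = FALSE))),
      class_attr = class_attr,
      label = label
    ),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf(
    "<transaction_db> N = %d transactions, %d distinct items%s\n",
    x$N, length(x$items),
    if (!is.null(x$label)) paste0(" [", x$label, "]") else ""
  ))
  invisible(x)
}

# Logical incidence matrix (N x |items|), the workhorse for exact counting.
incidence_matrix <- function(db) {
  items <- db$items
  mat <- matrix(FALSE, nrow = db$N, ncol = length(items),
                dimnames = list(NULL, items))
  for (i in seq_len(db$N)) {
    mat[i, db$transactions[[i]]] <- TRUE
  }
  mat
}

# Exact number of transactions containing `items` as a subset.
count_itemset <- function(db, items, inc = NULL) {
  stopifnot(length(items) >= 1)
  if (is.null(inc)) inc <- incidence_matrix(db)
  if (!all(items %in% colnames(inc))) return(0L)
  sub <- inc[, items, drop = FALSE]
  sum(rowSums(sub) == length(items))
}

# Inclusive minimum-support test on exact integer counts. The fractional
# threshold is converted once to the smallest admissible count; the 1e-9
# guard only absorbs binary representation error of min_support * N (e.g.
# 0.6 * 5), never a genuine sub-threshold count.
min_count_for <- function(min_support, N) {
  as.integer(ceiling(min_support * N - 1e-9))
}

# Canonical single-string key for an itemset (items sorted, unit-separator
# joined) -- used wherever itemsets index a table.
itemset_key <- function(items) {
  paste(sort(items), collapse = "\x1f")
}

key_to_items <- function(key) strsplit(key, "\x1f", fixed = TRUE)[[1]]

# Shared result container for both miners: a tibble with one row per frequent
# itemset, exact integer counts, support as count/N.
itemset_tibble <- function(keys, counts, N) {
  items <- lapply(keys, key_to_items)
  out <- tibble::tibble(
    items = items,
    key = as.character(keys),
    size = lengths(items),
    count = as.integer(counts),
    support = as.integer(counts) / N
  )
  out <- out[order(out$size, out$key), ]
  attr(out, "N") <- N
  out
}

#' Render / parse items
#'
#' `make_item()` renders an (attribute, level) pair as `"attribute=level"`;
#' `split_item()` inverts it. The encoding is lossless because `"="` is
#' forbidden in both parts.
#'
#' @param attr attribute name (no `"="`).
#' @param level category label (no `"="`).
#' @return `make_item()`: character item; `split_item()`: named character
#'   vector with elements `attr` and `level`.
#' @export
make_item <- function(attr, level) {
  if (any(grepl("=", c(attr, level), fixed = TRUE))) {
    stop("attribute names and level labels must not contain '='", call. = FALSE)
  }
  paste0(attr, "=", level)
}

#' @rdname make_item
#' @param item a rendered `"attribute=level"` string.
#' @export
split_item <- function(item) {
  pos <- regexpr("=", item, fixed = TRUE)
  if (pos < 0) stop("not a rendered item: ", item, call. = FALSE)
  c(attr = substr(item, 1, pos - 1),
    level = substr(item, pos + 1, nchar(item)))
}

item_attr <- function(items) {
  vapply(items, function(x) split_item(x)[["attr"]], character(1),
         USE.NAMES = FALSE)
}
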