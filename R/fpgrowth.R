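# FP-Growth: prefix-tree compression of the transaction database plus
# recursive mining over conditional pattern bases. Nodes are environments so
# parent/child/header links are true references.

new_fp_node <- function(item = NA_character_, parent = NULL) {
  e <- new.env(parent = emptyenv())
  e$item <- item
  e$count <- 0L
  e$children <- list()
  e$parent <- parent
  e$nxt <- NULL   # header chain: next node holding the same item
  e
}

# Core tree builder over count-weighted transactions; shared by the top-level
# tree and every conditional tree. `minc` is the absolute count threshold
# (always relative to the ORIGINAL database size).
build_weighted_tree <- function(wtxns, weights, minc) {
  tally <- new.env(parent = emptyenv())
  for (i in seq_along(wtxns)) {
    for (it in wtxns[[i]]) {
      prev <- if (exists(it, envir = tally, inherits = FALSE)) get(it, envir = tally) else 0L
      assign(it, prev + weights[i], envir = tally)
    }
  }
  items <- ls(tally)
  counts <- vapply(items, get, integer(1), envir = tally)
  keep <- counts >= minc
  items <- items[keep]; counts <- counts[keep]
  # descending count, ties broken lexicographically on the rendered item
  ord <- order(-counts, items)
  items <- items[ord]; counts <- counts[ord]
  rank <- stats::setNames(seq_along(items), items)

  root <- new_fp_node()
  heads <- stats::setNames(vector("list", length(items)), items)
  tails <- stats::setNames(vector("list", length(items)), items)

  for (i in seq_along(wtxns)) {
    txn <- wtxns[[i]]
    txn <- txn[txn %in% items]
    if (length(txn) == 0) next
    txn <- txn[order(rank[txn])]
    node <- root
    for (it in txn) {
      child <- node$children[[it]]
      if (is.null(child)) {
        child <- new_fp_node(it, node)
        node$children[[it]] <- child
        if (is.null(heads[[it]])) heads[[it]] <- child else tails[[it]]$nxt <- child
        tails[[it]] <- child
      }
      child$count <- child$count + weights[i]
      node <- child
    }
  }
  list(root = root, items = items, counts = stats::setNames(counts, items),
       heads = heads)
}

#' Build an FP-tree
#'
#' Compresses the database into a prefix tree: items below the support
#' threshold are discarded, the surviving items are written in descending
#' support order (ties broken lexicographically) identically in every
#' transaction, and shared prefixes merge into shared nodes carrying counts.
#' A header table threads all nodes of each item for traversal.
#'
#' @inheritParams apriori_mine
#' @return A list of class `fp_tree`: `root` (node), `items` (header order),
#'   `counts` (named item counts), `heads` (named list of header-chain head
#'   nodes), `minc`, `N`.
#' @export
build_fptree <- function(db, min_support) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]", call. = FALSE)
  }
  minc <- max(min_count_for(min_support, db$N), 1L)
  tree <- build_weighted_tree(db$transactions, rep(1L, db$N), minc)
  tree$minc <- minc
  tree$N <- db$N
  class(tree) <- "fp_tree"
  tree
}

# All nodes on the header chain of `item`.
chain_nodes <- function(tree, item) {
  out <- list()
  node <- tree$heads[[item]]
  while (!is.null(node)) {
    out[[length(out) + 1L]] <- node
    node <- node$nxt
  }
  out
}

#' FP-Growth frequent-itemset mining
#'
#' Mines the FP-tree recursively: for each item in ascending header order, the
#' prefix paths reaching its nodes form the conditional pattern base, which is
#' rebuilt as a smaller conditional tree and mined with the item appended to
#' the suffix. Output contract (itemsets, exact counts, inclusive threshold)
#' is identical to [apriori_mine()]; on any database the two return the same
#' set.
#'
#' @inheritParams apriori_mine
#' @return Same tibble shape as [apriori_mine()]; attribute `algorithm` is
#'   `"fpgrowth"`.
#' @export
fpgrowth_mine <- function(db, min_support, max_len = Inf) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]", call. = FALSE)
  }
  if (db$N < 1) stop("database is empty", call. = FALSE)
  minc <- max(min_count_for(min_support, db$N), 1L)

  acc_keys <- character(0)
  acc_counts <- integer(0)
  emit <- function(items, count) {
    acc_keys[length(acc_keys) + 1L] <<- itemset_key(items)
    acc_counts[length(acc_counts) + 1L] <<- count
  }

  mine <- function(tree, suffix) {
    for (item in rev(tree$items)) {  # ascending support order
      itemset <- c(item, suffix)
      emit(itemset, tree$counts[[item]])
      if (length(itemset) >= max_len) next
      # conditional pattern base: prefix path of every node of `item`
      paths <- list(); wts <- integer(0)
      for (node in chain_nodes(tree, item)) {
        prefix <- character(0)
        p <- node$parent
        while (!is.null(p) && !is.na(p$item)) {
          prefix <- c(prefix, p$item)
          p <- p$parent
        }
        if (length(prefix) > 0) {
          paths[[length(paths) + 1L]] <- prefix
          wts <- c(wts, node$count)
        }
      }
      if (length(paths) == 0) next
      cond <- build_weighted_tree(paths, wts, minc)
      if (length(cond$items) > 0) mine(cond, itemset)
    }
  }

  tree <- build_fptree(db, min_support)
  mine(tree, character(0))
  out <- itemset_tibble(acc_keys, acc_counts, db$N)
  attr(out, "algorithm") <- "fpgrowth"
  out
}

#' Text dump of an FP-tree
#'
#' Renders the tree as indented `item:count` lines (children in header,
#' i.e. insertion, order), for inspection and fixture-based tests.
#'
#' @param tree an `fp_tree` from [build_fptree()].
#' @return Character vector of lines, first line `"null"` for the root.
#' @export
fp_tree_lines <- function(tree) {
  lines <- character(0)
  walk <- function(node, depth) {
    label <- if (is.na(node$item)) "null" else paste0(node$item, ":", node$count)
    lines[length(lines) + 1L] <<- paste0(strrep("  ", depth), label)
    kids <- node$children
    if (length(kids) > 0) {
      ord <- order(match(names(kids), tree$items))
      for (k in kids[ord]) walk(k, depth + 1)
    }
  }
  walk(tree$root, 0)
  lines
}

# Internal: total number of item-bearing nodes (compression diagnostics).
fp_node_count <- function(tree) {
  n <- 0L
  walk <- function(node) {
    for (k in node$children) {
      n <<- n + 1L
      walk(k)
    }
  }
  walk(tree$root)
  n
}
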