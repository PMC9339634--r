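#' Level-wise frequent-itemset mining (Apriori)
#'
#' Classic bottom-up mining: frequent single items seed the lattice, each
#' level's candidates are produced by [join_candidates()] from the previous
#' level, and candidates are counted by an exact scan of the database.
#' Support is kept as an exact integer count; the fractional threshold is
#' converted once to the smallest admissible count, and the comparison is
#' inclusive (`support >= min_support`), so itemsets sitting exactly at the
#' threshold survive.
#'
#' @param db a [transaction_db()] with at least one transaction.
#' @param min_support minimum support fraction in `(0, 1]`.
#' @param max_len optional cap on itemset size (default unlimited).
#' @return A tibble with one row per frequent itemset: `items` (list of
#'   sorted item vectors), `key`, `size`, `count` (exact), `support`
#'   (`count / N`). Every subset of a returned itemset is also returned
#'   (downward closure). Attribute `algorithm` is `"apriori"`.
#' @export
apriori_mine <- function(db, min_support, max_len = Inf) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]", call. = FALSE)
  }
  if (db$N < 1) stop("database is empty", call. = FALSE)

  inc <- incidence_matrix(db)
  minc <- max(min_count_for(min_support, db$N), 1L)

  item_counts <- colSums(inc)
  freq1 <- names(item_counts)[item_counts >= minc]
  keys <- freq1
  counts <- as.integer(item_counts[freq1])

  level <- as.list(freq1)  # k-itemsets as sorted character vectors
  k <- 1L
  while (length(level) >= 2 && k < max_len) {
    cands <- join_candidates(level)
    if (length(cands) == 0) break
    kept <- list()
    kept_counts <- integer(0)
    for (cand in cands) {
      rows <- inc[, cand[1]]
      for (it in cand[-1]) rows <- rows & inc[, it]
      cnt <- sum(rows)
      if (cnt >= minc) {
        kept[[length(kept) + 1L]] <- cand
        kept_counts <- c(kept_counts, cnt)
      }
    }
    if (length(kept) == 0) break
    keys <- c(keys, vapply(kept, itemset_key, character(1)))
    counts <- c(counts, kept_counts)
    level <- kept
    k <- k + 1L
  }
  out <- itemset_tibble(keys, counts, db$N)
  attr(out, "algorithm") <- "apriori"
  out
}

#' Candidate generation for the Apriori level loop
#'
#' Joins every pair of frequent k-itemsets sharing their first k-1 items
#' (in canonical lexicographic item order) into a (k+1)-candidate, then prunes
#' any candidate having a k-subset absent from the frequent set -- the
#' downward-closure prune.
#'
#' @param frequent_k list of frequent k-itemsets (character vectors, all the
#'   same size `k >= 1`; item order within each is irrelevant).
#' @return List of sorted (k+1)-item candidates, deduplicated, in canonical
#'   order.
#' @export
join_candidates <- function(frequent_k) {
  stopifnot(is.list(frequent_k))
  if (length(frequent_k) == 0) return(list())
  sets <- lapply(frequent_k, function(x) sort(as.character(x)))
  k <- length(sets[[1]])
  if (any(lengths(sets) != k) || k < 1) {
    stop("all input itemsets must have the same size k >= 1", call. = FALSE)
  }
  freq_keys <- vapply(sets, itemset_key, character(1))
  if (anyDuplicated(freq_keys)) sets <- sets[!duplicated(freq_keys)]

  prefixes <- vapply(sets, function(x) paste(x[-k], collapse = "\x1f"), character(1))
  out <- list()
  for (grp in split(sets, prefixes)) {
    if (length(grp) < 2) next
    lasts <- vapply(grp, function(x) x[k], character(1))
    ord <- order(lasts)
    grp <- grp[ord]; lasts <- lasts[ord]
    for (i in seq_len(length(grp) - 1)) {
      for (j in seq((i + 1), length(grp))) {
        out[[length(out) + 1L]] <- c(grp[[i]], lasts[j])
      }
    }
  }
  if (length(out) == 0) return(list())
  # downward-closure prune: every k-subset must be frequent
  keyset <- new.env(parent = emptyenv())
  for (kk in vapply(sets, itemset_key, character(1))) assign(kk, TRUE, envir = keyset)
  keep <- vapply(out, function(cand) {
    all(vapply(seq_along(cand), function(d) {
      exists(itemset_key(cand[-d]), envir = keyset, inherits = FALSE)
    }, logical(1)))
  }, logical(1))
  out <- out[keep]
  keys <- vapply(out, itemset_key, character(1))
  out <- out[!duplicated(keys)]
  out[order(vapply(out, itemset_key, character(1)))]
}
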