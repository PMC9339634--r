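# Shared fixtures: random transaction databases and the exhaustive power-set
# oracle. The oracle never touches either miner's code path: it enumerates
# every nonempty subset of the item universe with combn() and counts each by
# a direct scan.

random_db <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(10:120, 1)
  if (is.null(m)) m <- sample(3:8, 1)
  items <- paste0("i", sprintf("%02d", seq_len(m)))
  p <- stats::runif(m, 0.15, 0.85)
  txns <- lapply(seq_len(n), function(i) items[stats::runif(m) < p])
  transaction_db(txns, label = paste0("random-", seed))
}

oracle_mine <- function(db, min_support) {
  items <- sort(unique(unlist(db$transactions)))
  n <- db$N
  inc <- vapply(items, function(it) {
    vapply(db$transactions, function(t) it %in% t, logical(1))
  }, logical(n))
  if (n == 1) inc <- matrix(inc, nrow = 1, dimnames = list(NULL, items))
  minc <- ceiling(min_support * n - 1e-9)
  keys <- character(0); counts <- integer(0)
  for (k in seq_along(items)) {
    sets <- utils::combn(items, k, simplify = FALSE)
    for (s in sets) {
      cnt <- sum(rowSums(inc[, s, drop = FALSE]) == k)
      if (cnt >= minc) {
        keys <- c(keys, paste(s, collapse = "\x1f"))
        counts <- c(counts, cnt)
      }
    }
  }
  data.frame(key = keys, count = counts, stringsAsFactors = FALSE)
}

# set-equality on (itemset, count) pairs
mined_signature <- function(mined) {
  sort(paste(mined$key, mined$count, sep = "@"))
}

expect_same_itemsets <- function(a, b) {
  expect_identical(mined_signature(a), mined_signature(b))
}

# a class-stratified toy group: random transactions plus a class item in all
stratified_db <- function(seed, class_item = "Class=Positive", n = NULL, m = NULL) {
  db <- random_db(seed, n = n, m = m)
  transaction_db(lapply(db$transactions, function(t) c(t, class_item)),
                 class_attr = "Class", label = db$label)
}
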