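#' Support and confidence of itemsets
#'
#' `support_of()` counts the transactions containing an itemset as a subset
#' and returns both the exact count and the fraction `count / N`.
#' `confidence_of()` is the conditional frequency of consequent `C` among
#' transactions containing antecedent `A`: `count(A u C) / count(A)`.
#'
#' @param db a [transaction_db()] with `N >= 1`.
#' @param items,A non-empty character vector of items.
#' @param C a single consequent item.
#' @return `support_of()`: list with `count` and `support`;
#'   `confidence_of()`: a fraction in `[0, 1]`.
#' @export
support_of <- function(db, items) {
  stopifnot(inherits(db, "transaction_db"), db$N >= 1)
  if (length(items) < 1) stop("itemset must be non-empty", call. = FALSE)
  cnt <- count_itemset(db, items)
  list(count = cnt, support = cnt / db$N)
}

#' @rdname support_of
#' @export
confidence_of <- function(db, A, C) {
  stopifnot(length(C) == 1)
  if (length(A) < 1) stop("antecedent must be non-empty", call. = FALSE)
  inc <- incidence_matrix(db)
  nA <- count_itemset(db, A, inc)
  if (nA == 0) {
    stop("confidence undefined: antecedent never occurs", call. = FALSE)
  }
  nAC <- count_itemset(db, union(A, C), inc)
  nAC / nA
}

#' Support/confidence thresholds
#'
#' @param min_support,min_confidence fractions in `(0, 1]`; defaults are the
#'   study's operating point (0.6 support, 0.9 confidence).
#' @return A `thresholds` object.
#' @export
thresholds <- function(min_support = 0.6, min_confidence = 0.9) {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1)
  structure(list(min_support = min_support, min_confidence = min_confidence),
            class = "thresholds")
}

#' Generate class-targeted association rules within a stratified group
#'
#' For each frequent itemset mined from the group, the class item is removed
#' to form the antecedent `A`, and the rule `A => class` is scored with
#' support `count(A u class) / N` and confidence `count(A u class) / count(A)`
#' -- both recomputed by direct scan of the group database, not copied from
#' the miner. Rules failing either threshold (inclusive comparison) are
#' removed. Because the group is class-stratified, the class item is in every
#' transaction and every surviving rule's confidence is exactly 1.
#'
#' @param group_db a class-stratified [transaction_db()] (every transaction
#'   contains `class_item`).
#' @param class_item the consequent item, e.g. `"Class=Positive"`.
#' @param frequent frequent itemsets from [apriori_mine()] or
#'   [fpgrowth_mine()] run on `group_db` at `th$min_support`.
#' @param th a [thresholds()] object.
#' @param max_antecedent optional cap on antecedent size (default unlimited).
#' @return A `rule_set`: tibble with `antecedent` (list of sorted item
#'   vectors), `antecedent_str` (`"; "`-joined), `consequent`, `count`
#'   (co-occurrences of `A u C`), `n_antecedent` (occurrences of `A`),
#'   `support`, `confidence`, in canonical order (descending support, then
#'   ascending antecedent string). Provenance (algorithm, dataset, group,
#'   thresholds, N) is attached as attribute `provenance`.
#' @export
generate_class_rules <- function(group_db, class_item, frequent, th,
                                 max_antecedent = Inf) {
  stopifnot(inherits(group_db, "transaction_db"), inherits(th, "thresholds"))
  in_all <- vapply(group_db$transactions, function(txn) class_item %in% txn,
                   logical(1))
  if (!all(in_all)) {
    stop("stratification violation: class item '", class_item,
         "' missing from transaction ", which(!in_all)[1], call. = FALSE)
  }
  N <- group_db$N
  inc <- incidence_matrix(group_db)
  minc <- max(min_count_for(th$min_support, N), 1L)

  antecedents <- lapply(frequent$items, function(x) sort(setdiff(x, class_item)))
  keys <- vapply(antecedents, itemset_key, character(1))
  keep <- nzchar(keys) & !duplicated(keys) & lengths(antecedents) <= max_antecedent
  antecedents <- antecedents[keep]

  rows <- lapply(antecedents, function(A) {
    nA <- count_itemset(group_db, A, inc)
    nAC <- count_itemset(group_db, union(A, class_item), inc)
    if (nA == 0) return(NULL)
    conf <- nAC / nA
    # inclusive thresholds on exact counts
    if (nAC < minc) return(NULL)
    if (nAC + 1e-9 < th$min_confidence * nA) return(NULL)
    tibble::tibble(
      antecedent = list(A),
      antecedent_str = paste(A, collapse = "; "),
      consequent = class_item,
      count = nAC,
      n_antecedent = nA,
      support = nAC / N,
      confidence = conf
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    tibble::tibble(
      antecedent = list(), antecedent_str = character(0),
      consequent = character(0), count = integer(0),
      n_antecedent = integer(0), support = numeric(0), confidence = numeric(0)
    )
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(-out$support, out$antecedent_str), ]
  attr(out, "provenance") <- list(
    algorithm = attr(frequent, "algorithm") %||% "unknown",
    dataset = group_db$label %||% "",
    group = split_item(class_item)[["level"]],
    min_support = th$min_support,
    min_confidence = th$min_confidence,
    N = N
  )
  class(out) <- c("rule_set", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Categorize rules as frequent or infrequent
#'
#' A rule is *frequent* iff its support and confidence both meet their
#' thresholds (inclusive); every other combination -- including low support
#' with high confidence -- is *infrequent*. Only frequent rules carry
#' knowledge-discovery weight in this design.
#'
#' @param rule a `rule_set` (or any list/data frame with `support` and
#'   `confidence` fields); vectorized.
#' @param th a [thresholds()] object.
#' @return Character vector of `"frequent"` / `"infrequent"`.
#' @export
categorize_rule <- function(rule, th) {
  stopifnot(inherits(th, "thresholds"))
  s <- rule$support
  cf <- rule$confidence
  ifelse(s + 1e-9 >= th$min_support & cf + 1e-9 >= th$min_confidence,
         "frequent", "infrequent")
}

# Half-up rounding to match reported 2-decimal metrics (round() is banker's).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Serialize / read rule sets
#'
#' `write_rule_set()` writes the CSV form (group, antecedents, consequent,
#' support and confidence rounded half-up to 2 decimals as reported, count)
#' and, if `json` is given, a JSON form carrying exact counts and provenance.
#' `read_rule_set()` restores a rule set from the JSON form.
#'
#' @param rs a `rule_set`.
#' @param csv,json output paths (`NULL` to skip either).
#' @param path JSON path written by `write_rule_set()`.
#' @return `write_rule_set()`: invisibly `rs`; `read_rule_set()`: a
#'   `rule_set`.
#' @export
write_rule_set <- function(rs, csv = NULL, json = NULL) {
  prov <- attr(rs, "provenance")
  if (!is.null(csv)) {
    flat <- tibble::tibble(
      group = if (nrow(rs) > 0) prov$group else character(0),
      antecedents = rs$antecedent_str,
      consequent = rs$consequent,
      support = round_half_up(rs$support),
      confidence = round_half_up(rs$confidence),
      count = rs$count
    )
    readr::write_csv(flat, csv, progress = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(
      provenance = prov,
      rules = lapply(seq_len(nrow(rs)), function(i) {
        list(antecedent = rs$antecedent[[i]], consequent = rs$consequent[i],
             count = rs$count[i], n_antecedent = rs$n_antecedent[i],
             support = rs$support[i], confidence = rs$confidence[i])
      })
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(rs)
}

#' @rdname write_rule_set
#' @export
read_rule_set <- function(path) {
  payload <- jsonlite::read_json(path)
  rows <- lapply(payload$rules, function(r) {
    A <- sort(unlist(r$antecedent))
    tibble::tibble(
      antecedent = list(A), antecedent_str = paste(A, collapse = "; "),
      consequent = r$consequent, count = as.integer(r$count),
      n_antecedent = as.integer(r$n_antecedent),
      support = as.numeric(r$support), confidence = as.numeric(r$confidence)
    )
  })
  out <- if (length(rows) == 0) {
    tibble::tibble(
      antecedent = list(), antecedent_str = character(0),
      consequent = character(0), count = integer(0),
      n_antecedent = integer(0), support = numeric(0), confidence = numeric(0)
    )
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(-out$support, out$antecedent_str), ]
  prov <- payload$provenance
  attr(out, "provenance") <- list(
    algorithm = prov$algorithm %||% "unknown", dataset = prov$dataset %||% "",
    group = prov$group %||% "", min_support = as.numeric(prov$min_support),
    min_confidence = as.numeric(prov$min_confidence), N = as.integer(prov$N)
  )
  class(out) <- c("rule_set", class(out))
  out
}

#' @export
print.rule_set <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<rule_set> %d rule(s) [%s | %s | group %s | s>=%.2g c>=%.2g]\n",
              nrow(x), prov$algorithm, prov$dataset, prov$group,
              prov$min_support, prov$min_confidence))
  if (nrow(x) > 0) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %s => %s  (support %.2f, confidence %.2f, n=%d)\n",
                  x$antecedent_str[i], x$consequent[i],
                  round_half_up(x$support[i]), round_half_up(x$confidence[i]),
                  x$count[i]))
    }
  }
  invisible(x)
}
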