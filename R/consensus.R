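#' Intersect rule sets from the two miners
#'
#' The mutual-rule stage: rules are keyed by (antecedent, consequent); keys
#' present in both inputs form the `mutual` set (carrying the first input's
#' metrics), keys unique to one input land in `only_first` / `only_second`.
#' Shared keys whose support, confidence or count disagree beyond
#' `metric_tolerance` are recorded in `metric_discrepancies` -- never silently
#' merged. Because both miners compute exact integer counts, the default
#' tolerance is 0 and any non-empty discrepancy list (or `only_*` set) is a
#' mining-bug detector, which is precisely this stage's value.
#'
#' @param a,b `rule_set`s sharing dataset, group and thresholds provenance
#'   (typically one from Apriori, one from FP-Growth).
#' @param metric_tolerance maximum tolerated absolute difference in support
#'   and confidence for a shared key to pass unflagged (default 0: exact, and
#'   counts must match too).
#' @return A `consensus_report`: list with `mutual`, `only_first`,
#'   `only_second` (all `rule_set`s) and `metric_discrepancies` (tibble of
#'   key, support_delta, confidence_delta, count_delta).
#' @export
mutual_rules <- function(a, b, metric_tolerance = 0) {
  stopifnot(inherits(a, "rule_set"), inherits(b, "rule_set"))
  pa <- attr(a, "provenance"); pb <- attr(b, "provenance")
  same <- identical(pa$dataset, pb$dataset) &&
    identical(pa$group, pb$group) &&
    isTRUE(all.equal(pa$min_support, pb$min_support)) &&
    isTRUE(all.equal(pa$min_confidence, pb$min_confidence))
  if (!same) {
    stop("comparison refused: rule sets differ in dataset/group/thresholds provenance",
         call. = FALSE)
  }
  key_a <- paste(a$antecedent_str, "=>", a$consequent)
  key_b <- paste(b$antecedent_str, "=>", b$consequent)
  shared <- intersect(key_a, key_b)

  subset_rules <- function(rs, keep, prov) {
    out <- rs[keep, , drop = FALSE]
    attr(out, "provenance") <- prov
    class(out) <- c("rule_set", class(out)[class(out) != "rule_set"])
    out
  }
  prov_m <- pa
  prov_m$algorithm <- paste0("mutual(", pa$algorithm, ",", pb$algorithm, ")")
  mutual <- subset_rules(a, key_a %in% shared, prov_m)
  only_first <- subset_rules(a, !key_a %in% shared, pa)
  only_second <- subset_rules(b, !key_b %in% shared, pb)

  ia <- match(shared, key_a); ib <- match(shared, key_b)
  s_delta <- a$support[ia] - b$support[ib]
  c_delta <- a$confidence[ia] - b$confidence[ib]
  n_delta <- a$count[ia] - b$count[ib]
  flag <- abs(s_delta) > metric_tolerance | abs(c_delta) > metric_tolerance |
    (metric_tolerance == 0 & n_delta != 0L)
  disc <- tibble::tibble(
    key = shared[flag],
    support_delta = s_delta[flag],
    confidence_delta = c_delta[flag],
    count_delta = n_delta[flag]
  )
  structure(
    list(mutual = mutual, only_first = only_first, only_second = only_second,
         metric_discrepancies = disc),
    class = "consensus_report"
  )
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf(
    "<consensus_report> mutual %d | only_first %d | only_second %d | discrepancies %d\n",
    nrow(x$mutual), nrow(x$only_first), nrow(x$only_second),
    nrow(x$metric_discrepancies)
  ))
  invisible(x)
}

#' Serialize a consensus report
#'
#' Writes the mutual rules as CSV (same layout as [write_rule_set()]) and a
#' JSON report with all four components.
#'
#' @param report a `consensus_report`.
#' @param csv,json output paths (`NULL` to skip either).
#' @return Invisibly, `report`.
#' @export
write_consensus <- function(report, csv = NULL, json = NULL) {
  stopifnot(inherits(report, "consensus_report"))
  if (!is.null(csv)) write_rule_set(report$mutual, csv = csv)
  if (!is.null(json)) {
    rs_list <- function(rs) {
      lapply(seq_len(nrow(rs)), function(i) {
        list(antecedent = rs$antecedent[[i]], consequent = rs$consequent[i],
             count = rs$count[i], support = rs$support[i],
             confidence = rs$confidence[i])
      })
    }
    payload <- list(
      provenance = attr(report$mutual, "provenance"),
      mutual = rs_list(report$mutual),
      only_first = rs_list(report$only_first),
      only_second = rs_list(report$only_second),
      metric_discrepancies = report$metric_discrepancies
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}
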