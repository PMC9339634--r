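group_rules <- function(seed, algorithm = c("apriori", "fpgrowth"),
                        ms = 0.3) {
  algorithm <- match.arg(algorithm)
  db <- stratified_db(seed, n = 50, m = 6)
  th <- thresholds(ms, 0.9)
  frequent <- if (algorithm == "apriori") apriori_mine(db, ms)
              else fpgrowth_mine(db, ms)
  generate_class_rules(db, "Class=Positive", frequent, th)
}

test_that("identical rule sets intersect to themselves", {
  a <- group_rules(1, "apriori")
  b <- group_rules(1, "fpgrowth")
  rep <- mutual_rules(a, b)
  expect_identical(nrow(rep$mutual), nrow(a))
  expect_identical(nrow(rep$only_first), 0L)
  expect_identical(nrow(rep$only_second), 0L)
  expect_identical(nrow(rep$metric_discrepancies), 0L)
})

test_that("the two miners are each other's integrity check on random groups", {
  for (seed in 2:8) {
    a <- group_rules(seed, "apriori")
    b <- group_rules(seed, "fpgrowth")
    rep <- mutual_rules(a, b)
    expect_identical(nrow(rep$only_first) + nrow(rep$only_second), 0L)
    expect_identical(nrow(rep$metric_discrepancies), 0L)
  }
})

test_that("disjoint rule sets have empty intersection and full only-sets", {
  a <- group_rules(9)
  stopifnot(nrow(a) >= 2)
  top <- a[1, , drop = FALSE]
  rest <- a[-1, , drop = FALSE]
  for (x in list(top, rest)) {
    attr(x, "provenance") <- attr(a, "provenance")
  }
  attr(top, "provenance") <- attr(a, "provenance")
  attr(rest, "provenance") <- attr(a, "provenance")
  class(top) <- class(a); class(rest) <- class(a)
  rep <- mutual_rules(top, rest)
  expect_identical(nrow(rep$mutual), 0L)
  expect_identical(nrow(rep$only_first), 1L)
  expect_identical(nrow(rep$only_second), nrow(a) - 1L)
})

test_that("swapping inputs swaps the only-sets and preserves mutual keys", {
  a <- group_rules(10, "apriori")
  b <- group_rules(10, "fpgrowth")
  r1 <- mutual_rules(a, b)
  r2 <- mutual_rules(b, a)
  key <- function(rs) sort(paste(rs$antecedent_str, rs$consequent))
  expect_identical(key(r1$mutual), key(r2$mutual))
  expect_identical(key(r1$only_first), key(r2$only_second))
  expect_identical(key(r1$only_second), key(r2$only_first))
})

test_that("metric disagreements are recorded, never silently merged", {
  a <- group_rules(11, "apriori")
  b <- group_rules(11, "fpgrowth")
  b$support[1] <- b$support[1] + 0.05
  b$count[1] <- b$count[1] + 1L
  rep <- mutual_rules(a, b)
  expect_identical(nrow(rep$metric_discrepancies), 1L)
  expect_equal(rep$metric_discrepancies$support_delta, -0.05)
  # within tolerance the same difference passes unflagged
  rep2 <- mutual_rules(a, b, metric_tolerance = 0.1)
  expect_identical(nrow(rep2$metric_discrepancies), 0L)
  # key partition still holds: mutual + only_first covers the first input
  expect_identical(nrow(rep$mutual) + nrow(rep$only_first), nrow(a))
})

test_that("mismatched provenance refuses comparison", {
  a <- group_rules(12)
  b <- group_rules(12, "fpgrowth")
  pb <- attr(b, "provenance")
  pb$group <- "Negative"
  attr(b, "provenance") <- pb
  expect_error(mutual_rules(a, b), "refused")
  a2 <- group_rules(12, ms = 0.3)
  b2 <- group_rules(12, "fpgrowth", ms = 0.4)
  expect_error(mutual_rules(a2, b2), "refused")
})
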