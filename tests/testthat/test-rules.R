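test_that("support_of counts subsets exactly", {
  db <- transaction_db(list(c("a", "b"), "a", "b"))
  expect_identical(support_of(db, "a"), list(count = 2L, support = 2 / 3))
  expect_identical(support_of(db, c("a", "b")),
                   list(count = 1L, support = 1 / 3))
  expect_identical(support_of(db, "zz")$count, 0L)
  everywhere <- transaction_db(replicate(5, c("x", "y"), simplify = FALSE))
  expect_identical(support_of(everywhere, "x"), list(count = 5L, support = 1))
  expect_error(support_of(db, character(0)), "non-empty")
})

test_that("confidence is the conditional frequency of the consequent", {
  db <- transaction_db(list(c("a", "c"), "a", "c"))
  expect_identical(confidence_of(db, "a", "c"), 0.5)
  sure <- transaction_db(list(c("a", "c"), c("a", "c"), "b"))
  expect_identical(confidence_of(sure, "a", "c"), 1.0)
  expect_error(confidence_of(db, "nope", "c"), "undefined")
  # algebraic identity conf = support(A u C) / support(A) on random DBs
  for (seed in 1:5) {
    rdb <- random_db(seed, n = 40, m = 5)
    A <- rdb$items[1]; C <- rdb$items[2]
    sA <- support_of(rdb, A)
    if (sA$count == 0) next
    sAC <- support_of(rdb, c(A, C))
    expect_equal(confidence_of(rdb, A, C), sAC$support / sA$support)
  }
})

test_that("uniform stratified group yields the trivial full-support rule", {
  db <- transaction_db(replicate(6, c("x=1", "Class=Positive"),
                                 simplify = FALSE),
                       class_attr = "Class")
  th <- thresholds(0.6, 0.9)
  rules <- generate_class_rules(db, "Class=Positive",
                                apriori_mine(db, th$min_support), th)
  expect_identical(nrow(rules), 1L)
  expect_identical(rules$antecedent_str, "x=1")
  expect_identical(rules$support, 1)
  expect_identical(rules$confidence, 1)
})

test_that("class rules carry group-relative support and exact confidence", {
  # 10-transaction positive group; item a in 8, b in 6, both in 5
  txns <- list(
    c("a", "b"), c("a", "b"), c("a", "b"), c("a", "b"), c("a", "b"),
    c("a"), c("a"), c("a"), c("b"), character(0)
  )
  db <- transaction_db(lapply(txns, function(t) c(t, "Class=Positive")),
                       class_attr = "Class")
  th <- thresholds(0.5, 0.9)
  rules <- generate_class_rules(db, "Class=Positive",
                                fpgrowth_mine(db, th$min_support), th)
  expect_identical(rules$support[rules$antecedent_str == "a"], 0.8)
  expect_identical(rules$support[rules$antecedent_str == "a; b"], 0.5)
  expect_true(all(rules$confidence == 1))
  # canonical order: descending support, then antecedent string
  expect_identical(rules$antecedent_str,
                   rules$antecedent_str[order(-rules$support,
                                              rules$antecedent_str)])
  # anti-monotonicity: extending an antecedent never increases support
  sup <- stats::setNames(rules$support, rules$antecedent_str)
  expect_lte(sup[["a; b"]], sup[["a"]])
  expect_lte(sup[["a; b"]], sup[["b"]])
})

test_that("stratification violations are refused", {
  db <- transaction_db(list(c("a", "Class=Positive"), "a"),
                       class_attr = "Class")
  th <- thresholds(0.5, 0.9)
  expect_error(
    generate_class_rules(db, "Class=Positive", apriori_mine(db, 0.5), th),
    "stratification"
  )
})

test_that("stratified-confidence theorem: every emitted confidence is exactly 1", {
  for (seed in 6:15) {
    db <- stratified_db(seed)
    ms <- stats::runif(1, 0.2, 0.7)
    th <- thresholds(ms, stats::runif(1, 0.5, 1))
    rules <- generate_class_rules(db, "Class=Positive",
                                  fpgrowth_mine(db, ms), th)
    expect_true(all(rules$confidence == 1))
    expect_true(all(rules$count <= rules$n_antecedent))
    expect_true(all(rules$n_antecedent <= db$N))
  }
})

test_that("rule categorization: frequent needs both thresholds, inclusively", {
  th <- thresholds(0.6, 0.9)
  expect_identical(categorize_rule(list(support = 0.88, confidence = 1.00), th),
                   "frequent")
  expect_identical(categorize_rule(list(support = 0.3, confidence = 0.95), th),
                   "infrequent")
  expect_identical(categorize_rule(list(support = 0.6, confidence = 0.9), th),
                   "frequent")
  expect_identical(categorize_rule(list(support = 0.95, confidence = 0.5), th),
                   "infrequent")
})

test_that("rule sets round-trip through the JSON serialization", {
  db <- stratified_db(123, n = 40, m = 5)
  th <- thresholds(0.3, 0.9)
  rules <- generate_class_rules(db, "Class=Positive",
                                apriori_mine(db, 0.3), th)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_rule_set(rules, csv = csv, json = json)
  back <- read_rule_set(json)
  expect_identical(back$antecedent_str, rules$antecedent_str)
  expect_identical(back$count, rules$count)
  expect_equal(back$support, rules$support)
  expect_identical(attr(back, "provenance")$group,
                   attr(rules, "provenance")$group)
  flat <- readr::read_csv(csv, show_col_types = FALSE)
  expect_identical(nrow(flat), nrow(rules))
  expect_true(all(flat$confidence == 1))
})
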