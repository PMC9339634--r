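test_that("reference-range discretization uses closed intervals", {
  sp <- spec_dataset1()
  expect_identical(discretize_value("T3", 5.0, sp), "T3=Abnormal")
  expect_identical(discretize_value("T3", 1.3, sp), "T3=Normal")
  expect_identical(discretize_value("TSH", 4.2, sp), "TSH=Normal")
  expect_identical(discretize_value("TSH", 4.21, sp), "TSH=Abnormal")
  expect_identical(discretize_value("TSH", 0.27, sp), "TSH=Normal")
  # order preservation: value in [lo, hi] <=> Normal, over a grid
  for (v in seq(0, 6, by = 0.1)) {
    lab <- split_item(discretize_value("TSH", v, sp))[["level"]]
    expect_identical(lab, if (v >= 0.27 && v <= 4.2) "Normal" else "Abnormal")
  }
})

test_that("age handling: decade bins half-open with closed top, threshold split at 50", {
  sp1 <- spec_dataset1()
  expect_identical(discretize_value("Age", 30, sp1), "Age=30-40")  # lower edge wins
  expect_identical(discretize_value("Age", 29.9, sp1), "Age=20-30")
  expect_identical(discretize_value("Age", 80, sp1), "Age=70-80")  # last bin closed
  expect_error(discretize_value("Age", 19, sp1), "Age")
  expect_error(discretize_value("Age", 81, sp1), "81")
  sp2 <- spec_dataset2()
  expect_identical(discretize_value("Age", 50, sp2), "Age=≤50")
  expect_identical(discretize_value("Age", 51, sp2), "Age=>50")
})

test_that("boolean spellings normalize to uniform False/True levels", {
  sp <- disc_spec(list(X = rule_boolean()))
  for (raw in c("f", "0", "N", "no", "FALSE")) {
    expect_identical(discretize_value("X", raw, sp), "X=False")
  }
  for (raw in c("t", "1", "Y", "yes", "TRUE")) {
    expect_identical(discretize_value("X", raw, sp), "X=True")
  }
  expect_error(discretize_value("X", "maybe", sp), "maybe")
})

test_that("class labels normalize to Negative/Positive with id-suffix stripping", {
  sp <- spec_dataset1()
  expect_identical(discretize_value("Class", "sick.|21", sp), "Class=Positive")
  expect_identical(discretize_value("Class", "negative.|3733", sp),
                   "Class=Negative")
  expect_identical(discretize_value("Class", "negative", sp), "Class=Negative")
})

test_that("item rendering is lossless", {
  it <- make_item("T3", "Abnormal")
  expect_identical(split_item(it), c(attr = "T3", level = "Abnormal"))
  expect_error(make_item("a=b", "x"), "=")
  expect_error(make_item("a", "x=y"), "=")
})

test_that("encode_transactions builds one transaction per record", {
  sp <- disc_spec(list(
    Sex = rule_categorical(recode = c(F = "F", M = "M")),
    T3 = rule_normal_range(1.3, 3.1),
    Class = rule_categorical(recode = c(sick = "Positive",
                                        negative = "Negative"))
  ))
  tab <- tibble::tibble(Sex = c("F", "F"), T3 = c("0.5", "0.5"),
                        Class = c("sick", "sick"))
  db <- encode_transactions(tab, sp, "Class")
  expect_identical(db$N, 2L)
  expect_identical(length(db$items), 3L)
  expect_identical(db$transactions[[1]],
                   sort(c("Sex=F", "T3=Abnormal", "Class=Positive")))
  # degenerate empty table
  empty <- encode_transactions(tab[0, ], sp, "Class")
  expect_identical(empty$N, 0L)
  # residual missing value is an error pointing at the record
  tab_na <- tab; tab_na$T3[2] <- NA
  expect_error(encode_transactions(tab_na, sp, "Class"), "record 2")
})

test_that("out-of-range values error by default or drop with a surfaced count", {
  sp <- disc_spec(list(Age = rule_bins(c(20, 30, 40)),
                       Class = rule_categorical()))
  tab <- tibble::tibble(Age = c("25", "85", "33"), Class = c("a", "b", "a"))
  expect_error(encode_transactions(tab, sp, "Class"), "85")
  db <- suppressMessages(encode_transactions(tab, sp, "Class",
                                             out_of_range = "drop"))
  expect_identical(db$N, 2L)
  expect_identical(attr(db, "n_out_of_range"), 1L)
})

test_that("class stratification partitions the database", {
  txns <- c(
    replicate(7, c("x=1", "Class=Negative"), simplify = FALSE),
    replicate(3, c("x=1", "Class=Positive"), simplify = FALSE)
  )
  db <- transaction_db(txns, class_attr = "Class")
  groups <- split_by_class(db)
  expect_identical(sort(names(groups)), c("Negative", "Positive"))
  expect_identical(groups$Negative$N, 7L)
  expect_identical(groups$Positive$N, 3L)
  expect_identical(sum(vapply(groups, function(g) g$N, integer(1))), db$N)
  for (g in names(groups)) {
    item <- make_item("Class", g)
    expect_true(all(vapply(groups[[g]]$transactions,
                           function(t) item %in% t, logical(1))))
  }
  # all-one-class database
  db1 <- transaction_db(txns[1:7], class_attr = "Class")
  expect_identical(names(split_by_class(db1)), "Negative")
})

test_that("bundled presets cover exactly the selected attribute sets", {
  sel1 <- dataset1_selection()
  expect_identical(length(sel1$names), 21L)
  expect_setequal(names(spec_dataset1()), sel1$names)
  sel2 <- dataset2_selection()
  expect_identical(length(sel2$names), 15L)
  expect_setequal(names(spec_dataset2()), sel2$names)
})
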