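two_level <- function(name, p_a, render = NULL) {
  syn_attr(name, c("A", "B"), c(A = p_a, B = 1 - p_a), render = render)
}

test_that("generation is bit-stable for a fixed seed", {
  cfg <- preset_dataset1_like(seed = 11)
  g1 <- generate_transactions(cfg)
  g2 <- generate_transactions(cfg)
  expect_identical(g1$table, g2$table)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_transactions(preset_dataset1_like(seed = 12))
  expect_false(identical(g1$table, g3$table))
})

test_that("ground truth recounts from the emitted table at zero missingness", {
  cfg <- synthetic_config(
    n = 800,
    class_levels = c(Neg = 0.7, Pos = 0.3),
    attributes = list(two_level("x", 0.6), two_level("y", 0.8),
                      two_level("z", 0.5)),
    planted_patterns = list(syn_pattern("Pos", c(x = "A", y = "A"), 0.55)),
    missing_rate = 0, seed = 5, class_attr = "cls"
  )
  gen <- generate_transactions(cfg)
  tab <- gen$table
  expect_identical(sum(gen$truth$class_counts), 800L)
  expect_identical(as.integer(gen$truth$class_counts[["Pos"]]),
                   sum(tab$cls == "Pos"))
  ic <- gen$truth$item_counts
  for (i in seq_len(nrow(ic))) {
    parts <- split_item(ic$item[i])
    expect_identical(
      ic$count[i],
      sum(tab$cls == ic$class[i] & tab[[parts[["attr"]]]] == parts[["level"]])
    )
  }
  pc <- gen$truth$pattern_counts
  direct <- sum(tab$cls == "Pos" & tab$x == "A" & tab$y == "A")
  expect_identical(pc$count[1], direct)
})

test_that("per-class marginals and planted joints land within 3 binomial SE", {
  cfg <- synthetic_config(
    n = 6000,
    class_levels = c(Neg = 0.5, Pos = 0.5),
    attributes = list(two_level("x", 0.7), two_level("y", 0.7),
                      two_level("w", 0.4)),
    planted_patterns = list(syn_pattern("Pos", c(x = "A", y = "A"), 0.7)),
    missing_rate = 0, seed = 9, class_attr = "cls"
  )
  gen <- generate_transactions(cfg)
  n_pos <- as.integer(gen$truth$class_counts[["Pos"]])
  se <- function(p, n) sqrt(p * (1 - p) / n)
  # marginal fidelity, both classes
  ic <- gen$truth$item_counts
  for (g in c("Neg", "Pos")) {
    n_g <- as.integer(gen$truth$class_counts[[g]])
    for (a in c("x", "y")) {
      cnt <- ic$count[ic$class == g & ic$item == paste0(a, "=A")]
      expect_lt(abs(cnt / n_g - 0.7), 3 * se(0.7, n_g))
    }
    cnt <- ic$count[ic$class == g & ic$item == "w=A"]
    expect_lt(abs(cnt / n_g - 0.4), 3 * se(0.4, n_g))
  }
  # planted joint: marginal equals the joint, so realized co-occurrence is
  # exactly the forced fraction
  pc <- gen$truth$pattern_counts
  expect_lt(abs(pc$count[1] / n_pos - 0.7), 3 * se(0.7, n_pos))
  # in the untouched class the same pair co-occurs near independence
  tab <- gen$table
  neg_joint <- mean(tab$x[tab$cls == "Neg"] == "A" &
                    tab$y[tab$cls == "Neg"] == "A")
  expect_lt(abs(neg_joint - 0.49), 3 * se(0.49, 6000 - n_pos))
})

test_that("missingness removes the expected fraction of records", {
  m <- 10
  cfg <- synthetic_config(
    n = 1000,
    class_levels = c(Neg = 1.0),
    attributes = lapply(paste0("a", 1:m), two_level, p_a = 0.5),
    missing_rate = 0.1, seed = 3
  )
  gen <- generate_transactions(cfg)
  kept <- nrow(drop_incomplete(gen$table))
  p_complete <- 0.9^(m + 1)  # class column is masked too
  se <- sqrt(p_complete * (1 - p_complete) / 1000)
  expect_lt(abs(kept / 1000 - p_complete), 3 * se)
})

test_that("invalid configurations are rejected with the offending detail", {
  attrs <- list(two_level("x", 0.6), two_level("y", 0.9))
  expect_error(
    synthetic_config(100, c(Neg = 0.5, Pos = 0.5), attrs,
                     planted_patterns = list(
                       syn_pattern("Pos", c(x = "A", y = "A"), 0.8))),
    "infeasible.*x=A"
  )
  expect_error(
    synthetic_config(100, c(Neg = 1.0), attrs,
                     planted_patterns = list(
                       syn_pattern("Neg", c(x = "A"), 0.5),
                       syn_pattern("Neg", c(x = "B", y = "A"), 0.3))),
    "overlapping"
  )
  expect_error(
    synthetic_config(100, c(Neg = 0.6, Pos = 0.5), attrs),
    "is not TRUE"
  )
  bad <- list(syn_attr("x", c("A", "B"), c(A = 0.6, B = 0.6)))
  expect_error(synthetic_config(100, c(Neg = 1.0), bad), "sum to 1")
})

test_that("presets mirror the two study designs' attribute sets", {
  c1 <- preset_dataset1_like()
  expect_identical(c1$n, 2800L)
  expect_setequal(c(names(c1$attributes), c1$class_attr),
                  dataset1_selection()$names)
  c2 <- preset_dataset2_like()
  expect_identical(c2$n, 303L)
  expect_setequal(c(names(c2$attributes), c2$class_attr),
                  dataset2_selection()$names)
  # emitted raw tables are ingest-ready: encode end-to-end without error
  gen <- generate_transactions(preset_dataset2_like(seed = 4, missing_rate = 0))
  db <- encode_transactions(gen$table, spec_dataset2(), "Thyroid_disease")
  expect_identical(db$N, 303L)
})
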