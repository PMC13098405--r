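test_that("single-cell split yields the 80/20 arithmetic", {
  parts <- data.frame(participant_id = sprintf("P%02d", 1:10),
                      group = "A", stringsAsFactors = FALSE)
  sp <- make_split(parts, 0.2, "group", strata = "label", seed = 1)
  expect_equal(length(sp$train), 8)
  expect_equal(length(sp$test), 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(make_split(parts, 0, "group"), "test_frac")
})

test_that("all recordings of a participant land on one side", {
  spec <- cohort_spec(n_per_group = 8, seed = 2)
  co <- generate_cohort(spec)
  tabs <- generate_feature_table(co, default_group_signature(), seed = 2)
  sp <- suppressWarnings(make_split(co, 0.2, "group", seed = 3))
  for (task in names(tabs)) {
    sides <- ifelse(tabs[[task]]$participant_id %in% sp$train, "train", "test")
    ## same participants, same side in every task table
    expect_identical(sides,
                     ifelse(tabs$NEG$participant_id %in% sp$train, "train", "test"))
  }
  expect_setequal(c(sp$train, sp$test), co$participant_id)
})

test_that("splits are deterministic and warn on singleton cells", {
  co <- generate_cohort(cohort_spec(n_per_group = 5, seed = 4))
  s1 <- suppressWarnings(make_split(co, 0.2, "group", seed = 7))
  s2 <- suppressWarnings(make_split(co, 0.2, "group", seed = 7))
  expect_identical(s1, s2)
  parts <- data.frame(participant_id = c("a", "b", "c"),
                      group = c("A", "A", "B"), stringsAsFactors = FALSE)
  expect_warning(make_split(parts, 0.4, "group", strata = "label", seed = 1),
                 "single participant")
})

test_that("folds partition the training set with stratified counts", {
  parts <- data.frame(participant_id = sprintf("P%02d", 1:25),
                      group = rep(c("A", "B", "C", "D", "E"), 5))
  fa <- make_folds(parts, k = 5, repeats = 2, label_col = "group", seed = 1)
  expect_length(fa$folds, 10)
  for (r in 1:2) {
    vals <- lapply(Filter(function(f) f$repeat_idx == r, fa$folds),
                   `[[`, "validation")
    expect_equal(vapply(vals, length, 1L), rep(5L, 5))
    expect_setequal(unlist(vals), parts$participant_id)
    expect_equal(anyDuplicated(unlist(vals)), 0)
  }
})

test_that("a class of 10 in 50 contributes exactly 2 per validation fold", {
  parts <- data.frame(participant_id = sprintf("P%02d", 1:50),
                      group = rep(c("A", "A", "A", "A", "B"), 10))
  fa <- make_folds(parts, k = 5, repeats = 1, label_col = "group", seed = 2)
  b_ids <- parts$participant_id[parts$group == "B"]
  for (f in fa$folds) expect_equal(sum(f$validation %in% b_ids), 2)
})

test_that("undersized classes are rejected with an actionable message", {
  parts <- data.frame(participant_id = sprintf("P%02d", 1:12),
                      group = c(rep("A", 9), rep("B", 3)))
  expect_error(make_folds(parts, k = 5, label_col = "group"),
               "smaller than k=5.*Reduce k")
})

test_that("oversampling balances classes and flags duplicates", {
  rows <- data.frame(label = c(rep("A", 10), rep("B", 4)), x = rnorm(14))
  rows <- speechstrat:::tag_training_rows(rows)
  os <- oversample(rows, "label", "oversample", seed = 1)
  expect_equal(unname(table(os$rows$label)["B"]), 10, ignore_attr = TRUE)
  expect_equal(sum(os$rows$.oversampled), 6)
  ## balanced input unchanged
  bal <- speechstrat:::tag_training_rows(
    data.frame(label = rep(c("A", "B"), 5), x = rnorm(10)))
  os2 <- oversample(bal, "label", "oversample", seed = 1)
  expect_equal(nrow(os2$rows), 10)
})

test_that("class-weight strategy emits inverse-frequency weights", {
  rows <- speechstrat:::tag_training_rows(
    data.frame(label = c(rep("A", 10), rep("B", 4))))
  os <- oversample(rows, "label", "class_weight", seed = 1)
  expect_equal(os$weights[["A"]], 1)
  expect_equal(os$weights[["B"]], 2.5)
  expect_equal(nrow(os$rows), 14)
})

test_that("oversampling refuses untagged (validation/test) rows", {
  rows <- data.frame(label = c("A", "B"))
  expect_error(oversample(rows, "label"), "fold-training rows")
})

test_that("no participant appears on both sides of any fold or split", {
  co <- generate_cohort(cohort_spec(n_per_group = 8, seed = 5))
  sp <- suppressWarnings(make_split(co, 0.2, "group", seed = 6))
  trc <- co[co$participant_id %in% sp$train, ]
  fa <- make_folds(trc, k = 5, repeats = 5, label_col = "physiotype", seed = 7)
  for (f in fa$folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_setequal(c(f$train, f$validation), sp$train)
    expect_length(intersect(f$validation, sp$test), 0)
  }
})

test_that("demographic stratification balances sex across sides", {
  ## chi-square of sex x side should be non-significant in most seeds
  ok <- vapply(1:40, function(s) {
    set.seed(s + 900)
    parts <- data.frame(
      participant_id = sprintf("P%03d", 1:500),
      group = sample(c("A", "B"), 500, replace = TRUE),
      age = runif(500, 55, 85),
      sex = sample(c("F", "M"), 500, replace = TRUE))
    sp <- suppressWarnings(make_split(parts, 0.2, "group", seed = s))
    side <- ifelse(parts$participant_id %in% sp$train, "train", "test")
    suppressWarnings(chisq.test(table(parts$sex, side))$p.value) > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
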