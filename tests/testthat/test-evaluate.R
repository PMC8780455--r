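balanced_labels <- function(n_per = 25, classes = c("A", "B", "C", "D")) {
  n <- n_per * length(classes)
  label_table(data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                         donor_id = sprintf("d%03d", seq_len(n)),
                         label = rep(classes, each = n_per)))
}

test_that("balanced cohorts split exactly 60/20/20 with stratification", {
  lt <- balanced_labels()
  splits <- stratified_group_shuffle_split(lt, 3, seed = 1)
  for (sp in splits) {
    expect_length(sp$train, 60L)
    expect_length(sp$val, 20L)
    expect_length(sp$test, 20L)
    assert_no_donor_leakage(sp, lt)
    lab_of <- stats::setNames(lt$label, lt$sample_id)
    for (part in c("train", "val", "test"))
      expect_true(all(table(lab_of[sp[[part]]]) ==
                        length(sp[[part]]) / 4))
  }
  # distinct sub-seeds give generally different partitions
  expect_false(identical(sort(splits[[1]]$test), sort(splits[[2]]$test)))
})

test_that("donors never straddle partitions", {
  df <- data.frame(sample_id = sprintf("s%02d", 1:40),
                   donor_id = rep(sprintf("d%02d", 1:20), each = 2),
                   label = rep(c("A", "B"), each = 20))
  lt <- label_table(df)
  splits <- stratified_group_shuffle_split(lt, 3, seed = 4)
  donor_of <- stats::setNames(lt$donor_id, lt$sample_id)
  for (sp in splits) {
    assert_no_donor_leakage(sp, lt)
    for (d in unique(lt$donor_id)) {
      in_part <- vapply(c("train", "val", "test"), function(p)
        any(donor_of[sp[[p]]] == d), logical(1))
      expect_equal(sum(in_part), 1L)
    }
  }
})

test_that("undersized classes fall back to train with a warning", {
  lt <- suppressWarnings(label_table(data.frame(
    sample_id = c("a1", "a2", "a3", "a4", "b1"),
    donor_id = c("da1", "da2", "da3", "da4", "db1"),
    label = c("A", "A", "A", "A", "B"))))
  expect_warning(splits <- stratified_group_shuffle_split(lt, 1, seed = 1),
                 "allocated wholly to train")
  expect_true("b1" %in% splits[[1]]$train)
})

test_that("metrics match a hand-worked confusion table", {
  # truth (A,A,B,B) vs predictions (A,B,B,B)
  prob <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.3, 0.7), c(0.1, 0.9))
  m <- score_predictions(c("A", "A", "B", "B"), prob, c("A", "B"))
  expect_equal(m$accuracy, 0.75)
  expect_equal(unname(m$per_class_f1["A"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m$per_class_f1["B"]), 0.8, tolerance = 1e-12)
  expect_equal(sum(m$confusion), 4L)
  # independent first-principles check of the same quantities
  y <- c("A", "A", "B", "B"); pred <- c("A", "B", "B", "B")
  for (cls in c("A", "B")) {
    tp <- sum(y == cls & pred == cls)
    prec <- tp / sum(pred == cls); rec <- tp / sum(y == cls)
    expect_equal(unname(m$per_class_f1[cls]), 2 * prec * rec / (prec + rec))
  }
})

test_that("perfect predictions give unit scores and top-k behaves", {
  prob <- diag(3)[c(1, 2, 3, 1), ]
  m <- score_predictions(c("x", "y", "z", "x"), prob, c("x", "y", "z"))
  expect_true(all(m$per_class_f1 == 1))
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$top_k), c(1, 1, 1))

  # true class ranked second: top-1 miss, top-2 hit
  m2 <- score_predictions("b", rbind(c(0.5, 0.3, 0.2)), c("a", "b", "c"))
  expect_equal(unname(m2$top_k), c(0, 1, 1))
  expect_true(all(diff(m2$top_k) >= 0))
  expect_error(score_predictions("q", rbind(c(0.5, 0.5)), c("a", "b")),
               "absent")
})

test_that("paired t-test matches the textbook formula and base R", {
  a <- c(0.5, 0.6, 0.7); b <- c(0.45, 0.50, 0.72)
  res <- paired_ttest(a, b)
  d <- a - b
  expect_equal(res$t, mean(d) / (stats::sd(d) / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$t, 1.2452, tolerance = 1e-3)
  expect_equal(res$df, 2)
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$p, tt$p.value)
  # antisymmetry
  expect_equal(paired_ttest(b, a)$t, -res$t)
  # identical vectors are degenerate with p reported as 1
  expect_warning(res0 <- paired_ttest(a, a), "zero")
  expect_true(is.nan(res0$t))
  expect_equal(res0$p, 1)
  # constant non-zero differences are undefined
  expect_warning(resc <- paired_ttest(a + 0.1, a), "zero-variance")
  expect_true(is.nan(resc$p))
})
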