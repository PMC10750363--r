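random_labels <- function(n, p = 0.6) {
  ifelse(runif(n) < p, "ASD", "non-ASD")
}

test_that("stratified group folds partition patients with balanced classes", {
  labs <- setNames(c(rep("ASD", 54), rep("non-ASD", 27)), sprintf("p%02d", 1:81))
  for (seed in 1:10) {
    fs <- stratified_group_kfold(labs, k = 5L, seed = seed)
    ids <- unlist(fs$folds)
    expect_setequal(ids, names(labs))          # exhaustive
    expect_false(anyDuplicated(ids) > 0)       # disjoint
    expect_identical(sort(lengths(fs$folds), decreasing = TRUE),
                     c(17L, 16L, 16L, 16L, 16L))
    for (f in fs$folds) {
      frac_expected <- 54 / 81 * length(f)
      expect_lte(abs(sum(labs[f] == "ASD") - frac_expected), 1)
    }
  }
  expect_error(stratified_group_kfold(labs[1:3], k = 5L),
               class = "gaitscreen_bad_folds")
  one_class <- setNames(rep("ASD", 10), paste0("q", 1:10))
  expect_error(stratified_group_kfold(one_class, k = 2L),
               class = "gaitscreen_bad_folds")
})

test_that("confusion counts match a brute-force tally", {
  set.seed(42)
  for (i in 1:20) {
    yt <- random_labels(40); yp <- random_labels(40)
    cm <- confusion(yt, yp)
    # independent elementwise loop
    tally <- matrix(0L, 2, 2)
    for (j in seq_along(yt)) {
      r <- if (yt[j] == "ASD") 1L else 2L
      c <- if (yp[j] == "ASD") 1L else 2L
      tally[r, c] <- tally[r, c] + 1L
    }
    expect_identical(unname(unclass(cm)), tally)
    expect_identical(sum(cm), 40L)
    # accuracy from the matrix equals the direct label-agreement mean
    expect_equal(accuracy(cm), mean(yt == yp))
  }
  perfect <- confusion(c("ASD", "non-ASD"), c("ASD", "non-ASD"))
  expect_identical(unname(unclass(perfect))[c(2, 3)], c(0L, 0L))
  expect_error(confusion("ASD", c("ASD", "ASD")),
               class = "gaitscreen_bad_labels")
})

test_that("F1 follows precision/recall and is scale invariant", {
  cm <- confusion(c("ASD", "ASD", "ASD", "non-ASD", "non-ASD"),
                  c("ASD", "ASD", "non-ASD", "ASD", "non-ASD"))
  prf <- precision_recall_f1(cm, positive = "ASD")
  expect_equal(unname(prf["precision"]), 2 / 3)
  expect_equal(unname(prf["recall"]), 2 / 3)
  expect_equal(unname(prf["f1"]),
               2 * prf[["precision"]] * prf[["recall"]] /
                 (prf[["precision"]] + prf[["recall"]]))
  scaled <- structure(unclass(cm) * 7, class = "gait_confusion")
  expect_equal(f1_score(scaled), f1_score(cm))
  perfect <- confusion(rep(c("ASD", "non-ASD"), 3), rep(c("ASD", "non-ASD"), 3))
  expect_equal(f1_score(perfect), 1.0)
})

test_that("rank AUROC matches the all-pairs oracle and pROC", {
  set.seed(7)
  yt <- random_labels(20)
  sc <- round(runif(20), 1)  # coarse scores force ties
  a <- auroc(yt, sc)
  # brute force over all positive-negative pairs, ties counted half
  pos <- sc[yt == "ASD"]; neg <- sc[yt == "non-ASD"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  expect_equal(a, tot / (length(pos) * length(neg)))
  expect_equal(a, as.numeric(suppressMessages(
    pROC::auc(pROC::roc(yt, sc, levels = c("non-ASD", "ASD"),
                        direction = "<")))))
  expect_equal(auroc(yt, as.numeric(yt == "ASD")),
               rater_auroc(confusion(yt, yt)))
  expect_equal(auroc(c("ASD", "non-ASD"), c(1, 0)), 1.0)
  expect_equal(auroc(c("ASD", "non-ASD", "ASD"), c(0.4, 0.4, 0.4)), 0.5)
  expect_error(auroc(c("ASD", "ASD"), c(0.1, 0.2)),
               class = "gaitscreen_empty")
})

test_that("rater reports reconstruct published-style metrics from ratios", {
  d1 <- report_from_ratios(rater_ratios(0.4074, 0.5926, 0.3704, 0.6296,
                                        54, 27))
  expect_equal(round(d1$accuracy, 4), 0.4815)
  expect_equal(round(d1$f1, 4), 0.4474)
  expect_equal(round(d1$auroc, 4), 0.5185)
  ident <- report_from_ratios(rater_ratios(1, 0, 0, 1, 10, 5))
  expect_equal(c(ident$accuracy, ident$f1, ident$auroc), c(1, 1, 1))
  expect_error(rater_ratios(0.5, 0.4, 0.5, 0.5, 10, 5))
  expect_error(rater_ratios(0.5, 0.5, 0.5, 0.5, 0, 5))
})

test_that("rater AUROC equals the rank AUROC of hard scores for random raters", {
  set.seed(11)
  for (i in 1:10) {
    yt <- random_labels(30)
    yp <- random_labels(30)
    cm <- confusion(yt, yp)
    expect_equal(rater_auroc(cm), auroc(yt, as.numeric(yp == "ASD")))
  }
})

test_that("CV aggregation is the arithmetic mean", {
  expect_equal(aggregate_cv(c(0.7, 0.8)), 0.75)
  expect_equal(aggregate_cv(0.5), 0.5)
  expect_error(aggregate_cv(numeric(0)), class = "gaitscreen_empty")
})
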