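test_that("cutoff_grid reproduces elementary confusion counts", {
  g <- cutoff_grid(c(10, 30), c("positive", "negative"), cutoffs = 20)
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity, 1)
  expect_equal(g$youden, 1)
  g2 <- cutoff_grid(c(10, 30), c("negative", "positive"), cutoffs = 20)
  expect_equal(g2$sensitivity, 0)
  expect_equal(g2$specificity, 0)
  expect_equal(g2$youden, -1)
  expect_error(cutoff_grid(c(1, 2), c("positive", "positive"), cutoffs = 1.5),
               "degenerate labels")
})

test_that("cutoff_grid equals exhaustive confusion-matrix counting", {
  set.seed(31)
  for (dir in c("<", ">=")) {
    scores <- round(runif(40, 10, 30), 1)
    labels <- sample(c("positive", "negative"), 40, replace = TRUE)
    cuts <- sort(unique(round(runif(10, 10, 30), 1)))
    g <- cutoff_grid(scores, labels, cutoffs = cuts, direction = dir)
    for (i in seq_along(cuts)) {
      test_pos <- if (dir == "<") scores < cuts[i] else scores >= cuts[i]
      tp <- sum(test_pos & labels == "positive")
      fn <- sum(!test_pos & labels == "positive")
      tn <- sum(!test_pos & labels == "negative")
      fp <- sum(test_pos & labels == "negative")
      expect_equal(g$sensitivity[i], tp / (tp + fn))
      expect_equal(g$specificity[i], tn / (tn + fp))
    }
  }
})

test_that("trapezoidal AUC handles degenerate and perfect grids", {
  expect_equal(trapezoidal_auc(data.frame(sensitivity = 1,
                                          specificity = 1)), 1)
  # chance-level single point
  expect_equal(trapezoidal_auc(data.frame(sensitivity = 0.5,
                                          specificity = 0.5)), 0.5)
})

test_that("trapezoidal AUC equals the pair-counting statistic on full grids", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(5:30, 1)
    scores <- round(rnorm(n, 20, 3), sample(0:1, 1))
    labels <- sample(c("lo", "hi"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    g <- cutoff_grid(scores, labels, positive = "hi", direction = ">=")
    auc <- trapezoidal_auc(g)
    oracle <- pair_count_auc(scores[labels == "hi"], scores[labels == "lo"])
    expect_equal(auc, oracle, tolerance = 1e-12)
    # flipping the class labels mirrors the AUC
    gf <- cutoff_grid(scores, labels, positive = "lo", direction = ">=")
    expect_equal(trapezoidal_auc(gf), 1 - auc, tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  set.seed(51)
  scores <- rnorm(60, 20, 3)
  labels <- rep(c("lo", "hi"), each = 30)
  scores[labels == "hi"] <- scores[labels == "hi"] + 2
  g <- cutoff_grid(scores, labels, positive = "hi", direction = ">=")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("lo", "hi"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(trapezoidal_auc(g), ref, tolerance = 1e-10)
})

test_that("accuracy bands follow the published boundaries", {
  expect_equal(accuracy_band(c(0.93, 0.82, 0.61, 0.45)),
               c("high", "moderate", "low", "below-chance"))
  expect_equal(accuracy_band(c(0.5, 0.7, 0.9, 0.901)),
               c("low", "moderate", "moderate", "high"))
})

test_that("the published grid is internally consistent apart from known typos", {
  combos <- expand.grid(d = c("s_ml", "sm_l"),
                        s = c("total", "male", "female"),
                        stringsAsFactors = FALSE)
  flagged <- list()
  for (i in seq_len(nrow(combos))) {
    g <- table1_grid(combos$d[i], combos$s[i])
    ok <- !is.na(g$sensitivity)
    recomputed <- g$sensitivity[ok] + g$specificity[ok] - 1
    bad <- attr(g, "inconsistent_rows")
    keep <- !(g$cutoff[ok] %in% bad)
    expect_true(all(abs(g$youden[ok][keep] - recomputed[keep]) <= 0.015))
    if (length(bad))
      flagged[[paste(combos$d[i], combos$s[i])]] <- bad
  }
  # exactly three misprinted rows exist, all in the S/ML male/female strata
  expect_equal(flagged,
               list(`s_ml male` = 16.5, `s_ml female` = c(15.5, 17.5)))
})

test_that("selection follows the floor, strictness and contiguity rules", {
  sel <- select_cutoffs(table1_grid("s_ml", "total"))
  expect_equal(sel$acceptable_range, c(18.5, 19.5))
  expect_equal(sel$chosen_cutoff, 18.5)
  expect_true(sel$youden_in_range)
  # non-strict floor admits the 20.5 row (sensitivity exactly 0.70)
  sel_ns <- select_cutoffs(table1_grid("s_ml", "total"), strict = FALSE)
  expect_equal(sel_ns$acceptable_range, c(18.5, 20.5))
  # non-strict floor reproduces the published male SM/L range 21.5-22.5
  sel_m <- select_cutoffs(table1_grid("sm_l", "male"), strict = FALSE)
  expect_equal(sel_m$acceptable_range, c(21.5, 22.5))
  # empty selection is a result, not an error
  sel_f <- select_cutoffs(table1_grid("sm_l", "female"))
  expect_null(sel_f$acceptable_range)
  expect_true(is.na(sel_f$chosen_cutoff))
  expect_false(sel_f$youden_in_range)
})

test_that("selection is unchanged by appending dominated cut-offs", {
  g <- table1_grid("s_ml", "total")
  base <- select_cutoffs(g)
  extra <- rbind(as.data.frame(g),
                 data.frame(cutoff = c(29, 30, 31), sensitivity = 0,
                            specificity = 1, youden = 0),
                 data.frame(cutoff = c(11, 12), sensitivity = 1,
                            specificity = 0, youden = 0))
  sel <- select_cutoffs(as_cutoff_grid(extra, "s_ml", "total"))
  expect_equal(sel$acceptable_range, base$acceptable_range)
  expect_equal(sel$max_youden, base$max_youden)
  expect_equal(sel$max_youden_cutoff, base$max_youden_cutoff)
})

test_that("joint threshold selection enforces the minimum separation", {
  joint <- select_tool_thresholds(table1_grid("s_ml", "total"),
                                  table1_grid("sm_l", "total"))
  expect_equal(joint$s_ml_cutoff, 18.5)
  expect_equal(joint$sm_l_cutoff, 21.5)
  expect_true(joint$separation_ok)
  expect_s3_class(joint$thresholds, "tool_thresholds")
  # demanding a wider gap than the grids allow trips the separation flag
  joint2 <- select_tool_thresholds(table1_grid("s_ml", "total"),
                                   table1_grid("sm_l", "total"),
                                   min_separation = 4)
  expect_false(joint2$separation_ok)
  expect_null(joint2$thresholds)
})

test_that("default candidate cut-offs bracket the scores at midpoints", {
  g <- cutoff_grid(c(14, 15, 17), c("hi", "lo", "hi"), positive = "hi",
                   direction = ">=")
  expect_equal(g$cutoff, c(13.25, 14.5, 16, 17.75))
  expect_equal(g$sensitivity[1], 1)  # everyone at or above the lowest
  expect_equal(g$specificity[nrow(g)], 1)
})
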