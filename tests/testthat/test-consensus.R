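test_that("consensus calls are exact set operations", {
  expect_true(consensus_call(TRUE, FALSE, "union"))
  expect_false(consensus_call(TRUE, FALSE, "intersection"))
  expect_true(consensus_call(TRUE, TRUE, "union"))
  expect_true(consensus_call(TRUE, TRUE, "intersection"))
  expect_false(consensus_call(FALSE, FALSE, "union"))
  # vectorised identity with logical operators
  set.seed(31)
  for (i in 1:20) {
    a <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    expect_identical(consensus_call(a, b, "union"), a | b)
    expect_identical(consensus_call(a, b, "intersection"), a & b)
  }
})

test_that("confusion counts, recall and precision are computed per model", {
  # hand-built 10-site set: 3 tp, 1 fp, 5 tn, 1 fn
  preds <- data.frame(
    call_rules = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                   FALSE, FALSE),
    label = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  )
  m <- evaluate_predictions(preds)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$tn, 5); expect_equal(m$fn, 1)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$tp + m$fp + m$tn + m$fn, nrow(preds))
  # perfect predictor
  p2 <- data.frame(call_rules = c(TRUE, TRUE, FALSE), label = c(1, 1, 0))
  m2 <- evaluate_predictions(p2)
  expect_equal(m2$recall, 1); expect_equal(m2$precision, 1)
  # all-negative predictor: recall 0, precision undefined
  p3 <- data.frame(call_rules = rep(FALSE, 4), label = c(1, 0, 0, 1))
  m3 <- evaluate_predictions(p3)
  expect_equal(m3$recall, 0)
  expect_true(is.na(m3$precision))
  expect_error(evaluate_predictions(p3[0, ]))
})

test_that("recall/precision ordering of consensus models holds on random sets", {
  set.seed(32)
  for (i in 1:30) {
    n <- 80
    preds <- data.frame(
      call_rules = sample(c(TRUE, FALSE), n, replace = TRUE),
      call_forest = sample(c(TRUE, FALSE), n, replace = TRUE),
      label = rbinom(n, 1, 0.3)
    )
    preds$call_union <- consensus_call(preds$call_rules, preds$call_forest,
                                       "union")
    preds$call_intersection <- consensus_call(preds$call_rules,
                                              preds$call_forest,
                                              "intersection")
    m <- evaluate_predictions(preds)
    rec <- setNames(m$recall, m$model)
    expect_gte(rec[["union"]], max(rec[["rules"]], rec[["forest"]]))
    expect_lte(rec[["intersection"]], min(rec[["rules"]], rec[["forest"]]))
    # union called set is the exact set union of the component call sets
    expect_identical(which(preds$call_union),
                     sort(union(which(preds$call_rules),
                                which(preds$call_forest))))
    expect_identical(which(preds$call_intersection),
                     sort(intersect(which(preds$call_rules),
                                    which(preds$call_forest))))
  }
})

test_that("AUROC matches hand-computed and oracle values", {
  # scores equal to labels: perfect ranking
  expect_equal(roc_auroc(c(1, 0, 1, 0), c(1, 0, 1, 0))$auroc, 1.0)
  # 4-point hand-computable case: 3 of 4 pos/neg pairs concordant
  r <- roc_auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(r$auroc, 0.75)
  # curve starts at (0,0) and ends at (1,1)
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  # degenerate labels rejected
  expect_error(roc_auroc(c(1, 2), c(1, 1)), "positive and one negative")
  # random sets with ties and -Inf (unscored) entries vs pair-counting
  set.seed(33)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    scores <- sample(c(-Inf, round(runif(8), 1)), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auroc(scores, labels)$auroc,
                 oracle_auroc(scores, labels))
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.25)
  ours <- roc_auroc(scores, labels)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("proportional-set construction tops negatives up to the ratio", {
  d <- gen_hairpin_dataset(10, 30, seed = 41)
  pool <- gen_hairpin_dataset(1, 5000, seed = 42)$sites
  pool <- pool[pool$label == 0, ]
  pool$gene <- paste0("pool_", pool$gene)  # ensure disjoint ids
  prop <- make_proportional_set(d$sites, pool, ratio = 468, seed = 5)
  expect_equal(sum(prop$label == 1), 10)
  expect_equal(sum(prop$label == 0), 4680)
  # positives carried over unchanged
  expect_identical(prop[prop$label == 1, ], d$sites[d$sites$label == 1, ])
  # ratio 3 already satisfied: identical to the testing set
  expect_identical(make_proportional_set(d$sites, pool, ratio = 3, seed = 5),
                   d$sites)
  # determinism
  expect_identical(prop, make_proportional_set(d$sites, pool, 468, seed = 5))
  # overlapping pool is an error
  expect_error(make_proportional_set(d$sites, d$sites[d$sites$label == 0, ],
                                     468, 1),
               "overlap")
})

test_that("adding true negatives never changes recall", {
  set.seed(43)
  preds <- data.frame(call_rules = sample(c(TRUE, FALSE), 40, TRUE),
                      label = rbinom(40, 1, 0.5))
  extra <- data.frame(call_rules = rep(FALSE, 60), label = 0)
  m1 <- evaluate_predictions(preds)
  m2 <- evaluate_predictions(rbind(preds, extra))
  expect_equal(m1$recall, m2$recall)
  expect_equal(m1$precision, m2$precision)  # no new false positives
  # negatives that include false positives reduce precision
  fp_extra <- data.frame(call_rules = rep(TRUE, 10), label = 0)
  m3 <- evaluate_predictions(rbind(preds, fp_extra))
  expect_lt(m3$precision, m1$precision)
  expect_equal(m3$recall, m1$recall)
})
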