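# brute-force tie-corrected Mann-Whitney AUC: independent oracle for roc_auc
mw_auc <- function(scores, truth, positive = "high") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

test_that("the 70/30 split partitions deterministically", {
  d <- data.frame(x = seq_len(441))
  sp <- split_cohort(d, 0.7, seed = 1)
  expect_identical(nrow(sp$train), 309L)  # round(441 * 0.7)
  expect_identical(nrow(sp$test), 132L)
  expect_identical(sort(c(sp$train$x, sp$test$x)), d$x)
  expect_length(intersect(sp$train$x, sp$test$x), 0L)

  sp2 <- split_cohort(d, 0.7, seed = 1)
  sp3 <- split_cohort(d, 0.7, seed = 2)
  expect_identical(sp$train$x, sp2$train$x)
  expect_false(identical(sp$train$x, sp3$train$x))
  expect_identical(nrow(sp3$train), 309L)

  tiny <- split_cohort(data.frame(x = 1:2), 0.5, seed = 1)
  expect_identical(nrow(tiny$train), 1L)
  expect_identical(nrow(tiny$test), 1L)
  expect_error(split_cohort(data.frame(x = 1), 0.5), "at least 2")
  expect_error(split_cohort(d, 1.2), "in \\(0, 1\\)")
  expect_error(split_cohort(data.frame(x = 1:3), 0.01), "empty partition")
})

test_that("predict_proba equals the full-evidence posterior query", {
  set.seed(61)
  bn <- random_bn(5, 3, edge_prob = 0.5)
  target <- bn$schema$outcome
  high <- bn$schema$variables[[target]]$categories[2]
  d <- sample_cohort(bn, 20, seed = 62)
  p <- predict_proba(bn, d, target, high)
  for (i in seq_len(nrow(d))) {
    ev <- as.list(d[i, setdiff(bn$dag$nodes, target), drop = FALSE])
    ev <- lapply(ev, as.character)
    q <- enumerate_query(bn, target, hard_evidence(ev))
    expect_equal(p[i], q$distribution[[high]], tolerance = 1e-12)
  }

  # target with no edges: posterior is the marginal for every record
  ind <- independent_bn(list(u = c(0.4, 0.6), y = c(0.7, 0.3)))
  d2 <- sample_cohort(ind, 10, seed = 63)
  expect_equal(predict_proba(ind, d2, "y", "y2"), rep(0.3, 10))

  expect_error(predict_proba(bn, d[, 1:2, drop = FALSE], target, high),
               "missing predictor")
})

test_that("predicted probabilities are calibrated in the large", {
  bn <- default_ha_ground_truth()
  d <- sample_cohort(bn, 50000, seed = 64)
  p <- predict_proba(bn, d)
  marg <- enumerated_marginal(bn, "mortality", "eliminate")[["high"]]
  se <- sqrt(marg * (1 - marg) / nrow(d))
  expect_lt(abs(mean(p) - marg), 4 * se)
})

test_that("classification threshold is boundary-inclusive and configurable", {
  p <- c(0.2, 0.5, 0.8)
  expect_identical(as.character(classify(p, 0.5)), c("low", "high", "high"))
  expect_identical(as.character(classify(p, 0)), rep("high", 3))
  expect_identical(as.character(classify(p, 0.9)), rep("low", 3))
  expect_error(classify(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("confusion metrics reproduce hand-computed rates", {
  pred <- c(rep("high", 42), rep("low", 8), rep("low", 38), rep("high", 12))
  truth <- c(rep("high", 42), rep("high", 8), rep("low", 38), rep("low", 12))
  m <- confusion_metrics(pred, truth)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(42L, 8L, 38L, 12L))
  expect_equal(m$sensitivity, 0.84)
  expect_equal(m$specificity, 0.76)
  expect_equal(m$accuracy, 0.80)
  expect_equal(m$balanced_accuracy, (0.84 + 0.76) / 2)
  expect_equal(m$ppv, 42 / 54)
  expect_equal(m$npv, 38 / 46)
  expect_equal(m$detection_rate, 0.42)
  expect_equal(m$detection_prevalence, 0.54)

  perfect <- confusion_metrics(truth, truth)
  for (f in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(perfect[[f]], 1)
  }

  expect_warning(m0 <- confusion_metrics(rep("low", 4),
                                         c("low", "low", "high", "high")),
                 "ppv undefined")
  expect_true(is.nan(m0$ppv))
  expect_error(confusion_metrics(c("high", "weird"), c("high", "low")),
               "outside")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(71)
  for (i in 1:50) {
    counts <- stats::rmultinom(1, sample(10:200, 1), rep(0.25, 4))
    pred <- c(rep("high", counts[1] + counts[2]),
              rep("low", counts[3] + counts[4]))
    truth <- c(rep("high", counts[1]), rep("low", counts[2]),
               rep("high", counts[3]), rep("low", counts[4]))
    m <- suppressWarnings(confusion_metrics(pred, truth))
    n <- m$tp + m$fp + m$tn + m$fn
    expect_equal(m$accuracy, (m$tp + m$tn) / n)
    if (!is.nan(m$balanced_accuracy)) {
      expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    }
    expect_lte(m$detection_rate, m$detection_prevalence)
    prevalence <- (m$tp + m$fn) / n
    if (!is.nan(m$sensitivity)) {
      expect_lte(m$detection_rate, m$sensitivity * prevalence + 1e-12)
    }
  }
})

test_that("tie-aware trapezoidal AUC matches reference cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("high", "high", "low", "low"))$auc, 1)
  tied <- roc_auc(rep(0.5, 6), c("high", "low", "high", "low", "high", "low"))
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$points,
               data.frame(fpr = c(0, 1), tpr = c(0, 1)))  # single segment
  # 4 positive-negative pairs: 3 wins, 1 loss
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6),
                       c("high", "low", "high", "low"))$auc, 0.75)
  expect_error(roc_auc(c(0.1, 0.9), c("high", "high")), "single class")
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(81)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    truth <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    r <- roc_auc(scores, truth)
    expect_equal(r$auc, mw_auc(scores, truth), tolerance = 1e-12)
    # ROC path is monotone from (0,0) to (1,1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(91)
  for (i in 1:10) {
    n <- 60
    scores <- round(stats::runif(n), 2)
    truth <- sample(c("high", "low"), n, replace = TRUE, prob = c(0.4, 0.6))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("low", "high"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-12)
  }
})

test_that("end-to-end validation approaches the Bayes limit on identifiable nets", {
  # a network whose CPTs the sample can actually pin down: the fitted
  # model's held-out AUC converges to the Bayes-optimal AUC of the truth
  set.seed(94)
  bn <- random_bn(6, 3, edge_prob = 0.5)
  target <- bn$schema$outcome
  high <- bn$schema$variables[[target]]$categories[1]  # one-vs-rest scoring
  d <- sample_cohort(bn, 20000, seed = 95)
  sp <- split_cohort(d, 0.7, seed = 96)
  fit <- fit_cpts_bayes(bn$dag, bn$schema, sp$train)
  p_fit <- predict_proba(fit, sp$test, target, high)
  p_opt <- predict_proba(bn, sp$test, target, high)
  truth_lbl <- as.character(sp$test[[target]])
  auc_fit <- roc_auc(p_fit, truth_lbl, positive = high)$auc
  auc_opt <- roc_auc(p_opt, truth_lbl, positive = high)$auc
  expect_lt(abs(auc_fit - auc_opt), 0.02)

  # the default cohort-scale network: discrimination above chance, below
  # the ground-truth ceiling (its outcome CPT dwarfs any realistic sample)
  ha <- default_ha_ground_truth()
  dh <- sample_cohort(ha, 20000, seed = 97)
  sph <- split_cohort(dh, 0.7, seed = 98)
  fith <- suppressWarnings(fit_cpts_bayes(ha$dag, ha$schema, sph$train))
  val <- evaluate_model(fith, sph$train, sph$test)
  opt_auc <- roc_auc(predict_proba(ha, sph$test),
                     as.character(sph$test$mortality))$auc
  expect_gt(val$test$roc$auc, 0.5)
  expect_lte(val$test$roc$auc, opt_auc + 0.02)
  expect_gte(val$train$roc$auc, val$test$roc$auc)
})
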