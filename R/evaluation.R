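#' Random train/test split
#'
#' Simple random partition (no stratification): `round(n * fraction)`
#' records go to the training set, the remainder to the test set.
#' Deterministic for a given seed.
#'
#' @param data Cohort data frame.
#' @param fraction Training fraction in (0, 1); default 0.7.
#' @param seed Integer seed, or `NULL`.
#' @return List with elements `train` and `test` (disjoint, exhaustive).
#' @export
split_cohort <- function(data, fraction = 0.7, seed = NULL) {
  n <- nrow(data)
  if (is.null(n) || n < 2L) stop2("need at least 2 records to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop2("fraction must be in (0, 1)")
  }
  n_train <- round(n * fraction)
  if (n_train < 1L || n_train > n - 1L) {
    stop2("split leaves an empty partition (n = ", n,
          ", fraction = ", fraction, ")")
  }
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Posterior probability of the high-risk state per record
#'
#' Conditions the network on every predictor of each record and returns the
#' exact posterior probability of `high_state` for the target. Equivalent to
#' a full-evidence [scenario_query()] per record, computed in vectorised
#' form: with all non-target variables observed, the posterior is
#' proportional to the joint probability at each target state.
#'
#' @param bn A fitted `bn_net`.
#' @param newdata Data frame supplying every predictor column (the target
#'   column, if present, is ignored).
#' @param target Target variable (default: schema outcome).
#' @param high_state Category whose probability is returned.
#' @return Numeric vector of probabilities, one per record.
#' @export
predict_proba <- function(bn, newdata, target = bn$schema$outcome,
                          high_state = "high") {
  nodes <- bn$dag$nodes
  if (!target %in% nodes) stop2("unknown target '", target, "'")
  cats <- schema_categories(bn$schema, target)
  if (!high_state %in% cats) {
    stop2("'", high_state, "' is not a category of '", target, "'")
  }
  preds <- setdiff(nodes, target)
  missing_cols <- setdiff(preds, names(newdata))
  if (length(missing_cols)) {
    stop2("newdata is missing predictor(s): ",
          paste(missing_cols, collapse = ", "))
  }
  df <- newdata[preds]
  for (v in preds) {
    col <- as.character(df[[v]])
    bad <- which(is.na(col) | !col %in% schema_categories(bn$schema, v))
    if (length(bad)) {
      stop2("column '", v, "' has invalid value in row ", bad[1])
    }
    df[[v]] <- factor(col, levels = schema_categories(bn$schema, v))
  }
  codes <- cohort_codes(df, bn$schema, preds)
  codes <- cbind(codes, matrix(1L, nrow(codes), 1L,
                               dimnames = list(NULL, target)))
  mass <- vapply(seq_along(cats), function(k) {
    codes[, target] <- k
    joint_probability_codes(bn, codes)
  }, numeric(nrow(codes)))
  if (is.null(dim(mass))) mass <- matrix(mass, nrow = 1L)
  total <- rowSums(mass)
  if (any(total <= 0)) {
    stop2("impossible evidence: record ", which(total <= 0)[1],
          " has zero probability under the model")
  }
  mass[, match(high_state, cats)] / total
}

#' Threshold probabilities into class labels
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold; a record is labelled positive when
#'   its probability is `>= threshold` (boundary inclusive). Default 0.5.
#' @param labels Length-2 character vector `c(negative, positive)`.
#' @return Factor of labels with levels `labels`.
#' @export
classify <- function(probabilities, threshold = 0.5,
                     labels = c("low", "high")) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop2("probabilities must lie in [0, 1]")
  }
  factor(ifelse(probabilities >= threshold, labels[2], labels[1]),
         levels = labels)
}

#' Confusion-matrix metrics
#'
#' Counts and derived rates for binary classification. Ratios with a zero
#' denominator are reported as `NaN` with a warning, never silently zero.
#' Detection rate is `TP / N` (fraction of all records correctly flagged
#' positive); detection prevalence is `(TP + FP) / N` (fraction flagged
#' positive at all).
#'
#' @param pred Predicted labels.
#' @param truth True labels (same length).
#' @param positive Positive-class label (default `"high"`).
#' @param negative Negative-class label (default `"low"`).
#' @return A list of class `bn_confusion` with counts `tp`, `fp`, `tn`,
#'   `fn` and rates `accuracy`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `detection_rate`, `detection_prevalence`.
#' @export
confusion_metrics <- function(pred, truth, positive = "high",
                              negative = "low") {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop2("pred and truth must have equal length")
  }
  allowed <- c(negative, positive)
  bad <- setdiff(unique(c(pred, truth)), allowed)
  if (length(bad)) {
    stop2("label '", bad[1], "' outside {", negative, ", ", positive, "}")
  }
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth == negative)
  tn <- sum(pred == negative & truth == negative)
  fn <- sum(pred == negative & truth == positive)
  n <- tp + fp + tn + fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = ratio(tp + tn, n, "accuracy"),
    balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens,
    specificity = spec,
    ppv = ratio(tp, tp + fp, "ppv"),
    npv = ratio(tn, tn + fn, "npv"),
    detection_rate = ratio(tp, n, "detection rate"),
    detection_prevalence = ratio(tp + fp, n, "detection prevalence")),
    class = "bn_confusion")
}

#' @export
print.bn_confusion <- function(x, ...) {
  cat("Confusion counts: TP", x$tp, "FP", x$fp, "TN", x$tn, "FN", x$fn, "\n")
  for (m in c("accuracy", "balanced_accuracy", "sensitivity", "specificity",
              "ppv", "npv", "detection_rate", "detection_prevalence")) {
    cat(sprintf("  %-21s %s\n", m,
                if (is.nan(x[[m]])) "undefined (zero denominator)"
                else sprintf("%.4f", x[[m]])))
  }
  invisible(x)
}

#' ROC curve and tie-aware AUC
#'
#' Sweeps every distinct score as a threshold (tied scores grouped, so the
#' curve of a discrete classifier is a few straight segments) and integrates
#' by the trapezoid rule. This equals the tie-corrected Mann-Whitney
#' statistic `U / (n+ * n-)` with ties counted one half.
#'
#' @param scores Numeric scores in `[0, 1]`, higher meaning more positive.
#' @param truth True labels.
#' @param positive Positive-class label (default `"high"`).
#' @return A list of class `bn_roc` with `points` (data frame of `fpr`,
#'   `tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = "high") {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) {
    stop2("scores and truth must have equal length")
  }
  if (any(scores < 0 | scores > 1, na.rm = TRUE) || anyNA(scores)) {
    stop2("scores must lie in [0, 1]")
  }
  is_pos <- truth == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop2("AUC undefined: truth contains a single class")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_pos[ord]
  # group tied scores: one ROC point per distinct threshold
  last_of_group <- c(s[-length(s)] != s[-1], TRUE)
  tpr <- c(0, cumsum(pos)[last_of_group] / n_pos)
  fpr <- c(0, cumsum(!pos)[last_of_group] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "bn_roc")
}

#' @export
print.bn_roc <- function(x, ...) {
  cat("ROC with", nrow(x$points), "points; AUC =", format(x$auc), "\n")
  invisible(x)
}

#' Train/test validation of a fitted network
#'
#' Scores both splits with [predict_proba()], thresholds into classes, and
#' reports confusion-matrix metrics plus tie-aware AUC per split.
#'
#' @param bn A fitted `bn_net`.
#' @param train,test Cohort data frames including the outcome column.
#' @param target Outcome variable (default: schema outcome).
#' @param high_state Positive-class category.
#' @param threshold Classification threshold (default 0.5).
#' @return A list of class `bn_validation` with elements `train` and `test`,
#'   each holding `metrics` (`bn_confusion`), `roc` (`bn_roc`) and `n`.
#' @export
evaluate_model <- function(bn, train, test, target = bn$schema$outcome,
                           high_state = "high", threshold = 0.5) {
  low_state <- setdiff(schema_categories(bn$schema, target), high_state)
  if (length(low_state) != 1L) {
    stop2("evaluate_model requires a binary target")
  }
  eval_split <- function(data) {
    p <- predict_proba(bn, data, target, high_state)
    pred <- classify(p, threshold, labels = c(low_state, high_state))
    truth <- as.character(data[[target]])
    list(metrics = confusion_metrics(pred, truth, positive = high_state,
                                     negative = low_state),
         roc = roc_auc(p, truth, positive = high_state),
         n = nrow(data))
  }
  structure(list(train = eval_split(train), test = eval_split(test),
                 threshold = threshold),
            class = "bn_validation")
}

#' @export
print.bn_validation <- function(x, ...) {
  for (split in c("train", "test")) {
    cat("==", split, "(n =", x[[split]]$n, ") AUC =",
        format(round(x[[split]]$roc$auc, 4)), "==\n")
    print(x[[split]]$metrics)
  }
  invisible(x)
}
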