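#' Random-forest model specification
#'
#' Hyperparameters of the exploratory stay classifier: 10 trees of
#' maximum depth 5 with nodes of two or more samples eligible to split
#' (so minimum terminal node size 1), evaluated with 5-fold
#' cross-validation on the training portion and a stratified hold-out
#' test split.
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth.
#' @param min_node_size minimum terminal node size (1 corresponds to a
#'   minimum of 2 samples for a split).
#' @param cv_folds cross-validation folds.
#' @param test_fraction fraction of stays held out for testing
#'   (stratified by class).
#' @param seed RNG seed governing the split and the forest.
#' @return an \code{rf_spec} list.
#' @export
rf_spec <- function(n_trees = 10, max_depth = 5, min_node_size = 1,
                    cv_folds = 5, test_fraction = 0.4, seed = 1) {
  ints <- c(n_trees = n_trees, max_depth = max_depth,
            min_node_size = min_node_size, cv_folds = cv_folds)
  if (any(ints < 1) || any(ints != trunc(ints)))
    stop("rf_spec fields must be positive integers", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size),
                 cv_folds = as.integer(cv_folds),
                 test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "rf_spec")
}

#' AUC by the rank-sum statistic
#'
#' Area under the ROC curve computed as the Mann-Whitney probability
#' that a randomly chosen positive scores above a randomly chosen
#' negative, with ties counted one half.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or 0/1 vector, \code{TRUE} = positive.
#' @return AUC in [0, 1]; \code{NA} if either class is empty.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix performance metrics
#'
#' Computes accuracy, sensitivity (smoker recall), specificity
#' (nonsmoker recall), per-class precision/recall/F1, class-size
#' weighted averages, and — when prediction scores are supplied — AUC by
#' the rank statistic. A metric whose denominator is an empty class is
#' reported as \code{NA} (undefined), never coerced to zero.
#'
#' @param tn,fp,fn,tp confusion-matrix cells; positives are smoker
#'   stays.
#' @param scores optional numeric scores for AUC.
#' @param score_labels optional logical labels aligned with
#'   \code{scores}.
#' @return an \code{evaluation_report} list: \code{confusion},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{per_class} tibble, \code{weighted} named vector, \code{auc},
#'   \code{n_test}, \code{class_sizes}.
#' @export
#' @examples
#' compute_metrics(tn = 37, fp = 1, fn = 1, tp = 3)
compute_metrics <- function(tn, fp, fn, tp, scores = NULL,
                            score_labels = NULL) {
  cells <- c(tn, fp, fn, tp)
  if (any(cells < 0) || sum(cells) == 0)
    stop("confusion cells must be >= 0 with positive total", call. = FALSE)
  n <- sum(cells)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_

  sens <- safe_div(tp, tp + fn)             # smoker recall
  spec <- safe_div(tn, tn + fp)             # nonsmoker recall
  prec_smoker <- safe_div(tp, tp + fp)
  prec_non <- safe_div(tn, tn + fn)
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || (p + r) == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  per_class <- tibble::tibble(
    class = c("nonsmoker", "smoker"),
    n = c(tn + fp, tp + fn),
    precision = c(prec_non, prec_smoker),
    recall = c(spec, sens),
    f1 = c(f1(prec_non, spec), f1(prec_smoker, sens))
  )
  w <- per_class$n / n
  wavg <- function(x) if (any(is.na(x) & w > 0)) NA_real_ else sum(w * x, na.rm = TRUE)
  weighted <- c(precision = wavg(per_class$precision),
                recall = wavg(per_class$recall),
                f1 = wavg(per_class$f1))
  auc <- if (!is.null(scores)) auc_rank(scores, score_labels) else NA_real_

  structure(
    list(confusion = c(tn = tn, fp = fp, fn = fn, tp = tp),
         accuracy = (tn + tp) / n,
         sensitivity = sens,
         specificity = spec,
         per_class = per_class,
         weighted = weighted,
         auc = auc,
         n_test = n,
         class_sizes = c(nonsmoker = tn + fp, smoker = tp + fn)),
    class = "evaluation_report"
  )
}

# stratified train/test index split
stratified_split <- function(labels, test_fraction) {
  test_idx <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  sort(test_idx)
}

#' Train and evaluate the exploratory stay classifier
#'
#' Fits a random forest on stay duration, mean RSSI and RSSI
#' variability to discriminate smoker from nonsmoker stays, using a
#' stratified hold-out split. Reports held-out confusion-matrix metrics
#' and rank-statistic AUC from the forest's predicted class
#' probabilities, plus the cross-validated accuracy on the training
#' portion. Deterministic given the data and \code{spec$seed}.
#'
#' @param features tibble with columns \code{dwell_min},
#'   \code{mean_rssi}, \code{sd_rssi}.
#' @param labels factor (or character) with levels \code{smoker} /
#'   \code{nonsmoker}; smoker is the positive class.
#' @param spec an [rf_spec()].
#' @return an \code{evaluation_report} (see [compute_metrics()]) with
#'   additional elements \code{cv_accuracy} and \code{test_index}.
#' @export
train_and_evaluate <- function(features, labels, spec = rf_spec()) {
  labels <- factor(as.character(labels), levels = c("nonsmoker", "smoker"))
  if (any(is.na(labels)))
    stop("labels must be 'smoker' or 'nonsmoker'", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("evaluation undefined: a single class is present", call. = FALSE)
  dat <- data.frame(
    dwell_min = features$dwell_min,
    mean_rssi = features$mean_rssi,
    sd_rssi = features$sd_rssi,
    label = labels
  )
  set.seed(spec$seed)
  test_idx <- stratified_split(dat$label, spec$test_fraction)
  train <- dat[-test_idx, , drop = FALSE]
  test <- dat[test_idx, , drop = FALSE]

  fit_rf <- function(d, seed) {
    ranger::ranger(label ~ dwell_min + mean_rssi + sd_rssi, data = d,
                   num.trees = spec$n_trees, max.depth = spec$max_depth,
                   min.node.size = spec$min_node_size,
                   probability = TRUE, seed = seed)
  }
  fit <- fit_rf(train, spec$seed)
  prob <- stats::predict(fit, data = test)$predictions[, "smoker"]
  pred_smoker <- prob >= 0.5
  truth_smoker <- test$label == "smoker"
  rep <- compute_metrics(
    tn = sum(!pred_smoker & !truth_smoker),
    fp = sum(pred_smoker & !truth_smoker),
    fn = sum(!pred_smoker & truth_smoker),
    tp = sum(pred_smoker & truth_smoker),
    scores = prob, score_labels = truth_smoker
  )

  # k-fold CV accuracy on the training portion (stratified folds)
  folds <- rep(NA_integer_, nrow(train))
  for (lv in levels(train$label)) {
    idx <- which(train$label == lv)
    folds[idx] <- sample(rep_len(seq_len(spec$cv_folds), length(idx)))
  }
  correct <- 0L
  for (k in seq_len(spec$cv_folds)) {
    tr <- train[folds != k, , drop = FALSE]
    te <- train[folds == k, , drop = FALSE]
    if (nrow(te) == 0 || length(unique(tr$label)) < 2) next
    f <- fit_rf(tr, spec$seed + k)
    p <- stats::predict(f, data = te)$predictions[, "smoker"] >= 0.5
    correct <- correct + sum(p == (te$label == "smoker"))
  }
  rep$cv_accuracy <- correct / nrow(train)
  rep$test_index <- test_idx
  rep
}
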