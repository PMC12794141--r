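#' @title Classification and regression metrics, cross-validation harness
#' @description
#' Accuracy and Matthews correlation from confusion counts, binary
#' cross-entropy, ranking metrics (tie-corrected Mann-Whitney AUC and
#' step-integrated precision-recall AUC), the coefficient of
#' determination, and a fold-based cross-validation driver.
#' @name evalx
NULL

#' Accuracy and Matthews correlation from confusion counts
#'
#' ACC = (TP + TN) / total; MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)
#' (TN+FP)(TN+FN)), with the conventional value 0 when any denominator
#' factor is zero.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return tibble with `acc` and `mcc`.
#' @export
mp_confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) abort("all confusion counts are zero")
  acc <- (tp + tn) / total
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  tibble(acc = acc, mcc = mcc)
}

#' Binary cross-entropy
#'
#' Mean of -[y log p + (1-y) log(1-p)], with probabilities clamped to
#' (eps, 1-eps).
#'
#' @param y binary labels in \{0, 1\}.
#' @param p predicted probabilities.
#' @param eps clamping constant.
#' @return scalar loss >= 0.
#' @export
mp_bce <- function(y, p, eps = 1e-7) {
  if (length(y) != length(p)) abort("`y` and `p` lengths differ")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Ranking metrics: ROC AUC and precision-recall AUC
#'
#' AUC uses the tie-corrected Mann-Whitney formulation (midranks); PR-AUC
#' uses conservative step integration of precision over recall (no linear
#' interpolation between operating points).
#'
#' @param labels binary labels in \{0, 1\}; both classes must be present.
#' @param scores real-valued scores, higher = more positive.
#' @return tibble with `auc` and `pr_auc`.
#' @export
mp_ranking_metrics <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(-scores)  # stable: ties keep record order
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / n1
  # collapse tied scores to a single operating point (the last of each run)
  s <- scores[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  prec <- prec[keep]; rec <- rec[keep]
  drec <- diff(c(0, rec))
  tibble(auc = auc, pr_auc = sum(prec * drec))
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot; can be negative for fits worse than the mean.
#'
#' @param targets observed values (>= 2, nonzero variance).
#' @param predictions predicted values.
#' @return scalar <= 1.
#' @export
mp_r_squared <- function(targets, predictions) {
  stopifnot(length(targets) == length(predictions))
  if (length(targets) < 2 || stats::sd(targets) == 0) {
    abort("targets must have nonzero variance")
  }
  1 - sum((targets - predictions)^2) / sum((targets - mean(targets))^2)
}

#' Cross-validate a model builder over pre-assigned folds
#'
#' For each fold: train the builder on the remaining folds, score the
#' held-out fold, and compute the requested metrics; folds whose training
#' portion contains a single class are skipped with a warning. Per-fold
#' predictions are kept for audit.
#'
#' @param data record tibble with `y` and `fold` columns (see
#'   [mp_assign_folds()]).
#' @param builder function(train, test, seed) returning a numeric score
#'   (probability) vector for `test`.
#' @param metrics subset of c("acc", "mcc", "auc", "pr_auc", "bce").
#' @param seed integer seed passed to the builder per fold.
#' @param threshold probability threshold for acc/mcc.
#' @return an `mp_metric_report`: `summary` (mean and sd per metric),
#'   `per_fold`, and `predictions` tibbles.
#' @export
mp_cross_validate <- function(data, builder,
                              metrics = c("acc", "mcc", "auc", "pr_auc", "bce"),
                              seed = 1, threshold = 0.5) {
  data <- as_tibble(data)
  stopifnot(all(c("y", "fold") %in% names(data)))
  folds <- sort(unique(data$fold))
  per_fold <- list(); preds <- list()
  for (f in folds) {
    train <- data[data$fold != f, ]
    test <- data[data$fold == f, ]
    if (length(unique(train$y)) < 2) {
      warn(sprintf("fold %s skipped: single-class training set", f))
      next
    }
    p <- builder(train, test, derive_seed(seed, paste0("fold_", f)))
    stopifnot(length(p) == nrow(test))
    preds[[as.character(f)]] <- tibble(fold = f, y = test$y, p = p,
      inchikey = if ("inchikey" %in% names(test)) test$inchikey else NA_character_)
    row <- tibble(fold = f)
    yhat <- as.integer(p >= threshold)
    if (any(c("acc", "mcc") %in% metrics)) {
      cm <- mp_confusion_metrics(sum(yhat == 1 & test$y == 1),
                                 sum(yhat == 0 & test$y == 0),
                                 sum(yhat == 1 & test$y == 0),
                                 sum(yhat == 0 & test$y == 1))
      if ("acc" %in% metrics) row$acc <- cm$acc
      if ("mcc" %in% metrics) row$mcc <- cm$mcc
    }
    if (any(c("auc", "pr_auc") %in% metrics) && length(unique(test$y)) == 2) {
      rm_ <- mp_ranking_metrics(test$y, p)
      if ("auc" %in% metrics) row$auc <- rm_$auc
      if ("pr_auc" %in% metrics) row$pr_auc <- rm_$pr_auc
    }
    if ("bce" %in% metrics) row$bce <- mp_bce(test$y, p)
    per_fold[[as.character(f)]] <- row
  }
  per_fold <- bind_rows(per_fold)
  if (nrow(per_fold) == 0) abort("no usable folds")
  msum <- per_fold |>
    tidyr::pivot_longer(-"fold", names_to = "metric") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(summary = msum, per_fold = per_fold,
                 predictions = bind_rows(preds)),
            class = "mp_metric_report")
}

#' @export
print.mp_metric_report <- function(x, ...) {
  cat("<mp_metric_report>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy mp_metric_report
#' @export
tidy.mp_metric_report <- function(x, ...) x$per_fold

#' @method glance mp_metric_report
#' @export
glance.mp_metric_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}
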