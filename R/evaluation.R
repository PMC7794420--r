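# Classification performance metrics: confusion matrix, accuracy/precision/
# sensitivity/F1/specificity, ROC curve and AUC. COPD is the positive class
# throughout; threshold ties count as positive.

#' Confusion matrix from predicted COPD probabilities
#'
#' @param p_copd numeric vector of predicted probabilities of COPD.
#' @param label character/factor vector with values "COPD" / "non-COPD".
#' @param threshold decision threshold; `p_copd >= threshold` predicts COPD
#'   (ties count positive).
#' @return object of class `confusion_matrix` with counts `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion <- function(p_copd, label, threshold = 0.5) {
  if (length(p_copd) == 0L) stop("no predictions", call. = FALSE)
  label <- check_labels(label)
  if (length(p_copd) != length(label))
    stop("predictions and labels differ in length", call. = FALSE)
  pred_pos <- p_copd >= threshold
  pos <- label == "COPD"
  structure(list(tp = sum(pred_pos & pos), fn = sum(!pred_pos & pos),
                 fp = sum(pred_pos & !pos), tn = sum(!pred_pos & !pos)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from raw counts
#' @param tp,fn,fp,tn non-negative counts (COPD = positive class).
#' @return object of class `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_matrix")
}

#' Scalar performance metrics from a confusion matrix
#'
#' Accuracy, precision, sensitivity (recall), F1 (harmonic mean of precision
#' and sensitivity) and specificity, all as fractions in \[0, 1\]. A ratio
#' with zero denominator is reported as 0 with a warning.
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector.
#' @export
eval_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator), reported as 0",
              call. = FALSE)
      0
    } else num / den
  }
  acc  <- (cm$tp + cm$tn) / n
  prec <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  sens <- safe_div(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_div(cm$tn, cm$tn + cm$fp, "specificity")
  f1 <- if (prec + sens == 0) {
    warning("F1 undefined (zero denominator), reported as 0", call. = FALSE)
    0
  } else 2 * prec * sens / (prec + sens)
  c(accuracy = acc, precision = prec, sensitivity = sens, f1 = f1,
    specificity = spec)
}

#' ROC curve and AUC from predicted COPD probabilities
#'
#' Threshold sweep over the unique scores; AUC by the trapezoidal rule,
#' which equals the Mann-Whitney probability that a random COPD subject
#' scores above a random non-COPD subject (ties counted half).
#'
#' @inheritParams confusion
#' @return list with `roc` (data.frame of `fpr`, `tpr`, starting at (0,0)
#'   and ending at (1,1), both non-decreasing) and `auc`.
#' @export
roc_auc <- function(p_copd, label) {
  label <- check_labels(label)
  pos <- label == "COPD"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes present", call. = FALSE)
  thr <- sort(unique(p_copd), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(p_copd >= t & pos) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(p_copd >= t & !pos) / n_neg, 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation report from pooled predictions
#'
#' @inheritParams confusion
#' @return object of class `eval_report`: scalar metrics, confusion matrix,
#'   ROC points and AUC.
#' @export
eval_report <- function(p_copd, label, threshold = 0.5) {
  cm <- confusion(p_copd, label, threshold)
  ra <- roc_auc(p_copd, label)
  structure(list(metrics = eval_metrics(cm), confusion = cm, roc = ra$roc,
                 auc = ra$auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0("<eval_report> acc %.3f | prec %.3f | sens %.3f | F1 %.3f | ",
           "spec %.3f | AUC %.3f\n"),
    m["accuracy"], m["precision"], m["sensitivity"], m["f1"],
    m["specificity"], x$auc))
  cat(sprintf("  confusion: TP %d  FN %d  FP %d  TN %d\n",
              x$confusion$tp, x$confusion$fn, x$confusion$fp, x$confusion$tn))
  invisible(x)
}

check_labels <- function(label) {
  label <- as.character(label)
  bad <- setdiff(unique(label), c("COPD", "non-COPD"))
  if (length(bad))
    stop("labels must be 'COPD' or 'non-COPD', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  label
}
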