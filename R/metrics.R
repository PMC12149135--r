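#' Classification metrics report
#'
#' Confusion counts at the given threshold (standard definitions: TP =
#' positives predicted positive, TN = negatives predicted negative),
#' accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient, plus threshold-free curves: the ROC (with trapezoidal
#' AUC; tied scores collapse to one operating point, so ties contribute
#' the average over threshold placements) and the precision-recall curve
#' (with step-wise AUPR, i.e. sum of precision times recall increment).
#'
#' @param probs predicted probabilities in `[0, 1]`
#' @param labels 0/1 true labels
#' @param threshold classification threshold (default 0.5)
#' @return Object of class `nm_metrics`: a list with integer counts
#'   `tp`, `fp`, `tn`, `fn`, scalar scores `acc`, `precision`, `recall`,
#'   `f1`, `mcc`, `auc`, `aupr`, and tibbles `roc_points` (`fpr`, `tpr`)
#'   and `pr_points` (`recall`, `precision`).
#' @export
compute_metrics <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0) stop("empty input", call. = FALSE)
  if (length(probs) != length(labels)) {
    stop("probs and labels differ in length", call. = FALSE)
  }
  stopifnot(all(probs >= 0 & probs <= 1), all(labels %in% c(0, 1)))
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  denom <- as.numeric(tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else 0

  curves <- score_curves(probs, labels)

  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, acc = acc,
                 precision = precision, recall = recall, f1 = f1,
                 mcc = mcc, auc = curves$auc, aupr = curves$aupr,
                 roc_points = curves$roc, pr_points = curves$pr,
                 n = length(labels), threshold = threshold),
            class = "nm_metrics")
}

# ROC and PR curves over all distinct score thresholds (descending)
score_curves <- function(probs, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]
  y <- labels[ord]
  # cumulative counts at each distinct threshold (ties grouped)
  cum_tp <- cumsum(y == 1)
  cum_fp <- cumsum(y == 0)
  last_of_tie <- c(p[-1] != p[-length(p)], TRUE)
  cum_tp <- cum_tp[last_of_tie]
  cum_fp <- cum_fp[last_of_tie]
  tpr <- if (n_pos > 0) cum_tp / n_pos else rep(0, length(cum_tp))
  fpr <- if (n_neg > 0) cum_fp / n_neg else rep(0, length(cum_fp))
  roc <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- tpr
  pr <- tibble::tibble(recall = c(0, rec), precision = c(1, prec))
  aupr <- sum(diff(pr$recall) * utils::tail(pr$precision, -1))
  list(roc = roc, auc = auc, pr = pr, aupr = aupr)
}

#' @export
print.nm_metrics <- function(x, ...) {
  cat("<nm_metrics> n =", x$n, "\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d (threshold %.2f)\n",
              x$tp, x$fp, x$tn, x$fn, x$threshold))
  cat(sprintf("  ACC %.4f  Precision %.4f  Recall %.4f  F1 %.4f\n",
              x$acc, x$precision, x$recall, x$f1))
  cat(sprintf("  MCC %.4f  AUC %.4f  AUPR %.4f\n", x$mcc, x$auc, x$aupr))
  invisible(x)
}

#' One-row tibble of the scalar metrics
#' @param x an `nm_metrics`
#' @param ... unused
#' @export
tidy.nm_metrics <- function(x, ...) {
  tibble::tibble(acc = x$acc, f1 = x$f1, precision = x$precision,
                 recall = x$recall, mcc = x$mcc, auc = x$auc,
                 aupr = x$aupr, tp = x$tp, fp = x$fp, tn = x$tn,
                 fn = x$fn, n = x$n)
}

#' ROC / PR curves of a metrics report
#'
#' @param object an `nm_metrics`
#' @param curve `"roc"`, `"pr"` or `"both"`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.nm_metrics <- function(object, curve = c("both", "roc", "pr"), ...) {
  curve <- match.arg(curve)
  roc <- dplyr::mutate(object$roc_points, panel = "ROC",
                       x = .data$fpr, y = .data$tpr)
  pr <- dplyr::mutate(object$pr_points, panel = "Precision-Recall",
                      x = .data$recall, y = .data$precision)
  df <- switch(curve, roc = roc, pr = pr,
               both = dplyr::bind_rows(roc[c("panel", "x", "y")],
                                       pr[c("panel", "x", "y")]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      subtitle = sprintf("AUC %.4f / AUPR %.4f", object$auc, object$aupr)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
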