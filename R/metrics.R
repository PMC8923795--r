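# Confusion-matrix metrics and the Mann-Whitney run comparison.

#' Confusion matrix for two-class predictions
#'
#' @param true_labels,predicted equal-length label vectors (factors or
#'   characters).
#' @param positive_class label value counted as positive.
#' @return Object of class `confusion_matrix` with integer `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(true_labels, predicted, positive_class = "positive") {
  t <- as.character(true_labels); p <- as.character(predicted)
  if (length(t) != length(p))
    fsgp_error("true and predicted label vectors differ in length",
               "fsgp_argument_error")
  if (length(t) == 0)
    fsgp_error("empty label vectors", "fsgp_argument_error")
  tp <- sum(t == positive_class & p == positive_class)
  fp <- sum(t != positive_class & p == positive_class)
  tn <- sum(t != positive_class & p != positive_class)
  fn <- sum(t == positive_class & p != positive_class)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, sensitivity (recall) `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, specificity `TN/(TN+FP)`. A zero denominator yields `NA`
#' (reported as undefined, not an error). Values are fractions; multiply by
#' 100 for the percentage convention used in reports.
#'
#' @param cm a [confusion()] result (or a list with tp/fp/tn/fn).
#' @return Named list of class `metric_set`.
#' @export
compute_metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total <= 0)
    fsgp_error("confusion matrix is empty", "fsgp_argument_error")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(accuracy = (cm$tp + cm$tn) / total,
                 sensitivity = safe(cm$tp, cm$tp + cm$fn),
                 precision = safe(cm$tp, cm$tp + cm$fp),
                 specificity = safe(cm$tn, cm$tn + cm$fp)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("accuracy %s, sensitivity %s, precision %s, specificity %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$precision),
              fmt(x$specificity)))
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum U statistic with midrank tie handling. The p-value is exact
#' (from the enumerative null distribution, via [stats::pwilcox]) when the
#' combined sample size is at most 16 and there are no ties, else a normal
#' approximation with tie and continuity corrections. The two-tailed exact
#' convention is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return Object of class `mann_whitney_result` with `u_statistic` (U of
#'   sample A), `p_two_tailed`, and `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    fsgp_error("both samples must be non-empty", "fsgp_argument_error")
  na <- length(sample_a); nb <- length(sample_b); n <- na + nb
  r <- rank(c(sample_a, sample_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  if (!ties && n <= 16) {
    lower <- pwilcox(u, na, nb)
    upper <- 1 - pwilcox(u - 1, na, nb)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    correction <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - correction)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- u - mu
      z <- (d - sign(d) * 0.5) / sqrt(sigma2)
      if (abs(d) < 0.5) z <- 0
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  structure(list(u_statistic = u, p_two_tailed = p, method = method),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-tailed p = %.4g (%s)\n",
              x$u_statistic, x$p_two_tailed, x$method))
  invisible(x)
}
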