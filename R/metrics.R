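# Evaluation suite: binary and multi-label metrics, per-disease curves,
# bootstrap confidence intervals and the label co-occurrence matrix.

#' Threshold-free ranking metrics
#'
#' `auc_score()` is the area under the ROC curve computed by the
#' rank-sum (Mann-Whitney) identity with midrank tie handling;
#' `aupr_score()` is the area under the precision-recall curve computed
#' as average precision (step-wise integration over distinct score
#' thresholds). Both return `NA` when only one class is present.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return scalar between 0 and 1, or `NA` if undefined.
#' @export
auc_score <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auc_score
#' @export
aupr_score <- function(labels, scores) {
  n1 <- sum(labels == 1)
  if (n1 == 0L || all(labels == 1)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Binary classification metrics
#'
#' Confusion counts at the decision threshold plus accuracy, Matthews
#' correlation coefficient, F1, recall, precision and specificity, and
#' the threshold-free AUC. With single-class labels, AUC and MCC are
#' reported as `NA` (undefined), not numbers.
#'
#' @param labels binary 0/1 vector.
#' @param probs probabilities between 0 and 1.
#' @param threshold decision threshold.
#' @return a `metric_report` list.
#' @export
binary_metrics <- function(labels, probs, threshold = 0.5) {
  abort_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  abort_if(any(probs < 0 | probs > 1), "probabilities must be in [0,1]")
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n <- tp + fp + tn + fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  structure(list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 acc = (tp + tn) / n, auc = auc_score(labels, probs),
                 mcc = mcc, f1 = f1, recall = rec, precision = prec,
                 specificity = spec, threshold = threshold),
            class = "metric_report")
}

#' Multi-label classification metrics
#'
#' Sample-averaged precision, recall and F1 over predicted label sets
#' (the averaging convention is recorded in the report; macro averaging
#' is available behind a flag), plus the Hamming loss (fraction of
#' wrong bits over N x K). An all-zero predicted set contributes
#' precision 0; a sample with an empty true and empty predicted set
#' counts as fully correct.
#'
#' @param label_matrix N x K binary matrix.
#' @param prob_matrix N x K probabilities.
#' @param threshold decision threshold.
#' @param average `"sample"` (default) or `"macro"`.
#' @return a `metric_report` list with `precision_ml`, `recall_ml`,
#'   `f1_ml`, `hamming_loss` and the averaging convention.
#' @export
multilabel_metrics <- function(label_matrix, prob_matrix, threshold = 0.5,
                               average = c("sample", "macro")) {
  average <- match.arg(average)
  Y <- as.matrix(label_matrix); P <- as.matrix(prob_matrix)
  abort_if(!all(dim(Y) == dim(P)), "label and probability shapes differ")
  pred <- (P >= threshold) * 1L
  hamming <- mean(pred != Y)
  if (average == "sample") {
    inter <- rowSums(pred * Y)
    npred <- rowSums(pred); ntrue <- rowSums(Y)
    prec <- ifelse(npred == 0, ifelse(ntrue == 0, 1, 0), inter / pmax(npred, 1))
    rec <- ifelse(ntrue == 0, ifelse(npred == 0, 1, 0), inter / pmax(ntrue, 1))
    f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
    out <- c(precision_ml = mean(prec), recall_ml = mean(rec),
             f1_ml = mean(f1))
  } else {
    per <- vapply(seq_len(ncol(Y)), function(k) {
      tp <- sum(pred[, k] == 1 & Y[, k] == 1)
      fp <- sum(pred[, k] == 1 & Y[, k] == 0)
      fn <- sum(pred[, k] == 0 & Y[, k] == 1)
      p <- if (tp + fp == 0) 0 else tp / (tp + fp)
      r <- if (tp + fn == 0) 0 else tp / (tp + fn)
      c(p, r, if (p + r == 0) 0 else 2 * p * r / (p + r))
    }, numeric(3))
    out <- c(precision_ml = mean(per[1, ]), recall_ml = mean(per[2, ]),
             f1_ml = mean(per[3, ]))
  }
  structure(list(precision_ml = unname(out["precision_ml"]),
                 recall_ml = unname(out["recall_ml"]),
                 f1_ml = unname(out["f1_ml"]),
                 hamming_loss = hamming, threshold = threshold,
                 average = average),
            class = "metric_report")
}

#' Per-disease AUC and AUPR
#'
#' For each disease class, positives are the records carrying that
#' label and negatives are all records not associated with it; AUC and
#' AUPR are computed per class (undefined markers when a class has no
#' positives or no negatives).
#'
#' @param label_matrix N x K binary matrix.
#' @param prob_matrix N x K probabilities.
#' @return data frame with columns `class`, `n_pos`, `auc`, `aupr`.
#' @export
per_disease_curves <- function(label_matrix, prob_matrix) {
  Y <- as.matrix(label_matrix); P <- as.matrix(prob_matrix)
  cls <- colnames(Y) %||% as.character(seq_len(ncol(Y)))
  data.frame(class = cls,
             n_pos = colSums(Y),
             auc = vapply(seq_len(ncol(Y)), function(k)
               auc_score(Y[, k], P[, k]), numeric(1)),
             aupr = vapply(seq_len(ncol(Y)), function(k)
               aupr_score(Y[, k], P[, k]), numeric(1)),
             row.names = NULL)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples evaluation rows with replacement `n_boot` times and
#' returns the percentile interval of the metric at the requested
#' level. Resamples on which the metric is undefined are redrawn (the
#' count is reported).
#'
#' @param labels binary vector (or matrix row-resampled jointly).
#' @param probs matching probabilities.
#' @param metric function `(labels, probs) -> scalar`.
#' @param n_boot bootstrap iterations.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `point`, `level`, `n_boot`,
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(labels, probs, metric, n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  lab_m <- is.matrix(labels)
  n <- if (lab_m) nrow(labels) else length(labels)
  point <- if (lab_m) metric(labels, probs) else metric(labels, probs)
  with_seed(derive_seed(seed, "bootstrap"), {
    vals <- numeric(n_boot); redrawn <- 0L
    for (b in seq_len(n_boot)) {
      v <- NA_real_; tries <- 0L
      while (is.na(v) && tries < 100L) {
        idx <- sample.int(n, n, replace = TRUE)
        v <- if (lab_m) metric(labels[idx, , drop = FALSE],
                               probs[idx, , drop = FALSE])
             else metric(labels[idx], probs[idx])
        tries <- tries + 1L
        if (is.na(v)) redrawn <- redrawn + 1L
      }
      abort_if(is.na(v), "metric undefined on 100 consecutive resamples")
      vals[b] <- v
    }
    alpha <- (1 - level) / 2
    q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
    list(lower = q[1], upper = q[2], point = point, level = level,
         n_boot = n_boot, n_redrawn = redrawn)
  })
}

#' Disease-label co-occurrence matrix
#'
#' Entry (i, j) is the fraction of records carrying both labels i and
#' j; the matrix is symmetric and its diagonal holds the marginal label
#' prevalences.
#'
#' @param label_matrix N x K binary matrix.
#' @return K x K numeric matrix.
#' @export
cooccurrence_matrix <- function(label_matrix) {
  Y <- as.matrix(label_matrix)
  crossprod(Y) / nrow(Y)
}

#' ROC and PR curve points for export
#'
#' @param labels binary vector.
#' @param probs probabilities.
#' @return data frame of curve points over the distinct thresholds
#'   (`roc_points`: threshold, fpr, tpr; `pr_points`: threshold,
#'   recall, precision).
#' @export
roc_points <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]; s <- probs[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  data.frame(threshold = s[last], fpr = fp / max(sum(labels == 0), 1),
             tpr = tp / max(sum(labels == 1), 1))
}

#' @rdname roc_points
#' @export
pr_points <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]; s <- probs[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  data.frame(threshold = s[last], recall = tp / max(sum(labels == 1), 1),
             precision = tp / pmax(tp + fp, 1))
}
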