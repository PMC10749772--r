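# Multi-label and multi-class evaluation suite. Conventions: binary calls
# derive from probabilities by the strict rule s > 0.5; undefined quantities
# (no predicted labels anywhere, single-class AUC columns) are returned as
# NA and excluded from averages rather than silently zeroed, except where a
# zero-numerator harmonic mean is conventionally 0.

calls_from_probs <- function(s_hat, threshold = 0.5) {
  matrix(as.integer(s_hat > threshold), nrow(s_hat), ncol(s_hat),
         dimnames = dimnames(s_hat))
}

#' Sample-averaged F1 (protein-function-challenge style)
#'
#' Average precision is the mean per-sample precision over the samples with
#' at least one predicted label; average recall is the mean per-sample
#' recall over all samples; their harmonic mean is the score. `NA` when no
#' sample has a predicted label. Every sample must have at least one true
#' label.
#'
#' @param y `N x M` binary ground truth.
#' @param s_hat `N x M` probabilities (calls derived at strict 0.5), or an
#'   already-binary call matrix via `y_hat`.
#' @param y_hat Optional explicit binary call matrix overriding `s_hat`.
#' @return Named vector with `AvgPre`, `AvgRec`, `AveF1`.
#' @export
ave_f1 <- function(y, s_hat = NULL, y_hat = NULL) {
  if (is.null(y_hat)) y_hat <- calls_from_probs(s_hat)
  if (any(rowSums(y) == 0))
    stop("every sample must have at least one true label")
  called <- rowSums(y_hat) > 0
  tp <- rowSums(y * y_hat)
  rec <- mean(tp / rowSums(y))
  if (!any(called))
    return(c(AvgPre = NA_real_, AvgRec = rec, AveF1 = NA_real_))
  pre <- mean(tp[called] / rowSums(y_hat)[called])
  f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  c(AvgPre = pre, AvgRec = rec, AveF1 = f1)
}

#' Micro-averaged precision, recall and F1
#'
#' Pooled true positives over pooled calls / truths across all samples and
#' labels. Precision is `NA` when there are no calls at all; the harmonic
#' mean with a zero numerator is 0 by convention.
#'
#' @inheritParams ave_f1
#' @return Named vector with `MiP`, `MiR`, `MiF`.
#' @export
micro_prf <- function(y, s_hat = NULL, y_hat = NULL) {
  if (is.null(y_hat)) y_hat <- calls_from_probs(s_hat)
  tp <- sum(y * y_hat)
  n_call <- sum(y_hat)
  n_true <- sum(y)
  mip <- if (n_call == 0) NA_real_ else tp / n_call
  mir <- if (n_true == 0) NA_real_ else tp / n_true
  mif <- if (is.na(mip) || is.na(mir)) NA_real_
         else if (mip + mir == 0) 0
         else 2 * mip * mir / (mip + mir)
  c(MiP = mip, MiR = mir, MiF = mif)
}

#' Precision at k
#'
#' Mean over samples of the fraction of true labels among the k
#' highest-probability labels. Ties are broken toward the lowest label
#' index (deterministic).
#'
#' @param y `N x M` binary ground truth.
#' @param s_hat `N x M` probabilities.
#' @param k Cut-off (default 1).
#' @return Scalar P at k.
#' @export
precision_at_k <- function(y, s_hat, k = 1L) {
  if (k > ncol(y)) stop("k exceeds the number of labels")
  hits <- vapply(seq_len(nrow(y)), function(i) {
    top <- order(-s_hat[i, ], seq_len(ncol(y)))[seq_len(k)]
    sum(y[i, top]) / k
  }, numeric(1))
  mean(hits)
}

#' Multi-class metrics (softmax mode)
#'
#' For one-hot ground truth and argmax calls: accuracy (fraction of samples
#' whose predicted class is correct), and macro precision / recall / F1
#' averaged over the M classes from pooled per-class counts. A class that is
#' never called has undefined precision, counted as 0 with a warning.
#'
#' @param y `N x M` one-hot ground truth.
#' @param s_hat `N x M` probabilities; the call is the argmax (ties toward
#'   the lowest index).
#' @return Named vector with `ACC`, `MaP`, `MaR`, `MaF`.
#' @export
multiclass_metrics <- function(y, s_hat) {
  if (any(rowSums(y) != 1)) stop("ground truth must be one-hot")
  M <- ncol(y)
  pred <- max.col(s_hat, ties.method = "first")
  y_hat <- matrix(0L, nrow(y), M)
  y_hat[cbind(seq_len(nrow(y)), pred)] <- 1L
  acc <- mean(rowSums(y * y_hat))
  tp <- colSums(y * y_hat)
  n_call <- colSums(y_hat)
  n_true <- colSums(y)
  if (any(n_call == 0))
    warning("class(es) never predicted; their precision counted as 0")
  prec <- ifelse(n_call == 0, 0, tp / n_call)
  rec <- ifelse(n_true == 0, 0, tp / n_true)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  c(ACC = acc, MaP = mean(prec), MaR = mean(rec), MaF = mean(f1))
}

#' Rank-based AUC for one label
#'
#' Mann-Whitney AUC with midranks for ties: the probability that a random
#' positive outranks a random negative. `NA` when the truth column is
#' single-class.
#'
#' @param scores Numeric score vector.
#' @param truth Binary vector of the same length.
#' @return Scalar AUC, or `NA` if undefined.
#' @export
auc_per_label <- function(scores, truth) {
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full evaluation report
#'
#' Computes the complete multi-label suite (sample-averaged F1, micro
#' P/R/F1, precision at k, per-label and average AUC) and, when requested,
#' the multi-class suite (ACC and macro P/R/F1 on one-hot truth with argmax
#' calls). Undefined per-label AUCs are excluded from the average.
#'
#' @param y `N x M` binary ground truth.
#' @param s_hat `N x M` probability matrix.
#' @param k Cut for precision at k (default 1).
#' @param multiclass Also compute the multi-class metrics (requires one-hot
#'   `y`).
#' @return An object of class `lncloc_metrics` (a list of the named values
#'   above plus `per_label_auc`).
#' @export
multilabel_metrics <- function(y, s_hat, k = 1L, multiclass = FALSE) {
  y <- as.matrix(y); s_hat <- as.matrix(s_hat)
  stopifnot(all(dim(y) == dim(s_hat)))
  af <- ave_f1(y, s_hat)
  mi <- micro_prf(y, s_hat)
  auc <- vapply(seq_len(ncol(y)), function(j) auc_per_label(s_hat[, j], y[, j]),
                numeric(1))
  names(auc) <- colnames(y)
  res <- list(ave_f1 = unname(af["AveF1"]), avg_precision = unname(af["AvgPre"]),
              avg_recall = unname(af["AvgRec"]), mip = unname(mi["MiP"]),
              mir = unname(mi["MiR"]), mif = unname(mi["MiF"]),
              p_at_k = precision_at_k(y, s_hat, k), k = as.integer(k),
              per_label_auc = auc,
              average_auc = if (all(is.na(auc))) NA_real_
                            else mean(auc, na.rm = TRUE),
              n = nrow(y))
  if (multiclass) res <- c(res, as.list(multiclass_metrics(y, s_hat)))
  structure(res, class = "lncloc_metrics")
}

#' @export
print.lncloc_metrics <- function(x, digits = 3, ...) {
  cat("Multi-label evaluation on", x$n, "samples\n")
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = digits,
                                                    format = "f"))
  cat(sprintf("  Ave-F1 %s  (AvgPre %s, AvgRec %s)\n", fmt(x$ave_f1),
              fmt(x$avg_precision), fmt(x$avg_recall)))
  cat(sprintf("  MiP %s  MiR %s  MiF %s\n", fmt(x$mip), fmt(x$mir),
              fmt(x$mif)))
  cat(sprintf("  P@%d %s   average AUC %s\n", x$k, fmt(x$p_at_k),
              fmt(x$average_auc)))
  cat("  per-label AUC:",
      paste(names(x$per_label_auc), fmt(x$per_label_auc), collapse = "  "),
      "\n")
  if (!is.null(x$ACC))
    cat(sprintf("  multiclass: ACC %s  MaP %s  MaR %s  MaF %s\n",
                fmt(x$ACC), fmt(x$MaP), fmt(x$MaR), fmt(x$MaF)))
  invisible(x)
}
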