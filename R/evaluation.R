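# Evaluation: patient-level stratified group k-fold CV, confusion
# matrices in the clinical-study cell convention, accuracy / F1 /
# AUROC, single-operating-point rater AUROC, and CV aggregation.
#
# Cell convention: rows are truth (row 1 = ASD, row 2 = non-ASD),
# columns are prediction (column 1 = ASD).  The study labels the four
# cells TP / FP / FN / TN *positionally* (its "FP" is truth-ASD
# predicted-non-ASD); the matrix is displayed with those names, but
# all metric arithmetic uses row/column positions.

GAIT_LEVELS <- c("ASD", "non-ASD")

as_gait_factor <- function(x) {
  x <- as.character(x)
  if (!all(x %in% GAIT_LEVELS))
    stop("labels must be 'ASD' or 'non-ASD'")
  factor(x, levels = GAIT_LEVELS)
}

#' Stratified group k-fold split at patient level
#'
#' Partitions patients into k validation folds such that (a) every
#' patient appears in exactly one validation fold — the same patient
#' never sits in training and validation simultaneously — and (b) the
#' class mix of every fold matches the cohort within one patient.
#' Greedy deterministic algorithm: per class, patients are shuffled
#' with the seed and dealt one at a time to the fold currently holding
#' the fewest patients of that class (ties: fewest patients overall,
#' then lowest fold index).
#'
#' @param labels named vector: patient_id -> "ASD"/"non-ASD".
#' @param k number of folds (default 5).
#' @param seed integer seed for the within-class shuffle.
#' @return object of class \code{gait_folds}: list \code{folds} of k
#'   character vectors of validation patient ids.
#' @export
stratified_group_kfold <- function(labels, k = 5L, seed = 1L) {
  if (is.null(names(labels))) stop("labels must be named by patient_id")
  if (anyDuplicated(names(labels))) stop("patient_ids must be unique")
  lab <- as_gait_factor(labels)
  names(lab) <- names(labels)
  if (k > length(lab))
    stop_gaitscreen("more folds than patients", "gaitscreen_bad_folds")
  if (nlevels(droplevels(lab)) < 2L)
    stop_gaitscreen("both classes must be present", "gaitscreen_bad_folds")
  folds <- replicate(k, character(0), simplify = FALSE)
  class_count <- matrix(0L, nrow = k, ncol = nlevels(lab))
  with_seed(seed, {
    for (ci in seq_len(nlevels(lab))) {
      ids <- names(lab)[as.integer(lab) == ci]
      ids <- sample(ids)
      for (id in ids) {
        total <- lengths(folds)
        cand <- which(class_count[, ci] == min(class_count[, ci]))
        cand <- cand[total[cand] == min(total[cand])]
        f <- cand[1L]
        folds[[f]] <- c(folds[[f]], id)
        class_count[f, ci] <- class_count[f, ci] + 1L
      }
    }
  })
  structure(list(folds = folds, k = as.integer(k), labels = lab),
            class = "gait_folds")
}

#' @export
print.gait_folds <- function(x, ...) {
  cat(sprintf("Stratified group %d-fold split of %d patients\n",
              x$k, length(x$labels)))
  for (i in seq_len(x$k)) {
    tab <- table(x$labels[x$folds[[i]]])
    cat(sprintf("  fold %d: %2d patients (%d ASD / %d non-ASD)\n",
                i, length(x$folds[[i]]), tab[["ASD"]], tab[["non-ASD"]]))
  }
  invisible(x)
}

#' Confusion matrix in the study's cell convention
#'
#' @param y_true,y_pred equal-length label vectors over
#'   \{"ASD", "non-ASD"\}.
#' @return object of class \code{gait_confusion}: 2 x 2 count matrix,
#'   rows = truth (ASD first), columns = prediction (ASD first).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_gaitscreen("y_true and y_pred must have equal length",
                    "gaitscreen_bad_labels")
  yt <- as_gait_factor(y_true)
  yp <- as_gait_factor(y_pred)
  m <- table(truth = yt, prediction = yp)
  structure(matrix(as.integer(m), 2L, 2L,
                   dimnames = list(truth = GAIT_LEVELS,
                                   prediction = GAIT_LEVELS)),
            class = "gait_confusion")
}

#' @export
print.gait_confusion <- function(x, ...) {
  cells <- matrix(c("TP", "FP", "FN", "TN"), 2L, byrow = TRUE)
  cat("Confusion matrix (rows = truth, cols = prediction; study cell names)\n")
  m <- unclass(x)
  for (i in 1:2) {
    cat(sprintf("  %-8s %5d (%s)  %5d (%s)\n", GAIT_LEVELS[i],
                m[i, 1L], cells[i, 1L], m[i, 2L], cells[i, 2L]))
  }
  invisible(x)
}

#' Accuracy from a confusion matrix
#'
#' Fraction of agreeing labels: (diagonal sum) / N — equivalently the
#' prevalence-weighted mean of the per-class row rates.
#'
#' @param cm a \code{gait_confusion} (or plain 2 x 2 matrix, truth in
#'   rows, ASD first).
#' @return accuracy in [0, 1].
#' @export
accuracy <- function(cm) {
  m <- unclass(cm)
  n <- sum(m)
  if (n == 0) stop_gaitscreen("empty confusion matrix", "gaitscreen_empty")
  (m[1L, 1L] + m[2L, 2L]) / n
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Precision = true positives / predicted positives, recall = true
#' positives / actual positives, F1 = their harmonic mean (0 when
#' precision + recall = 0).  The positive class is configurable; the
#' clinical positive category is ASD.
#'
#' @inheritParams accuracy
#' @param positive "ASD" or "non-ASD".
#' @return named numeric with \code{precision}, \code{recall},
#'   \code{f1}.
#' @export
precision_recall_f1 <- function(cm, positive = "ASD") {
  m <- unclass(cm)
  p <- match(match.arg(positive, GAIT_LEVELS), GAIT_LEVELS)
  tp <- m[p, p]
  pred_pos <- sum(m[, p])
  act_pos <- sum(m[p, ])
  if (act_pos == 0)
    stop_gaitscreen("no actual positives for this class", "gaitscreen_empty")
  prec <- if (pred_pos > 0) tp / pred_pos else 0
  rec <- tp / act_pos
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

#' @rdname precision_recall_f1
#' @export
f1_score <- function(cm, positive = "ASD") {
  unname(precision_recall_f1(cm, positive)[["f1"]])
}

#' Area under the ROC curve
#'
#' Rank statistic: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, ties counted one half
#' (Mann-Whitney); equals the trapezoidal area under the ROC curve.
#'
#' @param y_true labels over \{"ASD", "non-ASD"\}.
#' @param scores numeric scores for the positive class.
#' @param positive the positive class (default "ASD").
#' @return AUROC in [0, 1].
#' @export
auroc <- function(y_true, scores, positive = "ASD") {
  yt <- as_gait_factor(y_true)
  if (length(yt) != length(scores))
    stop_gaitscreen("labels and scores must have equal length",
                    "gaitscreen_bad_labels")
  pos <- yt == match.arg(positive, GAIT_LEVELS)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_gaitscreen("both classes must be present", "gaitscreen_empty")
  r <- rank(scores)  # average ranks on ties
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Single-operating-point AUROC of a hard rater
#'
#' A rater producing only hard labels has a one-point ROC curve; its
#' trapezoidal area is (sensitivity + specificity) / 2, identical to
#' the rank AUROC of 0/1 scores.
#'
#' @inheritParams accuracy
#' @return AUROC in [0, 1].
#' @export
rater_auroc <- function(cm) {
  m <- unclass(cm)
  if (sum(m[1L, ]) == 0 || sum(m[2L, ]) == 0)
    stop_gaitscreen("both truth classes must be present", "gaitscreen_empty")
  tpr <- m[1L, 1L] / sum(m[1L, ])
  tnr <- m[2L, 2L] / sum(m[2L, ])
  (tpr + tnr) / 2
}

#' Rater confusion ratios
#'
#' Row-normalized confusion ratios of a hard rater (as published in
#' the clinical observation experiment) plus the class sizes, from
#' which accuracy, F1 and AUROC are reconstructed without the raw
#' labels — all three metrics depend only on row rates and class
#' weights.
#'
#' @param tp,fp truth-ASD row rates (predicted ASD / non-ASD); must
#'   sum to 1.
#' @param fn,tn truth-non-ASD row rates (predicted ASD / non-ASD);
#'   must sum to 1.
#' @param n_asd,n_nonasd class sizes (positive weights).
#' @return object of class \code{gait_rater}.
#' @export
rater_ratios <- function(tp, fp, fn, tn, n_asd, n_nonasd) {
  if (abs(tp + fp - 1) > 1e-6 || abs(fn + tn - 1) > 1e-6)
    stop("row rates must sum to 1 per truth class")
  if (n_asd <= 0 || n_nonasd <= 0) stop("class weights must be positive")
  structure(list(rates = matrix(c(tp, fp, fn, tn), 2L, byrow = TRUE,
                                dimnames = list(truth = GAIT_LEVELS,
                                                prediction = GAIT_LEVELS)),
                 weights = c(ASD = n_asd, `non-ASD` = n_nonasd)),
            class = "gait_rater")
}

#' Metrics report from rater ratios
#'
#' @param r a \code{\link{rater_ratios}} object.
#' @param positive positive class for precision/recall/F1 (the
#'   published rater F1 values follow the non-ASD-positive convention).
#' @param snap_counts published row rates are rounded (typically to 4
#'   decimals) while the underlying confusion cells are counts; when
#'   TRUE (default), rate-times-weight products lying within 0.01 of a
#'   half-integer are snapped to it, undoing that rounding.  Accuracy
#'   and AUROC are insensitive to this; F1 recovers its exact value.
#' @return object of class \code{gait_metrics}: accuracy, precision,
#'   recall, f1, auroc.
#' @export
report_from_ratios <- function(r, positive = "non-ASD", snap_counts = TRUE) {
  stopifnot(inherits(r, "gait_rater"))
  m <- r$rates * r$weights[c(1L, 2L, 1L, 2L)]  # row-scaled pseudo-counts
  if (snap_counts) {
    snapped <- round(m * 2) / 2
    near <- abs(m - snapped) < 0.01
    m[near] <- snapped[near]
  }
  cm <- structure(m, class = "gait_confusion")
  prf <- precision_recall_f1(cm, positive)
  structure(list(accuracy = accuracy(cm),
                 precision = unname(prf[["precision"]]),
                 recall = unname(prf[["recall"]]),
                 f1 = unname(prf[["f1"]]),
                 auroc = rater_auroc(cm),
                 positive = positive),
            class = "gait_metrics")
}

#' @export
print.gait_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | F1 %.4f (positive: %s) | AUROC %.4f\n",
              x$accuracy, x$f1, x$positive, x$auroc))
  invisible(x)
}

#' Metrics report from predictions
#'
#' @param y_true,y_pred hard labels; \code{scores} positive-class
#'   scores for AUROC.
#' @param positive positive class (default "ASD").
#' @return a \code{gait_metrics} object.
#' @export
metrics_report <- function(y_true, y_pred, scores, positive = "ASD") {
  cm <- confusion(y_true, y_pred)
  prf <- precision_recall_f1(cm, positive)
  structure(list(accuracy = accuracy(cm),
                 precision = unname(prf[["precision"]]),
                 recall = unname(prf[["recall"]]),
                 f1 = unname(prf[["f1"]]),
                 auroc = auroc(y_true, scores, positive),
                 positive = positive),
            class = "gait_metrics")
}

#' Cross-validation aggregation
#'
#' Evaluation metrics are averaged across folds (arithmetic mean).
#'
#' @param values numeric vector of per-fold metric values.
#' @return their mean.
#' @export
aggregate_cv <- function(values) {
  if (length(values) == 0)
    stop_gaitscreen("no values to aggregate", "gaitscreen_empty")
  mean(values)
}

#' Plot a row-normalized confusion matrix
#'
#' Draws the matrix as a shaded 2 x 2 grid with the row-normalized
#' ratios printed in each cell (lighter = higher ratio within the truth
#' class), matching the usual presentation of clinical rater results.
#'
#' @param x a \code{gait_confusion}.
#' @param main plot title.
#' @param ... ignored.
#' @return the row-normalized matrix, invisibly.
#' @export
plot.gait_confusion <- function(x, main = "Confusion matrix", ...) {
  m <- unclass(x)
  rn <- m / rowSums(m)
  shades <- gray(0.35 + 0.6 * as.vector(rn))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 2), ylim = c(0, 2), asp = 1)
  k <- 0L
  for (i in 1:2) for (j in 1:2) {
    k <- k + 1L
    graphics::rect(j - 1, 2 - i, j, 3 - i,
                   col = gray(0.35 + 0.6 * rn[i, j]), border = "white")
    graphics::text(j - 0.5, 2.5 - i, sprintf("%.4f", rn[i, j]),
                   col = if (rn[i, j] > 0.6) "black" else "white")
  }
  graphics::axis(1, at = c(0.5, 1.5), labels = GAIT_LEVELS, tick = FALSE)
  graphics::axis(2, at = c(1.5, 0.5), labels = GAIT_LEVELS, tick = FALSE,
                 las = 2)
  graphics::mtext("prediction", side = 1, line = 2.2)
  graphics::mtext("truth", side = 2, line = 2.5)
  graphics::title(main)
  invisible(rn)
}
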