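#' Confusion matrix
#'
#' Entry `(i, j)` counts observations whose true label is class `i - 1` and
#' predicted label class `j - 1` (labels are 0-based integers, rows = truth,
#' columns = prediction).
#'
#' @param truth,pred integer vectors of equal length with labels in
#'   `0:(n_classes - 1)`.
#' @param n_classes number of classes `L`.
#' @return an `L x L` integer matrix.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths")
  }
  if (length(truth) > 0 &&
      (min(c(truth, pred)) < 0 || max(c(truth, pred)) >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  m <- matrix(0L, n_classes, n_classes)
  for (k in seq_along(truth)) {
    i <- truth[k] + 1L; j <- pred[k] + 1L
    m[i, j] <- m[i, j] + 1L
  }
  m
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' observed agreement \eqn{p_o} the normalized trace and expected agreement
#' \eqn{p_e = \sum_i r_i c_i / n^2} from the row/column marginals. When
#' \eqn{p_e = 1} (both marginals degenerate), the convention is
#' \eqn{\kappa = 1} if agreement is perfect and 0 otherwise.
#'
#' @param confusion square count matrix (rows = truth, cols = prediction).
#' @return scalar in \[-1, 1\].
#' @export
cohen_kappa <- function(confusion) {
  n <- sum(confusion)
  if (n < 1) stop("confusion matrix is empty")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - pe) < 1e-15) {
    return(if (abs(po - 1) < 1e-15) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Per-class precision and recall
#'
#' Precision is `TP / (TP + FP)` and recall `TP / (TP + FN)` for the given
#' positive class. A zero denominator yields `NaN` and a warning, the
#' declared convention for degenerate cases (e.g. a classifier that never
#' predicts the positive class has undefined precision).
#'
#' @param confusion square count matrix (rows = truth, cols = prediction).
#' @param positive_class 0-based class index treated as positive.
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(confusion, positive_class) {
  L <- nrow(confusion)
  i <- positive_class + 1L
  if (i < 1L || i > L) stop("positive_class out of range")
  tp <- confusion[i, i]
  fp <- sum(confusion[, i]) - tp
  fn <- sum(confusion[i, ]) - tp
  prec <- if (tp + fp == 0) {
    warning("no predicted positives; precision undefined (NaN)")
    NaN
  } else tp / (tp + fp)
  rec <- if (tp + fn == 0) {
    warning("no true positives in truth; recall undefined (NaN)")
    NaN
  } else tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' Full evaluation report
#'
#' Convenience wrapper assembling the confusion matrix, overall accuracy,
#' per-class and macro-averaged precision/recall, and Cohen's kappa.
#'
#' @inheritParams confusion_matrix
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(truth, pred, n_classes) {
  cm <- confusion_matrix(truth, pred, n_classes)
  n <- sum(cm)
  pr <- suppressWarnings(
    t(vapply(seq_len(n_classes) - 1L, function(k) precision_recall(cm, k),
             c(precision = 0, recall = 0))))
  rownames(pr) <- as.character(seq_len(n_classes) - 1L)
  structure(list(
    confusion = cm,
    accuracy = if (n > 0) sum(diag(cm)) / n else NaN,
    precision = pr[, "precision"],
    recall = pr[, "recall"],
    macro_precision = mean(pr[, "precision"], na.rm = TRUE),
    macro_recall = mean(pr[, "recall"], na.rm = TRUE),
    kappa = if (n > 0) cohen_kappa(cm) else NaN,
    n = n
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("evaluation over", x$n, "observations\n")
  cat("accuracy:", round(x$accuracy, 4), " kappa:", round(x$kappa, 4), "\n")
  cat("macro precision:", round(x$macro_precision, 4),
      " macro recall:", round(x$macro_recall, 4), "\n")
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Subject-grouped train/validation/test split
#'
#' Partitions subjects (not patches) into train/validation/test so that all
#' patches of one examinee land in the same subset, preventing leakage of a
#' subject's images across splits. Subject counts follow the requested
#' ratios by largest-remainder rounding after a seeded shuffle.
#'
#' @param manifest data frame with at least a `subject_id` column; one row
#'   per patch.
#' @param ratios positive length-3 numeric vector of train/val/test
#'   proportions (default `c(8, 1, 1)`).
#' @param seed integer seed for the subject shuffle.
#' @return an object of class `split_assignment`: list with `subjects`
#'   (data frame `subject_id`, `split`) and `manifest` (input plus a
#'   `split` column).
#' @export
group_split <- function(manifest, ratios = c(8, 1, 1), seed = 1L) {
  stopifnot(is.data.frame(manifest), "subject_id" %in% names(manifest),
            length(ratios) == 3L, all(ratios > 0))
  subjects <- sort(unique(as.character(manifest$subject_id)))
  ns <- length(subjects)
  if (ns < 3L) {
    stop("need at least 3 subjects for a 3-way grouped split; ",
         "use fewer splits for ", ns, " subject(s)")
  }
  subjects <- with_seed(seed, sample(subjects))
  target <- ns * ratios / sum(ratios)
  base <- floor(target)
  rem <- target - base
  short <- ns - sum(base)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  split_names <- c("train", "val", "test")
  assignment <- rep(split_names, times = base)
  sub_df <- data.frame(subject_id = subjects, split = assignment,
                       stringsAsFactors = FALSE)
  man <- manifest
  man$split <- sub_df$split[match(as.character(man$subject_id), sub_df$subject_id)]
  structure(list(subjects = sub_df, manifest = man, ratios = ratios,
                 seed = seed),
            class = "split_assignment")
}
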