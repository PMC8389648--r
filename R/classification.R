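#' Area under the ROC curve, rank (Mann-Whitney) formulation
#'
#' AUC is computed as the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted one half —
#' i.e. the normalized Mann-Whitney U of the decision scores.
#'
#' @param scores numeric decision values, larger = more case-like.
#' @param is_positive logical vector, TRUE for the positive (case) class.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, is_positive) {
  is_positive <- as.logical(is_positive)
  np <- sum(is_positive); nn <- sum(!is_positive)
  if (np == 0L || nn == 0L)
    stop("AUC needs at least one positive and one negative")
  r <- rank(scores)  # midranks give the tie = 1/2 convention
  (sum(r[is_positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics from confusion counts and decision scores
#'
#' @param counts named numeric vector with elements \code{TP}, \code{FP},
#'   \code{TN}, \code{FN}.
#' @param scores optional decision values for AUC.
#' @param is_positive logical truth labels aligned with \code{scores}.
#' @return A one-row data frame: counts, \code{sensitivity} = TP/(TP+FN),
#'   \code{specificity} = TN/(TN+FP), \code{accuracy} = (TP+TN)/total, and
#'   \code{auc} (NA when no scores are given).
#' @export
compute_metrics <- function(counts, scores = NULL, is_positive = NULL) {
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(counts)))
    stop("counts must be named TP, FP, TN, FN")
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion counts")
  auc <- NA_real_
  if (!is.null(scores)) auc <- auc_rank(scores, is_positive)
  data.frame(TP = tp, FP = fp, TN = tn, FN = fn,
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             accuracy = (tp + tn) / total,
             auc = auc)
}

# kernlab's decision-value sign convention depends on the order classes
# appear in the training data, so orient scores with the model's own
# predicted labels: TRUE means scores must be negated so that larger
# score = predicted positive.
.decision_flipped <- function(decision, response, positive) {
  agree <- mean((decision > 0) == (response == positive))
  !is.nan(agree) && agree < 0.5
}

# median-heuristic RBF bandwidth: kernel exp(-sigma * ||x - y||^2) with
# sigma = 1 / (2 h^2), h the median pairwise Euclidean distance
.median_sigma <- function(x) {
  h <- stats::median(stats::dist(x))
  if (!is.finite(h) || h <= 0) return(1)
  1 / (2 * h^2)
}

#' Cross-validated SVM classification of functionome profiles
#'
#' Radial-basis-kernel support vector classification of per-sample GSR
#' profiles, evaluated by stratified k-fold cross-validation repeated r
#' times with per-repeat reshuffling. Within a repeat the held-out
#' predictions of all folds are pooled into one confusion table and one
#' set of decision scores, from which sensitivity, specificity, accuracy
#' and AUC are computed (fold-averaged metrics are available instead).
#'
#' @param profiles numeric matrix, rows = samples, columns = features
#'   (typically a \code{\link{functionome}}).
#' @param labels factor or character vector of two class labels, aligned
#'   with the rows of \code{profiles}.
#' @param positive the positive-class label (default \code{"case"} when
#'   present, otherwise the first level).
#' @param folds number of cross-validation folds k (default 5).
#' @param repeats number of repeated cross-validations r (default 10).
#' @param seed integer seed governing all fold reshuffling.
#' @param C SVM regularization constant (default 1).
#' @param sigma RBF kernel parameter; default is the median heuristic
#'   computed on the full profile matrix.
#' @param fold_average if TRUE, compute metrics per fold and average them
#'   within each repeat instead of pooling predictions.
#' @return An object of class \code{ClassificationReport}: list with
#'   \code{per_repeat} (data frame of counts and metrics per repeat),
#'   \code{aggregate} (mean/min/max of each metric over repeats), and the
#'   settings \code{folds}, \code{repeats}, \code{seed}, \code{positive}.
#' @export
cross_validated_svm <- function(profiles, labels, positive = NULL,
                                folds = 5L, repeats = 10L, seed = 1L,
                                C = 1, sigma = NULL,
                                fold_average = FALSE) {
  x <- as.matrix(unclass(profiles))
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("'labels' must align with the profile rows")
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("binary classification needs exactly 2 classes, got ",
         length(classes))
  if (is.null(positive))
    positive <- if ("case" %in% classes) "case" else classes[1L]
  if (!positive %in% classes) stop("'positive' is not a class label")
  if (min(table(labels)) < folds)
    stop("each class needs at least 'folds' = ", folds, " members")
  if (is.null(sigma)) sigma <- .median_sigma(x)
  y <- factor(labels, levels = c(setdiff(classes, positive), positive))

  set.seed(seed)
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_of <- integer(nrow(x))
    for (cl in classes) {  # stratified assignment, reshuffled per repeat
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    pred <- character(nrow(x))
    score <- numeric(nrow(x))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      fit <- kernlab::ksvm(x[!test, , drop = FALSE], y[!test],
                           type = "C-svc", kernel = "rbfdot",
                           kpar = list(sigma = sigma), C = C,
                           scaled = FALSE)
      dtr <- kernlab::predict(fit, x[!test, , drop = FALSE],
                              type = "decision")[, 1L]
      rtr <- as.character(kernlab::predict(fit, x[!test, , drop = FALSE]))
      dte <- kernlab::predict(fit, x[test, , drop = FALSE],
                              type = "decision")[, 1L]
      flip <- .decision_flipped(dtr, rtr, positive)
      score[test] <- if (flip) -dte else dte
      pred[test] <- as.character(kernlab::predict(
        fit, x[test, , drop = FALSE]))
    }
    truth_pos <- labels == positive
    if (fold_average) {
      ms <- lapply(seq_len(folds), function(f) {
        sel <- fold_of == f
        cnt <- c(TP = sum(pred[sel] == positive & truth_pos[sel]),
                 FP = sum(pred[sel] == positive & !truth_pos[sel]),
                 TN = sum(pred[sel] != positive & !truth_pos[sel]),
                 FN = sum(pred[sel] != positive & truth_pos[sel]))
        compute_metrics(cnt, score[sel], truth_pos[sel])
      })
      m <- do.call(rbind, ms)
      rep_row <- data.frame(t(colMeans(m)))
    } else {
      cnt <- c(TP = sum(pred == positive & truth_pos),
               FP = sum(pred == positive & !truth_pos),
               TN = sum(pred != positive & !truth_pos),
               FN = sum(pred != positive & truth_pos))
      rep_row <- compute_metrics(cnt, score, truth_pos)
    }
    per_repeat[[r]] <- cbind(data.frame(repeat_id = r), rep_row)
  }
  per_repeat <- do.call(rbind, per_repeat)
  metrics <- c("sensitivity", "specificity", "accuracy", "auc")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_repeat[[m]]), 0),
    min = vapply(metrics, function(m) min(per_repeat[[m]]), 0),
    max = vapply(metrics, function(m) max(per_repeat[[m]]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_repeat = per_repeat, aggregate = aggregate,
                 folds = folds, repeats = repeats, seed = seed,
                 positive = positive, sigma = sigma, C = C),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("ClassificationReport: %d-fold CV x %d repeats (seed %d)\n",
              x$folds, x$repeats, x$seed))
  cat("  positive class:", x$positive, "\n")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-11s mean %.4f  range [%.4f, %.4f]\n",
                agg$metric[i], agg$mean[i], agg$min[i], agg$max[i]))
  invisible(x)
}
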