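#' Seeded k-fold assignment
#'
#' Indices are shuffled under the seed and dealt round-robin to folds, so fold
#' sizes never differ by more than one.  With `labels`, shuffling and dealing
#' happen within each label group while a running offset keeps the global
#' fold sizes balanced (stratification protects rare classes such as the
#' 11-member tPA family).
#'
#' @param n Number of items.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; identical seeds give identical splits.
#' @param labels Optional label vector of length `n` for stratification.
#' @return Integer vector of fold indices in `1..k`.
#' @export
#' @examples
#' table(make_folds(11, 5, seed = 1))  # sizes 3,2,2,2,2
make_folds <- function(n, k = 5, seed = 1, labels = NULL) {
  if (n < k) stop_pgact("need at least as many items (", n, ") as folds (",
                        k, ")")
  if (k < 2) stop_pgact("'k' must be at least 2")
  fold <- integer(n)
  with_seed(seed, {
    if (is.null(labels)) {
      ord <- sample.int(n)
      fold[ord] <- rep_len(seq_len(k), n)
    } else {
      if (length(labels) != n) stop_pgact("'labels' must have length n")
      offset <- 0L
      for (g in unique(labels)) {
        idx <- which(labels == g)
        ord <- idx[sample.int(length(idx))]
        fold[ord] <- ((offset + seq_along(ord) - 1L) %% k) + 1L
        offset <- (offset + length(ord)) %% k
      }
    }
  })
  fold
}

#' Classification metrics from binary confusion counts
#'
#' Accuracy, sensitivity and specificity in percent and the Matthews
#' correlation coefficient:
#' \deqn{ACC = 100 (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{SN = 100\, TP/(TP+FN)}
#' \deqn{SP = 100\, TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' A metric whose denominator is zero is reported as `NA` with a warning,
#' never as 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; alternatively pass a
#'   single named list/vector as `tp`.
#' @return Named list: `accuracy`, `sensitivity`, `specificity` (percent) and
#'   `mcc` (in `[-1, 1]`).
#' @export
#' @examples
#' confusion_metrics(tp = 95, fp = 16, tn = 84, fn = 5)
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp) || (length(tp) == 4 && !is.null(names(tp)))) {
    cm <- as.list(tp)
    tp <- cm$tp %||% cm$TP; fp <- cm$fp %||% cm$FP
    tn <- cm$tn %||% cm$TN; fn <- cm$fn %||% cm$FN
  }
  # doubles: the MCC denominator product overflows 32-bit integers easily
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0))
    stop_pgact("confusion counts must be non-negative numbers")
  total <- sum(counts)
  if (total == 0) stop_pgact("empty confusion matrix")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  acc <- 100 * (tp + tn) / total
  sn <- 100 * safe(tp, tp + fn, "sensitivity")
  sp <- 100 * safe(tn, tn + fp, "specificity")
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 == 0) {
    warning("MCC undefined (zero marginal)", call. = FALSE)
    NA_real_
  } else (tp * tn - fp * fn) / sqrt(den2)
  list(accuracy = acc, sensitivity = sn, specificity = sp, mcc = mcc)
}

#' Multiclass confusion table
#'
#' Rows are true labels, columns predicted labels, in the order the labels
#' are supplied through `levels` (defaults to the union, activator
#' subfamilies first).
#'
#' @param truth,predicted Equal-length label vectors.
#' @param levels Label ordering for rows/columns.
#' @return Integer matrix of counts (rows true, columns predicted).
#' @export
confusion_table <- function(truth, predicted,
                            levels = union(PGA_CLASSES,
                                           union(truth, predicted))) {
  if (length(truth) != length(predicted))
    stop_pgact("'truth' and 'predicted' must have the same length")
  as.matrix(table(factor(truth, levels = levels),
                  factor(predicted, levels = levels)))
}

#' Receiver operating characteristic curve and AUC
#'
#' Thresholds sweep the unique scores in descending order, with tied scores
#' grouped into a single step; the area under the curve is computed by the
#' trapezoidal rule, which makes it equal to the probability that a random
#' positive outscores a random negative, counting ties 1/2.
#'
#' @param scores Numeric decision values (larger = more positive).
#' @param labels Binary truth: +1/-1, logical, or `"PG"`/`"NON_PG"`.
#' @return Object of class `pga_roc`: `points` (threshold, fpr, tpr) from
#'   (0,0) to (1,1), and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "PG"
  pos <- as.logical(labels > 0 | labels == TRUE)
  if (!any(pos) || all(pos))
    stop_pgact("ROC needs both positive and negative labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores into single steps
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = c(Inf, rle(s)$values),
                                     fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "pga_roc")
}

#' @export
print.pga_roc <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `pga_roc` from [roc_curve()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pga_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "1 - specificity (FPR)", ylab = "sensitivity (TPR)",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Five-fold cross-validation of the hierarchical classifier
#'
#' The dataset is split into `k` folds; each fold is held out once while the
#' remaining folds train a full [pga_fit()] suite.  Reported level-1 metrics
#' (activator vs non-activator) are the unweighted mean of the per-fold
#' metric sets, as well as the per-fold values and the pooled counts.  The
#' subfamily assignment of every true activator is pooled across folds into a
#' multiclass confusion table (activators the level-1 gate rejected appear in
#' the `NON_PG` column), and pooled level-1 scores give a ROC curve.
#'
#' @param data A labelled `pga_dataset`.
#' @param method Feature encoding.
#' @param params Hyperparameters as from [pga_params()]; `NULL` for defaults.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold split.
#' @param stratify Stratify folds by label (default `FALSE`, a plain random
#'   split; set `TRUE` to protect rare subfamilies).
#' @param threshold Level-1 decision threshold.
#' @param pssm Passed to [feature_matrix()].
#' @param tol SMO stopping tolerance.
#' @return Object of class `pga_cv`: `metrics` (mean over folds),
#'   `fold_metrics` (data frame), `pooled` (summed confusion counts),
#'   `confusion` (subfamily confusion matrix), `scores` (per-sequence level-1
#'   scores with truth), `roc`, plus `k`, `seed`, `method`.
#' @export
cross_validate <- function(data, method = c("AC", "DC", "PSSM", "HYBRID"),
                           params = NULL, k = 5, seed = 1, stratify = FALSE,
                           threshold = 0, pssm = "mock", tol = 1e-3) {
  method <- match.arg(method)
  if (is.null(data$label)) stop_pgact("'data' must carry a 'label' column")
  n <- nrow(data)
  fold <- make_folds(n, k, seed, labels = if (stratify) data$label)

  fold_rows <- list()
  truth_sub <- character(0)
  pred_sub <- character(0)
  all_scores <- data.frame(id = character(0), score = numeric(0),
                           truth = character(0), fold = integer(0))
  pooled <- c(tp = 0, fp = 0, tn = 0, fn = 0)

  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    class(train) <- class(test) <- c("pga_dataset", "data.frame")
    if (length(unique(train$label %in% PGA_CLASSES)) < 2 ||
        !any(train$label == "NEG") || !any(train$label %in% PGA_CLASSES))
      stop_pgact("fold ", f, " leaves single-class training data; ",
                 "use stratify = TRUE")
    fit <- pga_fit(train, method, params = params, pssm = pssm, tol = tol)
    pr <- predict(fit, test, threshold = threshold, pssm = pssm)

    pos <- test$label %in% PGA_CLASSES
    called <- pr$level1_call == "PG"
    cm <- c(tp = sum(pos & called), fp = sum(!pos & called),
            tn = sum(!pos & !called), fn = sum(pos & !called))
    pooled <- pooled + cm
    m <- confusion_metrics(cm["tp"], cm["fp"], cm["tn"], cm["fn"])
    fold_rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                                 sensitivity = m$sensitivity,
                                 specificity = m$specificity, mcc = m$mcc)

    truth_sub <- c(truth_sub, test$label[pos])
    pred_sub <- c(pred_sub,
                  ifelse(called[pos], pr$subclass_call[pos], "NON_PG"))
    all_scores <- rbind(all_scores,
                        data.frame(id = test$id, score = pr$level1_score,
                                   truth = test$label, fold = f))
  }

  fold_metrics <- do.call(rbind, fold_rows)
  mean_metrics <- lapply(c(accuracy = "accuracy", sensitivity = "sensitivity",
                           specificity = "specificity", mcc = "mcc"),
                         function(col) mean(fold_metrics[[col]], na.rm = TRUE))
  confusion <- confusion_table(truth_sub, pred_sub,
                               levels = c(PGA_CLASSES, "NON_PG"))

  structure(list(metrics = mean_metrics,
                 fold_metrics = fold_metrics,
                 pooled = pooled,
                 confusion = confusion,
                 scores = all_scores,
                 roc = roc_curve(all_scores$score,
                                 all_scores$truth %in% PGA_CLASSES),
                 k = k, seed = seed, method = method),
            class = "pga_cv")
}

#' @export
print.pga_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (", x$method, " features)\n", sep = "")
  m <- x$metrics
  cat(sprintf("  ACC %.2f%%  SN %.2f%%  SP %.2f%%  MCC %.3f  AUC %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, m$mcc, x$roc$auc))
  cat("subfamily confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
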