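#' Train the weighted k-nearest-neighbour point model
#'
#' The point model classifies each line coordinate independently from its
#' four normalised curve features by an inverse-distance-weighted vote among
#' the `k` nearest training points (Euclidean distance). Training stores the
#' points and runs a grouped 10-fold cross-validation — folds assigned by
#' whole line samples, not points, so neighbouring coordinates of one line
#' never straddle a fold — recording per-fold and mean pixel-level accuracy.
#'
#' @param dataset An `icgfa_dataset`; rows with `split == "train"` are used
#'   (all rows if there is no split column).
#' @param k Neighbour count (default 10).
#' @param cv_folds Folds for cross-validation; skipped with a warning when
#'   there are fewer line samples than folds.
#' @param seed Seed for the fold assignment.
#' @return An `icgfa_knn` model with `cv_report` (per-fold accuracies) and
#'   `cv_accuracy` (their mean).
#' @export
train_knn <- function(dataset, k = 10, cv_folds = 10, seed = 1L) {
  d <- dataset
  if ("split" %in% names(d)) d <- d[d$split == "train", ]
  if (nrow(d) == 0) abort("no training rows")
  X <- as.matrix(d[, c("i_max", "upslope", "t_max", "t_half")])
  check_normalized(X)
  y <- zone_factor(as.character(d$label))
  if (any(table(y) == 0)) abort("all three classes must be present in training data")
  if (k < 1 || k > nrow(X)) abort("`k` must be between 1 and the training size")
  group <- if (all(c("video_id", "expert_id", "line_id") %in% names(d)))
    paste(d$video_id, d$expert_id, d$line_id) else as.character(seq_len(nrow(X)))
  cv_report <- NULL
  groups <- unique(group)
  if (length(groups) >= cv_folds) {
    set.seed(seed)
    fold_of <- setNames(sample(rep_len(seq_len(cv_folds), length(groups))), groups)
    folds <- fold_of[group]
    acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      if (sum(tr) < k) return(NA_real_)
      pred <- knn_vote(X[tr, , drop = FALSE], y[tr], X[!tr, , drop = FALSE], k)
      mean(pred == y[!tr])
    }, 0)
    cv_report <- tibble::tibble(fold = seq_len(cv_folds),
                                n = as.integer(table(factor(folds, seq_len(cv_folds)))),
                                accuracy = acc)
  } else {
    warn(sprintf("only %d line samples: %d-fold cross-validation skipped",
                 length(groups), cv_folds))
  }
  structure(list(X = X, y = y, k = k, weighting = "inverse_distance",
                 cv_report = cv_report,
                 cv_accuracy = if (!is.null(cv_report)) mean(cv_report$accuracy, na.rm = TRUE) else NA_real_),
            class = "icgfa_knn")
}

check_normalized <- function(X) {
  if (anyNA(X)) abort("features contain missing values")
  if (min(X) < -1e-6 || max(X) > 1 + 1e-6)
    abort("features must be normalised to [0, 1] (see `normalize_features()`)")
  invisible(X)
}

# inverse-distance weighted k-NN vote with deterministic tie-breaking:
# exact matches (distance ~ 0) vote by count among themselves; otherwise
# weighted votes, ties resolved by smallest mean neighbour distance, then by
# the fixed class order good < expert < poor.
knn_vote <- function(Xtr, ytr, Xq, k, block = 1024L) {
  nq <- nrow(Xq)
  out <- integer(nq)
  lv <- levels(ytr)
  r_tr <- rowSums(Xtr^2)
  for (s in seq(1, nq, by = block)) {
    e <- min(s + block - 1L, nq)
    Q <- Xq[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), r_tr, `+`) - 2 * tcrossprod(Q, Xtr)
    d2[d2 < 0] <- 0
    for (i in seq_len(nrow(Q))) {
      nn <- order(d2[i, ])[seq_len(k)]
      dd <- sqrt(d2[i, nn])
      cl <- as.integer(ytr[nn])
      if (any(dd < 1e-12)) {
        cnt <- tabulate(cl[dd < 1e-12], nbins = length(lv))
        out[s + i - 1L] <- which.max(cnt)  # first max = class order
        next
      }
      w <- 1 / dd
      score <- vapply(seq_along(lv), function(c) sum(w[cl == c]), 0)
      best <- which(score >= max(score) - 1e-12 * max(score))
      if (length(best) > 1) {
        meand <- vapply(best, function(c) mean(dd[cl == c]), 0)
        best <- best[meand <= min(meand) + 1e-12]
      }
      out[s + i - 1L] <- best[1]
    }
  }
  factor(lv[out], levels = lv)
}

#' Predict per-coordinate labels with the point model
#'
#' @param model An `icgfa_knn` from [train_knn()].
#' @param sample A line-sample tibble (coordinate rows with the four
#'   normalised features, e.g. from [condense_median()]).
#' @return The sample with a `label` column of predictions.
#' @export
predict_knn <- function(model, sample) {
  X <- as.matrix(sample[, c("i_max", "upslope", "t_max", "t_half")])
  check_normalized(X)
  sample$label <- knn_vote(model$X, model$y, X, model$k)
  sample
}

#' @export
predict.icgfa_knn <- function(object, newdata, ...) predict_knn(object, newdata)

#' @export
print.icgfa_knn <- function(x, ...) {
  cat(sprintf("<icgfa_knn> k = %d, %d training points, weighting: %s\n",
              x$k, nrow(x$X), x$weighting))
  if (!is.null(x$cv_report))
    cat(sprintf("  grouped %d-fold CV pixel accuracy: %.3f\n",
                nrow(x$cv_report), x$cv_accuracy))
  invisible(x)
}

#' @export
tidy.icgfa_knn <- function(x, ...) {
  if (is.null(x$cv_report)) return(tibble::tibble())
  x$cv_report
}

#' @export
glance.icgfa_knn <- function(x, ...) {
  tibble::tibble(k = x$k, n_points = nrow(x$X),
                 n_folds = if (is.null(x$cv_report)) 0L else nrow(x$cv_report),
                 cv_accuracy = x$cv_accuracy)
}
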