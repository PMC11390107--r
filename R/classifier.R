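# Feature-based classification of screening metric vectors: review labels,
# leakage-safe imputation/scaling, model training (logistic regression,
# random forest, k-NN), repeated stratified cross-validation, and
# AUROC/AUPRC evaluation.

#' Review label vocabulary
#'
#' The five labels a manual reviewer can assign to a figure. Classifier
#' training uses only the two definite labels.
#' @export
review_labels <- c("definitely_problematic", "probably_problematic",
                   "probably_okay", "definitely_okay", "grayscale")

.definite_labels <- c("definitely_problematic", "definitely_okay")

.check_labels <- function(labels) {
  bad <- setdiff(unique(labels), review_labels)
  if (length(bad) > 0) stop("unknown review label(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  labels
}

.feature_cols <- c("mean_pixelwise_dist", "max_ratio", "high_ratio_count",
                   "high_ratio_pixel_prop", "mean_spatial_dist")

#' Build a labeled example table from certified fixtures
#'
#' Computes the metric vector for each fixture and attaches its ground-truth
#' label, yielding the CSV-serializable table the classifiers consume.
#'
#' @param fixtures List of `certified_fixture` objects.
#' @param ... Passed to [compute_metric_vector()].
#' @return A data.frame with `source_id`, `label`, and the five metric
#'   columns plus `grayscale`.
#' @export
corpus_examples <- function(fixtures, ...) {
  rows <- lapply(fixtures, function(fx) {
    mv <- fx$metrics
    if (is.null(mv)) mv <- compute_metric_vector(fx$image, ...)
    cbind(data.frame(source_id = fx$image$source_id, label = fx$label),
          mv)
  })
  do.call(rbind, rows)
}

#' Impute and standardize features, training statistics only
#'
#' Undefined spatial distances (images with no high-ratio pair) are imputed
#' with the training-set maximum plus one — beyond any observed separation,
#' i.e. "least problematic". Features are then centered and scaled with
#' training-set statistics; test data, if given, is transformed with the
#' same statistics so no test information leaks into the fit.
#'
#' @param train Data.frame containing the five metric columns.
#' @param test Optional data.frame transformed with the training statistics.
#' @return List with `train` (matrix), `test` (matrix or NULL), and `stats`
#'   (the imputation value, centers, and scales).
#' @export
impute_and_scale <- function(train, test = NULL) {
  if (nrow(train) == 0) stop("no training examples", call. = FALSE)
  xtr <- as.matrix(train[, .feature_cols])
  finite_sp <- xtr[, "mean_spatial_dist"]
  impute_val <- if (all(is.na(finite_sp))) 1 else
    max(finite_sp, na.rm = TRUE) + 1
  xtr[is.na(xtr[, "mean_spatial_dist"]), "mean_spatial_dist"] <- impute_val
  centers <- colMeans(xtr)
  scales <- apply(xtr, 2, stats::sd)
  scales[scales == 0 | is.na(scales)] <- 1
  std <- function(x) sweep(sweep(x, 2, centers), 2, scales, "/")
  out_test <- NULL
  if (!is.null(test)) {
    xte <- as.matrix(test[, .feature_cols])
    xte[is.na(xte[, "mean_spatial_dist"]), "mean_spatial_dist"] <- impute_val
    out_test <- std(xte)
  }
  list(train = std(xtr), test = out_test,
       stats = list(impute = impute_val, center = centers, scale = scales))
}

#' Train a feature-based classifier
#'
#' Fits a binary classifier scoring the probability that an image is
#' definitely problematic. Only examples labeled `definitely_problematic` or
#' `definitely_okay` are used. Logistic regression and random forest weight
#' classes inversely to their frequency ("balanced"); k-NN uses k = 5 and no
#' weighting. Imputation and standardization statistics are estimated from
#' these examples and stored in the model for later prediction.
#'
#' @param examples Data.frame with the five metric columns and a `label`
#'   column of review labels.
#' @param algorithm `"logistic_regression"`, `"random_forest"`, or `"knn"`.
#' @param seed Integer seed (random forest bootstrap, k-NN tie-breaking).
#' @return A `cvd_model` object usable with [predict_scores()].
#' @export
train_model <- function(examples,
                        algorithm = c("logistic_regression", "random_forest",
                                      "knn"),
                        seed = 1L) {
  algorithm <- match.arg(algorithm)
  .check_labels(examples$label)
  ex <- examples[examples$label %in% .definite_labels, , drop = FALSE]
  y <- as.integer(ex$label == "definitely_problematic")
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least two examples of each definite class", call. = FALSE)
  }
  prep <- impute_and_scale(ex)
  x <- prep$train
  n <- length(y)
  class_w <- n / (2 * table(factor(y, levels = 0:1)))  # balanced
  fit <- switch(algorithm,
    logistic_regression = {
      df <- data.frame(x, y = y)
      w <- as.numeric(class_w[as.character(y)])
      suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                  data = df, weights = w))
    },
    random_forest = with_local_seed(seed, {
      randomForest::randomForest(x, factor(y, levels = 0:1),
                                 classwt = as.numeric(class_w))
    }),
    knn = list(x = x, y = y, k = 5))
  structure(list(algorithm = algorithm, fit = fit, stats = prep$stats,
                 seed = as.integer(seed), version = "cvdscreen-model-1"),
            class = "cvd_model")
}

#' @export
print.cvd_model <- function(x, ...) {
  cat(sprintf("<cvd_model %s  (%s)>\n", x$algorithm, x$version))
  invisible(x)
}

.apply_stats <- function(stats, newdata) {
  x <- as.matrix(newdata[, .feature_cols])
  x[is.na(x[, "mean_spatial_dist"]), "mean_spatial_dist"] <- stats$impute
  sweep(sweep(x, 2, stats$center), 2, stats$scale, "/")
}

#' Score new examples with a trained model
#'
#' @param model A `cvd_model`.
#' @param newdata Data.frame with the five metric columns.
#' @return Numeric vector of probabilities of `definitely_problematic`.
#' @export
predict_scores <- function(model, newdata) {
  stopifnot(inherits(model, "cvd_model"))
  x <- .apply_stats(model$stats, newdata)
  switch(model$algorithm,
    logistic_regression = as.numeric(
      stats::predict(model$fit, newdata = as.data.frame(x),
                     type = "response")),
    random_forest = as.numeric(
      stats::predict(model$fit, newdata = x, type = "prob")[, "1"]),
    knn = with_local_seed(model$seed, {
      pred <- class::knn(model$fit$x, x,
                         factor(model$fit$y, levels = 0:1),
                         k = model$fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    }))
}

#' Save / load a trained model
#'
#' Models serialize with a format version tag; loading checks it.
#' @param model A `cvd_model`.
#' @param path Destination file.
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cvd_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cvd_model") ||
      !identical(model$version, "cvdscreen-model-1")) {
    stop("not a cvdscreen model file (or unsupported version): ", path,
         call. = FALSE)
  }
  model
}

#' Plan repeated stratified cross-validation
#'
#' Three iterations of five-fold CV by default; within each iteration the
#' folds partition the examples, stratified by label so every fold sees both
#' classes when possible.
#'
#' @param labels Vector of binary labels (or review labels) to stratify on.
#' @param n_iterations Number of CV repetitions (default 3).
#' @param n_folds Folds per repetition (default 5).
#' @param seed Integer seed.
#' @return A `cv_plan`: list of per-iteration fold-assignment vectors.
#' @export
cv_plan <- function(labels, n_iterations = 3, n_folds = 5, seed = 1L) {
  n <- length(labels)
  stopifnot(n >= n_folds)
  assignments <- with_local_seed(seed, {
    lapply(seq_len(n_iterations), function(it) {
      fold <- integer(n)
      for (lv in unique(labels)) {
        idx <- sample(which(labels == lv))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      fold
    })
  })
  structure(list(n_iterations = n_iterations, n_folds = n_folds,
                 seed = as.integer(seed), fold_assignments = assignments),
            class = "cv_plan")
}

#' Evaluate probabilistic predictions
#'
#' Confusion counts at the cutoff, accuracy, precision, recall, AUROC by the
#' trapezoidal rule over the ROC curve, and AUPRC by the precision-recall
#' step integral. Tied scores are handled by grouping distinct score values
#' into single threshold steps.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param labels Binary labels (0/1 or logical).
#' @param cutoff Classification cutoff for the confusion counts.
#' @return A one-row data.frame: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `precision` (NA when nothing is called positive), `recall`, `auroc`,
#'   `auprc` (both NA when only one class is present).
#' @export
evaluate_predictions <- function(scores, labels, cutoff = 0.5) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% 0:1))
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) {
    auroc <- NA_real_; auprc <- NA_real_
  } else {
    ord <- order(scores, decreasing = TRUE)
    ys <- y[ord]; ss <- scores[ord]
    grp_end <- cumsum(rle(ss)$lengths)       # distinct-score thresholds
    ctp <- cumsum(ys)[grp_end]
    cfp <- (grp_end - cumsum(ys)[grp_end])
    tpr <- c(0, ctp / P); fpr <- c(0, cfp / N)
    auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    prec <- ctp / grp_end
    rec <- ctp / P
    auprc <- sum(diff(c(0, rec)) * prec)     # step integral
  }
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             accuracy = (tp + tn) / length(y),
             precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
             recall = if (P == 0) NA_real_ else tp / P,
             auroc = auroc, auprc = auprc)
}

#' Cross-validate a feature-based classifier
#'
#' For each fold of each iteration, a model is trained on the remaining
#' folds (imputation and scaling refit on that training split only) and
#' scored on the held-out fold. Summary AUROC and AUPRC take the median
#' across the folds of each iteration, then the mean across iterations.
#' Folds whose test split contains a single class are skipped with a
#' warning.
#'
#' @param examples Labeled example table (see [train_model()]).
#' @param algorithm Classifier name, as in [train_model()].
#' @param plan A [cv_plan()] built for these examples (definite labels only).
#' @return List with `folds` (per-fold evaluation rows) and `auroc`,
#'   `auprc` summaries.
#' @export
cross_validate <- function(examples, algorithm, plan) {
  stopifnot(inherits(plan, "cv_plan"))
  ex <- examples[examples$label %in% .definite_labels, , drop = FALSE]
  if (nrow(ex) != length(plan$fold_assignments[[1]])) {
    stop("plan was built for a different number of definite examples",
         call. = FALSE)
  }
  y <- as.integer(ex$label == "definitely_problematic")
  rows <- list()
  for (it in seq_len(plan$n_iterations)) {
    fold <- plan$fold_assignments[[it]]
    for (f in seq_len(plan$n_folds)) {
      test_idx <- which(fold == f)
      if (length(unique(y[test_idx])) < 2) {
        warning(sprintf("iteration %d fold %d has a single-class test set; ",
                        it, f), "skipping", call. = FALSE)
        next
      }
      model <- train_model(ex[-test_idx, , drop = FALSE], algorithm,
                           seed = plan$seed + 100 * it + f)
      sc <- predict_scores(model, ex[test_idx, , drop = FALSE])
      res <- evaluate_predictions(sc, y[test_idx])
      rows[[length(rows) + 1]] <- cbind(iteration = it, fold = f, res)
    }
  }
  folds <- do.call(rbind, rows)
  per_it <- function(col) {
    meds <- tapply(folds[[col]], folds$iteration, stats::median)
    mean(meds)
  }
  list(folds = folds, auroc = per_it("auroc"), auprc = per_it("auprc"))
}

#' Aggregate image-level review labels to an article label
#'
#' An article with at least one definitely-problematic image is definitely
#' problematic; otherwise, with at least one definitely-okay image it is
#' definitely okay; otherwise no label is assigned.
#'
#' @param labels Character vector of review labels for one article's images.
#' @return A single label string, or `NA_character_`.
#' @export
aggregate_article_labels <- function(labels) {
  .check_labels(labels)
  if (length(labels) == 0) stop("empty label group", call. = FALSE)
  if ("definitely_problematic" %in% labels) return("definitely_problematic")
  if ("definitely_okay" %in% labels) return("definitely_okay")
  NA_character_
}

#' Read / write labeled example tables
#'
#' CSV with columns `source_id`, `label`, the five metric columns, and
#' `grayscale`.
#' @param examples Example table.
#' @param path CSV path.
#' @return `path` invisibly; `read_examples` returns the table.
#' @export
write_examples <- function(examples, path) {
  utils::write.csv(examples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_examples
#' @export
read_examples <- function(path) {
  ex <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("source_id", "label", .feature_cols), names(ex))
  if (length(missing) > 0) {
    stop("example table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  .check_labels(ex$label)
  ex
}
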