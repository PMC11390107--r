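toy_examples <- function(n = 60, seed = 1, sep = 3) {
  # linearly separable in the first feature when sep is large
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  data.frame(
    source_id = sprintf("img%03d", seq_len(n)),
    label = ifelse(y == 1, "definitely_problematic", "definitely_okay"),
    mean_pixelwise_dist = rnorm(n, mean = y * sep),
    max_ratio = rnorm(n, mean = y * sep),
    high_ratio_count = rpois(n, 1 + 2 * y),
    high_ratio_pixel_prop = pmin(1, pmax(0, rnorm(n, 0.3 + 0.3 * y, 0.1))),
    mean_spatial_dist = ifelse(runif(n) < 0.1, NA, runif(n, 0, 100)),
    grayscale = FALSE)
}

test_that("impute_and_scale fills undefined spatial distances above max", {
  ex <- toy_examples(30)
  ex$mean_spatial_dist[c(3, 7)] <- NA
  out <- impute_and_scale(ex)
  expect_false(any(is.na(out$train)))
  expect_equal(out$stats$impute,
               max(ex$mean_spatial_dist, na.rm = TRUE) + 1)
  # standardized training features
  expect_equal(unname(colMeans(out$train)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(out$train, 2, sd)), rep(1, 5), tolerance = 1e-10)
})

test_that("test-set transformation uses training statistics only", {
  ex <- toy_examples(40)
  tr <- ex[1:30, ]; te <- ex[31:40, ]
  out <- impute_and_scale(tr, te)
  refit <- impute_and_scale(te)
  # refitting statistics on the test set changes the output => the shared
  # path really does use train statistics
  expect_false(isTRUE(all.equal(out$test, refit$train)))
  # and the transformation is the train one applied verbatim
  manual <- sweep(sweep(as.matrix(
    transform(te, mean_spatial_dist = ifelse(is.na(mean_spatial_dist),
                                             out$stats$impute,
                                             mean_spatial_dist))[,
      c("mean_pixelwise_dist", "max_ratio", "high_ratio_count",
        "high_ratio_pixel_prop", "mean_spatial_dist")]),
    2, out$stats$center), 2, out$stats$scale, "/")
  expect_equal(unname(out$test), unname(manual))
})

test_that("logistic regression separates a separable toy set", {
  ex <- toy_examples(60, sep = 6)
  model <- train_model(ex, "logistic_regression")
  sc <- predict_scores(model, ex)
  y <- as.integer(ex$label == "definitely_problematic")
  expect_equal(mean((sc >= 0.5) == y), 1.0)
})

test_that("training is deterministic and label inversion flips scores", {
  ex <- toy_examples(60)
  for (alg in c("logistic_regression", "random_forest", "knn")) {
    m1 <- train_model(ex, alg, seed = 9)
    m2 <- train_model(ex, alg, seed = 9)
    expect_equal(predict_scores(m1, ex), predict_scores(m2, ex),
                 label = alg)
  }
  inv <- toy_examples(60)
  inv$label <- ifelse(inv$label == "definitely_okay",
                      "definitely_problematic", "definitely_okay")
  s <- predict_scores(train_model(toy_examples(60), "logistic_regression"),
                      toy_examples(60))
  s_inv <- predict_scores(train_model(inv, "logistic_regression"), inv)
  expect_equal(s_inv, 1 - s, tolerance = 1e-6)
})

test_that("single-class input and unknown labels are rejected", {
  ex <- toy_examples(20)
  ex$label <- "definitely_okay"
  expect_error(train_model(ex, "logistic_regression"), "each definite class")
  bad <- toy_examples(10)
  bad$label[1] <- "meh"
  expect_error(train_model(bad, "knn"), "unknown review label")
})

test_that("probable labels are excluded from training", {
  ex <- toy_examples(80, sep = 6)
  with_probs <- ex
  # corrupt some rows with 'probable' labels and absurd features; if they
  # entered training, separation would fail
  probs <- seq(1, 80, by = 4)
  with_probs$label[probs] <- rep(c("probably_problematic", "probably_okay"),
                                 length.out = length(probs))
  with_probs$mean_pixelwise_dist[probs] <- rnorm(length(probs), 100, 50)
  model <- train_model(with_probs, "logistic_regression")
  keep <- ex[-probs, ]
  y <- as.integer(keep$label == "definitely_problematic")
  expect_equal(mean((predict_scores(model, keep) >= 0.5) == y), 1.0)
})

test_that("model round-trips through disk with a version check", {
  ex <- toy_examples(40)
  model <- train_model(ex, "random_forest", seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  re <- load_model(path)
  expect_equal(predict_scores(re, ex), predict_scores(model, ex))
  bogus <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bogus)
  expect_error(load_model(bogus), "not a cvdscreen model")
})

test_that("evaluate_predictions: frozen examples and undefined markers", {
  r <- evaluate_predictions(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auroc, 1.0)
  expect_equal(r$auprc, 1.0)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(2, 0, 2, 0))
  # brute-forced: one concordant pair of four
  r2 <- evaluate_predictions(c(0.9, 0.8, 0.3, 0.1), c(0, 1, 0, 1))
  expect_equal(r2$auroc, 0.25)
  expect_equal(r2$auroc, bf_auroc(c(0.9, 0.8, 0.3, 0.1), c(0, 1, 0, 1)))
  # nothing called positive -> precision undefined, counts still there
  r3 <- evaluate_predictions(c(0.1, 0.2), c(1, 0), cutoff = 0.5)
  expect_true(is.na(r3$precision))
  expect_equal(r3$tn + r3$fn, 2)
  # single-class labels -> curve areas undefined
  r4 <- evaluate_predictions(c(0.9, 0.2), c(1, 1))
  expect_true(is.na(r4$auroc) && is.na(r4$auprc))
  expect_equal(r4$tp, 1)
})

test_that("trapezoidal AUROC equals the Mann-Whitney formulation", {
  set.seed(19)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(evaluate_predictions(scores, y)$auroc, bf_auroc(scores, y),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- runif(200)
  y <- rbinom(200, 1, 0.3)
  expect_equal(evaluate_predictions(scores, y)$auroc,
               as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                              levels = c("0", "1"),
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("AUPRC of random scores approaches the minority fraction", {
  set.seed(31)
  y <- rbinom(2000, 1, 0.15)
  scores <- runif(2000)
  expect_equal(evaluate_predictions(scores, y)$auprc, mean(y),
               tolerance = 0.05)
})

test_that("cv_plan folds partition examples, stratified and reproducible", {
  labels <- rep(c("definitely_problematic", "definitely_okay"), c(20, 80))
  plan <- cv_plan(labels, seed = 4)
  expect_length(plan$fold_assignments, 3)
  for (fold in plan$fold_assignments) {
    expect_equal(sort(unique(fold)), 1:5)
    expect_equal(length(fold), 100)
    # stratification: each fold holds 4 of the 20 positives
    expect_equal(as.integer(table(fold[labels == "definitely_problematic"])),
                 rep(4L, 5))
  }
  expect_identical(plan$fold_assignments,
                   cv_plan(labels, seed = 4)$fold_assignments)
  expect_false(identical(plan$fold_assignments,
                         cv_plan(labels, seed = 5)$fold_assignments))
})

test_that("cross_validate aggregates median-then-mean and is seeded", {
  ex <- toy_examples(100, sep = 6)
  def <- ex$label
  plan <- cv_plan(def, seed = 8)
  res <- cross_validate(ex, "logistic_regression", plan)
  expect_equal(nrow(res$folds), 15)
  meds <- tapply(res$folds$auroc, res$folds$iteration, median)
  expect_equal(res$auroc, mean(meds))
  res2 <- cross_validate(ex, "logistic_regression", plan)
  expect_identical(res$auroc, res2$auroc)
  expect_gte(res$auroc, 0.99)
})

test_that("degenerate single-class test folds are skipped with a warning", {
  ex <- toy_examples(50, sep = 6)
  plan <- cv_plan(ex$label, n_iterations = 1, seed = 3)
  # force fold 1's test set to a single class
  fold <- plan$fold_assignments[[1]]
  y <- ex$label == "definitely_problematic"
  fold[y & fold == 1] <- 2
  plan$fold_assignments[[1]] <- fold
  expect_warning(res <- cross_validate(ex, "logistic_regression", plan),
                 "single-class")
  expect_equal(nrow(res$folds), 4)
})

test_that("article labels aggregate by worst-case rule", {
  expect_equal(aggregate_article_labels(
    c("definitely_okay", "definitely_problematic")), "definitely_problematic")
  expect_equal(aggregate_article_labels(
    c("definitely_okay", "probably_okay")), "definitely_okay")
  expect_true(is.na(aggregate_article_labels(
    c("grayscale", "probably_okay"))))
  expect_error(aggregate_article_labels(character()), "empty")
})

test_that("example tables round-trip through CSV", {
  ex <- toy_examples(15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_examples(ex, path)
  back <- read_examples(path)
  expect_equal(back$label, ex$label)
  expect_equal(back$mean_spatial_dist, ex$mean_spatial_dist)
  incomplete <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(source_id = "a", label = "definitely_okay"),
            incomplete, row.names = FALSE)
  expect_error(read_examples(incomplete), "lacks column")
})
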