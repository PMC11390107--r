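# Configurable CNN training harness: a baseline stack of eight 3x3
# convolutional layers (batch norm + ReLU each, widths 32, 32, 64, 128, 256,
# 512, 728, 728, stride-2 downsampling at each width increase), global
# average pooling and a sigmoid head; trained with Adam on binary
# cross-entropy. Supported configuration axes: class weighting, early
# stopping on validation AUROC, random horizontal flip / rotation
# augmentation, dropout on the pooled features, and transfer learning with
# an optional fine-tuning phase.

.paper_widths <- c(32, 32, 64, 128, 256, 512, 728, 728)

#' CNN training configuration
#'
#' Two profiles are provided: `"paper"` (input 224, full widths, 30 + 15
#' epochs) and `"desk"` (input 64, widths halved, up to 10 epochs) — the
#' desk profile trains on one CPU in minutes and is the default for tests
#' and examples. Any field can be overridden.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param input_size Square input side in pixels.
#' @param widths Integer vector of conv layer widths.
#' @param use_class_weighting Weight the minority class inversely to its
#'   frequency.
#' @param use_early_stopping Monitor validation AUROC and restore the best
#'   epoch's weights.
#' @param use_flip_rotation Random horizontal flips and rotations on
#'   training batches only.
#' @param rotation_threshold Rotation magnitude as a fraction of a full
#'   turn, 0.2 or 0.3 (used only when `use_flip_rotation`).
#' @param dropout_rate 0, 0.2, or 0.5; applied to the pooled features.
#' @param transfer_base `"none"`, `"resnet50"`, or `"mobilenetv2"`.
#' @param fine_tune Run a second, low-learning-rate phase with the base
#'   unfrozen (requires a transfer base).
#' @param epochs_initial,epochs_fine_tune Epoch budgets for the two phases.
#' @param lr_initial,lr_fine_tune Adam learning rates for the two phases.
#' @param batch_size Minibatch size.
#' @param val_fraction Stratified internal-validation fraction.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed for initialization, splits, and augmentation.
#' @return A validated `cnn_config` list.
#' @export
cnn_config <- function(profile = c("desk", "paper"),
                       input_size = NULL, widths = NULL,
                       use_class_weighting = FALSE,
                       use_early_stopping = FALSE,
                       use_flip_rotation = FALSE,
                       rotation_threshold = 0.2,
                       dropout_rate = 0,
                       transfer_base = c("none", "resnet50", "mobilenetv2"),
                       fine_tune = FALSE,
                       epochs_initial = NULL, epochs_fine_tune = 15,
                       lr_initial = 1e-3, lr_fine_tune = 1e-5,
                       batch_size = 16, val_fraction = 0.2, patience = 5,
                       seed = 1L) {
  profile <- match.arg(profile)
  transfer_base <- match.arg(transfer_base)
  if (is.null(input_size)) input_size <- if (profile == "desk") 64 else 224
  if (is.null(widths)) {
    widths <- if (profile == "desk") .paper_widths %/% 2 else .paper_widths
  }
  if (is.null(epochs_initial)) {
    epochs_initial <- if (profile == "desk") 10 else 30
  }
  problems <- character()
  if (fine_tune && transfer_base == "none") {
    problems <- c(problems, "fine_tune requires a transfer_base")
  }
  if (!rotation_threshold %in% c(0.2, 0.3)) {
    problems <- c(problems, "rotation_threshold must be 0.2 or 0.3")
  }
  if (!dropout_rate %in% c(0, 0.2, 0.5)) {
    problems <- c(problems, "dropout_rate must be 0, 0.2, or 0.5")
  }
  if (input_size < 8) problems <- c(problems, "input_size must be >= 8")
  if (length(problems) > 0) {
    stop("invalid CNN configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(profile = profile, input_size = as.integer(input_size),
                 widths = as.integer(widths),
                 use_class_weighting = use_class_weighting,
                 use_early_stopping = use_early_stopping,
                 use_flip_rotation = use_flip_rotation,
                 rotation_threshold = rotation_threshold,
                 dropout_rate = dropout_rate,
                 transfer_base = transfer_base, fine_tune = fine_tune,
                 epochs_initial = as.integer(epochs_initial),
                 epochs_fine_tune = as.integer(epochs_fine_tune),
                 lr_initial = lr_initial, lr_fine_tune = lr_fine_tune,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# stride 2 wherever the width increases over the previous layer
.layer_strides <- function(widths) {
  c(1L, ifelse(diff(widths) > 0, 2L, 1L))
}

.init_params <- function(widths, in_channels, seed) {
  with_local_seed(seed, {
    convs <- vector("list", length(widths))
    cin <- in_channels
    for (l in seq_along(widths)) {
      cout <- widths[l]
      fan_in <- cin * 9
      convs[[l]] <- list(
        W = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                   cout, fan_in),
        gamma = rep(1, cout), beta = rep(0, cout),
        rmean = rep(0, cout), rvar = rep(1, cout))
      cin <- cout
    }
    list(convs = convs,
         hw = stats::rnorm(cin, sd = sqrt(1 / cin)),
         hb = 0)
  })
}

#' Build the baseline CNN
#'
#' @param config A [cnn_config()] with `transfer_base = "none"`.
#' @return An untrained `cvd_cnn` (config, seeded initial weights, empty
#'   training log).
#' @export
build_baseline <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  if (config$transfer_base != "none") {
    stop("build_baseline requires transfer_base = 'none'; use ",
         "build_transfer()", call. = FALSE)
  }
  structure(list(config = config,
                 params = .init_params(config$widths, 3L, config$seed),
                 strides = .layer_strides(config$widths),
                 frozen_layers = integer(),
                 training_log = list()),
            class = "cvd_cnn")
}

#' Build a transfer-learning CNN from pre-trained base weights
#'
#' Loads a pre-trained convolutional base from `weights_dir`, freezes its
#' layers, and attaches a fresh global-pooling + dense sigmoid head. The
#' weights file must be named `<transfer_base>_weights.rds` and contain a
#' conv stack in this package's parameter format.
#'
#' @param config A [cnn_config()] with `transfer_base != "none"`.
#' @param weights_dir Directory holding the pre-trained weights file.
#' @return An untrained `cvd_cnn` with the base layers frozen.
#' @export
build_transfer <- function(config, weights_dir = getOption(
                             "cvdscreen.weights_dir", "~/.cvdscreen/weights")) {
  stopifnot(inherits(config, "cnn_config"))
  if (config$transfer_base == "none") {
    stop("build_transfer requires a transfer_base; use build_baseline()",
         call. = FALSE)
  }
  wfile <- file.path(path.expand(weights_dir),
                     paste0(config$transfer_base, "_weights.rds"))
  if (!file.exists(wfile)) {
    stop("pre-trained weights for '", config$transfer_base, "' not found.\n",
         "Obtain a converted weights file and place it at:\n  ", wfile,
         "\n(or pass `weights_dir`, or set options(cvdscreen.weights_dir=))",
         call. = FALSE)
  }
  base <- readRDS(wfile)
  stopifnot(is.list(base$convs))
  widths <- vapply(base$convs, function(l) nrow(l$W), integer(1))
  cin <- widths[length(widths)]
  head <- with_local_seed(config$seed, {
    list(hw = stats::rnorm(cin, sd = sqrt(1 / cin)), hb = 0)
  })
  structure(list(config = config,
                 params = list(convs = base$convs, hw = head$hw,
                               hb = head$hb),
                 strides = if (!is.null(base$strides)) as.integer(base$strides)
                           else .layer_strides(widths),
                 frozen_layers = seq_along(base$convs),
                 training_log = list()),
            class = "cvd_cnn")
}

#' @export
print.cvd_cnn <- function(x, ...) {
  cat(sprintf("<cvd_cnn %s input=%d widths=%s%s  %d logged epoch(s)>\n",
              x$config$profile, x$config$input_size,
              paste(x$config$widths, collapse = ","),
              if (length(x$frozen_layers)) " [frozen base]" else "",
              length(x$training_log)))
  invisible(x)
}

# images -> (3 x H*W) matrix with row-major pixel order, as the engine expects
.img_to_cols <- function(px) {
  t(matrix(aperm(px, c(2, 1, 3)), ncol = 3))  # pixel p = y*W + x
}

.prepare_batch <- function(imgs, size) {
  mats <- lapply(imgs, function(im) {
    .img_to_cols(resize_to_square(im, size)$pixels)
  })
  do.call(cbind, mats)
}

.flip_h <- function(px) px[, dim(px)[2]:1, , drop = FALSE]

# nearest-neighbor rotation about the image center, white fill
.rotate_nn <- function(px, theta) {
  h <- dim(px)[1]; w <- dim(px)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  sy <- round(cy + yy * cos(theta) - xx * sin(theta))
  sx <- round(cx + yy * sin(theta) + xx * cos(theta))
  ok <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
  out <- array(1, dim = dim(px))
  src <- cbind(sy[ok], sx[ok])
  for (k in 1:3) {
    ch <- px[, , k]
    plane <- matrix(1, h, w)
    plane[ok] <- ch[src]
    out[, , k] <- plane
  }
  out
}

.augment <- function(img, rotation_threshold) {
  px <- img$pixels
  if (stats::runif(1) < 0.5) px <- .flip_h(px)
  theta <- stats::runif(1, -rotation_threshold, rotation_threshold) * 2 * pi
  img$pixels <- .rotate_nn(px, theta)
  img
}

.predict_images <- function(model, imgs, chunk = 32) {
  size <- model$config$input_size
  out <- numeric(length(imgs))
  for (start in seq(1, length(imgs), by = chunk)) {
    idx <- start:min(start + chunk - 1, length(imgs))
    x <- .prepare_batch(imgs[idx], size)
    out[idx] <- cnn_predict_batch(model$params, x, size, size,
                                  length(idx), model$strides)
  }
  out
}

.auroc_of <- function(scores, y) {
  if (length(unique(y)) < 2) return(NA_real_)
  evaluate_predictions(scores, y)$auroc
}

.adam_state <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

#' Train a CNN on a labeled image corpus
#'
#' Splits off a stratified internal validation set, then runs minibatch Adam
#' on weighted binary cross-entropy. Per the configuration: the minority
#' class is up-weighted inversely to its frequency; training batches (never
#' validation) get random horizontal flips and rotations; validation AUROC
#' is logged every epoch and, with early stopping, the best epoch's weights
#' are restored. With a transfer base and `fine_tune`, a second phase
#' unfreezes the base at the fine-tuning learning rate, then refreezes it.
#'
#' @param model An untrained `cvd_cnn` from [build_baseline()] or
#'   [build_transfer()].
#' @param images List of `raster_image`s.
#' @param labels Binary vector (1 = definitely problematic) or review-label
#'   strings.
#' @return A trained `cvd_cnn` with `training_log` rows
#'   (epoch, phase, loss, val_auroc).
#' @export
train_cnn <- function(model, images, labels) {
  stopifnot(inherits(model, "cvd_cnn"))
  cfg <- model$config
  if (is.character(labels)) {
    labels <- as.integer(labels == "definitely_problematic")
  }
  y <- as.integer(labels)
  if (length(unique(y)) < 2) {
    stop("training corpus must contain both classes", call. = FALSE)
  }
  size <- cfg$input_size
  imgs <- lapply(images, resize_to_square, size = size)

  with_local_seed(cfg$seed, {
    # stratified internal validation split
    val_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, max(1, round(length(idx) * cfg$val_fraction)))
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_along(y), val_idx)

    wts <- rep(1, length(y))
    if (cfg$use_class_weighting) {
      freq <- table(factor(y, levels = 0:1)) / length(y)
      wts <- as.numeric(1 / (2 * freq[as.character(y)]))
    }

    phases <- list(list(name = "initial", epochs = cfg$epochs_initial,
                        lr = cfg$lr_initial, frozen = model$frozen_layers))
    if (cfg$fine_tune) {
      phases <- c(phases, list(list(name = "fine_tune",
                                    epochs = cfg$epochs_fine_tune,
                                    lr = cfg$lr_fine_tune,
                                    frozen = integer())))
    }

    params <- model$params
    log <- model$training_log
    for (phase in phases) {
      m1 <- .adam_state(params); m2 <- .adam_state(params)
      t_step <- 0
      best_auroc <- -Inf; best_params <- params; wait <- 0
      for (epoch in seq_len(phase$epochs)) {
        ord <- sample(tr_idx)
        ep_loss <- 0; nb <- 0
        for (start in seq(1, length(ord), by = cfg$batch_size)) {
          bidx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
          bim <- imgs[bidx]
          if (cfg$use_flip_rotation) {
            bim <- lapply(bim, .augment, cfg$rotation_threshold)
          }
          x <- .prepare_batch(bim, size)
          res <- cnn_train_batch(params, x, size, size, length(bidx),
                                 y[bidx], wts[bidx], model$strides,
                                 cfg$dropout_rate,
                                 sample.int(.Machine$integer.max, 1),
                                 TRUE)
          t_step <- t_step + 1
          upd <- .adam_update(params, res, m1, m2, t_step, phase$lr,
                              phase$frozen)
          params <- upd$params; m1 <- upd$m1; m2 <- upd$m2
          ep_loss <- ep_loss + res$loss; nb <- nb + 1
        }
        val_auroc <- .auroc_of(
          .predict_images(list(config = cfg, params = params,
                               strides = model$strides), imgs[val_idx]),
          y[val_idx])
        log[[length(log) + 1]] <- data.frame(
          epoch = epoch, phase = phase$name, loss = ep_loss / nb,
          val_auroc = val_auroc)
        if (cfg$use_early_stopping && !is.na(val_auroc)) {
          if (val_auroc > best_auroc) {
            best_auroc <- val_auroc; best_params <- params; wait <- 0
          } else {
            wait <- wait + 1
            if (wait >= cfg$patience) break
          }
        }
      }
      if (cfg$use_early_stopping && is.finite(best_auroc)) {
        params <- best_params
      }
    }
    model$params <- params
    model$training_log <- log
    model$val_idx <- val_idx
  })
  model
}

# Adam step; frozen conv layers receive no update but keep BN running stats.
.adam_update <- function(params, res, m1, m2, t, lr, frozen,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, s1, s2) {
    s1 <- beta1 * s1 + (1 - beta1) * g
    s2 <- beta2 * s2 + (1 - beta2) * g^2
    p <- p - lr * (s1 / (1 - beta1^t)) / (sqrt(s2 / (1 - beta2^t)) + eps)
    list(p = p, s1 = s1, s2 = s2)
  }
  for (l in seq_along(params$convs)) {
    params$convs[[l]]$rmean <- res$running[[l]]$rmean
    params$convs[[l]]$rvar <- res$running[[l]]$rvar
    if (l %in% frozen) next
    for (nm in c("W", "gamma", "beta")) {
      u <- step(params$convs[[l]][[nm]], res$grads[[l]][[nm]],
                m1$convs[[l]][[nm]], m2$convs[[l]][[nm]])
      params$convs[[l]][[nm]] <- u$p
      m1$convs[[l]][[nm]] <- u$s1
      m2$convs[[l]][[nm]] <- u$s2
    }
  }
  u <- step(params$hw, res$dhw, m1$hw, m2$hw)
  params$hw <- u$p; m1$hw <- u$s1; m2$hw <- u$s2
  u <- step(params$hb, res$dhb, m1$hb, m2$hb)
  params$hb <- u$p; m1$hb <- u$s1; m2$hb <- u$s2
  list(params = params, m1 = m1, m2 = m2)
}

#' Predict the probability that images are problematic
#'
#' @param model A trained `cvd_cnn`.
#' @param images A `raster_image` or list of them.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_cnn <- function(model, images) {
  stopifnot(inherits(model, "cvd_cnn"))
  if (inherits(images, "raster_image")) images <- list(images)
  .predict_images(model, images)
}

#' Save / load a trained CNN
#'
#' The checkpoint carries the full configuration alongside the weights.
#' @param model A `cvd_cnn`.
#' @param path Destination file.
#' @return `path` invisibly; `load_cnn` returns the model.
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "cvd_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cvd_cnn")) {
    stop("not a cvdscreen CNN checkpoint: ", path, call. = FALSE)
  }
  model
}
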