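# Batch screening reports and the command-line interface.

REPORT_SCHEMA_VERSION <- "1.0"

#' Screen one or more images for deuteranopia accessibility
#'
#' Computes the five metrics (and grayscale flag) per image. With two or more
#' images the corpus-relative rank-based combined score is added (rank is
#' meaningless for a single image); with a model, a probabilistic prediction
#' per image. Unreadable files are collected as failures and the run
#' continues.
#'
#' @param paths Image file path(s), or a directory (scanned non-recursively
#'   for PNG/JPEG).
#' @param severity Simulation severity (default 0.8).
#' @param model Optional `cvd_model` (feature-based) or `cvd_cnn`.
#' @param ratio_threshold High-ratio threshold (default 5).
#' @param seed Seed for spatial-distance subsampling.
#' @param write_previews Write a deuteranopia-simulated PNG next to each
#'   input (or into `out_dir`).
#' @param out_dir Destination for previews (default: beside the originals).
#' @param quiet Suppress per-image progress lines.
#' @return A `screening_report`: `rows` (one per processed image),
#'   `failures` (path + reason), and `meta` (parameters, schema version).
#' @export
screen <- function(paths, severity = 0.8, model = NULL, ratio_threshold = 5,
                   seed = 1L, write_previews = FALSE, out_dir = NULL,
                   quiet = FALSE) {
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) {
      list.files(p, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                 full.names = TRUE)
    } else p
  }))
  if (length(files) == 0) stop("no input images found", call. = FALSE)
  if (!quiet) {
    message(sprintf("screening %d image(s): severity=%.2f threshold=%g seed=%d",
                    length(files), severity, ratio_threshold, seed))
  }
  rows <- list(); failures <- list(); imgs <- list()
  for (f in files) {
    res <- tryCatch({
      img <- load_image(f)
      mv <- compute_metric_vector(img, severity = severity,
                                  ratio_threshold = ratio_threshold,
                                  seed = seed)
      if (write_previews) {
        dest <- if (is.null(out_dir)) dirname(f) else out_dir
        dir.create(dest, recursive = TRUE, showWarnings = FALSE)
        base <- tools::file_path_sans_ext(basename(f))
        write_png(simulate_deutan(img, severity),
                  file.path(dest, sprintf("%s.deutan%s.png", base, severity)))
      }
      list(img = img, row = cbind(data.frame(source_id = f), mv))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(path = f, reason = conditionMessage(res))
      if (!quiet) message("  FAILED ", f)
    } else {
      rows[[length(rows) + 1]] <- res$row
      imgs[[length(imgs) + 1]] <- res$img
      if (!quiet) message("  ok ", f)
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(rows) && nrow(rows) >= 2) {
    rows <- cbind(rows, combined_rank = rank_based_scores(rows)$combined)
  }
  if (!is.null(rows) && !is.null(model)) {
    rows$prediction <- if (inherits(model, "cvd_cnn")) {
      predict_cnn(model, imgs)
    } else {
      predict_scores(model, rows)
    }
  }
  structure(list(rows = rows,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 meta = list(schema_version = REPORT_SCHEMA_VERSION,
                             severity = severity,
                             ratio_threshold = ratio_threshold,
                             seed = seed,
                             package_version =
                               as.character(utils::packageVersion("cvdscreen")))),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  n <- if (is.null(x$rows)) 0 else nrow(x$rows)
  nf <- if (is.null(x$failures)) 0 else nrow(x$failures)
  cat(sprintf("<screening_report  %d image(s), %d failure(s)>\n", n, nf))
  if (n > 0) print(utils::head(x$rows, 10))
  invisible(x)
}

#' Write a screening report to CSV or JSON
#'
#' Column order is stable; the JSON schema is versioned; numeric values
#' round-trip losslessly. An empty failure list is omitted from the JSON.
#'
#' @param report A `screening_report`.
#' @param path Destination file.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(report, "screening_report"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# cvdscreen report schema %s severity %s",
                       report$meta$schema_version, report$meta$severity), con)
    utils::write.csv(report$rows, con, row.names = FALSE)
  } else {
    payload <- list(meta = report$meta, rows = report$rows)
    if (!is.null(report$failures)) payload$failures <- report$failures
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read back a CSV screening report
#'
#' @param path A CSV written by [write_report()].
#' @return The rows data.frame.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# CLI

.cli_usage <- "usage: cvdscreen <command> [options]

commands:
  simulate <path> [--severity S] [--out-dir D]
      write a deuteranopia-simulated PNG next to the input
  metrics <path|dir>... [--severity S] [--ratio-threshold T] [--seed N]
          [--out FILE]
      compute the five accessibility metrics (+ rank score in batch mode)
  train --manifest CSV --algorithm {lr,rf,knn} --out MODEL [--seed N]
      train a feature-based classifier from a labeled example table
  cv --manifest CSV [--algorithm {lr,rf,knn}] [--iterations 3] [--folds 5]
          [--seed N]
      repeated stratified cross-validation with AUROC/AUPRC summary
  predict <path|dir>... --model FILE [--out FILE]
      score images with a trained model
  fixtures --out DIR [--n 100] [--problem-fraction 0.1] [--seed N]
      generate a certified synthetic corpus with a manifest
options may also come from a YAML config file via --config FILE (flags win)."

.parse_cli <- function(args) {
  flags <- list(); positional <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        flags[[key]] <- TRUE
      } else {
        flags[[key]] <- args[i + 1]
        i <- i + 1
      }
    } else {
      positional <- c(positional, a)
    }
    i <- i + 1
  }
  if (!is.null(flags$config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("--config requires the yaml package", call. = FALSE)
    }
    conf <- yaml::read_yaml(flags$config)
    names(conf) <- gsub("-", "_", names(conf))
    for (k in setdiff(names(conf), names(flags))) flags[[k]] <- conf[[k]]
  }
  list(flags = flags, positional = positional)
}

.flag <- function(flags, name, default) {
  v <- flags[[name]]
  if (is.null(v)) return(default)
  if (is.numeric(default)) as.numeric(v) else v
}

.algo_name <- function(code) {
  switch(code,
         lr = "logistic_regression", rf = "random_forest", knn = "knn",
         logistic_regression = , random_forest = code,
         stop("unknown algorithm '", code, "' (use lr, rf, or knn)",
              call. = FALSE))
}

#' Command-line entry point
#'
#' Drives the `cvdscreen` CLI (see `inst/cli/cvdscreen`). Returns the exit
#' code instead of calling `quit()` so it can be tested in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 on full success, 1 on partial failures or
#'   usage errors.
#' @export
cvdscreen_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message(.cli_usage)
    return(1L)
  }
  cmd <- args[1]
  parsed <- .parse_cli(args[-1])
  fl <- parsed$flags; pos <- parsed$positional
  tryCatch({
    switch(cmd,
      simulate = {
        if (length(pos) == 0) stop("simulate: no input image", call. = FALSE)
        sev <- .flag(fl, "severity", 0.8)
        for (p in pos) {
          img <- load_image(p)
          dest <- if (is.null(fl$out_dir)) dirname(p) else {
            dir.create(fl$out_dir, recursive = TRUE, showWarnings = FALSE)
            fl$out_dir
          }
          out <- file.path(dest, sprintf("%s.deutan%s.png",
                                         tools::file_path_sans_ext(basename(p)),
                                         sev))
          write_png(simulate_deutan(img, sev), out)
          message("wrote ", out)
        }
        0L
      },
      metrics = {
        if (length(pos) == 0) stop("metrics: no inputs", call. = FALSE)
        rep <- screen(pos, severity = .flag(fl, "severity", 0.8),
                      ratio_threshold = .flag(fl, "ratio_threshold", 5),
                      seed = as.integer(.flag(fl, "seed", 1)))
        out <- .flag(fl, "out", "")
        if (nzchar(out)) write_report(rep, out) else print(rep)
        if (is.null(rep$failures)) 0L else 1L
      },
      train = {
        ex <- read_examples(fl$manifest)
        model <- train_model(ex, .algo_name(.flag(fl, "algorithm", "lr")),
                             seed = as.integer(.flag(fl, "seed", 1)))
        save_model(model, fl$out)
        message("model written to ", fl$out)
        0L
      },
      cv = {
        ex <- read_examples(fl$manifest)
        def <- ex[ex$label %in% .definite_labels, ]
        plan <- cv_plan(def$label,
                        n_iterations = as.integer(.flag(fl, "iterations", 3)),
                        n_folds = as.integer(.flag(fl, "folds", 5)),
                        seed = as.integer(.flag(fl, "seed", 1)))
        res <- cross_validate(ex, .algo_name(.flag(fl, "algorithm", "lr")),
                              plan)
        cat(sprintf("AUROC %.4f  AUPRC %.4f  (%d folds evaluated)\n",
                    res$auroc, res$auprc, nrow(res$folds)))
        0L
      },
      predict = {
        if (length(pos) == 0) stop("predict: no inputs", call. = FALSE)
        model <- tryCatch(load_model(fl$model),
                          error = function(e) load_cnn(fl$model))
        rep <- screen(pos, severity = .flag(fl, "severity", 0.8),
                      model = model,
                      seed = as.integer(.flag(fl, "seed", 1)))
        out <- .flag(fl, "out", "")
        if (nzchar(out)) write_report(rep, out) else print(rep)
        if (is.null(rep$failures)) 0L else 1L
      },
      fixtures = {
        n <- as.integer(.flag(fl, "n", 100))
        corpus <- make_labeled_corpus(
          n, problem_fraction = .flag(fl, "problem_fraction", 0.1),
          seed = as.integer(.flag(fl, "seed", 1)))
        mpath <- write_corpus(corpus, fl$out)
        ex <- corpus_examples(corpus)
        ex$source_id <- paste0(ex$source_id, ".png")
        write_examples(ex, file.path(fl$out, "examples.csv"))
        message("corpus of ", n, " fixtures written; manifest at ", mpath)
        0L
      },
      {
        message("unknown command '", cmd, "'\n", .cli_usage)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
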