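# S3 methods for fitted models and cross-validation reports.

#' @export
print.sttcnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sttcnn> variant %s: %d channels x %d samples -> %d classes\n",
              cfg$variant, cfg$n_channels, cfg$window_samples, cfg$n_classes))
  cat(sprintf("  d_model %d, h %d, %d encoder layer(s), %s head, %s parameters\n",
              cfg$d_model, cfg$h, cfg$n_encoder_layers,
              if (cfg_has_cnn(cfg)) sprintf("CNN (%d kernels)", cfg$conv_kernels)
              else "direct FC",
              format(tree_n_params(x$params), big.mark = ",")))
  cat(sprintf("  trained %d epoch(s) on %d segments; final loss %.4f\n",
              nrow(x$history), x$n_train, utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.sttcnn <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  loss: first %.4f, min %.4f (epoch %d)\n",
              h$loss[1], min(h$loss), which.min(h$loss)))
  if (any(!is.na(h$train_accuracy)))
    cat(sprintf("  last train accuracy: %.4f\n",
                utils::tail(stats::na.omit(h$train_accuracy), 1)))
  invisible(object)
}

#' Extract model parameters
#'
#' @param object a fitted `sttcnn` model.
#' @param flatten return a single named numeric vector instead of the
#'   nested parameter tree.
#' @param ... unused.
#' @return nested list of arrays, or a named numeric vector.
#' @export
coef.sttcnn <- function(object, flatten = FALSE, ...) {
  if (!flatten) return(object$params)
  leaves <- list()
  walk <- function(x, prefix) {
    nm <- names(x)
    for (i in seq_along(x)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      full <- paste(c(prefix, key), collapse = ".")
      if (is.list(x[[i]])) walk(x[[i]], c(prefix, key))
      else leaves[[full]] <<- as.vector(x[[i]])
    }
  }
  walk(object$params, character())
  out <- unlist(leaves)
  out
}

#' Plot the training loss curve
#'
#' @param x a fitted `sttcnn` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sttcnn <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "loss",
                 main = sprintf("%s training loss", x$config$variant), ...)
  invisible(x)
}

#' @export
print.sttcnn_cv <- function(x, ...) {
  cat(sprintf("<sttcnn_cv> %s, task '%s', %d-fold\n", x$variant, x$task, x$k))
  cat(sprintf("  accuracy: mean %.4f, variance %.6f\n", x$mean_accuracy, x$variance))
  cat("  per fold:", paste(sprintf("%.3f", x$accuracies), collapse = " "), "\n")
  cat(sprintf("  macro P %.4f  R %.4f  F1 %.4f\n", x$metrics$macro_precision,
              x$metrics$macro_recall, x$metrics$macro_f1))
  invisible(x)
}

#' @export
summary.sttcnn_cv <- function(object, ...) {
  print(object)
  cat("\nPooled confusion matrix:\n")
  print(object$confusion)
  invisible(object)
}

#' Plot per-fold accuracies
#'
#' @param x an `sttcnn_cv` report.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sttcnn_cv <- function(x, ...) {
  graphics::barplot(x$accuracies, names.arg = seq_along(x$accuracies),
                    xlab = "fold", ylab = "held-out accuracy", ylim = c(0, 1),
                    main = sprintf("%s %d-fold CV", x$variant, x$k), ...)
  graphics::abline(h = x$mean_accuracy, lty = 2)
  invisible(x)
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> fold %d: accuracy %.4f on %d held-out segments\n",
              x$fold_index, x$test_accuracy, x$n_test))
  invisible(x)
}

# --- checkpoints -------------------------------------------------------------

#' Save a fitted model as a JSON checkpoint
#'
#' A single versioned JSON archive holding the configuration and all named
#' parameter arrays (with dimensions), portable across platforms.
#'
#' @param model a fitted `sttcnn` model.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_sttcnn <- function(model, path) {
  stopifnot(inherits(model, "sttcnn"))
  ser <- function(x) {
    if (is.list(x)) return(lapply(x, ser))
    list(dim = dim(x) %||% length(x), data = as.vector(x))
  }
  obj <- list(schema_version = 1L,
              config = unclass(model$config),
              task = model$task, class_names = model$class_names,
              params = ser(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by [save_sttcnn()].
#' @return an `sttcnn` model usable with [predict.sttcnn()].
#' @export
load_sttcnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version > 1)
    stopf("unsupported checkpoint schema: %s", obj$schema_version %||% "missing")
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  deser <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data)) {
      if (length(x$dim) > 1) return(array(x$data, unlist(x$dim)))
      return(as.numeric(x$data))
    }
    lapply(x, deser)
  }
  structure(list(params = deser(obj$params), config = cfg,
                 train_config = NULL,
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      train_accuracy = numeric()),
                 n_train = NA_integer_, task = obj$task,
                 class_names = obj$class_names, stopped_epoch = NA_integer_,
                 call = NULL),
            class = "sttcnn")
}
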