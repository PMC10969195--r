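#' Training configuration
#'
#' Optimization settings for [sttcnn_fit()] and [cross_validate()]. Defaults
#' follow the reference regime: ten-fold cross-validation, Adam with
#' learning rate 1e-4, batch size 128, cross-entropy plus L2 loss.
#'
#' @param k_folds folds for cross-validation (>= 2).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param l2_lambda coefficient of the L2 penalty on weight matrices
#'   (biases and layer-norm parameters are not penalized).
#' @param max_epochs training epochs.
#' @param early_stop_patience stop when the epoch loss has not improved for
#'   this many epochs (`NULL` = never).
#' @param stop_train_accuracy stop once eval-mode accuracy on the training
#'   set reaches this value (`NULL` = never check).
#' @param seed seed controlling initialization, shuffling, dropout and fold
#'   assignment.
#' @param verbose print per-epoch loss.
#' @return an object of class `train_config`.
#' @export
train_config <- function(k_folds = 10, learning_rate = 1e-4, batch_size = 128,
                         l2_lambda = 1e-4, max_epochs = 100,
                         early_stop_patience = NULL, stop_train_accuracy = NULL,
                         seed = 1L, verbose = FALSE) {
  stopifnot(k_folds >= 2, learning_rate > 0, is_count(batch_size),
            l2_lambda >= 0, is_count(max_epochs))
  structure(list(k_folds = as.integer(k_folds), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), l2_lambda = l2_lambda,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 stop_train_accuracy = stop_train_accuracy,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

is_weight_name <- function(nm) grepl("^W[qkvo]$|_W[12]?$", nm)

# Sum of squares over penalized (weight-matrix) leaves.
l2_sum_weights <- function(p) {
  total <- 0
  walk <- function(x) {
    nm <- names(x)
    for (i in seq_along(x)) {
      if (is.list(x[[i]])) walk(x[[i]])
      else if (!is.null(nm) && is_weight_name(nm[i])) total <<- total + sum(x[[i]]^2)
    }
  }
  walk(p)
  total
}

# grads += 2 * lambda * params on penalized leaves (in place, by name).
add_l2_grads <- function(g, p, lambda) {
  nm <- names(p)
  for (i in seq_along(p)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
    if (is.list(p[[i]])) g[[key]] <- add_l2_grads(g[[key]], p[[i]], lambda)
    else if (is.character(key) && is_weight_name(key))
      g[[key]] <- g[[key]] + 2 * lambda * p[[i]]
  }
  g
}

#' Cross-entropy loss with L2 regularization
#'
#' Mean cross-entropy of the true classes under the softmax of `logits`,
#' plus `l2_lambda` times the sum of squared weight-matrix entries of
#' `params`. With uniform probabilities the cross-entropy term equals
#' `log(n_classes)`.
#'
#' @param logits `n x n_classes` matrix of unnormalized scores.
#' @param labels integer vector of 0-based true classes.
#' @param params optional parameter tree contributing the L2 term.
#' @param l2_lambda L2 coefficient.
#' @return scalar loss.
#' @export
loss <- function(logits, labels, params = NULL, l2_lambda = 0) {
  if (is.vector(logits)) logits <- matrix(logits, 1)
  n <- nrow(logits)
  stopifnot(length(labels) == n)
  if (any(labels < 0 | labels >= ncol(logits)))
    stopf("labels must be 0-based class indices < %d", ncol(logits))
  m <- apply(logits, 1, max)
  logz <- m + log(rowSums(exp(logits - m)))
  ce <- mean(logz - logits[cbind(seq_len(n), labels + 1L)])
  l2 <- if (!is.null(params) && l2_lambda > 0) l2_lambda * l2_sum_weights(params) else 0
  ce + l2
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(params) list(m = tree_zeros_like(params),
                                   v = tree_zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}

# --- fitting -----------------------------------------------------------------

#' Fit a spatial-temporal transformer EEG classifier
#'
#' Trains the selected variant on a labeled segment dataset with Adam,
#' minimizing mean cross-entropy plus an L2 penalty on the weight matrices.
#' Dropout is active during training; all reported accuracies use the
#' deterministic eval-mode forward pass. Reproducible given
#' `train_cfg$seed`.
#'
#' @param dataset a `segment_dataset` (see [assemble_dataset()],
#'   [generate_dataset()]).
#' @param variant architecture variant, see [model_config()]; ignored when
#'   `model_cfg` is given.
#' @param model_cfg a [model_config()]; by default one is built from the
#'   dataset geometry and `...`.
#' @param train_cfg a [train_config()].
#' @param ... further arguments to [model_config()] (e.g. `d_model`, `h`,
#'   `dropout`, `conv_kernels`).
#' @return an object of class `sttcnn`: the fitted parameters, both
#'   configurations, and a per-epoch training history. Supports
#'   [predict.sttcnn()], `print`, `summary`, `coef` and `plot`.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(n_channels = 4, sampling_rate = 16, trial_seconds = 6,
#'                        n_classes = 2, spatial_snr = 3, temporal_snr = 3,
#'                        temporal_freqs = c(3, 6))
#' ds <- generate_dataset(spec, n_trials_per_class = 2)
#' fit <- sttcnn_fit(ds, variant = "s-t", d_model = 8, h = 2, conv_kernels = 4,
#'                   train_cfg = train_config(max_epochs = 2, learning_rate = 1e-3))
#' predict(fit, ds, type = "class")
#' }
#' @export
sttcnn_fit <- function(dataset, variant = "st-tcnn", model_cfg = NULL,
                       train_cfg = train_config(), ...) {
  stopifnot(inherits(dataset, "segment_dataset"))
  if (is.null(model_cfg))
    model_cfg <- model_config(variant = variant,
                              n_channels = dim(dataset$x)[2],
                              window_samples = dim(dataset$x)[3],
                              n_classes = dataset$n_classes, ...)
  stopifnot(inherits(model_cfg, "model_config"), inherits(train_cfg, "train_config"))
  n <- n_segments(dataset)
  if (any(dataset$y >= model_cfg$n_classes))
    stopf("dataset labels exceed the configured number of classes")
  params <- init_params(model_cfg, seed = derive_seed(train_cfg$seed, 1))
  pe <- pe_tables(model_cfg)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_accuracy = numeric())
  best_loss <- Inf; stall <- 0L; stopped <- NA_integer_
  with_seed(derive_seed(train_cfg$seed, 2), {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      idx <- sample.int(n)
      ce_sum <- 0
      for (start in seq(1, n, by = train_cfg$batch_size)) {
        batch <- idx[start:min(start + train_cfg$batch_size - 1, n)]
        bn <- length(batch)
        grads <- NULL
        for (i in batch) {
          fw <- model_fwd_sample(dataset$x[i, , ], params, model_cfg, pe, "train")
          yi <- dataset$y[i] + 1L
          ce_sum <- ce_sum - log(max(fw$probs[yi], 1e-300))
          dlog <- fw$probs
          dlog[yi] <- dlog[yi] - 1
          g <- model_bwd_sample(dlog / bn, fw$cache, params, model_cfg)
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        grads <- add_l2_grads(grads, params, train_cfg$l2_lambda)
        st <- adam_step(params, grads, state, train_cfg$learning_rate)
        params <- st$params; state <- st$state
      }
      ep_loss <- ce_sum / n + train_cfg$l2_lambda * l2_sum_weights(params)
      if (!is.finite(ep_loss))
        stopf("training diverged at epoch %d (non-finite loss)", epoch)
      tr_acc <- NA_real_
      if (!is.null(train_cfg$stop_train_accuracy)) {
        pr <- predict_proba(dataset$x, params, model_cfg)
        tr_acc <- mean(max.col(pr, ties.method = "first") - 1L == dataset$y)
      }
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss, tr_acc)
      if (train_cfg$verbose)
        message(sprintf("epoch %3d  loss %.4f%s", epoch, ep_loss,
                        if (is.na(tr_acc)) "" else sprintf("  train acc %.3f", tr_acc)))
      if (!is.na(tr_acc) && tr_acc >= train_cfg$stop_train_accuracy) {
        stopped <- epoch; break
      }
      if (!is.null(train_cfg$early_stop_patience)) {
        if (ep_loss < best_loss - 1e-8) { best_loss <- ep_loss; stall <- 0L }
        else stall <- stall + 1L
        if (stall >= train_cfg$early_stop_patience) { stopped <- epoch; break }
      }
    }
  })
  structure(list(params = params, config = model_cfg, train_config = train_cfg,
                 history = history, n_train = n, task = dataset$task,
                 class_names = dataset$class_names,
                 stopped_epoch = stopped, call = match.call()),
            class = "sttcnn")
}

#' Predict emotion classes for new segments
#'
#' @param object a fitted [sttcnn_fit()] model.
#' @param newdata a `segment_dataset` or an array
#'   `[batch, n_channels, window_samples]`.
#' @param type `"prob"` for the class-probability matrix, `"class"` for
#'   0-based hard class indices, `"label"` for class names.
#' @param ... unused.
#' @return matrix of probabilities, integer vector, or character vector.
#' @export
predict.sttcnn <- function(object, newdata, type = c("prob", "class", "label"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "segment_dataset")) newdata$x else newdata
  P <- predict_proba(x, object$params, object$config)
  if (type == "prob") return(P)
  cls <- max.col(P, ties.method = "first") - 1L
  if (type == "class") cls else object$class_names[cls + 1L]
}

# --- cross-validation --------------------------------------------------------

#' Stratified fold assignment
#'
#' Partitions segments into `k` disjoint, exhaustive folds with per-class
#' counts balanced within one segment. With `grouped = TRUE` all segments of
#' a trial stay in one fold (guarding against temporal autocorrelation
#' between neighboring windows of the same trial).
#'
#' @param dataset a `segment_dataset`.
#' @param k number of folds.
#' @param seed assignment seed.
#' @param grouped keep whole trials together.
#' @return integer vector in `1..k`, one entry per segment.
#' @export
make_folds <- function(dataset, k = 10, seed = 1L, grouped = FALSE) {
  stopifnot(inherits(dataset, "segment_dataset"), k >= 2)
  n <- n_segments(dataset)
  if (n < k) stopf("dataset of %d segments cannot fill %d folds", n, k)
  folds <- integer(n)
  with_seed(derive_seed(seed, 5), {
    if (grouped) {
      key <- paste(dataset$info$subject_id, dataset$info$trial_id)
      trials <- unique(key)
      t_class <- dataset$y[match(trials, key)]
      t_fold <- integer(length(trials))
      for (cl in unique(t_class)) {
        tix <- sample(which(t_class == cl))
        t_fold[tix] <- rep_len(seq_len(k), length(tix))
      }
      folds <- t_fold[match(key, trials)]
    } else {
      for (cl in unique(dataset$y)) {
        cix <- which(dataset$y == cl)
        if (length(cix) < k)
          stopf("class %d has %d segments, fewer than k = %d: stratification impossible",
                cl, length(cix), k)
        folds[sample(cix)] <- rep_len(seq_len(k), length(cix))
      }
    }
  })
  folds
}

#' Train on all folds but one, evaluate on the held-out fold
#'
#' @param dataset a `segment_dataset`.
#' @param folds fold assignment from [make_folds()].
#' @param fold_index fold to hold out.
#' @param model_cfg a [model_config()] (or `NULL` to build from the dataset
#'   and `variant`).
#' @param train_cfg a [train_config()]; the fold trains under a seed derived
#'   from `train_cfg$seed` and `fold_index`.
#' @param variant used when `model_cfg` is `NULL`.
#' @param ... passed to [model_config()] when building it.
#' @return a `fold_result`: held-out accuracy, confusion matrix, training
#'   history, and the fitted model.
#' @export
train_fold <- function(dataset, folds, fold_index, model_cfg = NULL,
                       train_cfg = train_config(), variant = "st-tcnn", ...) {
  stopifnot(length(folds) == n_segments(dataset), fold_index %in% folds)
  test_idx <- which(folds == fold_index)
  train_idx <- which(folds != fold_index)
  tc <- train_cfg
  tc$seed <- derive_seed(train_cfg$seed, 100 + fold_index)
  fit <- sttcnn_fit(dataset_subset(dataset, train_idx), variant = variant,
                    model_cfg = model_cfg, train_cfg = tc, ...)
  test <- dataset_subset(dataset, test_idx)
  pred <- predict(fit, test, type = "class")
  cm <- confusion_matrix(test$y, pred, dataset$n_classes)
  structure(list(fold_index = fold_index,
                 test_accuracy = mean(pred == test$y),
                 confusion = cm, history = fit$history, model = fit,
                 n_test = length(test_idx)),
            class = "fold_result")
}

#' k-fold cross-validation of a variant
#'
#' Runs [train_fold()] for every fold of a stratified partition and pools
#' the results: per-fold accuracies, their mean and (population) variance,
#' the pooled confusion matrix over all held-out predictions, and the full
#' metric report.
#'
#' @inheritParams train_fold
#' @param grouped passed to [make_folds()].
#' @param folds optional precomputed fold assignment; defaults to
#'   [make_folds()] with `train_cfg$k_folds` and `train_cfg$seed`.
#' @return an object of class `sttcnn_cv`.
#' @export
cross_validate <- function(dataset, model_cfg = NULL, train_cfg = train_config(),
                           variant = "st-tcnn", folds = NULL, grouped = FALSE, ...) {
  if (is.null(folds))
    folds <- make_folds(dataset, k = train_cfg$k_folds, seed = train_cfg$seed,
                        grouped = grouped)
  k <- max(folds)
  results <- lapply(seq_len(k), function(i)
    train_fold(dataset, folds, i, model_cfg = model_cfg, train_cfg = train_cfg,
               variant = variant, ...))
  accs <- vapply(results, function(r) r$test_accuracy, 0)
  pooled <- Reduce(`+`, lapply(results, function(r) unclass(r$confusion)))
  class(pooled) <- "confusion_matrix"
  used_variant <- if (!is.null(model_cfg)) model_cfg$variant else variant
  structure(list(fold_results = results, accuracies = accs,
                 mean_accuracy = mean(accs),
                 variance = mean((accs - mean(accs))^2),
                 confusion = pooled, metrics = metrics_from_confusion(pooled),
                 variant = used_variant, task = dataset$task, k = k,
                 folds = folds),
            class = "sttcnn_cv")
}
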