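# Training protocol, stratified split / k-fold cross-validation, MPCE,
# and the three-way model comparison.

#' Training configuration
#'
#' Defaults follow the published protocol: 3,000 full passes over the
#' training set in seeded-shuffled mini-batches of 100, Adam with learning
#' rate 1e-3, categorical cross-entropy on one-hot targets, no early
#' stopping.  `epochs` is routinely lowered for smoke-scale runs.
#'
#' @param epochs full passes over the training data (default 3000).
#' @param batch_size mini-batch size (default 100); the final short batch
#'   of each epoch is used as well.
#' @param seed integer seed driving weight initialization, shuffling and
#'   dropout; a (data, config) pair determines the fit exactly.
#' @param learning_rate Adam step size (default 1e-3).
#' @param standardize_inputs if `TRUE`, features are z-scored with the
#'   training-set mean/sd before entering the network (the same transform
#'   is applied at prediction time).  Default `FALSE`: raw reflectances.
#' @param split_fraction fraction of each class assigned to the training
#'   set by [split_train_test()] (default 0.5).
#' @return object of class `training_config`.
#' @export
training_config <- function(epochs = 3000L, batch_size = 100L, seed = 1L,
                            learning_rate = 1e-3,
                            standardize_inputs = FALSE,
                            split_fraction = 0.5) {
  stopifnot(is_count(epochs, 1L), is_count(batch_size, 1L),
            learning_rate > 0, split_fraction > 0, split_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 learning_rate = learning_rate,
                 standardize_inputs = isTRUE(standardize_inputs),
                 split_fraction = split_fraction),
            class = "training_config")
}

#' Stratified train/test split
#'
#' Splits each class separately so both partitions keep the global class
#' balance; `ceiling(fraction * n_class)` pixels of each class go to the
#' training set (rounding toward train).  Reproducible given `seed`.
#'
#' @param ds a [spectral_dataset()] containing both classes.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `spectral_dataset` elements `train` and `test`; the
#'   two are disjoint and their union is `ds`.
#' @export
split_train_test <- function(ds, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"), fraction > 0, fraction < 1)
  cc <- class_counts(ds)
  if (any(cc < 2L))
    stop("both classes need at least 2 pixels for a stratified split",
         call. = FALSE)
  train_idx <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(ds$label == cl)
      sample(idx, ceiling(fraction * length(idx)))
    }))
  })
  train_idx <- sort(train_idx)
  reclass <- function(df) structure(df, band_wavelengths = SARG_WAVELENGTHS,
                                    class = c("spectral_dataset",
                                              "data.frame"))
  df <- as.data.frame(ds)
  list(train = reclass(df[train_idx, , drop = FALSE]),
       test = reclass(df[-train_idx, , drop = FALSE]))
}

fit_scaling <- function(x, enabled) {
  if (!enabled) return(NULL)
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  list(mean = mu, sd = sd_)
}

apply_scaling <- function(scaling, x) {
  if (is.null(scaling)) return(x)
  sweep(sweep(x, 2L, scaling$mean), 2L, scaling$sd, "/")
}

# Core training loop on raw matrices.  Returns the trained layer list and
# per-epoch train/test accuracy curves (evaluation mode, so batch norm uses
# running statistics and dropout is off).
nn_train <- function(model, xtr, ytr, xte, yte, config) {
  layers <- model$layers
  state <- adam_init(layers)
  ntr <- nrow(xtr)
  bs <- config$batch_size
  curves <- data.frame(epoch = seq_len(config$epochs),
                       train_accuracy = NA_real_, test_accuracy = NA_real_)
  step <- 0L
  eval_acc <- function(lys, x, y) {
    m2 <- model; m2$layers <- lys
    p <- softmax_rows(model_forward(m2, x, training = FALSE)$logits)
    mean(hard_calls(p) == y)
  }
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(ntr)
      starts <- seq(1L, ntr, by = bs)
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + bs - 1L, ntr)]
        m2 <- model; m2$layers <- layers
        fw <- model_forward(m2, xtr[idx, , drop = FALSE], training = TRUE)
        layers <- fw$layers                    # batch-norm running stats
        loss <- softmax_xent(fw$logits, ytr[idx])
        total <- loss$loss + l2_penalty(layers)
        if (!is.finite(total))
          stop(sprintf("non-finite training loss at epoch %d, batch %d",
                       epoch, bi), call. = FALSE)
        grads <- model_backward(layers, fw$caches, loss$dlogits)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, step,
                         lr = config$learning_rate)
        layers <- upd$layers
        state <- upd$state
      }
      curves$train_accuracy[epoch] <- eval_acc(layers, xtr, ytr)
      curves$test_accuracy[epoch] <- eval_acc(layers, xte, yte)
    }
  })
  model$layers <- layers
  list(model = model, curves = curves)
}

#' Fit a Sargassum classifier
#'
#' The single entry point for training: builds the requested architecture,
#' runs the mini-batch protocol, and returns a classed fit with the
#' learning curves.  When `test` is omitted the data are split with
#' [split_train_test()] using `config$split_fraction` and `config$seed`.
#'
#' @param spec an `arch_spec`, or a model name (`"erisnet"`, `"mlp"`,
#'   `"fcn"`).
#' @param data training [spectral_dataset()] (or the full table if `test`
#'   is `NULL`).
#' @param test held-out [spectral_dataset()], or `NULL` to split `data`.
#' @param config a [training_config()].
#' @return object of class `sarg_fit`: the trained model, per-epoch
#'   `curves` (train/test accuracy), the config, and the final/best test
#'   accuracies.  Methods: `print`, `summary`, `predict`, `plot`.
#' @examples
#' ds <- simulate_pixels(sim_config(seed = 1, n_per_class = 60))
#' fit <- sarg_fit("mlp", ds, config = training_config(epochs = 5,
#'                 batch_size = 30, seed = 1))
#' predict(fit, ds[1:3, ])
#' @export
sarg_fit <- function(spec, data, test = NULL,
                     config = training_config()) {
  if (is.character(spec)) spec <- arch_spec(spec)
  stopifnot(inherits(spec, "arch_spec"),
            inherits(data, "spectral_dataset"),
            inherits(config, "training_config"))
  if (is.null(test)) {
    parts <- split_train_test(data, config$split_fraction, config$seed)
    data <- parts$train; test <- parts$test
  }
  xtr <- features(data); xte <- features(test)
  scaling <- fit_scaling(xtr, config$standardize_inputs)
  xtr <- apply_scaling(scaling, xtr); xte <- apply_scaling(scaling, xte)
  model <- build_model(spec, config$seed)
  run <- nn_train(model, xtr, data$label, xte, test$label, config)
  final <- run$curves[nrow(run$curves), ]
  structure(list(spec = spec, model = run$model, curves = run$curves,
                 config = config, scaling = scaling,
                 n_train = nrow(data), n_test = nrow(test),
                 test_accuracy = final$test_accuracy,
                 train_accuracy = final$train_accuracy,
                 best_test_accuracy = max(run$curves$test_accuracy)),
            class = "sarg_fit")
}

#' @export
print.sarg_fit <- function(x, ...) {
  cat(sprintf(
    "<sarg_fit> %s: %d epochs x batch %d on %d train / %d test pixels\n",
    x$spec$name, x$config$epochs, x$config$batch_size, x$n_train, x$n_test))
  cat(sprintf("  final train accuracy %.4f | final test accuracy %.4f (best %.4f)\n",
              x$train_accuracy, x$test_accuracy, x$best_test_accuracy))
  invisible(x)
}

#' @export
summary.sarg_fit <- function(object, ...) {
  print(object)
  cat("  architecture:\n")
  print(object$spec)
  invisible(object)
}

#' @export
#' @param type `"prob"` for class probabilities, `"class"` for hard 0/1
#'   calls (ties at 0.5 go to class 0).
#' @rdname sarg_fit
predict.sarg_fit <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else hard_calls(p)
}

#' @export
plot.sarg_fit <- function(x, ...) {
  graphics::plot(x$curves$epoch, x$curves$train_accuracy, type = "l",
                 ylim = range(c(x$curves$train_accuracy,
                                x$curves$test_accuracy)),
                 xlab = "epoch", ylab = "accuracy",
                 main = sprintf("%s learning curves", x$spec$name), ...)
  graphics::lines(x$curves$epoch, x$curves$test_accuracy, lty = 2)
  graphics::legend("bottomright", legend = c("train", "test"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Classification accuracy on a held-out set
#'
#' Fraction of pixels whose predicted class (argmax probability, ties at
#' 0.5 to class 0) equals the label.
#'
#' @param object a `sarg_fit` or `sargnet_model`.
#' @param test a non-empty [spectral_dataset()].
#' @return accuracy in [0, 1].
#' @export
evaluate_accuracy <- function(object, test) {
  if (nrow(test) == 0L) stop_nodata("empty test set: no accuracy to compute")
  mean(hard_calls(predict_proba(object, test)) == test$label)
}

#' Mean per-class error statistic over cross-validation folds
#'
#' The arithmetic mean over folds of the per-fold fraction correct,
#' `MPCE = (1/k) * sum_i e_i / c_i`, where `e_i` is the number of
#' correctly classified pixels in fold i and `c_i` the fold size.
#'
#' @param per_fold_correct integer vector of correct counts, one per fold.
#' @param per_fold_total integer vector of fold sizes (all positive).
#' @return MPCE in [0, 1].
#' @export
mpce <- function(per_fold_correct, per_fold_total) {
  stopifnot(length(per_fold_correct) == length(per_fold_total),
            length(per_fold_total) >= 1L)
  if (any(per_fold_total <= 0))
    stop("every fold must have a positive size", call. = FALSE)
  if (any(per_fold_correct < 0) || any(per_fold_correct > per_fold_total))
    stop("correct counts must lie in [0, fold size]", call. = FALSE)
  mean(per_fold_correct / per_fold_total)
}

# Seeded stratified fold assignment: within each class, shuffled indices
# are dealt into k near-equal groups; each class's remainder pixels go to
# the folds with the smallest running totals, so overall fold sizes differ
# by at most one.
make_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    totals <- integer(k)
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      q <- length(idx) %/% k
      r <- length(idx) %% k
      sizes <- rep(q, k)
      if (r > 0) {
        extra <- order(totals, seq_len(k))[seq_len(r)]
        sizes[extra] <- sizes[extra] + 1L
      }
      stops <- cumsum(sizes)
      starts <- c(1L, utils::head(stops, -1L) + 1L)
      for (f in seq_len(k))
        if (sizes[f] > 0) fold[idx[starts[f]:stops[f]]] <- f
      totals <- totals + sizes
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions the data into k stratified folds, trains a freshly built
#' model on each k-1 complement, evaluates on the held-out fold, and
#' aggregates with [mpce()].  Fold f uses seed `config$seed + f` for its
#' build and training so folds are independent but the whole procedure is
#' reproducible.
#'
#' @param spec an `arch_spec` or model name.
#' @param ds a [spectral_dataset()]; each class must have at least k
#'   pixels.
#' @param k number of folds (default 5).
#' @param config a [training_config()].
#' @return object of class `cv_result`: `k`, `fold` assignment,
#'   `per_fold_correct` (e_i), `per_fold_total` (c_i),
#'   `per_fold_accuracy`, and `mpce`.
#' @export
kfold_cv <- function(spec, ds, k = 5L, config = training_config()) {
  if (is.character(spec)) spec <- arch_spec(spec)
  stopifnot(inherits(ds, "spectral_dataset"), is_count(k, 2L))
  cc <- class_counts(ds)
  if (any(cc < k))
    stop(sprintf("each class needs at least k = %d pixels (have %d / %d)",
                 k, cc[["n_with"]], cc[["n_without"]]), call. = FALSE)
  fold <- make_folds(ds$label, k, config$seed)
  correct <- integer(k); total <- integer(k)
  df <- as.data.frame(ds)
  reclass <- function(d) structure(d, band_wavelengths = SARG_WAVELENGTHS,
                                   class = c("spectral_dataset",
                                             "data.frame"))
  for (f in seq_len(k)) {
    cfg <- config; cfg$seed <- config$seed + f
    fit <- sarg_fit(spec, reclass(df[fold != f, , drop = FALSE]),
                    test = reclass(df[fold == f, , drop = FALSE]),
                    config = cfg)
    total[f] <- sum(fold == f)
    correct[f] <- round(fit$test_accuracy * total[f])
  }
  structure(list(k = as.integer(k), fold = fold,
                 per_fold_correct = correct, per_fold_total = total,
                 per_fold_accuracy = correct / total,
                 mpce = mpce(correct, total),
                 spec_name = spec$name, seed = config$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold stratified CV (seed %d)\n",
              x$spec_name, x$k, x$seed))
  cat("  fold accuracies:",
      paste(sprintf("%.4f", x$per_fold_accuracy), collapse = " "), "\n")
  cat(sprintf("  MPCE = %.4f\n", x$mpce))
  invisible(x)
}

#' Three-way model comparison
#'
#' Runs the published evaluation protocol for each requested model: the
#' MLP and FCN baselines with the 50/50 stratified split, ERISNet with
#' k-fold cross-validation (`protocol = "paper"`, the default).  Setting
#' `protocol` to `"split"` or `"kfold"` runs every model under that single
#' protocol for a like-for-like comparison.  All models share `config`
#' (and hence the seed).
#'
#' @param ds a [spectral_dataset()].
#' @param config a [training_config()].
#' @param models subset of `c("mlp", "fcn", "erisnet")`.
#' @param protocol `"paper"`, `"split"` or `"kfold"`.
#' @param k folds for the cross-validated models (default 5).
#' @return object of class `model_comparison`: a results data.frame
#'   (model, protocol, accuracy, best_accuracy) plus the per-model curves
#'   or CV results.
#' @export
compare_models <- function(ds, config = training_config(),
                           models = c("mlp", "fcn", "erisnet"),
                           protocol = c("paper", "split", "kfold"),
                           k = 5L) {
  protocol <- match.arg(protocol)
  models <- match.arg(models, c("mlp", "fcn", "erisnet"),
                      several.ok = TRUE)
  rows <- list(); details <- list()
  for (m in models) {
    use_kfold <- switch(protocol, paper = (m == "erisnet"),
                        split = FALSE, kfold = TRUE)
    if (use_kfold) {
      cv <- kfold_cv(m, ds, k = k, config = config)
      details[[m]] <- cv
      rows[[m]] <- data.frame(model = m, protocol = sprintf("%d-fold", k),
                              accuracy = cv$mpce,
                              best_accuracy = max(cv$per_fold_accuracy))
    } else {
      fit <- sarg_fit(m, ds, config = config)
      details[[m]] <- fit
      rows[[m]] <- data.frame(model = m, protocol = "50/50 split",
                              accuracy = fit$test_accuracy,
                              best_accuracy = fit$best_test_accuracy)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, details = details, seed = config$seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (seed", x$seed, ")\n")
  tab <- x$table
  tab$accuracy <- round(tab$accuracy, digits)
  tab$best_accuracy <- round(tab$best_accuracy, digits)
  print(tab, row.names = FALSE)
  if (nrow(x$table) > 1L) {
    cat("Pairwise accuracy deltas (row - column, percentage points):\n")
    acc <- x$table$accuracy
    d <- outer(acc, acc, "-") * 100
    dimnames(d) <- list(x$table$model, x$table$model)
    print(round(d, 2))
  }
  invisible(x)
}
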