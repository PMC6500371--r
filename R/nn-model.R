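# Turning an arch_spec into a trainable model and running its forward pass.

#' Build a trainable model from an architecture spec
#'
#' Instantiates weights for an [erisnet_spec()], [mlp_spec()] or
#' [fcn_spec()].  Dense and convolution kernels use Glorot-uniform
#' initialization, LSTM recurrent kernels are orthogonal with the forget
#' gate biased open; construction is a pure function of `seed`, so the
#' same seed always yields the same initial weights (and therefore the
#' same untrained predictions).
#'
#' @param spec an `arch_spec`.
#' @param seed integer seed for weight initialization.
#' @return object of class `sargnet_model`.
#' @seealso [predict_proba()], [sarg_fit()]
#' @export
build_model <- function(spec, seed) {
  stopifnot(inherits(spec, "arch_spec"))
  L <- spec$input_layout[1]; ch <- spec$input_layout[2]
  sequence_model <- length(spec$conv_blocks) + length(spec$recurrent_blocks) >
    0L || spec$global_pool
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  with_seed(seed, {
    for (cb in spec$conv_blocks) {
      add(layer_conv1d(L, ch, cb$n_filters, cb$kernel_size, l2 = cb$l2))
      if (spec$conv_order == "conv_relu_bn_drop") {
        add(layer_relu())
        if (cb$batch_norm) add(layer_bn(cb$n_filters))
        if (cb$dropout_rate > 0) add(layer_dropout(cb$dropout_rate))
      } else {                               # conv -> BN -> ReLU
        if (cb$batch_norm) add(layer_bn(cb$n_filters))
        add(layer_relu())
        if (cb$dropout_rate > 0) add(layer_dropout(cb$dropout_rate))
      }
      ch <- cb$n_filters
    }
    for (rb in spec$recurrent_blocks) {
      add(layer_lstm(ch, rb$n_units, rb$return_sequences))
      if (rb$batch_norm) add(layer_bn(rb$n_units))
      ch <- rb$n_units
    }
    if (spec$global_pool) add(layer_gap())
    width <- if (sequence_model) ch else {
      add(layer_flatten())
      prod(spec$input_layout)
    }
    nd <- length(spec$dense_blocks)
    for (i in seq_len(nd)) {
      db <- spec$dense_blocks[[i]]
      add(layer_dense(width, db$n_units))
      if (db$activation == "relu") add(layer_relu())
      if (db$dropout_rate > 0) add(layer_dropout(db$dropout_rate))
      width <- db$n_units
    }
  })
  structure(list(spec = spec, layers = layers, seed = as.integer(seed),
                 needs_sequence = sequence_model),
            class = "sargnet_model")
}

# Reshape an [n, 14] feature matrix to the spec's input layout.  Columns
# are already ordered [rhos 412..2130, rhot 412..2130], so a plain dim
# change yields (14, 1) as one signal and (7, 2) as rhos/rhot channels.
shape_input <- function(model, x) {
  x <- as.matrix(x)
  lay <- model$spec$input_layout
  if (ncol(x) != prod(lay))
    stop(sprintf("feature width %d does not match input layout %d x %d",
                 ncol(x), lay[1], lay[2]), call. = FALSE)
  if (model$needs_sequence) dim(x) <- c(nrow(x), lay[1], lay[2])
  x
}

# Full forward pass; returns logits, per-layer caches, and the layer list
# with updated batch-norm running statistics.
model_forward <- function(model, x, training = FALSE) {
  layers <- model$layers
  caches <- vector("list", length(layers))
  h <- shape_input(model, x)
  for (i in seq_along(layers)) {
    fw <- nn_forward(layers[[i]], h, training)
    h <- fw$y
    caches[[i]] <- fw$cache
    layers[[i]] <- fw$layer
  }
  list(logits = h, caches = caches, layers = layers)
}

model_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  d <- dlogits
  for (i in rev(seq_along(layers))) {
    bw <- nn_backward(layers[[i]], caches[[i]], d)
    d <- bw$dx
    grads[[i]] <- bw$grads
  }
  grads
}

#' Class probabilities for a batch of pixels
#'
#' Runs the model in evaluation mode (dropout off, batch normalization on
#' its running statistics), so repeated calls on the same inputs are
#' identical.
#'
#' @param model a `sargnet_model` (or a fitted [sarg_fit()] object, whose
#'   input standardization is then applied).
#' @param x an `[n, 14]` feature matrix, or a [spectral_dataset()].
#' @return `[n, 2]` matrix of class probabilities, columns
#'   `p_without`, `p_with`; rows sum to 1.
#' @export
predict_proba <- function(model, x) {
  if (inherits(model, "sarg_fit")) {
    x <- apply_scaling(model$scaling, if (inherits(x, "spectral_dataset"))
      features(x) else as.matrix(x))
    model <- model$model
  } else if (inherits(x, "spectral_dataset")) x <- features(x)
  stopifnot(inherits(model, "sargnet_model"))
  p <- softmax_rows(model_forward(model, x, training = FALSE)$logits)
  colnames(p) <- c("p_without", "p_with")
  p
}

# Hard 0/1 calls from probabilities; a tie at exactly 0.5 goes to class 0.
hard_calls <- function(prob) as.integer(prob[, 2L] > 0.5)

#' @export
count_params.sargnet_model <- function(x, ...) {
  as.integer(sum(vapply(x$layers, function(l)
    sum(vapply(l$params, length, numeric(1))), numeric(1))))
}

#' @export
print.sargnet_model <- function(x, ...) {
  cat(sprintf("<sargnet_model> %s, %s trainable parameters (seed %d)\n",
              x$spec$name, format(count_params(x), big.mark = ","), x$seed))
  invisible(x)
}
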