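# Declarative classifier architectures: ERISNet and its two baselines.
# A spec is pure data (verifiable structure, serializable to YAML/JSON);
# build_model() turns it into trainable weights.

conv_block <- function(n_filters, kernel_size, dropout_rate = 0,
                       l2 = 0, batch_norm = TRUE) {
  stopifnot(is_count(n_filters, 1L), is_count(kernel_size, 1L),
            dropout_rate >= 0, dropout_rate < 1, l2 >= 0)
  list(n_filters = as.integer(n_filters),
       kernel_size = as.integer(kernel_size),
       activation = "relu", batch_norm = batch_norm,
       dropout_rate = dropout_rate, l2 = l2)
}

recurrent_block <- function(n_units = 64L, return_sequences = FALSE,
                            batch_norm = TRUE) {
  stopifnot(is_count(n_units, 1L))
  list(n_units = as.integer(n_units), batch_norm = batch_norm,
       return_sequences = return_sequences)
}

dense_block <- function(n_units, activation = c("relu", "softmax"),
                        dropout_rate = 0) {
  activation <- match.arg(activation)
  stopifnot(is_count(n_units, 1L), dropout_rate >= 0, dropout_rate < 1)
  list(n_units = as.integer(n_units), activation = activation,
       dropout_rate = dropout_rate)
}

check_layout <- function(input_layout) {
  input_layout <- as.integer(input_layout)
  if (!(length(input_layout) == 2L &&
        (all(input_layout == c(14L, 1L)) || all(input_layout == c(7L, 2L)))))
    stop("unsupported input layout: must be c(14, 1) or c(7, 2)",
         call. = FALSE)
  input_layout
}

new_arch_spec <- function(name, input_layout, conv_blocks = list(),
                          recurrent_blocks = list(), dense_blocks = list(),
                          conv_order = c("conv_relu_bn_drop", "conv_bn_relu"),
                          global_pool = FALSE) {
  conv_order <- match.arg(conv_order)
  head <- dense_blocks[[length(dense_blocks)]]
  if (head$activation != "softmax" || head$n_units != 2L)
    stop("final dense block must be a 2-unit softmax head", call. = FALSE)
  structure(list(name = name, input_layout = input_layout,
                 conv_blocks = conv_blocks,
                 recurrent_blocks = recurrent_blocks,
                 dense_blocks = dense_blocks,
                 conv_order = conv_order, global_pool = global_pool),
            class = "arch_spec")
}

#' ERISNet architecture specification
#'
#' The convolutional-recurrent Sargassum classifier: nine 1D convolutional
#' blocks whose (filters, kernel) sequence repeats the motif
#' (64,8), (128,5), (128,3) three times, each block being
#' convolution -> ReLU -> batch normalization -> dropout with an L2 weight
#' penalty on the kernel; then two 64-unit LSTM blocks (the first emitting
#' its full output sequence, the second only its final state), each
#' followed by batch normalization; then a single 2-unit softmax
#' classification block.  Same-length padding keeps the sequence axis
#' alive through all nine blocks.
#'
#' @param input_layout `c(14, 1)` (default: the 14 attributes as one
#'   signal, ordered rhos 412..2130 then rhot 412..2130) or `c(7, 2)`
#'   (7 wavelengths, rhos/rhot as two channels).
#' @param dropout_rate dropout inside each conv block (default 0.2).
#' @param l2 L2 penalty coefficient on conv kernels (default 1e-3).
#' @return an `arch_spec`.
#' @seealso [mlp_spec()], [fcn_spec()], [build_model()], [count_params()]
#' @export
erisnet_spec <- function(input_layout = c(14, 1), dropout_rate = 0.2,
                         l2 = 1e-3) {
  input_layout <- check_layout(input_layout)
  motif <- list(c(64L, 8L), c(128L, 5L), c(128L, 3L))
  convs <- lapply(rep(motif, 3L), function(fk)
    conv_block(fk[1], fk[2], dropout_rate = dropout_rate, l2 = l2))
  new_arch_spec(
    name = "erisnet", input_layout = input_layout, conv_blocks = convs,
    recurrent_blocks = list(recurrent_block(64L, return_sequences = TRUE),
                            recurrent_block(64L, return_sequences = FALSE)),
    dense_blocks = list(dense_block(2L, "softmax")),
    conv_order = "conv_relu_bn_drop")
}

#' Multilayer perceptron baseline specification
#'
#' Three 500-unit ReLU hidden layers with dropout rates 0.2, 0.2, 0.3 at
#' the end of each, then a 2-unit softmax head, on the flat 14-feature
#' input.  Trainable parameter count: 509,502.
#'
#' @return an `arch_spec`.
#' @export
mlp_spec <- function() {
  new_arch_spec(
    name = "mlp", input_layout = c(14L, 1L),
    dense_blocks = list(dense_block(500L, "relu", 0.2),
                        dense_block(500L, "relu", 0.2),
                        dense_block(500L, "relu", 0.3),
                        dense_block(2L, "softmax")))
}

#' Fully convolutional network baseline specification
#'
#' Three 1D conv blocks of (128, 8), (256, 5), (128, 3)
#' (convolution -> batch normalization -> ReLU), global average pooling
#' over the sequence axis, and a 2-unit softmax head.
#'
#' @inheritParams erisnet_spec
#' @return an `arch_spec`.
#' @export
fcn_spec <- function(input_layout = c(14, 1)) {
  input_layout <- check_layout(input_layout)
  new_arch_spec(
    name = "fcn", input_layout = input_layout,
    conv_blocks = list(conv_block(128L, 8L), conv_block(256L, 5L),
                       conv_block(128L, 3L)),
    dense_blocks = list(dense_block(2L, "softmax")),
    conv_order = "conv_bn_relu", global_pool = TRUE)
}

#' Architecture spec for a model by name
#' @param model `"erisnet"`, `"mlp"` or `"fcn"`.
#' @param input_layout passed to the conv architectures.
#' @return an `arch_spec`.
#' @export
arch_spec <- function(model = c("erisnet", "mlp", "fcn"),
                      input_layout = c(14, 1)) {
  switch(match.arg(model),
         erisnet = erisnet_spec(input_layout),
         mlp = mlp_spec(),
         fcn = fcn_spec(input_layout))
}

#' Trainable parameter count of an architecture
#'
#' Closed-form count over the block list: a conv block contributes
#' `(kernel * in_channels + 1) * filters` plus `2 * filters` for batch
#' normalization; an LSTM block `4 * (in + units + 1) * units` plus
#' `2 * units` for its batch normalization; a dense block
#' `(in + 1) * units`.  Batch-norm running statistics are not trainable
#' and are not counted.
#'
#' @param x an `arch_spec` or a built `sargnet_model`.
#' @param ... unused.
#' @return integer parameter count.
#' @export
count_params <- function(x, ...) UseMethod("count_params")

#' @export
count_params.arch_spec <- function(x, ...) {
  total <- 0L
  ch <- x$input_layout[2]
  for (cb in x$conv_blocks) {
    total <- total + (cb$kernel_size * ch + 1L) * cb$n_filters
    if (cb$batch_norm) total <- total + 2L * cb$n_filters
    ch <- cb$n_filters
  }
  for (rb in x$recurrent_blocks) {
    total <- total + 4L * (ch + rb$n_units + 1L) * rb$n_units
    if (rb$batch_norm) total <- total + 2L * rb$n_units
    ch <- rb$n_units
  }
  width <- if (length(x$conv_blocks) + length(x$recurrent_blocks) == 0L)
    prod(x$input_layout) else ch   # flat input for pure-dense nets
  for (db in x$dense_blocks) {
    total <- total + (width + 1L) * db$n_units
    width <- db$n_units
  }
  as.integer(total)
}

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec> %s  (input %d x %d)\n", x$name,
              x$input_layout[1], x$input_layout[2]))
  i <- 0L
  for (cb in x$conv_blocks) {
    i <- i + 1L
    cat(sprintf("  conv%-2d  %3d filters x %d  [%s%s%s]\n", i,
                cb$n_filters, cb$kernel_size,
                if (x$conv_order == "conv_relu_bn_drop") "relu,bn" else "bn,relu",
                if (cb$dropout_rate > 0)
                  sprintf(",drop %.2g", cb$dropout_rate) else "",
                if (cb$l2 > 0) sprintf(",l2 %.2g", cb$l2) else ""))
  }
  for (rb in x$recurrent_blocks)
    cat(sprintf("  lstm    %3d units%s%s\n", rb$n_units,
                if (rb$return_sequences) " (sequence)" else " (last state)",
                if (rb$batch_norm) " [bn]" else ""))
  for (db in x$dense_blocks)
    cat(sprintf("  dense   %3d units [%s%s]\n", db$n_units, db$activation,
                if (db$dropout_rate > 0)
                  sprintf(",drop %.2g", db$dropout_rate) else ""))
  if (x$global_pool) cat("  global average pooling before head\n")
  cat(sprintf("  trainable parameters: %s\n",
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Serialize / restore an architecture spec
#'
#' Specs are pure data; these helpers write and read them as YAML so a run
#' configuration can be archived alongside its results.
#'
#' @param spec an `arch_spec`.
#' @param path file path.
#' @return `write_arch_spec()` returns `path` invisibly;
#'   `read_arch_spec()` returns an `arch_spec`.
#' @export
write_arch_spec <- function(spec, path) {
  stopifnot(inherits(spec, "arch_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_arch_spec
#' @export
read_arch_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  new_arch_spec(name = raw$name,
                input_layout = check_layout(unlist(raw$input_layout)),
                conv_blocks = raw$conv_blocks,
                recurrent_blocks = raw$recurrent_blocks,
                dense_blocks = raw$dense_blocks,
                conv_order = raw$conv_order,
                global_pool = isTRUE(raw$global_pool))
}
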