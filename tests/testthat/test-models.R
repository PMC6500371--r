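# Architecture specs and built models: structure, parameter counts,
# probability contracts, reproducibility.

test_that("ERISNet spec repeats the (64,8),(128,5),(128,3) motif thrice", {
  s <- erisnet_spec()
  expect_length(s$conv_blocks, 9L)
  expect_length(s$recurrent_blocks, 2L)
  expect_length(s$dense_blocks, 1L)
  filters <- vapply(s$conv_blocks, `[[`, integer(1), "n_filters")
  kernels <- vapply(s$conv_blocks, `[[`, integer(1), "kernel_size")
  expect_equal(filters, rep(c(64L, 128L, 128L), 3L))
  expect_equal(kernels, rep(c(8L, 5L, 3L), 3L))
  expect_equal(sum(filters[1:3]), 320L)
  expect_true(all(vapply(s$conv_blocks, `[[`, logical(1), "batch_norm")))
  expect_true(all(vapply(s$conv_blocks, `[[`, numeric(1),
                         "dropout_rate") > 0))
  expect_true(all(vapply(s$conv_blocks, `[[`, numeric(1), "l2") > 0))
  expect_true(s$recurrent_blocks[[1]]$return_sequences)
  expect_false(s$recurrent_blocks[[2]]$return_sequences)
  expect_equal(s$recurrent_blocks[[1]]$n_units, 64L)
  head <- s$dense_blocks[[1]]
  expect_equal(c(head$n_units, head$activation), c("2", "softmax"))
})

test_that("MLP spec: 3 x 500 hidden, dropout (0.2, 0.2, 0.3), softmax head", {
  s <- mlp_spec()
  expect_length(s$conv_blocks, 0L)
  expect_length(s$recurrent_blocks, 0L)
  widths <- vapply(s$dense_blocks, `[[`, integer(1), "n_units")
  drops <- vapply(s$dense_blocks, `[[`, numeric(1), "dropout_rate")
  expect_equal(widths, c(500L, 500L, 500L, 2L))
  expect_equal(drops[1:3], c(0.2, 0.2, 0.3))
  expect_equal(s$dense_blocks[[4]]$activation, "softmax")
})

test_that("FCN spec: (128,8),(256,5),(128,3), conv->BN->ReLU, pooled head", {
  s <- fcn_spec()
  expect_equal(vapply(s$conv_blocks, `[[`, integer(1), "n_filters"),
               c(128L, 256L, 128L))
  expect_equal(vapply(s$conv_blocks, `[[`, integer(1), "kernel_size"),
               c(8L, 5L, 3L))
  expect_equal(s$conv_order, "conv_bn_relu")
  expect_true(s$global_pool)
  # pooled feature width = last block's filter count feeds the head
  m <- build_model(s, 1)
  dense <- Filter(function(l) l$type == "dense", m$layers)[[1]]
  expect_equal(dense$c_in, 128L)
})

test_that("parameter counts match closed-form layer formulas", {
  # MLP: sum over (fan_in + 1) * fan_out for 14 -> 500 -> 500 -> 500 -> 2
  dims <- c(14, 500, 500, 500, 2)
  mlp_count <- 0
  for (i in 1:4) mlp_count <- mlp_count + (dims[i] + 1) * dims[i + 1]
  expect_equal(mlp_count, 509502)
  expect_equal(count_params(mlp_spec()), 509502L)
  expect_equal(count_params(build_model(mlp_spec(), 3)), 509502L)

  # FCN (14,1): conv (k*c_in+1)*f + 2f batch norm; dense (128+1)*2
  fcn_count <- (8 * 1 + 1) * 128 + 2 * 128 +
    (5 * 128 + 1) * 256 + 2 * 256 +
    (3 * 256 + 1) * 128 + 2 * 128 +
    129 * 2
  expect_equal(count_params(fcn_spec()), fcn_count)
  expect_equal(count_params(build_model(fcn_spec(), 3)), fcn_count)

  # ERISNet (14,1): nine conv blocks, two LSTMs 4*(in+H+1)*H with their
  # batch norms, dense head
  chans <- c(1, rep(c(64, 128, 128), 3))
  fk <- rep(c(8, 5, 3), 3)
  eris_count <- 0
  for (i in 1:9)
    eris_count <- eris_count + (fk[i] * chans[i] + 1) * chans[i + 1] +
      2 * chans[i + 1]
  eris_count <- eris_count + 4 * (128 + 64 + 1) * 64 + 2 * 64 +
    4 * (64 + 64 + 1) * 64 + 2 * 64 + (64 + 1) * 2
  expect_equal(count_params(erisnet_spec()), eris_count)
  expect_equal(count_params(build_model(erisnet_spec(), 3)), eris_count)
})

test_that("softmax rows sum to 1 for all architectures and layouts", {
  ds <- simulate_pixels(sim_config(seed = 10, n_per_class = 8))
  for (nm in c("mlp", "fcn", "erisnet"))
    for (lay in list(c(14, 1), c(7, 2))) {
      if (nm == "mlp" && !all(lay == c(14, 1))) next
      m <- build_model(arch_spec(nm, input_layout = lay), 5)
      p <- predict_proba(m, ds)
      expect_equal(dim(p), c(16L, 2L))
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(rowSums(p), rep(1, 16), tolerance = 1e-6)
    }
  expect_error(erisnet_spec(input_layout = c(5, 3)), "layout")
  expect_error(fcn_spec(input_layout = c(14, 2)), "layout")
})

test_that("same seed -> identical model; different seed -> different", {
  ds <- simulate_pixels(sim_config(seed = 11, n_per_class = 6))
  for (nm in c("mlp", "fcn", "erisnet")) {
    spec <- arch_spec(nm)
    p1 <- predict_proba(build_model(spec, 7), ds)
    p2 <- predict_proba(build_model(spec, 7), ds)
    p3 <- predict_proba(build_model(spec, 8), ds)
    expect_identical(p1, p2)
    expect_false(isTRUE(all.equal(p1, p3)))
  }
})

test_that("evaluation is deterministic; training-mode dropout is not", {
  ds <- simulate_pixels(sim_config(seed = 12, n_per_class = 10))
  m <- build_model(erisnet_spec(), 9)
  x <- as.matrix(as.data.frame(ds)[, sargnet:::feature_cols()])
  e1 <- predict_proba(m, x)
  e2 <- predict_proba(m, x)
  expect_identical(e1, e2)
  # identical input rows give identical probability rows
  x2 <- rbind(x[1, ], x[1, ])
  pp <- predict_proba(m, x2)
  expect_equal(pp[1, ], pp[2, ])
  # stochastic forward passes under dropout differ between draws
  set.seed(1)
  t1 <- sargnet:::model_forward(m, x, training = TRUE)$logits
  t2 <- sargnet:::model_forward(m, x, training = TRUE)$logits
  expect_false(isTRUE(all.equal(t1, t2)))
  # feature-width mismatch is a shape error
  expect_error(predict_proba(m, x[, 1:7]), "width")
})

test_that("hard predictions are the argmax of the probabilities", {
  ds <- simulate_pixels(sim_config(seed = 13, n_per_class = 10))
  m <- build_model(mlp_spec(), 2)
  p <- predict_proba(m, ds)
  expect_identical(sargnet:::hard_calls(p),
                   as.integer(apply(p, 1, which.max) - 1L))
})

test_that("specs survive a YAML round trip", {
  path <- tempfile(fileext = ".yaml")
  s <- erisnet_spec()
  write_arch_spec(s, path)
  s2 <- read_arch_spec(path)
  expect_equal(count_params(s2), count_params(s))
  expect_equal(s2$name, "erisnet")
  expect_length(s2$conv_blocks, 9L)
})
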