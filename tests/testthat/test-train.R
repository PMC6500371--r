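# Training protocol, stratified split / k-fold machinery, MPCE.

test_that("stratified split reproduces the per-class ceiling arithmetic", {
  ds <- spectral_dataset(raw_pixel_df(2306, 2209))
  parts <- split_train_test(ds, 0.5, seed = 1)
  expect_equal(nrow(parts$train), 2258L)   # ceil(1153) + ceil(1104.5)
  expect_equal(nrow(parts$test), 2257L)
  expect_equal(unname(class_counts(parts$train)), c(1153L, 1105L))
  # disjoint, exhaustive, conservation of class counts
  expect_equal(unname(class_counts(parts$train) + class_counts(parts$test)),
               unname(class_counts(ds)))
  expect_equal(nrow(parts$train) + nrow(parts$test), nrow(ds))
  # reproducible given the seed; different seeds differ
  parts2 <- split_train_test(ds, 0.5, seed = 1)
  expect_identical(parts$train, parts2$train)
  parts3 <- split_train_test(ds, 0.5, seed = 2)
  expect_false(identical(parts$train, parts3$train))
  ds_one <- spectral_dataset(raw_pixel_df(1, 50))
  expect_error(split_train_test(ds_one, 0.5, 1), "at least 2")
})

test_that("MPCE equals a literal loop-and-average oracle", {
  expect_equal(mpce(c(10, 10), c(10, 10)), 1.0)
  expect_equal(mpce(c(8, 9), c(10, 10)), 0.85)
  set.seed(30)
  for (case in 1:100) {
    k <- sample(2:10, 1)
    tot <- sample(5:50, k, replace = TRUE)
    cor_ <- vapply(tot, function(t) sample(0:t, 1), integer(1))
    acc <- 0
    for (i in seq_len(k)) acc <- acc + cor_[i] / tot[i]
    expect_equal(mpce(cor_, tot), acc / k, tolerance = 1e-15)
  }
  expect_error(mpce(c(1, 2), c(2, 0)), "positive")
  expect_error(mpce(c(3), c(2)), "correct counts")
})

test_that("k-fold folds are a seeded stratified partition", {
  ds <- spectral_dataset(raw_pixel_df(2306, 2209))
  fold <- sargnet:::make_folds(ds$label, 5L, seed = 3)
  expect_setequal(unique(fold), 1:5)
  # disjoint and exhaustive by construction of the assignment vector;
  # overall fold sizes are exactly equal here (4515 / 5)
  expect_equal(as.vector(table(fold)), rep(903L, 5L))
  # class proportions within one pixel of the global ratio
  for (f in 1:5) {
    n1 <- sum(ds$label[fold == f] == 1L)
    expect_lte(abs(n1 - 2306 / 5), 1)
  }
  expect_identical(fold, sargnet:::make_folds(ds$label, 5L, seed = 3))
  expect_false(identical(fold, sargnet:::make_folds(ds$label, 5L, seed = 4)))
})

test_that("training on separable data reaches perfect accuracy quickly", {
  ds <- simulate_pixels(sim_config(seed = 3, n_per_class = 30,
                                   noise_scale = 0))
  epochs <- c(mlp = 20, fcn = 30, erisnet = 15)
  for (nm in names(epochs)) {
    fit <- sarg_fit(nm, ds, test = ds,
                    config = smoke_config(epochs[[nm]], seed = 4,
                                          batch_size = 20))
    expect_equal(fit$train_accuracy, 1.0,
                 label = sprintf("%s final train accuracy", nm))
    expect_lte(which(fit$curves$train_accuracy == 1)[1], 200)
  }
})

test_that("learning curves have one entry per epoch and fits reproduce", {
  ds <- simulate_pixels(sim_config(seed = 5, n_per_class = 40))
  cfg <- smoke_config(6, seed = 9, batch_size = 25)
  f1 <- sarg_fit("mlp", ds, config = cfg)
  f2 <- sarg_fit("mlp", ds, config = cfg)
  expect_equal(nrow(f1$curves), 6L)
  expect_true(all(f1$curves$train_accuracy >= 0 &
                    f1$curves$train_accuracy <= 1))
  expect_identical(f1$curves, f2$curves)
  expect_identical(predict(f1, ds), predict(f2, ds))
  expect_equal(f1$n_train, 40L)
  expect_equal(f1$n_test, 40L)
})

test_that("accuracy evaluation uses argmax with ties toward class 0", {
  ds <- simulate_pixels(sim_config(seed = 6, n_per_class = 10))
  # exact tie probabilities must be called as class 0
  tie <- matrix(0.5, 4, 2)
  expect_identical(sargnet:::hard_calls(tie), rep(0L, 4))
  fit <- sarg_fit("mlp", ds, test = ds, config = smoke_config(2, seed = 1,
                                                              batch_size = 10))
  acc <- evaluate_accuracy(fit, ds)
  expect_equal(acc, mean(predict(fit, ds, type = "class") == ds$label))
  expect_error(evaluate_accuracy(fit, ds[0, ]), "empty test set")
})

test_that("k-fold CV partitions, trains per fold, and aggregates by MPCE", {
  ds <- simulate_pixels(sim_config(seed = 8, n_per_class = 30,
                                   noise_scale = 0))
  cv <- kfold_cv("mlp", ds, k = 2, config = smoke_config(12, seed = 2,
                                                         batch_size = 15))
  expect_equal(cv$k, 2L)
  expect_equal(sum(cv$per_fold_total), nrow(ds))
  expect_equal(cv$per_fold_accuracy, cv$per_fold_correct / cv$per_fold_total)
  expect_equal(cv$mpce, mean(cv$per_fold_accuracy))
  # separable data: every fold classifies perfectly
  expect_equal(cv$mpce, 1.0)
  expect_error(kfold_cv("mlp", simulate_pixels(sim_config(1,
    n_per_class = 3)), k = 5), "at least k")
})

test_that("non-finite losses abort with a diagnostic naming the batch", {
  ds <- simulate_pixels(sim_config(seed = 9, n_per_class = 10))
  cfg <- training_config(epochs = 1, batch_size = 10, seed = 1,
                         learning_rate = 1e250)
  expect_error(sarg_fit("mlp", ds, test = ds, config = cfg),
               "non-finite training loss at epoch")
})

test_that("compare_models mirrors the published protocol split", {
  ds <- simulate_pixels(sim_config(seed = 10, n_per_class = 40))
  cmp <- compare_models(ds, config = smoke_config(3, seed = 5,
                                                  batch_size = 20),
                        models = c("mlp", "fcn"), protocol = "paper")
  expect_equal(nrow(cmp$table), 2L)
  expect_true(all(cmp$table$protocol == "50/50 split"))
  one <- compare_models(ds, config = smoke_config(2, seed = 5,
                                                  batch_size = 20),
                        models = "mlp")
  expect_equal(nrow(one$table), 1L)
  # deltas recomputable from the table itself
  d <- outer(cmp$table$accuracy, cmp$table$accuracy, "-")
  expect_equal(d[1, 2], cmp$table$accuracy[1] - cmp$table$accuracy[2])
})
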