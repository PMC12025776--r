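test_that("binary cross-entropy matches its closed forms", {
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_loss(c(1, 0, 1, 0), rep(0.5, 4)), log(2),
               tolerance = 1e-12)
  # direct evaluation of the defining formula
  expect_equal(bce_loss(c(1, 0), c(0.8, 0.4)), -(log(0.8) + log(0.6)) / 2,
               tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(0.8, 0.4)), 0.36698, tolerance = 1e-4)
  expect_error(bce_loss(c(1, 0), 0.5), "equal length")
  expect_error(bce_loss(c(1, 2), c(0.5, 0.5)), "binary")
})

test_that("stratified splits respect class proportions exactly", {
  labels <- rep(c(1L, 3L), times = c(60, 40))
  idx <- stratified_split(labels, c(0.4, 0.3, 0.3), seed = 1)
  expect_equal(sum(labels[idx$train] == 1L), 24)
  expect_equal(sum(labels[idx$train] == 3L), 16)
  expect_equal(lengths(idx), c(train = 40L, val = 30L, test = 30L))

  idx2 <- stratified_split(labels, c(0.4, 0.3, 0.3), seed = 1)
  expect_identical(idx, idx2)
})

test_that("splits are disjoint and exhaustive for random datasets", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(12:80, 1)
    labels <- sample(1:3, n, replace = TRUE)
    while (any(table(factor(labels, 1:3)) < 3)) {
      labels <- sample(1:3, n, replace = TRUE)
    }
    idx <- stratified_split(labels, seed = i)
    all_idx <- c(idx$train, idx$val, idx$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0)
    # per-class proportions within one sample of the global fractions
    for (cl in 1:3) {
      ncl <- sum(labels == cl)
      expect_lte(abs(sum(labels[idx$train] == cl) - 0.4 * ncl), 1)
      expect_lte(abs(sum(labels[idx$val] == cl) - 0.3 * ncl), 1)
    }
  }
  expect_error(stratified_split(c(1, 1, 1, 2, 2)), "at least 3")
})

test_that("splitting a dataset preserves signals and labels", {
  d <- tiny_dataset()
  sp <- stratified_split(d, seed = 2)
  expect_s3_class(sp$train, "ppg_dataset")
  n_total <- sum(vapply(sp, function(s) length(s$signals), integer(1)))
  expect_equal(n_total, length(d$signals))
  # label conservation through the split
  expect_equal(sum(vapply(sp, function(s) sum(s$binary_labels), integer(1))),
               sum(d$binary_labels))
})

test_that("the early-stopping rule fires after `patience` flat epochs", {
  # validation loss constant from epoch 3 onward -> stop at epoch 53
  hist <- c(1, 0.9, 0.8, rep(0.8, 100))
  expect_equal(early_stop_epoch(hist, patience = 50), 53)
  # strictly decreasing loss never triggers the rule
  expect_equal(early_stop_epoch(seq(1, 0.5, length.out = 200), 50), 200)
  # ties do not reset patience
  expect_equal(early_stop_epoch(c(0.5, 0.6, 0.5, 0.6, 0.5, 0.6), 3), 4)
})

test_that("training checkpoints the epoch with minimum validation loss", {
  d <- preprocess_dataset(tiny_dataset(),
                          preprocess_config(target_fs = 64,
                                            butter_cutoff = 30))
  sp <- stratified_split(d, seed = 3)
  cfg <- tiny_config("cnn_mlp", 128)
  ctl <- train_control(max_epochs = 12, patience = 12, batch_size = 8,
                       seed = 3)
  fit <- train_network(build_model(cfg, seed = 3), sp$train, sp$val, ctl)
  expect_equal(nrow(fit$history), fit$stopped_epoch)
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  expect_equal(fit$history$val_loss[fit$best_epoch], fit$best_val_loss)
  # the returned checkpoint reproduces the best validation loss
  va <- dataset_matrix(sp$val)
  expect_equal(bce_loss(va$y, net_forward(fit$net, va$x)$prob),
               fit$best_val_loss, tolerance = 1e-12)
})

test_that("identical seeds give identical training runs", {
  d <- preprocess_dataset(tiny_dataset(),
                          preprocess_config(target_fs = 64,
                                            butter_cutoff = 30))
  sp <- stratified_split(d, seed = 4)
  cfg <- tiny_config("cnn_kan", 128)
  ctl <- train_control(max_epochs = 5, patience = 5, batch_size = 8,
                       seed = 9)
  f1 <- train_network(build_model(cfg, seed = 9), sp$train, sp$val, ctl)
  f2 <- train_network(build_model(cfg, seed = 9), sp$train, sp$val, ctl)
  expect_identical(f1$history, f2$history)
  te <- dataset_matrix(sp$test)
  expect_identical(net_forward(f1$net, te$x)$prob,
                   net_forward(f2$net, te$x)$prob)
})

test_that("grid search ranks configurations by validation AUC", {
  d <- preprocess_dataset(tiny_dataset(16, 8, 8),
                          preprocess_config(target_fs = 64,
                                            butter_cutoff = 30))
  sp <- stratified_split(d, seed = 5)
  space <- list(
    tiny_config("cnn_mlp", 128),
    model_config("cnn_mlp", input_length = 128, conv_channels = 2,
                 conv_kernel = 5, ff_dims = c(4)),
    model_config("cnn_mlp", input_length = 999, conv_channels = 2,
                 conv_kernel = 5, ff_dims = c(4)))  # fails: wrong length
  ctl <- train_control(max_epochs = 4, patience = 4, batch_size = 8,
                       seed = 5)
  gs <- grid_search(space, sp$train, sp$val, ctl)
  expect_equal(nrow(gs$leaderboard), 3)
  ok <- gs$leaderboard[gs$leaderboard$status == "ok", ]
  expect_equal(nrow(ok), 2)
  expect_equal(gs$leaderboard$val_auc[1], max(ok$val_auc))
  # the failing configuration is recorded, not fatal
  expect_match(gs$leaderboard$status[3], "failed")
})

test_that("train configuration validates its invariants", {
  expect_error(train_control(patience = 300, max_epochs = 200), "patience")
  expect_error(train_control(split_fractions = c(0.5, 0.5, 0.5)), "summing")
  expect_error(train_control(threshold = 1), "strictly inside")
})
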