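# Metrics, optimizer plumbing, determinism, checkpoints.

test_that("metrics agree with hand-computed oracles", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3), "scalar")
  expect_equal(m$rmse, 0)
  expect_equal(m$pearson, 1)
  expect_equal(m$spearman, 1)
  m2 <- compute_metrics(-c(1, 2, 3.5), c(1, 2, 3.5), "scalar")
  expect_equal(m2$pearson, -1)
  m3 <- compute_metrics(c(1, 2, 3), c(1, 2, 4), "scalar")
  expect_equal(m3$rmse, 1 / sqrt(3))
  expect_equal(m3$mse, 1 / 3)
  expect_equal(m3$n, 3L)
  # zero-variance predictions: correlations flagged undefined, never 0
  m4 <- compute_metrics(c(2, 2, 2), c(1, 2, 3), "scalar")
  expect_true(is.na(m4$pearson))
  expect_true(m4$undefined_correlations)
  # classification
  m5 <- compute_metrics(c("R", "S", "R", "R"), c("R", "S", "S", "R"),
                        "class")
  expect_equal(m5$accuracy, 0.75)
})

test_that("vector metrics average correlations per coordinate axis", {
  set.seed(61)
  truth <- matrix(rnorm(60L), 20L, 3L)
  pred <- truth + matrix(rnorm(60L, sd = 0.01), 20L, 3L)
  m <- compute_metrics(pred, truth, "vector")
  expect_equal(m$mse, mean((pred - truth)^2))
  by_axis <- mean(vapply(1:3, function(k) cor(pred[, k], truth[, k]),
                         numeric(1L)))
  expect_equal(m$pearson, by_axis, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(m$mse))
})

test_that("adam updates every learnable array", {
  st <- tiny_state(6L, seed = 62L)
  cfg <- tiny_config(out_node = c(2L, 0L))
  params <- init_for(st, cfg)
  fw <- gcpnet_forward(st, params, cfg, keep_cache = TRUE)
  g_s <- matrix(1, nrow(fw$node$s), ncol(fw$node$s))
  grads <- gcpnet_backward(g_s, NULL, fw$cache, params, cfg)
  upd <- adam_step(params, grads, adam_init(params), lr = 1e-2)
  # the embedding weights moved
  expect_gt(max(abs(upd$params$embed_node$w_s - params$embed_node$w_s)), 0)
  expect_equal(upd$state$t, 1L)
})

test_that("training is deterministic per seed and zero epochs skip training", {
  mols <- generate_chiral_dataset(40L, seed = 63L)
  graphs <- lapply(mols, featurize_molecule)
  y <- lapply(mols, function(m) if (m$label == "R") 2L else 1L)
  cfg <- gcpnet_config(hidden_node = c(8L, 3L), hidden_edge = c(6L, 2L),
                       out_node = c(2L, 0L), n_layers = 1L, k = 4L,
                       gcp = gcp_config(omega = 1L))
  ck1 <- train_model(graphs, y, "class", cfg, epochs = 3L,
                     batch_size = 16L, seed = 7L)
  ck2 <- train_model(graphs, y, "class", cfg, epochs = 3L,
                     batch_size = 16L, seed = 7L)
  expect_identical(ck1$history, ck2$history)
  expect_equal(ck1$params$embed_node$w_s, ck2$params$embed_node$w_s)
  m1 <- evaluate_model(ck1, graphs, y)
  m2 <- evaluate_model(ck2, graphs, y)
  expect_identical(m1$accuracy, m2$accuracy)

  ck0 <- train_model(graphs, y, "class", cfg, epochs = 0L, seed = 7L)
  expect_null(ck0$history)
  m0 <- evaluate_model(ck0, graphs, y)
  expect_true(is.finite(m0$accuracy))
  # dataset order does not change evaluation
  perm <- rev(seq_along(graphs))
  mp <- evaluate_model(ck0, graphs[perm], y[perm])
  expect_equal(mp$accuracy, m0$accuracy)
})

test_that("ablation flags map onto the advertised symmetry classes", {
  cfg <- ablation_config("no_frames")
  expect_false(cfg$use_frames)
  expect_true(cfg$use_residual)
  expect_error(ablation_config("nonsense"))
  # frame-free networks cannot see reflections; framed ones can
  aud <- audit_self_consistency(seed = 64L, n_nodes = 16L, n_motions = 5L)
  expect_gt(aud$mirror_diff_frames, 1e-3)
  expect_lt(aud$mirror_diff_noframes, 1e-10)
})

test_that("checkpoints round-trip through JSON with identical predictions", {
  mols <- generate_chiral_dataset(20L, seed = 65L)
  graphs <- lapply(mols, featurize_molecule)
  y <- lapply(mols, function(m) if (m$label == "R") 2L else 1L)
  cfg <- gcpnet_config(hidden_node = c(8L, 3L), hidden_edge = c(6L, 2L),
                       out_node = c(2L, 0L), n_layers = 1L, k = 4L,
                       gcp = gcp_config(omega = 1L))
  ck <- train_model(graphs, y, "class", cfg, epochs = 1L, seed = 8L)
  path <- withr::local_tempfile(fileext = ".json")
  checkpoint_save(ck, path)
  back <- checkpoint_load(path)
  expect_equal(back$params$embed_node$w_s, ck$params$embed_node$w_s,
               tolerance = 1e-12)
  m1 <- evaluate_model(ck, graphs, y)
  m2 <- evaluate_model(back, graphs, y)
  expect_equal(m1$predictions, m2$predictions)
  # YAML configuration round-trip
  ypath <- withr::local_tempfile(fileext = ".yaml")
  config_save_yaml(cfg, ypath)
  cfg2 <- config_load_yaml(ypath)
  expect_equal(cfg2$hidden_node, cfg$hidden_node)
  expect_equal(cfg2$gcp$lambda, cfg$gcp$lambda)
  expect_identical(cfg2$update_positions, cfg$update_positions)
})

test_that("training diverging to non-finite loss aborts with a diagnostic", {
  mols <- generate_chiral_dataset(10L, seed = 66L)
  graphs <- lapply(mols, featurize_molecule)
  y <- lapply(mols, function(m) if (m$label == "R") 2L else 1L)
  cfg <- gcpnet_config(hidden_node = c(8L, 3L), hidden_edge = c(6L, 2L),
                       out_node = c(2L, 0L), n_layers = 1L, k = 4L,
                       gcp = gcp_config(omega = 1L))
  expect_error(train_model(graphs, y, "class", cfg, epochs = 3L,
                           lr = 1e150, seed = 9L),
               "non-finite")
})
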