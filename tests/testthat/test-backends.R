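test_that("the registry ships two reference backends with distinct splits", {
  ids <- list_backends()
  expect_true(all(c("randomForest", "extraTrees") %in% ids))
  expect_true(all(c("randomForest_fixed", "extraTrees_fixed") %in% ids))
  expect_false(get_backend("randomForest")$deterministic)
  expect_true(get_backend("randomForest_fixed")$deterministic)
  expect_error(get_backend("nope"), "unknown backend")
  expect_error(register_backend(get_backend("randomForest")),
               "already registered")
})

test_that("replicate seeds are reproducible, 31-bit, and stream-separated", {
  s1 <- replicate_seed(1, "b", "sig001", 3, 7)
  expect_identical(s1, replicate_seed(1, "b", "sig001", 3, 7))
  expect_false(s1 == replicate_seed(1, "b", "sig001", 3, 8))
  expect_false(s1 == replicate_seed(2, "b", "sig001", 3, 7))
  expect_lt(s1, 2^31)
  # deterministic mode collapses the replicate axis
  d1 <- replicate_seed(1, "b", "sig001", 3, 7, deterministic = TRUE)
  d2 <- replicate_seed(1, "b", "sig001", 3, 99, deterministic = TRUE)
  expect_identical(d1, d2)
})

test_that("an oracle signature yields AUC 1 with any backend", {
  labels <- rep(c("healthy", "tumor"), 12)
  values <- exp(matrix(rnorm(24 * 3), 24, 3))
  values[, 1] <- (labels == "tumor") + 0.01  # label indicator feature
  ds <- expression_dataset(values, labels, positive_class = "tumor",
                           feature_ids = c("ind", "n1", "n2"))
  parts <- make_partitions(ds, 0.5, 1, seed = 1)
  for (backend in c("randomForest", "extraTrees")) {
    res <- fit_predict_auc(backend, ds, "ind", parts$train_indices[[1]],
                           seed = 1, ntree = 50)
    expect_equal(res$auc, 1.0)
    expect_gte(res$runtime_seconds, 0)
    expect_false(is.na(res$oob_error))
  }
})

test_that("shuffled labels give chance-level AUC on a noise signature", {
  aucs <- vapply(1:100, function(i) {
    set.seed(i)
    ds <- noise_dataset(n_pairs = 10, n_features = 2, seed = i)
    ds$labels <- sample(ds$labels)
    ds$pair_ids <- NULL  # shuffling breaks the paired structure
    parts <- make_partitions(ds, 0.5, 1, seed = i)
    fit_predict_auc("randomForest", ds, c("g1", "g2"),
                    parts$train_indices[[1]], seed = i, ntree = 30)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("fits are deterministic for fixed seed and partition", {
  ds <- simulate_expression(10, 5, 3, effect_size = 1, seed = 3)
  parts <- make_partitions(ds, 0.5, 1, seed = 3)
  for (backend in c("randomForest", "extraTrees")) {
    a <- fit_predict_auc(backend, ds, paste0("g", 1:3),
                         parts$train_indices[[1]], seed = 5, ntree = 50)
    b <- fit_predict_auc(backend, ds, paste0("g", 1:3),
                         parts$train_indices[[1]], seed = 5, ntree = 50)
    expect_identical(a$auc, b$auc)
    expect_identical(a$oob_error, b$oob_error)
  }
})

test_that("signature and backend failures carry useful context", {
  ds <- noise_dataset(5, 3)
  parts <- make_partitions(ds, 0.5, 1, seed = 1)
  expect_error(fit_predict_auc("randomForest", ds, "absent",
                               parts$train_indices[[1]], 1),
               "not in dataset")
  failing <- forest_backend("failing", "mock",
                            fit_fun = function(...) stop("boom"))
  expect_error(fit_predict_auc(failing, ds, "g1",
                               parts$train_indices[[1]], 1),
               "backend 'failing' failed: boom")
})

test_that("ntree tuning fits k x q models per grid value", {
  counter <- new_counter()
  backend <- mock_backend("tuner", oob_fun = function(nt) 0.2,
                          counter = counter)
  ds <- simulate_expression(n_pairs = 10, n_features = 3, seed = 1)
  curve <- tune_ntree(backend, ds, grid = c(10L, 20L), k = 50, q = 25,
                      P = 0.9, seed = 1)
  expect_identical(curve$n_models_per_point, 1250L)
  expect_identical(counter$n, 2L * 1250L)
  # flat curve: the first grid value already sits on the plateau
  expect_identical(curve$selected_ntree, 10L)
})

test_that("plateau selection picks the first stabilised grid value", {
  # decreasing then flat from the 5th grid point
  errs <- c(0.30, 0.20, 0.12, 0.08, 0.050, 0.049, 0.051, 0.050)
  grid <- as.integer(seq(10, 80, by = 10))
  backend <- mock_backend("curve",
                          oob_fun = function(nt) errs[match(nt, grid)])
  ds <- simulate_expression(n_pairs = 6, n_features = 3, seed = 1)
  curve <- tune_ntree(backend, ds, grid = grid, k = 2, q = 2,
                      seed = 1, plateau_tolerance = 0.005)
  expect_identical(curve$selected_ntree, 50L)
  expect_equal(curve$mean_oob_error, errs)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tuning_curve(curve, tsv)
  df <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(df$mean_oob_error, errs)
})

test_that("tuning refuses backends without out-of-bag support", {
  backend <- mock_backend("no_oob")
  ds <- simulate_expression(n_pairs = 6, n_features = 3, seed = 1)
  expect_error(tune_ntree(backend, ds, grid = c(10L), k = 2, q = 2),
               "out-of-bag")
  expect_error(tune_ntree("randomForest", ds, grid = c(20L, 10L),
                          k = 2, q = 2),
               "strictly increasing")
})

test_that("the default tree grid is coarse below 100 and the dense grid is available", {
  g <- default_ntree_grid()
  expect_identical(g[1:10], as.integer(seq(10, 100, by = 10)))
  expect_identical(g[length(g)], 1200L)
  expect_false(is.unsorted(g, strictly = TRUE))
  expect_identical(ntree_grid(10), as.integer(seq(10, 1200, by = 10)))
})
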