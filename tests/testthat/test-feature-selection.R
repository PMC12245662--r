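test_that("variance prefilter keeps the dominant-variance features", {
  set.seed(1)
  values <- exp(matrix(rnorm(10 * 5, sd = 0.3), 10, 5))
  values[, 3] <- exp(rnorm(10, sd = 3))
  ds <- expression_dataset(values, rep(c("a", "b"), 5),
                           feature_ids = paste0("f", 1:5))
  expect_identical(variance_prefilter(ds, 1)$feature_ids, "f3")
  expect_identical(variance_prefilter(ds, 5)$feature_ids, ds$feature_ids)
  expect_error(variance_prefilter(ds, 6), "exceeds")
  expect_error(variance_prefilter(ds, 0), ">= 1")
})

test_that("inflated-variance features are recovered from noise", {
  hits <- vapply(1:100, function(i) {
    set.seed(i)
    noise <- matrix(rnorm(40 * 100), 40, 100)
    inflated <- matrix(rnorm(40 * 10, sd = 3), 40, 10)
    values <- exp(cbind(inflated, noise))
    ds <- expression_dataset(values, rep(c("a", "b"), 20),
                             feature_ids = sprintf("f%03d", 1:110))
    kept <- variance_prefilter(ds, 10)$feature_ids
    setequal(kept, sprintf("f%03d", 1:10))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("kuncheva index matches its closed form", {
  expect_equal(kuncheva_index(letters[1:5], letters[1:5], 100), 1.0)
  expect_equal(kuncheva_index(c("a", "b", "c"), c("d", "e", "f"), 10),
               (0 - 0.9) / (3 - 0.9))
  expect_equal(kuncheva_index(c("a", "b", "c"), c("a", "e", "f"), 10),
               (1 - 0.9) / (3 - 0.9))
  expect_error(kuncheva_index(c("a", "b"), c("a"), 10), "equal size")
  expect_error(kuncheva_index(letters[1:5], letters[1:5], 5), "undefined")
})

test_that("kuncheva index is symmetric, bounded, and 1 only for identity", {
  universe <- letters[1:5]
  pairs <- utils::combn(universe, 2, simplify = FALSE)
  for (a in pairs) {
    for (b in pairs) {
      k_ab <- kuncheva_index(a, b, 5)
      expect_equal(k_ab, kuncheva_index(b, a, 5))
      expect_gte(k_ab, -1)
      expect_lte(k_ab, 1)
      expect_identical(k_ab == 1, setequal(a, b))
    }
  }
})

fake_ranking <- function(ids, ranks) {
  data.frame(feature_id = ids, aggregate_rank = ranks,
             stringsAsFactors = FALSE)
}

test_that("spearman rank stability spans identity to antisymmetry", {
  r1 <- fake_ranking(letters[1:10], 1:10)
  expect_equal(spearman_rank_stability(r1, r1), 1.0)
  r2 <- fake_ranking(letters[1:10], 10:1)
  expect_equal(spearman_rank_stability(r1, r2), -1.0)
  expect_error(
    spearman_rank_stability(r1, fake_ranking(LETTERS[1:10], 1:10)),
    "universes")
})

test_that("independent random rankings have near-zero mean correlation", {
  set.seed(42)
  vals <- replicate(200, {
    a <- fake_ranking(paste0("f", 1:50), sample(50))
    b <- fake_ranking(paste0("f", 1:50), sample(50))
    spearman_rank_stability(a, b)
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("a perfect separator is ranked first under both measures", {
  set.seed(7)
  values <- exp(matrix(rnorm(30 * 6), 30, 6))
  labels <- rep(c("healthy", "tumor"), 15)
  values[, 4] <- exp(rnorm(30) + 8 * (labels == "tumor"))
  ds <- expression_dataset(values, labels, positive_class = "tumor",
                           feature_ids = paste0("f", 1:6))
  rk <- rank_features(ds, "randomForest", n_repeats = 2, seed = 1,
                      ntree = 100)
  expect_identical(rk$feature_id[1], "f4")
  expect_equal(rk$aggregate_rank[1], 1)
  expect_gt(rk$impurity_score[1], max(rk$impurity_score[-1]))
  expect_gt(rk$permutation_score[1], max(rk$permutation_score[-1]))
})

test_that("duplicated informative features share the top of the ranking", {
  set.seed(8)
  labels <- rep(c("healthy", "tumor"), 20)
  info <- rnorm(40) + 3 * (labels == "tumor")
  values <- exp(cbind(info, info, matrix(rnorm(40 * 5), 40, 5)))
  ds <- expression_dataset(values, labels, positive_class = "tumor",
                           feature_ids = paste0("f", 1:7))
  rk <- rank_features(ds, "randomForest", n_repeats = 20, seed = 2,
                      ntree = 100)
  expect_setequal(rk$feature_id[1:2], c("f1", "f2"))
})

test_that("no feature dominates the ranking of pure noise", {
  firsts <- vapply(1:50, function(i) {
    ds <- noise_dataset(n_pairs = 10, n_features = 10, seed = i)
    rk <- rank_features(ds, "randomForest", n_repeats = 1, seed = i,
                        ntree = 40)
    rk$feature_id[1]
  }, character(1))
  expect_lt(max(table(firsts)) / 50, 0.20)
})

test_that("feature ranking is reproducible bit-for-bit under a seed", {
  ds <- separable_dataset(n_pairs = 8, n_features = 6)
  a <- rank_features(ds, "randomForest", n_repeats = 2, seed = 5, ntree = 50)
  b <- rank_features(ds, "randomForest", n_repeats = 2, seed = 5, ntree = 50)
  expect_identical(a, b)
})

test_that("rank_features demands both importance modes", {
  b <- mock_backend()
  ds <- noise_dataset(5, 4)
  expect_error(rank_features(ds, b, 1, 1), "impurity importance")
})

test_that("stable size selection recovers a small strong-feature set", {
  runs <- vapply(1:20, function(i) {
    ds <- simulate_expression(n_pairs = 20, n_features = 20,
                              n_informative = 4, effect_size = 6, seed = i)
    sel <- select_stable_size(ds, "randomForest", candidate_sizes = 2:10,
                              n_resamples = 6, P = 0.5, seed = i,
                              ntree = 100)
    c(size_ok = sel$n_selected <= 6,
      found = all(paste0("g", 1:4) %in% sel$selected_features))
  }, logical(2))
  expect_gte(mean(runs["size_ok", ]), 0.9)
  expect_gte(mean(runs["found", ]), 0.9)
})

test_that("a single-candidate list is a forced choice", {
  ds <- separable_dataset(n_pairs = 8, n_features = 8)
  sel <- select_stable_size(ds, "randomForest", candidate_sizes = 5,
                            n_resamples = 3, seed = 1, ntree = 40)
  expect_identical(sel$n_selected, 5L)
})

test_that("pure noise fails the stability floors and is flagged", {
  ds <- noise_dataset(n_pairs = 12, n_features = 15, seed = 3)
  sel <- select_stable_size(ds, "randomForest", candidate_sizes = c(3, 5),
                            n_resamples = 4, seed = 3, ntree = 40)
  expect_false(sel$met_floors)
})
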