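test_that("coefficient of variation matches hand-computed values", {
  expect_identical(coefficient_of_variation(rep(1.0, 25)), 0)
  expect_equal(coefficient_of_variation(c(0.8, 0.9, 1.0)), 0.1 / 0.9)
  expect_equal(coefficient_of_variation(c(0.5, 0.5, 0.5, 0.7)), 0.1 / 0.55)
  expect_error(coefficient_of_variation(0.5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "non-positive mean")
})

test_that("the stability matrix flags exactly the dispersed cells", {
  constant <- grid_from_tensor(array(0.95, dim = c(3, 4, 5)))
  sm <- stability_matrix(constant, t = 0)
  expect_true(all(sm$stable))
  expect_true(all(sm$cv == 0))

  perturbed <- constant
  perturbed$auc[2, 3, 1] <- 0.95 + 1e-9  # one bit-level perturbation
  sm <- stability_matrix(perturbed, t = 0)
  expect_identical(sum(!sm$stable), 1L)
  expect_false(sm$stable[2, 3])
})

test_that("cv values equal an independent per-cell oracle", {
  tensor <- random_auc_tensor(4, 5, 6, seed = 21)
  grid <- grid_from_tensor(tensor)
  sm <- stability_matrix(grid, t = 0.002)
  for (s in 1:4) {
    for (n in 1:5) {
      vals <- tensor[s, n, ]
      cv <- sd(vals) / mean(vals)
      expect_equal(sm$cv[s, n], cv, tolerance = 1e-14)
      expect_identical(sm$stable[s, n], cv <= 0.002)
    }
  }
})

test_that("hr/hs/aggregate match an exhaustive counting oracle", {
  expect_equal(hr_vector(matrix(TRUE, 21, 50)), rep(1.0, 50))
  col <- matrix(FALSE, 21, 1); col[1:7, 1] <- TRUE
  expect_equal(hr_vector(col), 1 / 3)
  row <- matrix(FALSE, 1, 50); row[1, 1:10] <- TRUE
  expect_equal(hs_vector(row), 0.2)
  expect_equal(aggregate_scores(c(0.5, 0, 0.25), c(1))$resampling_score,
               0.375)
  expect_identical(aggregate_scores(c(0, 0), c(0, 0)),
                   list(resampling_score = 0, signature_score = 0))
  expect_identical(aggregate_scores(rep(1, 7), rep(1, 6)),
                   list(resampling_score = 1, signature_score = 1))

  set.seed(77)
  for (i in 1:1000) {
    m <- matrix(runif(42) < runif(1), 6, 7)
    hr <- hr_vector(m)
    hs <- hs_vector(m)
    # exhaustive cell-counting oracle
    hr_oracle <- numeric(7)
    hs_oracle <- numeric(6)
    for (n in 1:7) hr_oracle[n] <- sum(m[, n]) / 6
    for (s in 1:6) hs_oracle[s] <- sum(m[s, ]) / 7
    expect_identical(unname(hr), hr_oracle)
    expect_identical(unname(hs), hs_oracle)
    agg <- aggregate_scores(hr, hs)
    expect_equal(agg$resampling_score,
                 if (any(hr_oracle > 0)) mean(hr_oracle[hr_oracle > 0]) else 0)
    expect_equal(agg$signature_score,
                 if (any(hs_oracle > 0)) mean(hs_oracle[hs_oracle > 0]) else 0)
    expect_true(all(c(hr, hs, unlist(agg)) >= 0 &
                      c(hr, hs, unlist(agg)) <= 1))
  }
})

test_that("stable cells grow monotonically with the threshold", {
  tensor <- random_auc_tensor(5, 6, 4, seed = 31)
  tensor[1, , ] <- 0.9  # some hyper-stable rows too
  grid <- grid_from_tensor(tensor)
  thresholds <- c(0, 0.002, 0.004, 0.008, 0.05, 0.5)
  prev <- NULL
  prev_count <- -1L
  for (t in thresholds) {
    sm <- stability_matrix(grid, t)
    if (!is.null(prev)) {
      expect_true(all(sm$stable[prev]))  # cellwise superset
    }
    expect_gte(sum(sm$stable), prev_count)
    prev <- sm$stable
    prev_count <- sum(sm$stable)
  }
})

test_that("hyper-stability is relative stability at t = 0", {
  tensor <- random_auc_tensor(4, 4, 3, seed = 41)
  tensor[2, 2, ] <- 0.75
  grid <- grid_from_tensor(tensor)
  sm <- stability_matrix(grid, 0)
  identical_oracle <- matrix(FALSE, 4, 4)
  for (s in 1:4) {
    for (n in 1:4) {
      vals <- tensor[s, n, ]
      identical_oracle[s, n] <- all(vals == vals[1])
    }
  }
  expect_identical(unname(sm$stable), identical_oracle)
})

test_that("dot-matrix dependency classification follows the blank-line rule", {
  base <- matrix(TRUE, 10, 10)

  type_a <- base
  type_a[1:3, ] <- FALSE  # 30% blank rows
  expect_identical(classify_dependency(type_a), "signature_dependent")

  type_b <- base
  type_b[, 1:3] <- FALSE  # 30% blank columns
  expect_identical(classify_dependency(type_b), "resampling_dependent")

  type_c <- base
  type_c[1:3, ] <- FALSE
  type_c[, 1:3] <- FALSE
  expect_identical(classify_dependency(type_c), "mixed")
  expect_identical(classify_dependency(base), "mixed")

  sparse <- matrix(FALSE, 10, 10)
  sparse[1, 1:2] <- TRUE  # density 0.02
  expect_identical(classify_dependency(sparse), "unclassified")

  expect_error(classify_dependency(base, row_gap_frac = 0), "\\(0, 1\\)")
})

test_that("a full report scores an all-true matrix as 1/1 at any shape", {
  for (dims in list(c(2, 9, 3), c(7, 2, 2))) {
    grid <- grid_from_tensor(array(0.9, dim = dims))
    rep_ <- stability_report(grid, t = 0)
    expect_equal(rep_$resampling_score, 1)
    expect_equal(rep_$signature_score, 1)
    expect_equal(rep_$mean_auc, 0.9)
  }
})

test_that("report serialisation writes scores, cv and the dot matrix", {
  tensor <- random_auc_tensor(3, 4, 5, seed = 51)
  grid <- grid_from_tensor(tensor)
  rep_ <- stability_report(grid, t = 0.01)
  jf <- withr::local_tempfile(fileext = ".json")
  write_stability_report(rep_, jf)
  obj <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(obj$resampling_score, rep_$resampling_score)
  expect_equal(obj$signature_score, rep_$signature_score)
  expect_identical(obj$dependency_class, rep_$dependency_class)

  dm <- withr::local_tempfile(fileext = ".tsv")
  write_dot_matrix(rep_, dm)
  df <- utils::read.table(dm, sep = "\t", header = TRUE)
  expect_identical(dim(df), c(3L, 5L))  # id column + 4 partitions
  expect_true(all(unlist(df[, -1]) %in% 0:1))
})
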