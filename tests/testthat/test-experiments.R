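test_that("trial-wise CV folds partition trials with grasp stratification", {
  folds <- trial_cv_split(1:30, rep(1:6, each = 5), n_folds = 5, seed = 1)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(tests) == 6))
  strata <- rep(1:6, each = 5)
  for (f in folds) {
    expect_equal(sort(table(strata[f$test])), sort(rep(1L, 6)),
                 ignore_attr = TRUE)          # one trial per grasp
    expect_setequal(c(f$train, f$test), 1:30)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_setequal(unlist(tests), 1:30)        # test folds cover all trials
  expect_equal(sum(lengths(tests)), 30)       # ... exactly once
  expect_error(trial_cv_split(1:30, strata, n_folds = 1), "n_folds")
  expect_error(trial_cv_split(1:6, rep(1, 6), n_folds = 7), "stratum")
  expect_error(trial_cv_split(c(1, 1, 2), rep(1, 3), 2), "unique")
})

test_that("within-position decoding is near-perfect on separable synthetics", {
  f <- day1_features()
  res <- within_position(f, position = 5, seed = 1)
  expect_s3_class(res, "experiment_result")
  expect_true(all(res$per_subject >= 0 & res$per_subject <= 1))
  expect_gt(res$mean, 0.95)
  expect_error(within_position(f, position = 9), "no data")
  one_grasp <- f[f$grasp == 1, ]
  expect_error(within_position(one_grasp, position = 5), "2 grasp classes")
})

test_that("accuracy is invariant to window order", {
  f <- day1_features()
  res1 <- within_position(f, position = 2, seed = 3)
  set.seed(42)
  res2 <- within_position(f[sample(nrow(f)), ], position = 2, seed = 3)
  expect_equal(res1$mean, res2$mean)
})

test_that("transfer diagonal reproduces within-position on the same folds", {
  f <- day1_features()
  tm <- transfer_matrix(f, seed = 7)
  expect_equal(dim(tm$extras$matrix), c(5, 5))
  for (pos in c(2, 5, 8)) {
    wp <- within_position(f, position = pos, seed = 7)
    expect_equal(tm$extras$matrix[paste0("P", pos), paste0("P", pos)],
                 wp$mean, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("OVR equals the mean of off-diagonal row cells at equal weights", {
  ## all positions contribute equally many windows, so the pooled (micro)
  ## OVR accuracy must equal the plain mean of the row's off-diagonal cells
  f <- day1_features()
  tm <- transfer_matrix(f, seed = 2)
  m <- tm$extras$matrix
  for (s in seq_len(nrow(m))) {
    expect_equal(unname(tm$extras$ovr[s]), mean(m[s, -s]), tolerance = 1e-10)
  }
})

test_that("transfer requires every position in every session", {
  f <- day1_features()
  expect_error(transfer_matrix(f[f$position != 4, ],
                               positions = c(2, 4, 5, 6, 8)), "lacks")
  expect_error(transfer_matrix(f[f$position == 5, ]), "at least 2")
})

test_that("position-per-grasp reports one column per grasp", {
  f <- day1_features()
  res <- position_per_grasp(f, seed = 1)
  expect_length(res$extras$per_grasp, 6)
  expect_named(res$extras$per_grasp, as.character(1:6))
  expect_true(all(res$extras$per_grasp >= 0 & res$extras$per_grasp <= 1))
  expect_error(position_per_grasp(f[f$grasp != 3, ]), "grasp 3")
})

test_that("zero position shift keeps position decoding at chance", {
  f0 <- cached("day1_delta0",
               synth_features(participants = 1, days = 1, delta = 0,
                              seed = 21))
  res <- position_per_grasp(f0, seed = 1)
  expect_lt(abs(res$mean - 1 / 5), 0.12)
})

test_that("a strong position shift makes positions decodable", {
  f1 <- cached("day1_delta1",
               synth_features(participants = 1, days = 1, delta = 1,
                              seed = 22))
  res <- position_per_grasp(f1, seed = 1)
  expect_gt(res$mean, 0.9)
})
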