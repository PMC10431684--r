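test_that("init_model is seeded, shaped, and degenerate at scale 0", {
  p <- mf_params(k = 4, seed = 9)
  m1 <- init_model(5, 7, p)
  m2 <- init_model(5, 7, p)
  expect_identical(m1, m2)
  expect_equal(dim(m1$P), c(5, 4))
  expect_equal(dim(m1$Q), c(4, 7))
  expect_equal(m1$b_row, numeric(5))

  p0 <- mf_params(k = 2, init_scale = 0)
  m0 <- init_model(3, 3, p0)
  m0$mu <- 0.7
  expect_equal(predict_score(m0, c(1, 3), c(2, 2)), c(0.7, 0.7))
})

test_that("predict_score is the biased dot product", {
  m <- init_model(2, 2, mf_params(k = 1, init_scale = 0))
  m$mu <- 0.5; m$b_row <- c(0.1, 0); m$b_col <- c(0, 0.2)
  m$P[1, 1] <- 0.5; m$Q[1, 2] <- 0.2
  expect_equal(predict_score(m, 1, 2), 0.5 + 0.1 + 0.2 + 0.1)
  expect_error(predict_score(m, 3, 1), "out of range")
})

test_that("sgd_update fixed point, bias-only arithmetic, and contraction", {
  p <- mf_params(k = 1, lam = 0, gamma = 0.1)
  m <- init_model(2, 2, p)
  m$mu <- 0.3
  # zero residual with lam = 0 changes nothing
  a <- predict_score(m, 1, 1)
  m2 <- sgd_update(m, list(i = 1, j = 1, a = a), p)
  expect_equal(m2, m)

  # bias-only (k = 0) model: both biases move by gamma * e
  m0 <- new_factor_model_for_test(2, 2)
  m0u <- sgd_update(m0, list(i = 1, j = 2, a = 1), p)
  expect_equal(m0u$b_row[1], 0.1)
  expect_equal(m0u$b_col[2], 0.1)

  # repeated single-sample updates contract the residual monotonically
  m3 <- init_model(1, 1, mf_params(k = 2, lam = 0, gamma = 0.05, seed = 2))
  errs <- numeric(50)
  for (t in 1:50) {
    errs[t] <- abs(1 - predict_score(m3, 1, 1))
    m3 <- sgd_update(m3, list(i = 1, j = 1, a = 1), p)
  }
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[50], errs[1] * 0.05)
})

test_that("the C++ epoch kernel reproduces repeated R updates bit-for-bit", {
  p <- mf_params(k = 3, lam = 0.1, gamma = 0.02, seed = 7)
  base <- init_model(5, 6, p)
  base$mu <- 0.4
  ii <- c(1L, 3L, 2L, 5L, 3L); jj <- c(2L, 6L, 1L, 4L, 2L)
  aa <- c(1, 0, 1, 0, 1)
  mr <- base
  for (t in seq_along(ii)) {
    mr <- sgd_update(mr, list(i = ii[t], j = jj[t], a = aa[t]), p)
  }
  mc <- base
  mc$P <- mc$P + 0; mc$Q <- mc$Q + 0   # force copies before in-place kernel
  mc$b_row <- mc$b_row + 0; mc$b_col <- mc$b_col + 0
  fcalink:::sgd_epoch(mc$P, mc$Q, mc$b_row, mc$b_col, mc$mu,
                      ii, jj, aa, seq_along(ii), p$gamma, p$lam)
  expect_identical(mr$P, mc$P)
  expect_identical(mr$Q, mc$Q)
  expect_identical(mr$b_row, mc$b_row)
  expect_identical(mr$b_col, mc$b_col)
})

test_that("train_mf reconstructs noiseless low-rank matrices", {
  # rank-1: all-ones 4x4
  net <- net_from_matrix(matrix(1, 4, 4))
  m <- train_mf(training_set(net, NULL),
                mf_params(k = 1, lam = 1e-4, gamma = 0.05, max_iters = 200,
                          seed = 3))
  sc <- predict_score(m, rep(1:4, each = 4), rep(1:4, 4))
  expect_true(all(abs(sc - 1) < 0.05))

  # rank-2 block-diagonal 6x6, every cell as a sample
  A <- kronecker(diag(2), matrix(1, 3, 3))
  net2 <- net_from_matrix(A)
  ts <- raw_training_set(net2)
  m2 <- train_mf(ts, mf_params(k = 2, lam = 0, gamma = 0.05, max_iters = 400,
                               seed = 5))
  pred <- predict_score(m2, ts$i, ts$j)
  expect_lt(sqrt(mean((ts$a - pred)^2)), 0.05)
})

test_that("train_mf is deterministic, logs a decreasing objective, sets mu", {
  net <- net_from_matrix(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1)))
  ts <- raw_training_set(net)
  p <- mf_params(k = 2, lam = 0.01, gamma = 0.02, max_iters = 50, seed = 8)
  m1 <- train_mf(ts, p)
  m2 <- train_mf(ts, p)
  expect_identical(m1, m2)
  expect_equal(m1$mu, mean(ts$a))
  tr <- attr(m1, "objective_trace")
  expect_equal(length(tr), 50)
  expect_lt(tr[50], tr[1])
  expect_equal(tr[50], mf_objective(m1, ts, p$lam))
  expect_error(train_mf(structure(list(i = integer(), j = integer(),
                                       a = numeric(), n_rows = 2, n_cols = 2),
                                  class = "training_set"), p),
               "empty training set")
})

test_that("training sets reject bad input and raw mode covers all unobserved", {
  net <- net_from_matrix(rbind(c(1, 0), c(0, 0)))
  ts <- raw_training_set(net)
  expect_equal(length(ts$i), 4)         # 1 positive + 3 unobserved negatives
  expect_equal(sum(ts$a), 1)
  expect_error(training_set(net, data.frame(left = "zz", right = "b1")),
               "outside")
  expect_error(training_set(net, net$present), "duplicate")
})

test_that("score_all_unobserved matches predict_score and honors exclude", {
  net <- net_from_matrix(rbind(c(1, 0), c(0, 0)))
  m <- init_model(2, 2, mf_params(k = 2, seed = 1))
  m$mu <- 0.2
  sc <- score_all_unobserved(m, net)
  expect_equal(nrow(sc), 3)
  for (r in seq_len(nrow(sc))) {
    expect_equal(sc$score[r],
                 predict_score(m, match(sc$left[r], net$left),
                               match(sc$right[r], net$right)))
  }
  expect_equal(nrow(score_all_unobserved(m, net, exclude = sc)), 0)
  big <- init_model(4, 4, mf_params(k = 2))
  expect_error(score_all_unobserved(big, net), "shape")
})

test_that("model serialization round-trips", {
  f <- withr::local_tempfile(fileext = ".json")
  m <- init_model(3, 4, mf_params(k = 2, seed = 6))
  m$mu <- 0.31
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$P, m$P)
  expect_equal(m2$Q, m$Q)
  expect_equal(m2$mu, m$mu)
  g <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), g, auto_unbox = TRUE)
  expect_error(load_model(g), "not a fcalink model")
})
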