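test_that("observation embedding is the matrix-vector product Q o", {
  m <- cml(2, 2, 2, seed = 1)
  m$Q <- diag(2)
  expect_equal(embed_observation(m, c(0, 1)), c(0, 1))
  m$Q <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]]
  expect_equal(embed_observation(m, onehot(2, 2)), c(2, 4))
  expect_equal(embed_observation(m, c(0.5, 0.5)), c(1.5, 3.5))
  expect_error(embed_observation(m, c(1, 0, 0)), "length")
})

test_that("next-state prediction adds the action embedding", {
  m <- cml(2, 2, 2, seed = 1)
  m$V <- matrix(0, 2, 2)
  expect_equal(predict_next_state(m, c(3, 4), onehot(1, 2)), c(3, 4))
  m$V <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(predict_next_state(m, c(1, 0), c(1, 0)), c(1, 1))
  m2 <- cml(3, 4, 5, seed = 1)
  s <- embed_observation(m2, onehot(2, 3))
  expect_equal(predict_next_state(m2, s, onehot(3, 4)), s + m2$V[, 3])
  expect_error(predict_next_state(m, c(1, 0, 0), c(1, 0)), "length")
})

test_that("plasticity is gated by the prediction error", {
  # perfect prediction: no Q or V change
  m <- cml(2, 2, 2, eta_q = 0.1, eta_v = 0.1, eta_w = 0, seed = 1)
  m$Q <- diag(2)
  m$V <- matrix(c(-1, 1, 0, 0), 2, 2)  # V a1 = o2 - o1 exactly
  m2 <- apply_plasticity(m, onehot(1, 2), onehot(1, 2), onehot(2, 2))
  expect_equal(m2$Q, m$Q)
  expect_equal(m2$V, m$V)
  # zero learning rate: V unchanged regardless of error
  m <- cml(2, 2, 2, eta_v = 0, seed = 2)
  m2 <- apply_plasticity(m, onehot(1, 2), onehot(1, 2), onehot(2, 2))
  expect_equal(m2$V, m$V)
  # single-step hand computation with identity Q, zero V
  m <- cml(2, 2, 2, eta_q = 0, eta_v = 0.01, eta_w = 0, seed = 3)
  m$Q <- diag(2)
  m$V <- matrix(0, 2, 2)
  m2 <- apply_plasticity(m, onehot(1, 2), onehot(1, 2), onehot(2, 2))
  expect_equal(m2$V[, 1], 0.01 * c(-1, 1))
  expect_equal(m2$V[, 2], c(0, 0))
})

test_that("Q update moves the next observation's column toward the prediction", {
  m <- cml(2, 2, 2, eta_q = 0.1, eta_v = 0, eta_w = 0, seed = 1)
  m$Q <- diag(2)
  m$V <- matrix(0, 2, 2)
  # err = o2col - o1col - 0 = (-1, 1); delta Q[,2] = -eta_q * err
  m2 <- apply_plasticity(m, onehot(1, 2), onehot(1, 2), onehot(2, 2))
  expect_equal(m2$Q[, 2], c(0, 1) - 0.1 * c(-1, 1))
  expect_equal(m2$Q[, 1], c(1, 0))
})

test_that("both W rules learn and the transpose rule tracks the state change", {
  set.seed(4)
  m <- cml(3, 2, 10, eta_q = 0, eta_v = 0, eta_w = 0.5,
           w_rule = "transpose", seed = 5)
  ds <- m$Q[, 2] - m$Q[, 1]
  m2 <- apply_plasticity(m, onehot(1, 3), onehot(1, 2), onehot(2, 3))
  expect_equal(m2$W[1, ], m$W[1, ] + 0.5 * (ds - m$W[1, ]))
  expect_equal(m2$W[2, ], m$W[2, ])
  mr <- cml(3, 2, 10, eta_q = 0, eta_v = 0, eta_w = 0.01,
            w_rule = "regression", seed = 5)
  mr2 <- apply_plasticity(mr, onehot(1, 3), onehot(1, 2), onehot(2, 3))
  expect_equal(mr2$W,
               mr$W + 0.01 * (onehot(1, 2) - drop(mr$W %*% ds)) %o% ds)
})

test_that("utilities are scalar products with the goal direction", {
  m <- cml(2, 2, 2, seed = 1)
  expect_equal(compute_utilities(m, c(0, 0), use_w = FALSE), c(0, 0))
  m$V <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_equal(compute_utilities(m, c(3, 4), use_w = FALSE), c(3, 8))
  # orthonormal columns pick out the matching action
  m$V <- diag(2)
  expect_equal(compute_utilities(m, m$V[, 2], use_w = FALSE), c(0, 1))
  m$W <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(compute_utilities(m, c(5, 7), use_w = TRUE), c(5, 7))
})

test_that("winner-take-all selection is deterministic and affordance-gated", {
  expect_onehot(select_action(c(0.2, 0.9, 0.1), c(1, 1, 1)), 2L)
  # tie broken by the lowest index
  expect_onehot(select_action(c(0.9, 0.9, 0.1), c(1, 1, 1)), 1L)
  # gating masks the larger utility
  expect_onehot(select_action(c(5, 1), c(0, 1)), 2L)
  # an unafforded action can never win even if all afforded utilities < 0
  expect_onehot(select_action(c(-2, -3, 4), c(1, 1, 0)), 1L)
  expect_error(select_action(c(1, 2), c(0, 0)), "no afforded action")
  # identical inputs always give the identical action
  u <- stats::rnorm(6)
  g <- c(1, 1, 0, 1, 1, 1)
  picks <- replicate(20, which(select_action(u, g) == 1))
  expect_true(all(picks == picks[1]))
})

test_that("quantization snaps to the grid and is lossless for many bits", {
  m <- cml(3, 4, 10, seed = 1)
  mq <- quantize_weights(m, 32)
  expect_equal(mq$Q, m$Q, tolerance = 1e-7)
  m$V <- matrix(seq(0, 1, length.out = 40), 10, 4)
  m1 <- quantize_weights(m, 1)
  expect_true(all(m1$V %in% c(0, 1)))
  expect_error(quantize_weights(m, 0), "bits")
})

test_that("model checkpoints round-trip bit-exactly", {
  m <- small_trained()$model
  path <- withr::local_tempfile(fileext = ".rds")
  save_cml(m, path)
  m2 <- load_cml(path)
  expect_identical(m2, m)
})

test_that("V columns have near-orthogonal Gaussian initialization at n_s = 1000", {
  m <- cml(32, 100, 1000, seed = 42)
  C <- action_cosine_matrix(m)
  off <- abs(C[upper.tri(C)])
  expect_lt(max(off), 0.15)
})

test_that("column normalization keeps V columns at unit norm through updates", {
  m <- cml(4, 4, 50, eta_v = 0.2, normalize_v = TRUE, seed = 6)
  expect_equal(unname(sqrt(colSums(m$V^2))), rep(1, 4))
  m <- apply_plasticity(m, onehot(1, 4), onehot(2, 4), onehot(3, 4))
  expect_equal(unname(sqrt(colSums(m$V^2))), rep(1, 4))
})
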