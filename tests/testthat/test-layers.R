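test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(8, 6)
  # pos 0: sin terms 0, cos terms 1
  expect_equal(pe[1, c(1, 3, 5)], rep(0, 3))
  expect_equal(pe[1, c(2, 4, 6)], rep(1, 3))
  # pos 1, d = 4, i = 0: sin(1)
  expect_equal(positional_encoding(2, 4)[2, 1], sin(1), tolerance = 1e-9)
  expect_equal(positional_encoding(2, 4)[2, 1], 0.841471, tolerance = 1e-6)
  # direct evaluation across the table
  d <- 6
  for (pos in 0:7) for (i in 0:(d / 2 - 1)) {
    expect_equal(pe[pos + 1, 2 * i + 1], sin(pos / 10000^(2 * i / d)))
    expect_equal(pe[pos + 1, 2 * i + 2], cos(pos / 10000^(2 * i / d)))
  }
  # Pythagorean pairing and range
  expect_true(all(abs(pe[, c(1, 3, 5)]^2 + pe[, c(2, 4, 6)]^2 - 1) < 1e-9))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(4, 5), "even")
})

test_that("scaled dot-product attention matches hand cases and the loop oracle", {
  # single key: weight 1, output = value
  r <- scaled_dot_product_attention(matrix(1), matrix(1), matrix(2))
  expect_equal(r$output, matrix(2))
  expect_equal(r$weights, matrix(1))
  # two identical keys: uniform weights, output = mean of values
  r <- scaled_dot_product_attention(matrix(1, 1, 2),
                                    matrix(1, 2, 2),
                                    matrix(c(3, 7), 2, 1))
  expect_equal(r$output, matrix(5))
  expect_equal(r$weights, matrix(0.5, 1, 2))
  # random instances vs element-by-element oracle
  set.seed(21)
  for (rep_i in 1:5) {
    Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(20), 5, 4)
    V <- matrix(rnorm(10), 5, 2)
    got <- scaled_dot_product_attention(Q, K, V)
    want <- sdpa_oracle(Q, K, V)
    expect_lt(max(abs(got$output - want$output)), 1e-6)
    expect_lt(max(abs(got$weights - want$weights)), 1e-6)
    expect_equal(rowSums(got$weights), rep(1, 3), tolerance = 1e-6)
    expect_true(all(got$weights >= 0))
  }
  expect_error(scaled_dot_product_attention(matrix(1, 2, 3), matrix(1, 2, 2),
                                            matrix(1, 2, 2)), "disagree")
})

test_that("multi-head attention equals the explicit per-head loop", {
  set.seed(31)
  d <- 16; h <- 8; L <- 8
  mk <- function() matrix(rnorm(d * d, sd = 0.3), d, d)
  p <- list(Wq = mk(), bq = rnorm(d), Wk = mk(), bk = rnorm(d),
            Wv = mk(), bv = rnorm(d), Wo = mk(), bo = rnorm(d))
  X <- matrix(rnorm(L * d), L, d)
  got <- multi_head_attention(X, p, h)
  expect_identical(dim(got), dim(X))
  # oracle: project, slice heads, attend, concat, reproject
  addb <- function(M, b) sweep(M, 2, b, `+`)
  Q <- addb(X %*% p$Wq, p$bq); K <- addb(X %*% p$Wk, p$bk); V <- addb(X %*% p$Wv, p$bv)
  dk <- d / h
  heads <- lapply(seq_len(h), function(j) {
    cols <- (j - 1) * dk + seq_len(dk)
    sdpa_oracle(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                V[, cols, drop = FALSE])$output
  })
  want <- addb(do.call(cbind, heads) %*% p$Wo, p$bo)
  expect_lt(max(abs(got - want)), 1e-6)
  # h = 1 with identity output projection reduces to plain attention
  p1 <- p; p1$Wo <- diag(d); p1$bo <- numeric(d)
  got1 <- multi_head_attention(X, p1, 1)
  want1 <- sdpa_oracle(Q, K, V)$output
  expect_lt(max(abs(got1 - want1)), 1e-8)
  expect_error(multi_head_attention(X, p, 3), "divisible")
})

test_that("encoder block normalizes, is deterministic in eval mode, and degrades to stacked layer norms", {
  set.seed(41)
  cfg <- tiny_cfg()
  p <- init_params(cfg, 2)$temporal$layers[[1]]
  X <- matrix(rnorm(12 * 8), 12, 8)
  y1 <- encoder_block(X, p, h = 2, dropout = 0, mode = "eval")
  y2 <- encoder_block(X, p, h = 2, dropout = 0, mode = "eval")
  expect_identical(y1, y2)
  expect_identical(dim(y1), dim(X))
  expect_error(encoder_block(X * NA, p, h = 2), "non-finite")

  # layer-norm rows have mean 0, variance 1 before scale/shift
  ln <- sttcnn:::layernorm_fwd(X, rep(1, 8), rep(0, 8))$out
  expect_lt(max(abs(rowMeans(ln))), 1e-4)
  expect_equal(apply(ln, 1, function(r) mean(r^2)), rep(1, 12), tolerance = 1e-4)

  # zero attention + zero feed-forward weights: block is LN(LN(X))
  p0 <- p
  for (nm in c("Wq", "Wk", "Wv", "Wo", "ff_W1", "ff_W2"))
    p0[[nm]] <- p0[[nm]] * 0
  ln1 <- sttcnn:::layernorm_fwd(X, p0$ln1_g, p0$ln1_b)$out
  want <- sttcnn:::layernorm_fwd(ln1, p0$ln2_g, p0$ln2_b)$out
  expect_equal(encoder_block(X, p0, h = 2), want, tolerance = 1e-12)
})

test_that("dropout only acts in train mode and preserves expectation", {
  X <- matrix(1, 50, 40)
  expect_identical(sttcnn:::dropout_fwd(X, 0.3, "eval")$out, X)
  set.seed(5)
  d <- sttcnn:::dropout_fwd(X, 0.3, "train")
  expect_true(any(d$out == 0))
  expect_equal(mean(d$out), 1, tolerance = 0.05)  # inverted scaling
})
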