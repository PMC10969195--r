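# Network primitives, each as a forward (with cache) / backward pair.
# Everything operates on one sample at a time: X is a seq_len x features
# matrix; batching is a loop in the training code with gradient accumulation.

addb <- function(M, b) M + rep(b, each = nrow(M))

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# d/dS of Y = softmax_rows(S), given dY and Y
softmax_rows_bwd <- function(dY, Y) Y * (dY - rowSums(dY * Y))

#' Sinusoidal positional encoding table
#'
#' Builds the deterministic sine/cosine table added to token embeddings so
#' that token order survives permutation-invariant attention: row `pos + 1`
#' holds `sin(pos / 10000^(2i/d))` at even (0-based) dimensions `2i` and
#' `cos(pos / 10000^(2i/d))` at odd dimensions `2i + 1`.
#'
#' @param max_pos number of positions (rows); positions are 0-based.
#' @param d embedding dimension (even).
#' @return a `max_pos` x `d` matrix with entries in \[-1, 1\].
#' @examples
#' pe <- positional_encoding(4, 8)
#' pe[1, ]  # pos 0: sin terms 0, cos terms 1
#' @export
positional_encoding <- function(max_pos, d) {
  stopifnot(max_pos >= 1, d >= 2)
  if (d %% 2 != 0) stopf("positional encoding needs an even dimension, got %d", d)
  pos <- 0:(max_pos - 1)
  i <- 0:(d / 2 - 1)
  ang <- outer(pos, 1 / 10000^(2 * i / d))   # max_pos x d/2
  pe <- matrix(0, max_pos, d)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` with a row-wise softmax, the
#' similarity-weighted value aggregation at the heart of the transformer
#' encoder.
#'
#' @param Q,K,V numeric matrices: `n x d_k`, `m x d_k`, `m x d_v`.
#' @param d_k key dimension used in the scaling factor; defaults to
#'   `ncol(Q)`.
#' @return list with `output` (`n x d_v`) and `weights` (`n x m`,
#'   nonnegative rows summing to 1).
#' @examples
#' scaled_dot_product_attention(matrix(1), matrix(1), matrix(2))$output
#' @export
scaled_dot_product_attention <- function(Q, K, V, d_k = ncol(Q)) {
  if (ncol(Q) != ncol(K)) stopf("Q (%d cols) and K (%d cols) disagree", ncol(Q), ncol(K))
  if (nrow(K) != nrow(V)) stopf("K (%d rows) and V (%d rows) disagree", nrow(K), nrow(V))
  A <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  list(output = A %*% V, weights = A)
}

#' Multi-head attention
#'
#' Runs `h` scaled dot-product attention heads on learned subspace
#' projections of the input and reprojects the concatenated head outputs:
#' `Concat(head_1, ..., head_h) W_O`, each head attending over `d_model / h`
#' dimensional projections.
#'
#' @param X `seq_len x d_model` input.
#' @param p named list of projection parameters: `Wq`, `Wk`, `Wv`, `Wo`
#'   (`d_model x d_model`) and biases `bq`, `bk`, `bv`, `bo` (`d_model`).
#' @param h number of heads; must divide `d_model`.
#' @return `seq_len x d_model` matrix.
#' @export
multi_head_attention <- function(X, p, h) {
  mha_fwd(X, p, h)$out
}

mha_fwd <- function(X, p, h) {
  d <- ncol(X)
  if (d %% h != 0) stopf("d_model %d not divisible by h = %d", d, h)
  dk <- d / h
  Q <- addb(X %*% p$Wq, p$bq)
  K <- addb(X %*% p$Wk, p$bk)
  V <- addb(X %*% p$Wv, p$bv)
  Hcat <- matrix(0, nrow(X), d)
  A_list <- vector("list", h)
  for (j in seq_len(h)) {
    cols <- (j - 1) * dk + seq_len(dk)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
    A_list[[j]] <- A
    Hcat[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- addb(Hcat %*% p$Wo, p$bo)
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, A = A_list, Hcat = Hcat, h = h))
}

mha_bwd <- function(dO, cache, p) {
  X <- cache$X; h <- cache$h
  d <- ncol(X); dk <- d / h
  g <- list(Wo = t(cache$Hcat) %*% dO, bo = colSums(dO))
  dH <- dO %*% t(p$Wo)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (j in seq_len(h)) {
    cols <- (j - 1) * dk + seq_len(dk)
    A <- cache$A[[j]]
    dHj <- dH[, cols, drop = FALSE]
    Vj <- cache$V[, cols, drop = FALSE]
    dA <- dHj %*% t(Vj)
    dV[, cols] <- t(A) %*% dHj
    dS <- softmax_rows_bwd(dA, A)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE] / sqrt(dk)
  }
  g$Wq <- t(X) %*% dQ; g$bq <- colSums(dQ)
  g$Wk <- t(X) %*% dK; g$bk <- colSums(dK)
  g$Wv <- t(X) %*% dV; g$bv <- colSums(dV)
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dX, grads = g)
}

# --- layer normalization (per token/row, population variance, eps 1e-5) ------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  out <- addb(xhat * rep(g, each = nrow(X)), b)
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  d <- ncol(dY)
  dxhat <- dY * rep(cache$g, each = nrow(dY))
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# --- position-wise feed-forward: Linear -> ReLU -> Linear --------------------

ffn_fwd <- function(X, p) {
  H1 <- addb(X %*% p$ff_W1, p$ff_b1)
  R <- H1 * (H1 > 0)
  out <- addb(R %*% p$ff_W2, p$ff_b2)
  list(out = out, cache = list(X = X, H1 = H1, R = R))
}

ffn_bwd <- function(dY, cache, p) {
  g <- list(ff_W2 = t(cache$R) %*% dY, ff_b2 = colSums(dY))
  dH1 <- (dY %*% t(p$ff_W2)) * (cache$H1 > 0)
  g$ff_W1 <- t(cache$X) %*% dH1
  g$ff_b1 <- colSums(dH1)
  list(dX = dH1 %*% t(p$ff_W1), grads = g)
}

# --- inverted dropout --------------------------------------------------------

dropout_fwd <- function(X, rate, mode) {
  if (mode != "train" || rate <= 0) return(list(out = X, mask = NULL))
  mask <- (stats::runif(length(X)) >= rate) / (1 - rate)
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# --- 3x3 same-padding convolution over an H x W x Cin map --------------------
# Implemented as nine shifted matrix products; output kept as (H*W) x K with
# column-major pixel order, matching array(HxWxK) reshapes.

conv2d_fwd <- function(X, Wt, b) {
  dm <- dim(X); H <- dm[1]; W <- dm[2]; Cin <- dm[3]; K <- dim(Wt)[4]
  Xp <- array(0, c(H + 2, W + 2, Cin))
  Xp[1 + seq_len(H), 1 + seq_len(W), ] <- X
  Y <- matrix(rep(b, each = H * W), H * W, K)
  for (di in 0:2) for (dj in 0:2) {
    Xs <- matrix(Xp[di + seq_len(H), dj + seq_len(W), ], H * W, Cin)
    Y <- Y + Xs %*% matrix(Wt[di + 1, dj + 1, , ], Cin, K)
  }
  list(out = Y, cache = list(Xp = Xp, H = H, W = W, Cin = Cin, K = K))
}

conv2d_bwd <- function(dY, cache, Wt) {
  H <- cache$H; W <- cache$W; Cin <- cache$Cin; K <- cache$K
  dW <- array(0, dim(Wt))
  dXp <- array(0, dim(cache$Xp))
  for (di in 0:2) for (dj in 0:2) {
    Xs <- matrix(cache$Xp[di + seq_len(H), dj + seq_len(W), ], H * W, Cin)
    dW[di + 1, dj + 1, , ] <- t(Xs) %*% dY
    dXs <- dY %*% t(matrix(Wt[di + 1, dj + 1, , ], Cin, K))
    dXp[di + seq_len(H), dj + seq_len(W), ] <-
      dXp[di + seq_len(H), dj + seq_len(W), , drop = FALSE] + array(dXs, c(H, W, Cin))
  }
  list(dX = dXp[1 + seq_len(H), 1 + seq_len(W), , drop = FALSE],
       dW = dW, db = colSums(dY))
}

# --- 2x2 max pooling, stride 2, trailing row/column dropped ------------------

maxpool_fwd <- function(X) {
  dm <- dim(X); H <- dm[1]; W <- dm[2]; K <- dm[3]
  H2 <- H %/% 2; W2 <- W %/% 2
  ro <- seq_len(H2) * 2 - 1; co <- seq_len(W2) * 2 - 1
  cand <- cbind(as.vector(X[ro, co, , drop = FALSE]),
                as.vector(X[ro + 1, co, , drop = FALSE]),
                as.vector(X[ro, co + 1, , drop = FALSE]),
                as.vector(X[ro + 1, co + 1, , drop = FALSE]))
  idx <- max.col(cand, ties.method = "first")
  n <- nrow(cand)
  out <- cand[cbind(seq_len(n), idx)]
  list(out = out, cache = list(idx = idx, H = H, W = W, K = K, H2 = H2, W2 = W2))
}

maxpool_bwd <- function(dY, cache) {
  H <- cache$H; W <- cache$W; K <- cache$K; H2 <- cache$H2; W2 <- cache$W2
  q <- seq_len(H2 * W2 * K) - 1L
  r <- q %% H2 + 1L
  cc <- (q %/% H2) %% W2 + 1L
  k <- q %/% (H2 * W2) + 1L
  dr <- c(0L, 1L, 0L, 1L)[cache$idx]
  dc <- c(0L, 0L, 1L, 1L)[cache$idx]
  flat <- (2L * r - 1L + dr) + (2L * cc - 2L + dc) * H + (k - 1L) * H * W
  dX <- array(0, c(H, W, K))
  dX[flat] <- dY
  dX
}
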