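#' Architecture configuration
#'
#' Collects every hyperparameter of the dual-branch transformer + CNN
#' classifier and selects which of the four variants to build:
#'
#' * `"st-tcnn"` — both branches, convolutional fusion head (the full model);
#' * `"st-t"` — both branches, concatenated features straight into the
#'   fully connected classifier (no CNN);
#' * `"s-t"` — spatial branch only (attention across channels), CNN head;
#' * `"t-t"` — temporal branch only (attention across time points), CNN head.
#'
#' Defaults follow the reference training regime: embedding width 64, 8
#' attention heads, one encoder block per branch, feed-forward width
#' 4 x d_model, dropout 0.3, 64 convolution kernels of size 3 x 3 and one
#' 2 x 2 max-pooling stage.
#'
#' @param variant one of `"st-tcnn"`, `"st-t"`, `"s-t"`, `"t-t"`
#'   (case-insensitive).
#' @param n_channels,window_samples,n_classes input/output geometry.
#' @param d_model token embedding dimension (even, divisible by `h`).
#' @param h number of attention heads.
#' @param n_encoder_layers encoder blocks per branch.
#' @param ff_dim feed-forward hidden width; default `4 * d_model`.
#' @param dropout dropout rate in \[0, 1), applied after attention, after the
#'   feed-forward sublayer, and before the final classifier.
#' @param conv_kernels number of kernels in each convolution layer.
#' @param use_pe add the sinusoidal positional encoding to the embeddings.
#' @param input_standardize z-score each segment per channel before
#'   embedding (raw microvolt magnitudes destabilize dot-product attention).
#' @return an object of class `model_config`.
#' @export
model_config <- function(variant = c("st-tcnn", "st-t", "s-t", "t-t"),
                         n_channels, window_samples, n_classes,
                         d_model = 64, h = 8, n_encoder_layers = 1,
                         ff_dim = 4 * d_model, dropout = 0.3,
                         conv_kernels = 64, use_pe = TRUE,
                         input_standardize = TRUE) {
  variant <- match.arg(tolower(variant[1]), c("st-tcnn", "st-t", "s-t", "t-t"))
  stopifnot(is_count(n_channels), is_count(window_samples), is_count(n_classes),
            n_classes >= 2, is_count(d_model), is_count(h),
            is_count(n_encoder_layers), is_count(ff_dim), is_count(conv_kernels))
  if (d_model %% h != 0) stopf("d_model (%d) must be divisible by h (%d)", d_model, h)
  if (d_model %% 2 != 0) stopf("d_model must be even for the sinusoidal encoding")
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  structure(list(variant = variant, n_channels = as.integer(n_channels),
                 window_samples = as.integer(window_samples),
                 n_classes = as.integer(n_classes), d_model = as.integer(d_model),
                 h = as.integer(h), n_encoder_layers = as.integer(n_encoder_layers),
                 ff_dim = as.integer(ff_dim), dropout = dropout,
                 conv_kernels = as.integer(conv_kernels), use_pe = isTRUE(use_pe),
                 input_standardize = isTRUE(input_standardize)),
            class = "model_config")
}

cfg_branches <- function(cfg) switch(cfg$variant,
  "st-tcnn" = c("spatial", "temporal"),
  "st-t"    = c("spatial", "temporal"),
  "s-t"     = "spatial",
  "t-t"     = "temporal")

cfg_has_cnn <- function(cfg) cfg$variant != "st-t"

branch_seq_len <- function(cfg, branch)
  if (branch == "spatial") cfg$n_channels else cfg$window_samples

branch_in_dim <- function(cfg, branch)
  if (branch == "spatial") cfg$window_samples else cfg$n_channels

# Total token count of the concatenated feature map fed to the head.
cfg_map_rows <- function(cfg)
  sum(vapply(cfg_branches(cfg), function(b) branch_seq_len(cfg, b), 0L))

cfg_fc_in <- function(cfg) {
  L <- cfg_map_rows(cfg)
  if (cfg_has_cnn(cfg)) (L %/% 2) * (cfg$d_model %/% 2) * cfg$conv_kernels
  else L * cfg$d_model
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_encoder_layer <- function(d, ff_dim) {
  list(Wq = glorot(d, d), bq = numeric(d),
       Wk = glorot(d, d), bk = numeric(d),
       Wv = glorot(d, d), bv = numeric(d),
       Wo = glorot(d, d), bo = numeric(d),
       ln1_g = rep(1, d), ln1_b = numeric(d),
       ff_W1 = glorot(d, ff_dim), ff_b1 = numeric(ff_dim),
       ff_W2 = glorot(ff_dim, d), ff_b2 = numeric(d),
       ln2_g = rep(1, d), ln2_b = numeric(d))
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains; the parameter
#' tree's shape is a pure function of the configuration.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for the draws.
#' @return nested named list of numeric arrays.
#' @export
init_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    p <- list()
    for (b in cfg_branches(cfg)) {
      in_dim <- branch_in_dim(cfg, b)
      p[[b]] <- list(emb_W = glorot(in_dim, cfg$d_model),
                     emb_b = numeric(cfg$d_model),
                     layers = lapply(seq_len(cfg$n_encoder_layers), function(i)
                       init_encoder_layer(cfg$d_model, cfg$ff_dim)))
    }
    K <- cfg$conv_kernels
    if (cfg_has_cnn(cfg)) {
      p$head <- list(
        conv1_W = glorot(9, 9 * K, dims = c(3, 3, 1, K)),
        conv1_b = numeric(K),
        conv2_W = glorot(9 * K, 9 * K, dims = c(3, 3, K, K)),
        conv2_b = numeric(K),
        fc_W = glorot(cfg_fc_in(cfg), cfg$n_classes),
        fc_b = numeric(cfg$n_classes))
    } else {
      p$head <- list(fc_W = glorot(cfg_fc_in(cfg), cfg$n_classes),
                     fc_b = numeric(cfg$n_classes))
    }
    p
  })
}

#' Count trainable parameters
#'
#' @param cfg a [model_config()].
#' @return integer: total number of scalar parameters implied by the
#'   configuration.
#' @export
count_params <- function(cfg) tree_n_params(init_params(cfg, seed = 0L))

# --- encoder block -----------------------------------------------------------

#' Transformer encoder block
#'
#' One post-norm encoder block: multi-head self-attention and a
#' position-wise feed-forward network (Linear -> ReLU -> Linear), each
#' followed by dropout, a residual connection and layer normalization.
#' Eval mode disables dropout and is deterministic.
#'
#' @param X `seq_len x d_model` input matrix.
#' @param p layer parameter list as built by [init_params()] (one element of
#'   `params[[branch]]$layers`).
#' @param h number of attention heads.
#' @param dropout dropout rate.
#' @param mode `"eval"` or `"train"`.
#' @return `seq_len x d_model` matrix.
#' @export
encoder_block <- function(X, p, h, dropout = 0, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (any(!is.finite(X))) stopf("non-finite values in encoder input")
  encoder_fwd(X, p, h, dropout, mode)$out
}

encoder_fwd <- function(X, p, h, dropout, mode) {
  att <- mha_fwd(X, p, h)
  d1 <- dropout_fwd(att$out, dropout, mode)
  ln1 <- layernorm_fwd(X + d1$out, p$ln1_g, p$ln1_b)
  ff <- ffn_fwd(ln1$out, p)
  d2 <- dropout_fwd(ff$out, dropout, mode)
  ln2 <- layernorm_fwd(ln1$out + d2$out, p$ln2_g, p$ln2_b)
  list(out = ln2$out,
       cache = list(att = att$cache, m1 = d1$mask, ln1 = ln1$cache,
                    ff = ff$cache, m2 = d2$mask, ln2 = ln2$cache))
}

encoder_bwd <- function(dY, cache, p) {
  l2 <- layernorm_bwd(dY, cache$ln2)
  g <- list(ln2_g = l2$dg, ln2_b = l2$db)
  dF <- dropout_bwd(l2$dX, cache$m2)
  fb <- ffn_bwd(dF, cache$ff, p)
  g[names(fb$grads)] <- fb$grads
  dN1 <- l2$dX + fb$dX
  l1 <- layernorm_bwd(dN1, cache$ln1)
  g$ln1_g <- l1$dg; g$ln1_b <- l1$db
  dA <- dropout_bwd(l1$dX, cache$m1)
  ab <- mha_bwd(dA, cache$att, p)
  g[names(ab$grads)] <- ab$grads
  list(dX = l1$dX + ab$dX, grads = g)
}

# --- branch: embed tokens, add PE, run encoder stack -------------------------

branch_fwd <- function(Xin, bp, cfg, pe, mode) {
  E <- addb(Xin %*% bp$emb_W, bp$emb_b)
  if (cfg$use_pe) E <- E + pe
  caches <- vector("list", cfg$n_encoder_layers)
  H <- E
  for (l in seq_len(cfg$n_encoder_layers)) {
    enc <- encoder_fwd(H, bp$layers[[l]], cfg$h, cfg$dropout, mode)
    H <- enc$out
    caches[[l]] <- enc$cache
  }
  list(out = H, cache = list(Xin = Xin, enc = caches))
}

branch_bwd <- function(dY, cache, bp, cfg) {
  g <- list(layers = vector("list", cfg$n_encoder_layers))
  dH <- dY
  for (l in rev(seq_len(cfg$n_encoder_layers))) {
    eb <- encoder_bwd(dH, cache$enc[[l]], bp$layers[[l]])
    g$layers[[l]] <- eb$grads
    dH <- eb$dX
  }
  g$emb_W <- t(cache$Xin) %*% dH
  g$emb_b <- colSums(dH)
  g
}

#' Run one branch of the model over a batch of segments
#'
#' Arranges each segment for the requested branch (spatial: tokens are
#' channels, features are the time course; temporal: tokens are time points,
#' features are the cross-channel vector), embeds tokens linearly to
#' `d_model`, adds the positional encoding (unless disabled), and applies
#' the encoder stack.
#'
#' @param x_batch array `[batch, n_channels, window_samples]` (a
#'   `segment_dataset$x`), or a single channels x samples matrix.
#' @param branch `"spatial"` or `"temporal"`.
#' @param params full parameter tree from [init_params()].
#' @param cfg the [model_config()].
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @return array `[batch, seq_len, d_model]`.
#' @export
branch_forward <- function(x_batch, branch = c("spatial", "temporal"),
                           params, cfg, mode = c("eval", "train")) {
  branch <- match.arg(branch); mode <- match.arg(mode)
  if (is.matrix(x_batch)) x_batch <- array(x_batch, c(1, dim(x_batch)))
  if (!branch %in% cfg_branches(cfg))
    stopf("variant '%s' has no %s branch", cfg$variant, branch)
  stopifnot(dim(x_batch)[2] == cfg$n_channels,
            dim(x_batch)[3] == cfg$window_samples)
  L <- branch_seq_len(cfg, branch)
  pe <- positional_encoding(L, cfg$d_model)
  out <- array(0, c(dim(x_batch)[1], L, cfg$d_model))
  for (i in seq_len(dim(x_batch)[1])) {
    x <- x_batch[i, , ]
    if (cfg$input_standardize) x <- standardize_segment(x)
    Xin <- if (branch == "spatial") x else t(x)
    out[i, , ] <- branch_fwd(Xin, params[[branch]], cfg, pe, mode)$out
  }
  out
}

standardize_segment <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2)) + 1e-8
  (x - mu) / s
}

# --- full forward/backward for one segment -----------------------------------

model_fwd_sample <- function(x, params, cfg, pe_list, mode) {
  if (cfg$input_standardize) x <- standardize_segment(x)
  branches <- cfg_branches(cfg)
  bout <- list(); bcache <- list()
  for (b in branches) {
    Xin <- if (b == "spatial") x else t(x)
    r <- branch_fwd(Xin, params[[b]], cfg, pe_list[[b]], mode)
    bout[[b]] <- r$out; bcache[[b]] <- r$cache
  }
  M <- do.call(rbind, unname(bout))           # map_rows x d_model
  hp <- params$head
  cache <- list(branches = bcache, seq_lens = vapply(bout, nrow, 0L))
  if (cfg_has_cnn(cfg)) {
    c1 <- conv2d_fwd(array(M, c(nrow(M), ncol(M), 1)), hp$conv1_W, hp$conv1_b)
    r1 <- c1$out * (c1$out > 0)
    c2 <- conv2d_fwd(array(r1, c(nrow(M), ncol(M), cfg$conv_kernels)),
                     hp$conv2_W, hp$conv2_b)
    r2 <- c2$out * (c2$out > 0)
    mp <- maxpool_fwd(array(r2, c(nrow(M), ncol(M), cfg$conv_kernels)))
    v <- mp$out
    cache$c1 <- c1$cache; cache$a1 <- c1$out; cache$c2 <- c2$cache
    cache$a2 <- c2$out; cache$mp <- mp$cache
  } else {
    v <- as.vector(M)
  }
  dv <- dropout_fwd(matrix(v, 1), cfg$dropout, mode)
  logits <- as.vector(dv$out %*% hp$fc_W + hp$fc_b)
  cache$vmask <- dv$mask; cache$v <- as.vector(dv$out)
  e <- exp(logits - max(logits))
  list(probs = e / sum(e), logits = logits, cache = cache)
}

model_bwd_sample <- function(dlogits, cache, params, cfg) {
  hp <- params$head
  g <- list(head = list(fc_W = cache$v %o% dlogits, fc_b = dlogits))
  dv <- as.vector(hp$fc_W %*% dlogits)
  dv <- dropout_bwd(dv, cache$vmask)
  L <- sum(cache$seq_lens); d <- cfg$d_model
  if (cfg_has_cnn(cfg)) {
    dmp <- maxpool_bwd(dv, cache$mp)
    dr2 <- matrix(dmp, L * d, cfg$conv_kernels) * (cache$a2 > 0)
    cb2 <- conv2d_bwd(dr2, cache$c2, hp$conv2_W)
    g$head$conv2_W <- cb2$dW; g$head$conv2_b <- cb2$db
    dr1 <- matrix(cb2$dX, L * d, cfg$conv_kernels) * (cache$a1 > 0)
    cb1 <- conv2d_bwd(dr1, cache$c1, hp$conv1_W)
    g$head$conv1_W <- cb1$dW; g$head$conv1_b <- cb1$db
    dM <- matrix(cb1$dX, L, d)
  } else {
    dM <- matrix(dv, L, d)
  }
  offset <- 0L
  for (b in cfg_branches(cfg)) {
    Lb <- cache$seq_lens[[b]]
    dYb <- dM[offset + seq_len(Lb), , drop = FALSE]
    g[[b]] <- branch_bwd(dYb, cache$branches[[b]], params[[b]], cfg)
    offset <- offset + Lb
  }
  g[c(cfg_branches(cfg), "head")]
}

pe_tables <- function(cfg) {
  out <- list()
  for (b in cfg_branches(cfg))
    out[[b]] <- positional_encoding(branch_seq_len(cfg, b), cfg$d_model)
  out
}

#' Class probabilities for a batch of segments
#'
#' Deterministic eval-mode forward pass of the configured variant.
#'
#' @param x_batch array `[batch, n_channels, window_samples]` or a single
#'   channels x samples matrix.
#' @param params parameter tree from [init_params()] or a fitted model.
#' @param cfg the [model_config()].
#' @param mode `"eval"` or `"train"` (train mode draws dropout masks from
#'   the current RNG state).
#' @return `batch x n_classes` matrix of class probabilities; rows sum to 1.
#' @export
predict_proba <- function(x_batch, params, cfg, mode = "eval") {
  if (is.matrix(x_batch)) x_batch <- array(x_batch, c(1, dim(x_batch)))
  stopifnot(dim(x_batch)[2] == cfg$n_channels,
            dim(x_batch)[3] == cfg$window_samples)
  pe <- pe_tables(cfg)
  n <- dim(x_batch)[1]
  P <- matrix(0, n, cfg$n_classes)
  for (i in seq_len(n))
    P[i, ] <- model_fwd_sample(x_batch[i, , ], params, cfg, pe, mode)$probs
  colnames(P) <- NULL
  P
}
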