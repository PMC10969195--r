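test_that("branch sequence lengths follow the input arrangement", {
  # full-scale geometry: 62 channels x 600 samples, embedding width 64
  cfg <- model_config("st-t", n_channels = 62, window_samples = 600,
                      n_classes = 3)
  p <- init_params(cfg, 1)
  set.seed(2)
  x <- array(rnorm(2 * 62 * 600), c(2, 62, 600))
  s_out <- branch_forward(x, "spatial", p, cfg)
  t_out <- branch_forward(x, "temporal", p, cfg)
  expect_identical(dim(s_out), c(2L, 62L, 64L))    # tokens = channels
  expect_identical(dim(t_out), c(2L, 600L, 64L))   # tokens = time points
})

test_that("spatial branch is channel-permutation-equivariant iff PE is off", {
  cfg_off <- model_config("s-t", n_channels = 6, window_samples = 20,
                          n_classes = 2, d_model = 8, h = 2, conv_kernels = 2,
                          dropout = 0, use_pe = FALSE)
  cfg_on <- cfg_off; cfg_on$use_pe <- TRUE
  p <- init_params(cfg_off, 3)
  set.seed(8)
  x <- matrix(rnorm(6 * 20), 6, 20)
  perm <- c(4, 1, 6, 2, 5, 3)
  out <- branch_forward(x, "spatial", p, cfg_off)[1, , ]
  out_p <- branch_forward(x[perm, ], "spatial", p, cfg_off)[1, , ]
  expect_lt(max(abs(out_p - out[perm, ])), 1e-5)   # equivariant without PE
  out_on <- branch_forward(x, "spatial", p, cfg_on)[1, , ]
  out_on_p <- branch_forward(x[perm, ], "spatial", p, cfg_on)[1, , ]
  expect_gt(max(abs(out_on_p - out_on[perm, ])), 1e-3)  # PE breaks the symmetry
})

test_that("class probabilities are well-formed for every variant", {
  set.seed(12)
  x <- array(rnorm(4 * 5 * 12), c(4, 5, 12))
  for (v in c("st-tcnn", "st-t", "s-t", "t-t")) {
    cfg <- tiny_cfg(v)
    p <- init_params(cfg, 5)
    P <- predict_proba(x, p, cfg)
    expect_identical(dim(P), c(4L, 3L))
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
    # eval-mode determinism
    expect_identical(P, predict_proba(x, p, cfg))
  }
  # four-quadrant task gives a 4-column output
  cfg4 <- tiny_cfg(n_classes = 4)
  expect_identical(ncol(predict_proba(x, init_params(cfg4, 1), cfg4)), 4L)
})

test_that("all-zero classifier weights yield uniform class probabilities", {
  cfg <- tiny_cfg("st-t")
  p <- init_params(cfg, 2)
  p$head$fc_W <- p$head$fc_W * 0
  p$head$fc_b <- p$head$fc_b * 0
  P <- predict_proba(array(rnorm(2 * 5 * 12), c(2, 5, 12)), p, cfg)
  expect_equal(as.vector(P), rep(1 / 3, 6), tolerance = 1e-12)
})

test_that("parameter count is a pure function of the configuration", {
  c1 <- model_config("st-tcnn", n_channels = 8, window_samples = 96,
                     n_classes = 2, d_model = 16, h = 4, conv_kernels = 8)
  c2 <- model_config("st-t", n_channels = 8, window_samples = 96,
                     n_classes = 3, d_model = 16, h = 4)
  c3 <- model_config("t-t", n_channels = 5, window_samples = 12, n_classes = 3,
                     d_model = 8, h = 2, ff_dim = 16, conv_kernels = 3)
  expect_identical(count_params(c1), 15578)
  expect_identical(count_params(c2), 13251)
  expect_identical(count_params(c3), 981)
  # independent of the initialization draw
  expect_identical(sttcnn:::tree_n_params(init_params(c1, 99)), 15578)
})

test_that("backpropagation matches finite differences on every variant", {
  set.seed(42)
  x <- matrix(rnorm(5 * 12), 5, 12)
  getleaf <- function(p, path) { for (k in path) p <- p[[k]]; p }
  setleaf <- function(p, path, v) {
    if (length(path) == 1) { p[[path[[1]]]] <- v; return(p) }
    p[[path[[1]]]] <- setleaf(p[[path[[1]]]], path[-1], v); p
  }
  for (variant in c("st-tcnn", "st-t", "s-t", "t-t")) {
    cfg <- tiny_cfg(variant)
    params <- init_params(cfg, 3)
    pe <- sttcnn:::pe_tables(cfg)
    nll <- function(p) {
      fw <- sttcnn:::model_fwd_sample(x, p, cfg, pe, "eval")
      -log(fw$probs[2])
    }
    fw <- sttcnn:::model_fwd_sample(x, params, cfg, pe, "eval")
    dlog <- fw$probs; dlog[2] <- dlog[2] - 1
    g <- sttcnn:::model_bwd_sample(dlog, fw$cache, params, cfg)
    br <- sttcnn:::cfg_branches(cfg)[1]
    paths <- list(list("head", "fc_W"), list(br, "emb_W"),
                  list(br, "layers", 1L, "Wq"), list(br, "layers", 1L, "ln2_b"),
                  list(br, "layers", 1L, "ff_W1"))
    if (variant != "st-t") paths <- c(paths, list(list("head", "conv1_W"),
                                                  list("head", "conv2_b")))
    eps <- 1e-5
    for (path in paths) {
      leaf <- getleaf(params, path); gleaf <- getleaf(g, path)
      for (ii in sample(length(leaf), min(3, length(leaf)))) {
        pp <- leaf; pp[ii] <- pp[ii] + eps
        lp <- nll(setleaf(params, path, pp))
        pp[ii] <- pp[ii] - 2 * eps
        lm <- nll(setleaf(params, path, pp))
        num <- (lp - lm) / (2 * eps)
        expect_equal(gleaf[ii], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("checkpoints round-trip configuration and predictions", {
  cfg <- tiny_cfg("st-tcnn")
  set.seed(3)
  ds_x <- array(rnorm(3 * 5 * 12), c(3, 5, 12))
  model <- structure(list(params = init_params(cfg, 7), config = cfg,
                          history = data.frame(), n_train = 0L, task = "pnn",
                          class_names = c("a", "b", "c"),
                          stopped_epoch = NA_integer_, call = NULL),
                     class = "sttcnn")
  path <- file.path(withr::local_tempdir(), "ckpt.json")
  save_sttcnn(model, path)
  back <- load_sttcnn(path)
  expect_identical(back$config$variant, "st-tcnn")
  expect_equal(predict(back, ds_x), predict(model, ds_x), tolerance = 1e-12)
})
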