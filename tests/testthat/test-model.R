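test_that("model configuration enforces its invariants", {
  expect_error(model_config("patho", n_heads = 3L, d_model = 8L), "divide")
  expect_error(model_config("patho", dropout = 1), "dropout")
  expect_error(model_config("disease", site_width = 537L), "binary task")
  cfg <- model_config("patho")
  expect_equal(cfg$d_k, 32L)
  expect_equal(cfg$lstm_hidden, 512L)
  expect_equal(cfg$site_width, 537L)
  expect_equal(model_config("disease")$n_out, 15L)
})

test_that("multi-head self-attention is row-stochastic and matches hand math", {
  set.seed(5)
  d <- 4L
  X <- matrix(rnorm(3 * d), 3, d)
  I <- diag(d)
  r <- multihead_self_attention(X, I, I, I, I, n_heads = 1L)
  A <- r$attention[[1]]
  expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-6)
  # hand-computed softmax(X X^T / sqrt(d)) X
  S <- X %*% t(X) / sqrt(d)
  Ah <- exp(S - apply(S, 1, max)); Ah <- Ah / rowSums(Ah)
  expect_equal(r$output, Ah %*% X, tolerance = 1e-12)
  # single position: attention weight exactly one, output = V %*% Wo
  Wo <- matrix(rnorm(d * d), d, d)
  r1 <- multihead_self_attention(X[1, , drop = FALSE], I, I, I, Wo)
  expect_equal(r1$attention[[1]], matrix(1, 1, 1))
  expect_equal(r1$output, X[1, , drop = FALSE] %*% Wo)
  # row-stochastic under random inputs and projections, multiple heads
  for (draw in 1:100) {
    n <- sample(2:6, 1)
    X <- matrix(rnorm(n * 8), n, 8)
    Ws <- replicate(4, matrix(rnorm(64), 8, 8), simplify = FALSE)
    rr <- multihead_self_attention(X, Ws[[1]], Ws[[2]], Ws[[3]], Ws[[4]],
                                   n_heads = 2L)
    for (A in rr$attention) {
      expect_equal(rowSums(A), rep(1, n), tolerance = 1e-6)
    }
  }
})

test_that("disease-protein cross-attention averages over positions", {
  set.seed(6)
  d <- 8L
  E <- matrix(rnorm(15 * d), 15, d)
  P <- matrix(rnorm(101 * d), 101, d)
  r <- fuse_disease_protein(P, E)
  expect_equal(dim(r$embedding), c(15L, d))
  expect_equal(rowSums(r$attention), rep(1, 15), tolerance = 1e-6)
  # constant protein embedding: any attention distribution averages it
  Pc <- matrix(rep(rnorm(d), each = 101), 101, d)
  rc <- fuse_disease_protein(Pc, E)
  expect_equal(rc$embedding, matrix(rep(Pc[1, ], each = 15), 15, d),
               tolerance = 1e-9)
  # pad masking removes positions from the support
  pm <- c(rep(TRUE, 50), rep(FALSE, 51))
  rm <- fuse_disease_protein(P, E, pm)
  expect_true(all(rm$attention[, 51:101] < 1e-12))
})

test_that("wild-mutant fusion subtracts and attends as stated", {
  set.seed(7)
  Wd <- matrix(rnorm(15 * 8), 15, 8)
  Md <- matrix(rnorm(15 * 8), 15, 8)
  r <- fuse_wild_mutant(Wd, Md)
  expect_equal(r$sub_dis_prot, Wd - Md)
  expect_equal(fuse_wild_mutant(Md, Wd)$sub_dis_prot, -(Wd - Md))
  expect_equal(fuse_wild_mutant(Wd, Wd)$sub_dis_prot, Wd * 0)
  # K = 1: softmax over a single row makes attention output the mutant row
  r1 <- fuse_wild_mutant(Wd[1, , drop = FALSE], Md[1, , drop = FALSE])
  expect_equal(r1$attn_dis_prot, Md[1, , drop = FALSE])
  expect_equal(rowSums(r$attention), rep(1, 15), tolerance = 1e-6)
})

test_that("forward pass honours shape contracts and is deterministic", {
  fx <- fixture_feature_set()
  cfg <- fixture_tiny_config("patho", fx$feats$input_width)
  params <- init_model(cfg, seed = 2L)
  fb <- feature_batch(fx$feats, 1:6, cfg)
  fw <- model_forward(params, cfg, fb)
  ns <- asNamespace("tmpatho")
  z <- ns$tp_value(fw$tape, fw$logits)
  expect_equal(dim(z), c(6L, 1L))
  probs <- 1 / (1 + exp(-z))
  expect_true(all(probs > 0 & probs < 1))
  # evaluation mode is bit-reproducible
  fw2 <- model_forward(params, cfg, fb)
  expect_identical(z, ns$tp_value(fw2$tape, fw2$logits))
  # protein embedding contract
  P <- ns$tp_value(fw$tape, fw$prot_wild)
  expect_equal(dim(P), c(6L * 101L, cfg$d_model))
  # transmembrane branch width: linear + conv channels
  TME <- ns$tp_value(fw$tape, fw$tm_embedding)
  expect_equal(ncol(TME), cfg$tm_linear_width +
                 cfg$conv_channels * length(cfg$conv_kernels))
  # disease task: fifteen outputs, site vector rejected
  cfgd <- fixture_tiny_config("disease", fx$feats$input_width)
  paramsd <- init_model(cfgd, seed = 2L)
  fbd <- feature_batch(fx$feats, 1:6, cfgd)
  fwd <- model_forward(paramsd, cfgd, fbd)
  expect_equal(dim(ns$tp_value(fwd$tape, fwd$logits)), c(6L, 15L))
  fbd_bad <- fbd; fbd_bad$site <- fb$site
  expect_error(model_forward(paramsd, cfgd, fbd_bad), "multi-label")
  fb_bad <- fb; fb_bad$site <- NULL
  expect_error(model_forward(params, cfg, fb_bad), "site-vector")
})

test_that("every parameter group receives gradient on a random batch", {
  fx <- fixture_feature_set()
  ns <- asNamespace("tmpatho")
  for (task in c("patho", "disease")) {
    cfg <- fixture_tiny_config(task, fx$feats$input_width)
    params <- init_model(cfg, seed = 3L)
    fb <- feature_batch(fx$feats, 1:8, cfg)
    fw <- model_forward(params, cfg, fb, training = FALSE)
    y <- if (task == "patho") matrix(rep(c(0, 1), 4), ncol = 1)
         else matrix(rbinom(8 * 15, 1, 0.3), 8, 15)
    loss <- ns$tp_bce_logits(fw$tape, fw$logits, y)
    g <- ns$tp_backward(fw$tape, loss,
                        stats::setNames(unlist(fw$param_ids),
                                        names(fw$param_ids)))
    dead <- names(Filter(function(x) max(abs(x)) == 0, g))
    expect_length(dead, 0L)
  }
})

test_that("the single-sample protein encoder yields the 101 x d_model embedding", {
  fx <- fixture_feature_set()
  cfg <- fixture_tiny_config("patho", fx$feats$input_width)
  params <- init_model(cfg, seed = 4L)
  m <- fx$feats$wild[1:101, , drop = FALSE]
  out <- protein_encoder(m, params, cfg, pad_mask = fx$feats$pad[1, ])
  expect_equal(dim(out), c(101L, cfg$d_model))
  expect_identical(out, protein_encoder(m, params, cfg,
                                        pad_mask = fx$feats$pad[1, ]))
})
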