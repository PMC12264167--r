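# The tape is internal machinery; these tests reach it through :::
# deliberately, since gradient correctness underwrites every training
# result the package reports.

test_that("composite tape gradients match central differences", {
  ns <- asNamespace("tmpatho")
  set.seed(1)
  X <- matrix(rnorm(12), 3, 4)
  Y <- matrix(rbinom(8, 1, 0.5), 4, 2)
  build <- function(W1, W2, g, b) {
    t <- ns$tape_new()
    x <- ns$tp_const(t, X)
    w1 <- ns$tp_push(t, W1); w2 <- ns$tp_push(t, W2)
    gg <- ns$tp_push(t, g); bb <- ns$tp_push(t, b)
    z <- ns$tp_layernorm_rows(t, ns$tp_mm(t, x, w1), gg, bb)
    z <- ns$tp_relu(t, z)
    a <- ns$tp_softmax_rows(t, ns$tp_mm(t, z, ns$tp_transpose(t, z)))
    z2 <- ns$tp_hcat(t, c(ns$tp_sigmoid(t, ns$tp_mm(t, a, z)),
                          ns$tp_tanh(t, z)))
    z4 <- ns$tp_rows(t, z2, c(1, 2, 2, 3))
    loss <- ns$tp_bce_logits(t, ns$tp_cols(t, z4, 1:2), Y)
    list(t = t, loss = loss, ids = c(W1 = w1, W2 = w2, g = gg, b = bb))
  }
  W1 <- matrix(rnorm(20) * 0.5, 4, 5); W2 <- matrix(rnorm(10), 5, 2)
  g <- matrix(runif(5, 0.5, 1.5), 1, 5); b <- matrix(rnorm(5) * 0.1, 1, 5)
  r <- build(W1, W2, g, b)
  grads <- ns$tp_backward(r$t, r$loss, r$ids)
  params <- list(W1 = W1, W2 = W2, g = g, b = b)
  for (nm in names(params)) {
    num <- numeric_grad(function(P) {
      ps <- params; ps[[nm]] <- P
      rr <- do.call(build, ps)
      ns$tp_value(rr$t, rr$loss)[1]
    }, params[[nm]])
    expect_equal(grads[[nm]], num, tolerance = 1e-6)
  }
})

test_that("fused BiLSTM gradients match central differences", {
  ns <- asNamespace("tmpatho")
  set.seed(2)
  B <- 2L; W <- 5L; D <- 3L; h <- 2L
  X <- matrix(rnorm(B * W * D), B * W, D)
  P <- list(Wf = matrix(rnorm(D * 4 * h) * 0.4, D, 4 * h),
            Uf = matrix(rnorm(h * 4 * h) * 0.4, h, 4 * h),
            bf = matrix(rnorm(4 * h) * 0.1, 1, 4 * h),
            Wb = matrix(rnorm(D * 4 * h) * 0.4, D, 4 * h),
            Ub = matrix(rnorm(h * 4 * h) * 0.4, h, 4 * h),
            bb = matrix(rnorm(4 * h) * 0.1, 1, 4 * h))
  target <- matrix(rnorm(B * W * 2 * h), B * W, 2 * h)
  build <- function(pp) {
    t <- ns$tape_new()
    x <- ns$tp_const(t, X)
    ids <- lapply(pp, function(v) ns$tp_push(t, v))
    H <- ns$tp_bilstm(t, x, ids$Wf, ids$Uf, ids$bf, ids$Wb, ids$Ub, ids$bb,
                      B, W)
    loss <- ns$tp_bce_logits(t, H, (target > 0) * 1)
    list(t = t, loss = loss, ids = ids)
  }
  r <- build(P)
  grads <- ns$tp_backward(r$t, r$loss,
                          stats::setNames(unlist(r$ids), names(r$ids)))
  for (nm in names(P)) {
    num <- numeric_grad(function(M) {
      pp <- P; pp[[nm]] <- M
      rr <- build(pp)
      ns$tp_value(rr$t, rr$loss)[1]
    }, P[[nm]], eps = 1e-6)
    expect_equal(grads[[nm]], num, tolerance = 1e-4)
  }
})

test_that("fused attention ops match plain oracles and their numeric gradients", {
  ns <- asNamespace("tmpatho")
  set.seed(3)
  B <- 2L; W <- 4L; d <- 6L; K <- 3L
  Q <- matrix(rnorm(B * W * d), B * W, d)
  Km <- matrix(rnorm(B * W * d), B * W, d)
  V <- matrix(rnorm(B * W * d), B * W, d)
  mask <- rbind(c(0, 0, 0, -1e9), c(0, 0, 0, 0))
  # value oracle: per-sample multihead_self_attention with identity maps
  t1 <- ns$tape_new()
  ids <- lapply(list(Q, Km, V), function(m) ns$tp_push(t1, m))
  out <- ns$tp_value(t1, ns$tp_mhsa(t1, ids[[1]], ids[[2]], ids[[3]],
                                    B, W, 2L, mask))
  for (s in 1:B) {
    rows <- (s - 1) * W + 1:W
    dk <- d / 2
    for (hh in 1:2) {
      cols <- (hh - 1) * dk + 1:dk
      S <- Q[rows, cols] %*% t(Km[rows, cols]) / sqrt(dk) +
        rep(mask[s, ], each = W)
      A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
      expect_equal(out[rows, cols], A %*% V[rows, cols], tolerance = 1e-12)
    }
  }
  # gradients of the fused self-attention
  target <- (matrix(rnorm(B * W * d), B * W, d) > 0) * 1
  buildm <- function(q, k, v) {
    t <- ns$tape_new()
    iq <- ns$tp_push(t, q); ik <- ns$tp_push(t, k); iv <- ns$tp_push(t, v)
    loss <- ns$tp_bce_logits(t, ns$tp_mhsa(t, iq, ik, iv, B, W, 2L, mask),
                             target)
    list(t = t, loss = loss, ids = c(q = iq, k = ik, v = iv))
  }
  r <- buildm(Q, Km, V)
  grads <- ns$tp_backward(r$t, r$loss, r$ids)
  mats <- list(q = Q, k = Km, v = V)
  for (nm in names(mats)) {
    num <- numeric_grad(function(M) {
      ms <- mats; ms[[nm]] <- M
      rr <- buildm(ms$q, ms$k, ms$v)
      ns$tp_value(rr$t, rr$loss)[1]
    }, mats[[nm]], eps = 1e-6)
    expect_equal(grads[[nm]], num, tolerance = 1e-5)
  }
  # fusion stage: value oracle via the exported plain functions
  E <- matrix(rnorm(K * d) * 0.5, K, d)
  t2 <- ns$tape_new()
  ie <- ns$tp_push(t2, E); ipw <- ns$tp_push(t2, Q); ipm <- ns$tp_push(t2, Km)
  fus <- ns$tp_value(t2, ns$tp_fusion(t2, ie, ipw, ipm, B, W, mask))
  for (s in 1:B) {
    rows <- (s - 1) * W + 1:W
    dpw <- fuse_disease_protein(Q[rows, ], E, mask[s, ] == 0)
    dpm <- fuse_disease_protein(Km[rows, ], E, mask[s, ] == 0)
    wm <- fuse_wild_mutant(dpw$embedding, dpm$embedding)
    expect_equal(fus[s, ], c(as.vector(t(wm$attn_dis_prot)),
                             as.vector(t(wm$sub_dis_prot))),
                 tolerance = 1e-10)
  }
  # gradients of the fused fusion stage
  targetf <- (matrix(rnorm(B * 2 * K * d), B, 2 * K * d) > 0) * 1
  buildf <- function(e, pw, pm) {
    t <- ns$tape_new()
    ie <- ns$tp_push(t, e); iw <- ns$tp_push(t, pw); im <- ns$tp_push(t, pm)
    loss <- ns$tp_bce_logits(t, ns$tp_fusion(t, ie, iw, im, B, W, mask),
                             targetf)
    list(t = t, loss = loss, ids = c(e = ie, pw = iw, pm = im))
  }
  rf <- buildf(E, Q, Km)
  gradsf <- ns$tp_backward(rf$t, rf$loss, rf$ids)
  matsf <- list(e = E, pw = Q, pm = Km)
  for (nm in names(matsf)) {
    num <- numeric_grad(function(M) {
      ms <- matsf; ms[[nm]] <- M
      rr <- buildf(ms$e, ms$pw, ms$pm)
      ns$tp_value(rr$t, rr$loss)[1]
    }, matsf[[nm]], eps = 1e-6)
    expect_equal(gradsf[[nm]], num, tolerance = 1e-5)
  }
})

test_that("conv-maxpool gradients match central differences", {
  ns <- asNamespace("tmpatho")
  set.seed(4)
  X <- matrix(rnorm(3 * 12), 3, 12)
  Wc <- matrix(rnorm(3 * 2) * 0.5, 3, 2)
  bc <- matrix(rnorm(2) * 0.1, 1, 2)
  target <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  build <- function(x, w, b) {
    t <- ns$tape_new()
    ix <- ns$tp_push(t, x); iw <- ns$tp_push(t, w); ib <- ns$tp_push(t, b)
    loss <- ns$tp_bce_logits(t, ns$tp_conv1d_maxpool(t, ix, iw, ib), target)
    list(t = t, loss = loss, ids = c(x = ix, w = iw, b = ib))
  }
  r <- build(X, Wc, bc)
  grads <- ns$tp_backward(r$t, r$loss, r$ids)
  mats <- list(x = X, w = Wc, b = bc)
  for (nm in names(mats)) {
    num <- numeric_grad(function(M) {
      ms <- mats; ms[[nm]] <- M
      rr <- build(ms$x, ms$w, ms$b)
      ns$tp_value(rr$t, rr$loss)[1]
    }, mats[[nm]], eps = 1e-6)
    expect_equal(grads[[nm]], num, tolerance = 1e-5)
  }
})
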