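# The four-module fusion network: protein representation learning
# (BiLSTM + transformer encoder), protein-disease cross-attention
# fusion, transmembrane-environment encoding, and classification heads.

#' Model configuration
#'
#' Architecture hyperparameters. Defaults follow the published network
#' where stated (512 LSTM hidden units per direction, 768-wide
#' transmembrane text input, 537-wide site vector for the binary task);
#' encoder depth, width and head count are configurable so both the
#' full-scale network and a desk-scale variant are expressible.
#'
#' @param task `"patho"` (binary pathogenicity; one sigmoid output; the
#'   537-dim site vector feeds the head) or `"disease"` (15 independent
#'   sigmoid outputs; no site vector).
#' @param input_width per-residue feature width entering the BiLSTM
#'   (1493 under the default embedder and scale catalogue).
#' @param lstm_hidden hidden units per LSTM direction.
#' @param d_model transformer/fusion embedding width.
#' @param n_heads self-attention heads (must divide `d_model`).
#' @param n_encoder_layers encoder layers.
#' @param d_ff position-wise feed-forward width.
#' @param dropout dropout probability in [0, 1).
#' @param disease_count number of disease queries K (2 for the binary
#'   task, 15 for the disease task).
#' @param tm_input_width transmembrane text-embedding width.
#' @param tm_linear_width width of the linear branch of the TM encoder.
#' @param conv_kernels kernel sizes of the TM convolution branch.
#' @param conv_channels channels per kernel size.
#' @param site_width site-vector width (binary task only).
#' @param head_hidden hidden width of the classification MLP.
#' @param window_len sequence-window length.
#' @param positional add sinusoidal positional encodings before the
#'   encoder.
#' @return a `model_config` list.
#' @export
model_config <- function(task = c("patho", "disease"),
                         input_width = 1493L,
                         lstm_hidden = 512L, d_model = 256L, n_heads = 8L,
                         n_encoder_layers = 2L, d_ff = 2L * d_model,
                         dropout = 0.2,
                         disease_count = if (task[1] == "patho") 2L else 15L,
                         tm_input_width = 768L, tm_linear_width = 32L,
                         conv_kernels = c(3L, 5L), conv_channels = 8L,
                         site_width = if (task[1] == "patho") 537L else NULL,
                         head_hidden = 64L, window_len = 101L,
                         positional = TRUE) {
  task <- match.arg(task)
  abort_if(d_model %% n_heads != 0L, "n_heads must divide d_model")
  abort_if(dropout < 0 || dropout >= 1, "dropout must be in [0, 1)")
  abort_if(task == "disease" && !is.null(site_width),
           "the site vector feeds the head only in the binary task")
  cfg <- list(task = task, input_width = as.integer(input_width),
              lstm_hidden = as.integer(lstm_hidden),
              d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              d_k = as.integer(d_model / n_heads),
              n_encoder_layers = as.integer(n_encoder_layers),
              d_ff = as.integer(d_ff), dropout = dropout,
              disease_count = as.integer(disease_count),
              tm_input_width = as.integer(tm_input_width),
              tm_linear_width = as.integer(tm_linear_width),
              conv_kernels = as.integer(conv_kernels),
              conv_channels = as.integer(conv_channels),
              site_width = if (is.null(site_width)) NULL else as.integer(site_width),
              head_hidden = as.integer(head_hidden),
              window_len = as.integer(window_len),
              n_out = if (task == "patho") 1L else 15L,
              positional = isTRUE(positional))
  cfg$tm_out_width <- cfg$tm_linear_width +
    cfg$conv_channels * length(cfg$conv_kernels)
  cfg$head_in_width <- 2L * cfg$disease_count * cfg$d_model +
    cfg$tm_out_width + (cfg$site_width %||% 0L)
  structure(cfg, class = "model_config")
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

#' Initialise model parameters
#'
#' Glorot-uniform weight matrices, zero biases (LSTM forget-gate bias
#' initialised to 1), unit LayerNorm gains. Wild-type and mutant
#' sequences share one protein encoder.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return named list of parameter matrices.
#' @export
init_model <- function(config, seed) {
  with_seed(derive_seed(seed, "init"), {
    h <- config$lstm_hidden; D <- config$input_width; d <- config$d_model
    p <- list()
    for (dir in c("f", "b")) {
      p[[paste0("lstm_W", dir)]] <- glorot(D, 4L * h)
      p[[paste0("lstm_U", dir)]] <- glorot(h, 4L * h)
      bb <- matrix(0, 1L, 4L * h)
      bb[1L, seq.int(h + 1L, 2L * h)] <- 1  # forget gate bias
      p[[paste0("lstm_b", dir)]] <- bb
    }
    p$red_W <- glorot(2L * h, d); p$red_b <- matrix(0, 1L, d)
    for (l in seq_len(config$n_encoder_layers)) {
      pre <- paste0("enc", l, "_")
      p[[paste0(pre, "Wq")]] <- glorot(d, d)
      p[[paste0(pre, "Wk")]] <- glorot(d, d)
      p[[paste0(pre, "Wv")]] <- glorot(d, d)
      p[[paste0(pre, "Wo")]] <- glorot(d, d)
      p[[paste0(pre, "ln1_g")]] <- matrix(1, 1L, d)
      p[[paste0(pre, "ln1_b")]] <- matrix(0, 1L, d)
      p[[paste0(pre, "ffn_W1")]] <- glorot(d, config$d_ff)
      p[[paste0(pre, "ffn_b1")]] <- matrix(0, 1L, config$d_ff)
      p[[paste0(pre, "ffn_W2")]] <- glorot(config$d_ff, d)
      p[[paste0(pre, "ffn_b2")]] <- matrix(0, 1L, d)
      p[[paste0(pre, "ln2_g")]] <- matrix(1, 1L, d)
      p[[paste0(pre, "ln2_b")]] <- matrix(0, 1L, d)
    }
    p$dis_E <- matrix(stats::rnorm(config$disease_count * d, sd = 0.1),
                      config$disease_count, d)
    p$tm_Wlin <- glorot(config$tm_input_width, config$tm_linear_width)
    p$tm_blin <- matrix(0, 1L, config$tm_linear_width)
    for (k in config$conv_kernels) {
      p[[paste0("tm_conv", k, "_w")]] <- glorot(k, config$conv_channels)
      p[[paste0("tm_conv", k, "_b")]] <- matrix(0, 1L, config$conv_channels)
    }
    p$head_W1 <- glorot(config$head_in_width, config$head_hidden)
    p$head_b1 <- matrix(0, 1L, config$head_hidden)
    p$head_W2 <- glorot(config$head_hidden, config$n_out)
    p$head_b2 <- matrix(0, 1L, config$n_out)
    p
  })
}

sinusoidal_encoding <- function(len, d) {
  pos <- seq_len(len) - 1L
  out <- matrix(0, len, d)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^(2 * (i - 1) / d)
    out[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= d) out[, 2L * i] <- cos(pos * freq)
  }
  out
}

# Shared-weight protein encoder on the tape: BiLSTM over the window
# (fused op), linear reduction to d_model, then stacked multi-head
# self-attention encoder layers (fused op) with residual connections,
# row LayerNorm and a position-wise feed-forward block. X is
# sample-major (B * window_len rows); mask_add is a B x window_len
# additive attention mask (0 real, -1e9 pad).
encode_protein_tape <- function(tp, pid, cfg, Xid, B, mask_add, training) {
  W <- cfg$window_len; d <- cfg$d_model
  H <- tp_bilstm(tp, Xid, pid$lstm_Wf, pid$lstm_Uf, pid$lstm_bf,
                 pid$lstm_Wb, pid$lstm_Ub, pid$lstm_bb, B, W)
  E <- tp_add_bias(tp, tp_mm(tp, H, pid$red_W), pid$red_b)
  if (cfg$positional) {
    pe <- sinusoidal_encoding(W, d)
    E <- tp_add(tp, E, tp_const(tp, pe[rep(seq_len(W), B), , drop = FALSE]))
  }
  X <- E
  for (l in seq_len(cfg$n_encoder_layers)) {
    pre <- paste0("enc", l, "_")
    Qa <- tp_mm(tp, X, pid[[paste0(pre, "Wq")]])
    Ka <- tp_mm(tp, X, pid[[paste0(pre, "Wk")]])
    Va <- tp_mm(tp, X, pid[[paste0(pre, "Wv")]])
    O <- tp_mhsa(tp, Qa, Ka, Va, B, W, cfg$n_heads, mask_add)
    O <- tp_mm(tp, O, pid[[paste0(pre, "Wo")]])
    O <- tp_dropout(tp, O, cfg$dropout, training)
    X <- tp_layernorm_rows(tp, tp_add(tp, X, O),
                           pid[[paste0(pre, "ln1_g")]],
                           pid[[paste0(pre, "ln1_b")]])
    FF <- tp_add_bias(tp,
      tp_mm(tp, tp_relu(tp, tp_add_bias(tp,
        tp_mm(tp, X, pid[[paste0(pre, "ffn_W1")]]),
        pid[[paste0(pre, "ffn_b1")]])),
        pid[[paste0(pre, "ffn_W2")]]),
      pid[[paste0(pre, "ffn_b2")]])
    FF <- tp_dropout(tp, FF, cfg$dropout, training)
    X <- tp_layernorm_rows(tp, tp_add(tp, X, FF),
                           pid[[paste0(pre, "ln2_g")]],
                           pid[[paste0(pre, "ln2_b")]])
  }
  X
}

#' Disease-protein cross-attention (plain matrices)
#'
#' Each of the K learnable disease-query rows attends over the window
#' positions of one protein embedding:
#' `softmax(Q_d K_p^T / sqrt(d_k)) V_p`, with the protein embedding
#' serving as both keys and values; pad positions are masked out.
#'
#' @param prot_embedding window_len x d_model protein embedding.
#' @param disease_queries K x d_model disease embedding.
#' @param pad_mask logical window mask (`TRUE` = real residue).
#' @return list with `embedding` (K x d_model) and `attention`
#'   (row-stochastic K x window_len).
#' @export
fuse_disease_protein <- function(prot_embedding, disease_queries,
                                 pad_mask = rep(TRUE, nrow(prot_embedding))) {
  d <- ncol(disease_queries)
  S <- tcrossprod(disease_queries, prot_embedding) / sqrt(d)
  S <- S + rep(ifelse(pad_mask, 0, -1e9), each = nrow(disease_queries))
  A <- softmax_rows_plain(S)
  list(embedding = A %*% prot_embedding, attention = A)
}

#' Wild-mutant cross-attention and subtraction (plain matrices)
#'
#' The wild-type dis-prot embedding attends over the mutant one
#' (`softmax(Q_w K_m^T / sqrt(d_k)) V_m`), and the wild-minus-mutant
#' subtraction embedding is returned alongside.
#'
#' @param wild_dis_prot,mutant_dis_prot K x d_model embeddings.
#' @return list with `attn_dis_prot`, `sub_dis_prot` (both
#'   K x d_model) and `attention` (row-stochastic K x K).
#' @export
fuse_wild_mutant <- function(wild_dis_prot, mutant_dis_prot) {
  d <- ncol(wild_dis_prot)
  A <- softmax_rows_plain(tcrossprod(wild_dis_prot, mutant_dis_prot) /
                            sqrt(d))
  list(attn_dis_prot = A %*% mutant_dis_prot,
       sub_dis_prot = wild_dis_prot - mutant_dis_prot,
       attention = A)
}

#' Full forward pass of the fusion network
#'
#' Builds the computational tape for a batch: shared-weight protein
#' encoding of the wild-type and mutant windows, disease-protein
#' cross-attention for both, wild-mutant cross-attention plus the
#' wild-minus-mutant subtraction embedding, the transmembrane-
#' environment branch, and the classification MLP.
#'
#' @param params parameter list from [init_model()].
#' @param config a [model_config()].
#' @param batch list with `wild`, `mutant` (sample-major
#'   `B*window_len x input_width` matrices), `pad` (`B x window_len`
#'   logical), `tm` (`B x tm_input_width`), `site` (`B x site_width`,
#'   binary task only) and `B`.
#' @param training apply dropout.
#' @return list with the tape, node ids (`logits`, `attn_dis_prot`,
#'   `sub_dis_prot`, `prot_wild`, `prot_mut`, `tm_embedding`) and the
#'   parameter node-id map.
#' @export
model_forward <- function(params, config, batch, training = FALSE) {
  cfg <- config; B <- batch$B; W <- cfg$window_len; K <- cfg$disease_count
  abort_if(ncol(batch$wild) != cfg$input_width,
           sprintf("input width %d does not match config (%d)",
                   ncol(batch$wild), cfg$input_width))
  abort_if(ncol(batch$tm) != cfg$tm_input_width,
           "transmembrane input width does not match config")
  abort_if(cfg$task == "disease" && !is.null(batch$site),
           "site vector supplied in multi-label mode")
  if (cfg$task == "patho") {
    abort_if(is.null(batch$site) || ncol(batch$site) != cfg$site_width,
             "binary task requires the site-vector block")
  }
  tp <- tape_new(1024L)
  pid <- lapply(params, function(v) tp_push(tp, v))
  # additive attention mask, shared by wild and mutant (same geometry)
  mask_add <- ifelse(batch$pad, 0, -1e9)
  Xw <- tp_const(tp, batch$wild); Xm <- tp_const(tp, batch$mutant)
  Pw <- encode_protein_tape(tp, pid, cfg, Xw, B, mask_add, training)
  Pm <- encode_protein_tape(tp, pid, cfg, Xm, B, mask_add, training)
  FUS <- tp_fusion(tp, pid$dis_E, Pw, Pm, B, W, mask_add)
  # transmembrane environment branch: global linear + local convolutions
  TM <- tp_const(tp, batch$tm)
  lin <- tp_relu(tp, tp_add_bias(tp, tp_mm(tp, TM, pid$tm_Wlin), pid$tm_blin))
  convs <- lapply(cfg$conv_kernels, function(k) {
    tp_relu(tp, tp_conv1d_maxpool(tp, TM, pid[[paste0("tm_conv", k, "_w")]],
                                  pid[[paste0("tm_conv", k, "_b")]]))
  })
  TME <- tp_hcat(tp, c(lin, unlist(convs)))
  head_in <- c(FUS, TME)
  if (!is.null(batch$site)) head_in <- c(head_in, tp_const(tp, batch$site))
  HIN <- tp_hcat(tp, head_in)
  H1 <- tp_relu(tp, tp_add_bias(tp, tp_mm(tp, HIN, pid$head_W1), pid$head_b1))
  H1 <- tp_dropout(tp, H1, cfg$dropout, training)
  logits <- tp_add_bias(tp, tp_mm(tp, H1, pid$head_W2), pid$head_b2)
  list(tape = tp, logits = logits, param_ids = pid,
       prot_wild = Pw, prot_mut = Pm, fusion = FUS,
       tm_embedding = TME)
}

#' Predicted probabilities for a feature set
#'
#' Runs evaluation-mode forward passes in chunks and applies the output
#' sigmoid.
#'
#' @param params parameter list.
#' @param config a [model_config()].
#' @param features feature set from [featurize_mutations()].
#' @param idx optional record indices to score.
#' @param chunk chunk size.
#' @return N x n_out matrix of probabilities in (0, 1).
#' @export
model_predict <- function(params, config, features, idx = NULL, chunk = 256L) {
  idx <- idx %||% seq_len(features$n)
  out <- matrix(NA_real_, length(idx), config$n_out)
  at <- 1L
  for (part in split(idx, ceiling(seq_along(idx) / chunk))) {
    fw <- model_forward(params, config, feature_batch(features, part, config),
                        training = FALSE)
    z <- tp_value(fw$tape, fw$logits)
    out[seq.int(at, at + length(part) - 1L), ] <- 1 / (1 + exp(-z))
    at <- at + length(part)
  }
  out
}

#' Encode one residue feature matrix with the protein encoder
#'
#' Single-sample convenience wrapper exposing the
#' `window_len x d_model` protein embedding.
#'
#' @param matrix a `residue_feature_matrix` (window_len x input_width).
#' @param params,config model parameters and configuration.
#' @param pad_mask logical vector (`TRUE` = real residue).
#' @return `window_len x d_model` numeric matrix.
#' @export
protein_encoder <- function(matrix, params, config,
                            pad_mask = rep(TRUE, nrow(matrix))) {
  abort_if(ncol(matrix) != config$input_width,
           sprintf("input width %d does not match config (%d)",
                   ncol(matrix), config$input_width))
  tp <- tape_new(1024L)
  pid <- lapply(params, function(v) tp_push(tp, v))
  mask_add <- matrix(ifelse(pad_mask, 0, -1e9), nrow = 1L)
  X <- tp_const(tp, unclass(matrix))
  node <- encode_protein_tape(tp, pid, config, X, 1L, mask_add,
                              training = FALSE)
  tp_value(tp, node)
}

#' Multi-head self-attention of a single sequence
#'
#' Stand-alone application of the scaled-dot-product multi-head
#' self-attention (per-head softmax(Q K^T / sqrt(d_k)) V, heads
#' concatenated and mapped by the output projection). Exposed for
#' direct verification against hand-computed examples.
#'
#' @param X n x d_model input matrix.
#' @param Wq,Wk,Wv d_model x d_model projection matrices (head blocks
#'   side by side).
#' @param Wo d_model x d_model output projection.
#' @param n_heads number of heads.
#' @param mask optional additive attention mask (n x n).
#' @return list with `output` (n x d_model) and `attention` (list of
#'   per-head row-stochastic n x n matrices).
#' @export
multihead_self_attention <- function(X, Wq, Wk, Wv, Wo, n_heads = 1L,
                                     mask = NULL) {
  d <- ncol(X)
  abort_if(d %% n_heads != 0L, "n_heads must divide d_model")
  dk <- d / n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  heads <- vector("list", n_heads); attn <- vector("list", n_heads)
  for (hh in seq_len(n_heads)) {
    cols <- (hh - 1L) * dk + seq_len(dk)
    sc <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    if (!is.null(mask)) sc <- sc + mask
    e <- exp(sc - apply(sc, 1L, max))
    A <- e / rowSums(e)
    attn[[hh]] <- A
    heads[[hh]] <- A %*% V[, cols, drop = FALSE]
  }
  list(output = do.call(cbind, heads) %*% Wo, attention = attn)
}
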