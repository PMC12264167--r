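# End-to-end desk-scale experiment: simulate, featurise, train both
# heads, evaluate against the planted signal.

#' Subset a feature set by record indices
#'
#' @param features a `feature_set`.
#' @param idx record indices to keep.
#' @return a `feature_set` over the selected records.
#' @export
subset_features <- function(features, idx) {
  W <- features$window_len
  rows <- as.vector(vapply(idx, function(i) (i - 1L) * W + seq_len(W),
                           integer(W)))
  structure(list(wild = features$wild[rows, , drop = FALSE],
                 mutant = features$mutant[rows, , drop = FALSE],
                 pad = features$pad[idx, , drop = FALSE],
                 tm = features$tm[idx, , drop = FALSE],
                 site = features$site[idx, , drop = FALSE],
                 n = length(idx), window_len = W,
                 input_width = features$input_width,
                 records = features$records[idx, , drop = FALSE]),
            class = "feature_set")
}

#' Desk-scale model configuration
#'
#' The compact network used by the synthetic-recovery experiments:
#' same architecture as [model_config()] but with reduced widths so
#' training fits a single CPU core in minutes. The embedder width must
#' match the feature set it is applied to.
#'
#' @param task `"patho"` or `"disease"`.
#' @param input_width per-residue feature width.
#' @param tm_input_width transmembrane text-embedding width.
#' @return a `model_config`.
#' @export
tiny_model_config <- function(task, input_width, tm_input_width = 768L) {
  model_config(task = task, input_width = input_width,
               lstm_hidden = 16L, d_model = 32L, n_heads = 2L,
               n_encoder_layers = 1L, d_ff = 64L,
               tm_input_width = tm_input_width, tm_linear_width = 16L,
               conv_kernels = c(3L, 5L), conv_channels = 4L,
               head_hidden = 32L)
}

#' Planted-signal recovery experiment
#'
#' Simulates a complete synthetic dataset, featurises it with the
#' deterministic stub embedders, trains the compact fusion network on
#' both tasks and evaluates on held-out mutations: binary metrics on
#' the pathogenicity task and per-class AUC on the multi-label disease
#' task (reported separately for the well-separated classes). This is
#' the package's end-to-end correctness experiment: the labels are
#' functions of features the pipeline computes, so held-out recovery
#' exercises the full stack.
#'
#' @param seed integer seed for every source of randomness.
#' @param n_train,n_test simulated training-pool and test sizes.
#' @param epochs_patho,epochs_disease training epochs per task.
#' @param embed_width stub sequence-embedder width.
#' @param learning_rate desk-scale learning rate (both tasks).
#' @param quiet suppress progress messages.
#' @return list with `binary` (metric report), `disease` (per-class
#'   curve table), `disease_overall` (multi-label report),
#'   `separated_auc` (named per-class AUC of the well-separated
#'   classes), sizes, and both checkpoints' training logs.
#' @export
planted_recovery_experiment <- function(seed, n_train = 2000L,
                                        n_test = 500L,
                                        epochs_patho = 6L,
                                        epochs_disease = 18L,
                                        embed_width = 16L,
                                        learning_rate = 1e-3,
                                        quiet = TRUE) {
  scfg <- synth_config(n_mutations = n_train + n_test,
                       seed = derive_seed(seed, "synthesis"))
  ds <- gen_dataset(scfg)
  feats <- featurize_mutations(
    ds$records, ds$sequences, ds$pssms, ds$tables,
    seq_embedder = seq_embedder_stub(width = embed_width,
                                     seed = derive_seed(seed, "seq-embed")),
    text_embedder = text_embedder_stub(seed = derive_seed(seed, "text-embed")))
  pool <- seq_len(n_train)
  test_idx <- seq.int(n_train + 1L, n_train + n_test)
  pool_split <- split_random(n_train, ratios = c(9, 1, 0),
                             seed = derive_seed(seed, "pool-split"))

  # --- binary pathogenicity task ---------------------------------------------
  y <- ds$records$patho_label
  cfg_b <- tiny_model_config("patho", feats$input_width)
  tc_b <- train_config("patho", learning_rate = learning_rate,
                       epochs = epochs_patho,
                       seed = derive_seed(seed, "train-patho"))
  ck_b <- train_model(feats, y, list(train = pool_split$train,
                                     valid = pool_split$valid),
                      cfg_b, tc_b, quiet = quiet)
  probs_b <- predict_checkpoint(ck_b, feats, test_idx)
  binary <- binary_metrics(y[test_idx], as.vector(probs_b))

  # --- multi-label disease task (pathogenic records only) --------------------
  dis_pool <- intersect(pool, which(y == 1L))
  dis_test <- intersect(test_idx, which(y == 1L))
  Yd <- disease_label_matrix(ds$records$disease_labels)
  feats_d <- feats
  dsplit <- split_random(length(dis_pool), ratios = c(9, 1, 0),
                         seed = derive_seed(seed, "dis-split"))
  cfg_d <- tiny_model_config("disease", feats$input_width)
  tc_d <- train_config("disease", learning_rate = learning_rate,
                       batch_size = 128L, epochs = epochs_disease,
                       seed = derive_seed(seed, "train-disease"))
  sub_all <- c(dis_pool, dis_test)
  feats_sub <- subset_features(feats_d, sub_all)
  # the full feature matrices are no longer needed; release them before
  # the second training run to halve peak memory
  feats <- feats_d <- NULL
  gc(verbose = FALSE)
  Ysub <- Yd[sub_all, , drop = FALSE]
  tr_ids <- seq_along(dis_pool)
  ck_d <- train_model(feats_sub, Ysub,
                      list(train = tr_ids[dsplit$train],
                           valid = tr_ids[dsplit$valid]),
                      cfg_d, tc_d, quiet = quiet)
  te_ids <- seq.int(length(dis_pool) + 1L, length(sub_all))
  probs_d <- predict_checkpoint(ck_d, feats_sub, te_ids)
  colnames(probs_d) <- disease_codes()
  curves <- per_disease_curves(Ysub[te_ids, , drop = FALSE], probs_d)
  overall <- multilabel_metrics(Ysub[te_ids, , drop = FALSE], probs_d)
  sep <- curves$auc[seq_len(scfg$n_separated)]
  names(sep) <- curves$class[seq_len(scfg$n_separated)]

  list(binary = binary, disease = curves, disease_overall = overall,
       separated_auc = sep,
       n_train = n_train, n_test = n_test,
       n_disease_train = length(dis_pool), n_disease_test = length(dis_test),
       log_patho = ck_b$log, log_disease = ck_d$log,
       checkpoints = list(patho = ck_b, disease = ck_d))
}
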