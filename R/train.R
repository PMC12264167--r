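# Training: binary cross-entropy loss, Adam, best-by-validation-F1
# checkpointing.

#' Training configuration
#'
#' Defaults follow the published protocol per task: binary cross-entropy
#' loss, Adam, learning rate 0.001 with batch size 128 for the binary
#' pathogenicity task and 0.0001 with batch size 256 for the multi-label
#' disease task, 100 epochs, dropout 0.2, with the best parameters kept
#' by validation F1. No early stopping.
#'
#' @param task `"patho"` or `"disease"`.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param dropout dropout probability.
#' @param checkpoint_metric validation metric used to select the saved
#'   parameters (currently `"f1"`).
#' @param threshold decision threshold for validation metrics.
#' @param seed integer seed driving shuffling, dropout and
#'   initialisation.
#' @return a `train_config` list.
#' @export
train_config <- function(task = c("patho", "disease"),
                         learning_rate = if (task[1] == "patho") 1e-3 else 1e-4,
                         batch_size = if (task[1] == "patho") 128L else 256L,
                         epochs = 100L, dropout = 0.2,
                         checkpoint_metric = "f1", threshold = 0.5,
                         seed = 1L) {
  task <- match.arg(task)
  abort_if(learning_rate <= 0 || batch_size < 1L || epochs < 1L,
           "rates and sizes must be positive")
  abort_if(!checkpoint_metric %in% "f1",
           "unsupported checkpoint metric")
  structure(list(task = task, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 checkpoint_metric = checkpoint_metric,
                 threshold = threshold, seed = as.integer(seed)),
            class = "train_config")
}

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      state$lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + state$eps)
  }
  list(state = state, params = params)
}

validation_f1 <- function(task, labels, probs, threshold) {
  if (task == "patho") {
    m <- binary_metrics(as.vector(labels), as.vector(probs), threshold)
    v <- m$f1
  } else {
    m <- multilabel_metrics(labels, probs, threshold)
    v <- m$f1_ml
  }
  if (is.na(v)) 0 else v
}

#' Train the fusion network
#'
#' Minibatch BCE training with Adam under the task's hyperparameters;
#' after each epoch the validation split is scored and the parameters
#' with the best validation F1 are retained. Aborts with diagnostics if
#' the loss becomes non-finite. Fully seed-reproducible.
#'
#' @param features a `feature_set` from [featurize_mutations()].
#' @param labels numeric vector (binary task) or `n x 15` binary matrix
#'   (disease task).
#' @param split list with integer index vectors `train` and `valid`.
#' @param config a [model_config()]; its dropout is overridden by the
#'   training configuration's.
#' @param tconf a [train_config()].
#' @param quiet suppress per-epoch progress messages.
#' @return a `tmpatho_checkpoint`: list with `params` (best), `config`,
#'   `tconf`, `log` (per-epoch train loss and validation F1),
#'   `best_epoch`, `best_f1`.
#' @export
train_model <- function(features, labels, split, config, tconf,
                        quiet = FALSE) {
  abort_if(length(intersect(split$train, split$valid)) > 0L,
           "train and valid splits overlap")
  config$dropout <- tconf$dropout
  y_all <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1L)
  abort_if(nrow(y_all) != features$n, "labels do not match the feature set")
  abort_if(ncol(y_all) != config$n_out, "label width does not match the task")
  with_seed(derive_seed(tconf$seed, "train"), {
    params <- init_model(config, seed = derive_seed(tconf$seed, "init"))
    opt <- adam_new(params, tconf$learning_rate)
    log <- vector("list", tconf$epochs)
    best <- list(f1 = -Inf, epoch = NA_integer_, params = params)
    for (ep in seq_len(tconf$epochs)) {
      perm <- split$train[sample.int(length(split$train))]
      batches <- split(perm, ceiling(seq_along(perm) / tconf$batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        ids <- batches[[bi]]
        fb <- feature_batch(features, ids, config)
        fw <- model_forward(params, config, fb, training = TRUE)
        loss_id <- tp_bce_logits(fw$tape, fw$logits,
                                 y_all[ids, , drop = FALSE])
        loss <- tp_value(fw$tape, loss_id)[1L]
        abort_if(!is.finite(loss),
                 sprintf("non-finite loss at epoch %d batch %d", ep, bi))
        losses[bi] <- loss
        g <- tp_backward(fw$tape, loss_id,
                         stats::setNames(unlist(fw$param_ids),
                                         names(fw$param_ids)))
        upd <- adam_step(opt, params, g)
        opt <- upd$state; params <- upd$params
      }
      vf1 <- if (length(split$valid) > 0L) {
        probs <- model_predict(params, config, features, split$valid)
        validation_f1(config$task, y_all[split$valid, , drop = FALSE],
                      probs, tconf$threshold)
      } else NA_real_
      log[[ep]] <- list(epoch = ep, train_loss = mean(losses),
                        valid_f1 = vf1)
      if (!quiet) {
        log_msg("epoch %d/%d: train loss %.4f, valid F1 %s", ep,
                tconf$epochs, mean(losses),
                ifelse(is.na(vf1), "NA", sprintf("%.3f", vf1)))
      }
      if (!is.na(vf1) && vf1 > best$f1) {
        best <- list(f1 = vf1, epoch = ep, params = params)
      }
    }
    if (!is.finite(best$f1)) best <- list(f1 = NA_real_,
                                          epoch = tconf$epochs,
                                          params = params)
    structure(list(params = best$params, config = config, tconf = tconf,
                   log = log, best_epoch = best$epoch, best_f1 = best$f1,
                   feature_layout = list(window_len = features$window_len,
                                         input_width = features$input_width,
                                         site_layout = site_vector_layout())),
              class = "tmpatho_checkpoint")
  })
}

#' Score a feature set with a trained checkpoint
#'
#' @param checkpoint a `tmpatho_checkpoint`.
#' @param features a `feature_set`.
#' @param idx optional record indices.
#' @return N x n_out matrix of probabilities.
#' @export
predict_checkpoint <- function(checkpoint, features, idx = NULL) {
  abort_if(features$input_width != checkpoint$feature_layout$input_width,
           "feature width does not match the checkpoint")
  model_predict(checkpoint$params, checkpoint$config, features, idx)
}

#' Save / load a checkpoint archive
#'
#' The archive holds the parameters, both configurations and the
#' feature-layout metadata, so predictions are reproducible from the
#' archive alone.
#'
#' @param checkpoint a `tmpatho_checkpoint`.
#' @param path file path.
#' @return `path` (writer) or the checkpoint (reader).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  abort_if(!inherits(ck, "tmpatho_checkpoint"), "not a checkpoint archive")
  ck
}
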