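# Batch featurisation: residue matrices, transmembrane text embeddings
# and site vectors for a table of mutation records.

#' Featurise a mutation table for the fusion network
#'
#' Computes, for every record: the wild-type and mutant
#' `window_len x input_width` residue feature matrices (stored
#' sample-major in two big matrices), the window pad mask, the
#' transmembrane-context text embedding and the 537-dim site feature
#' vector.
#'
#' @param records a validated `mutation_table`.
#' @param sequences named character vector of protein sequences.
#' @param pssms named list of raw PSSMs keyed by `protein_id`.
#' @param tables property-table list (`scales`, `subst`, `contact`).
#' @param seq_embedder a `seq_embedder` (default stub).
#' @param text_embedder a `text_embedder` (default stub).
#' @param half_width window half-width (50 gives the 101-window).
#' @return a `feature_set` list: `wild`, `mutant`
#'   (`n*window_len x input_width`), `pad` (`n x window_len`), `tm`
#'   (`n x text width`), `site` (`n x 537`), `n`, `window_len`,
#'   `input_width`, `records`.
#' @export
featurize_mutations <- function(records, sequences, pssms, tables,
                                seq_embedder = seq_embedder_stub(),
                                text_embedder = text_embedder_stub(),
                                half_width = 50L) {
  n <- nrow(records)
  abort_if(n == 0L, "no records to featurise")
  W <- 2L * half_width + 1L
  D <- seq_embedder$width + nrow(tables$scales)
  wild <- matrix(0, n * W, D)
  mutant <- matrix(0, n * W, D)
  pad <- matrix(FALSE, n, W)
  tm <- matrix(0, n, text_embedder$width)
  site <- matrix(0, n, sum(site_vector_layout()))
  for (i in seq_len(n)) {
    r <- records[i, ]
    seq <- sequences[[r$protein_id]]
    abort_if(is.null(seq), sprintf("no sequence for %s", r$protein_id))
    rm <- residue_matrices(seq, r$position, r$mut, tables$scales,
                           seq_embedder, half_width)
    rows <- (i - 1L) * W + seq_len(W)
    wild[rows, ] <- rm$wild
    mutant[rows, ] <- rm$mutant
    pad[i, ] <- rm$pad_mask
    tm[i, ] <- tm_context_feature(r$protein_name, seq, r$position, r$wt,
                                  r$mut, r$topology, r$n_tm_segments,
                                  backend = text_embedder)$embedding
    site[i, ] <- site_feature_vector(seq, r$position, r$wt, r$mut,
                                     pssms[[r$protein_id]], tables)
  }
  structure(list(wild = wild, mutant = mutant, pad = pad, tm = tm,
                 site = site, n = n, window_len = W, input_width = D,
                 records = records),
            class = "feature_set")
}

#' Assemble one model batch from a feature set
#'
#' @param features a `feature_set`.
#' @param ids record indices.
#' @param config a [model_config()]; decides whether the site vector is
#'   attached (binary task only).
#' @return batch list for [model_forward()].
#' @export
feature_batch <- function(features, ids, config) {
  W <- features$window_len
  rows <- as.vector(vapply(ids, function(i) (i - 1L) * W + seq_len(W),
                           integer(W)))
  list(wild = features$wild[rows, , drop = FALSE],
       mutant = features$mutant[rows, , drop = FALSE],
       pad = features$pad[ids, , drop = FALSE],
       tm = features$tm[ids, , drop = FALSE],
       site = if (config$task == "patho")
         features$site[ids, , drop = FALSE] else NULL,
       B = length(ids))
}
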