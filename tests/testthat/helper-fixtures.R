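# Shared fixtures, built in code at test time.

# small deterministic property tables with the full stated cardinalities
fixture_tables <- function(seed = 99L) gen_property_tables(seed)

# a short protein with a known topology string
fixture_protein <- function() {
  list(id = "P1",
       sequence = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ",
       topology = paste0(strrep("i", 10), strrep("H", 20), strrep("o", 26)))
}

# ten mutation records against two reference sequences, with documented
# violations:
#   r3 position beyond the sequence end        -> INVALID_POSITION
#   r7 wild-type letter mismatch               -> INVALID_WT
#   r2, r5, r8, r10 cite a single source db    -> dropped by the source filter
# survivors of validate + filter_min_sources: r1, r4, r6, r9
fixture_toy_records <- function() {
  seqs <- c(PA = "MKTAYIAKQR", PB = "GGVLLSWYTR")
  recs <- mutation_table(
    protein_id = c("PA", "PA", "PA", "PA", "PA", "PB", "PB", "PB", "PB", "PB"),
    position = c(2L, 3L, 15L, 5L, 7L, 3L, 7L, 2L, 9L, 10L),
    wt = c("K", "T", "K", "Y", "A", "V", "S", "G", "T", "R"),
    mut = c("R", "A", "N", "F", "V", "I", "A", "A", "S", "Q"),
    sources = c("ClinVar;COSMIC", "ClinVar", "ClinVar;Humsavar",
                "SwissVar;ClinVar;COSMIC", "COSMIC", "Humsavar;SwissVar",
                "ClinVar;1000Genomes", "SwissVar", "COSMIC;ClinVar",
                "1000Genomes"),
    patho_label = c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
    topology = c("i", "i", "o", "H", "H", "o", "S", "i", "B", "o"),
    n_tm_segments = 2L)
  list(records = recs, sequences = seqs,
       expected_verdicts = c("VALID", "VALID", "INVALID_POSITION", "VALID",
                             "VALID", "VALID", "INVALID_WT", "VALID",
                             "VALID", "VALID"),
       survivors = c(1L, 4L, 6L, 9L))
}

# tiny model configuration for fast structural tests
fixture_tiny_config <- function(task = "patho", input_width, tm_width = 32L) {
  model_config(task = task, input_width = input_width,
               lstm_hidden = 4L, d_model = 8L, n_heads = 2L,
               n_encoder_layers = 1L, d_ff = 16L, dropout = 0.2,
               tm_input_width = tm_width, tm_linear_width = 4L,
               conv_kernels = c(3L, 5L), conv_channels = 2L,
               head_hidden = 8L)
}

# tiny featurised dataset for model and training tests
fixture_feature_set <- function(n_mutations = 24L, seed = 31L,
                                embed_width = 4L, text_width = 32L) {
  scfg <- synth_config(n_mutations = n_mutations, n_proteins = 8L,
                       len_range = c(80L, 160L), seed = seed)
  ds <- gen_dataset(scfg)
  feats <- featurize_mutations(
    ds$records, ds$sequences, ds$pssms, ds$tables,
    seq_embedder = seq_embedder_stub(width = embed_width, seed = seed),
    text_embedder = text_embedder_stub(width = text_width, seed = seed))
  list(ds = ds, feats = feats)
}

# central-difference numeric gradient of fn(param) w.r.t. one matrix
numeric_grad <- function(fn, P, eps = 1e-5) {
  out <- P * 0
  for (i in seq_along(P)) {
    p1 <- P; p1[i] <- p1[i] + eps
    p2 <- P; p2[i] <- p2[i] - eps
    out[i] <- (fn(p1) - fn(p2)) / (2 * eps)
  }
  out
}
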