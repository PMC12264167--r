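# tmpatho

Pathogenicity and disease-category prediction for missense variants in
human transmembrane proteins.

## The problem

Roughly a quarter of the human proteome is membrane-embedded, and
missense variants in transmembrane proteins underlie diseases across
essentially every organ system. Most variant-effect predictors answer
only a binary question — pathogenic or neutral — and are trained on
general proteins. `tmpatho` implements a pipeline built specifically for
transmembrane proteins that answers two questions for a single
amino-acid substitution:

1. **Is it pathogenic?** (binary classification), and
2. **Which of 15 disease categories is it associated with?**
   (multi-label classification — one variant may drive several
   diseases, e.g. a nervous-system and a musculoskeletal disorder at
   once).

## The model

Each variant is described by three feature families:

- **Per-residue window representation.** The protein is truncated to a
  101-residue window centred on the mutation site. Each residue carries
  a sequence embedding (default width 1280, from a pluggable embedder
  backend; a deterministic seeded stub ships with the package) plus 213
  physicochemical property scales, giving a 101 × 1493 matrix per
  sequence, computed for both the wild-type and the mutant window.
- **537-dim mutation-site vector.** Concatenation of: per-scale
  property differences mutant−wild (213), substitution-matrix scores
  (94), contact-potential differences over the ±3 neighbourhood (47), a
  raw PSSM site triplet (wild score, mutant score, difference; 3), a
  Gaussian-weighted local profile of the sigmoid-normalised PSSM
  (7 × 20 = 140, weights `w_j = exp(-j²/2)` so `w₀ = 1`), hydrophobicity
  and polarity sliding-window deltas
  `ΔP = P(mut) − mean(P(wild window))` at window sizes 3–11 (10), and
  six-category residue-class distribution deltas at the same windows
  (30).
- **Transmembrane context text.** A fixed natural-language template
  ("Transmembrane protein …, the residue at position … is mutated from
  … to …, the topology of the mutation site is …, and the number of
  transmembrane fragments … is …") rendered per variant and embedded to
  a 768-dim vector by a pluggable text backend (deterministic stub by
  default).

The network fuses them in four modules: (1) a shared-weight protein
encoder — BiLSTM (512 hidden units per direction at full scale, 1024
concatenated) → linear reduction → transformer encoder layers with
multi-head self-attention `softmax(QKᵀ/√d_k)V`; (2) a protein–disease
fusion module in which K learnable disease-query embeddings
cross-attend over the wild-type and mutant protein embeddings
(`softmax(Q_d K_pᵀ/√d_k) V_p`), followed by wild→mutant cross-attention
and a wild−mutant subtraction embedding; (3) a transmembrane-environment
encoder (linear branch + 1-D convolutions with global max-pooling over
the text embedding); (4) a sigmoid MLP head — one output for
pathogenicity (with the 537-dim site vector as an extra input), fifteen
for disease categories. Training is BCE + Adam (defaults: lr 0.001 /
batch 128 binary, lr 0.0001 / batch 256 multi-label, 100 epochs,
dropout 0.2, best checkpoint by validation F1), on a compact reverse-mode
autodiff tape implemented in the package — gradients are verified
against central differences in the test suite.

A seeded synthetic-data generator produces complete studies (proteins
with residue-level topology, PSSMs, property tables of the stated
cardinalities, labelled mutations) in which pathogenicity follows a
planted rule — `1[β₀ + β₁·Δhydropathy + β₂·1(TM site) + ε > 0]` — and
disease labels are thresholded projections of the site vector, so
held-out recovery of the signal exercises the entire stack.

## Worked example

```r
library(tmpatho)

# simulate a complete synthetic study: proteins, topologies, PSSMs,
# property tables, and mutations with planted pathogenicity signal
cfg <- synth_config(n_mutations = 400, seed = 7)
ds  <- gen_dataset(cfg)
table(ds$records$patho_label)
#>   0   1
#> 216 184

# featurise every mutation: 101x229 residue matrices (16-wide stub
# embedder + 213 property scales), 768-dim text embeddings, 537-dim
# site vectors
feats <- featurize_mutations(ds$records, ds$sequences, ds$pssms, ds$tables,
                             seq_embedder = seq_embedder_stub(width = 16, seed = 7),
                             text_embedder = text_embedder_stub(seed = 7))
dim(feats$site)
#> [1] 400 537

# train the compact fusion network on 300 mutations, test on 100
sp <- list(train = 1:270, valid = 271:300)
ck <- train_model(feats, ds$records$patho_label, sp,
                  tiny_model_config("patho", feats$input_width),
                  train_config("patho", epochs = 8, seed = 7), quiet = TRUE)
probs <- predict_checkpoint(ck, feats, 301:400)
m <- binary_metrics(ds$records$patho_label[301:400], as.vector(probs))
round(c(auc = m$auc, mcc = m$mcc, f1 = m$f1, acc = m$acc), 3)
#>   auc   mcc    f1   acc
#> 0.848 0.606 0.765 0.810
```

The held-out AUC of 0.85 on this small run shows the network recovering
the planted hydrophobicity/topology signal from the computed features;
the full-size experiment (`planted_recovery_experiment()`, 2000 training
/ 500 test mutations) reaches a held-out binary AUC above 0.9 and
per-class AUC above 0.85 for the four well-separated synthetic disease
classes.

A command-line surface is available as well (`inst/cli/tmpatho`):
`simulate`, `featurize`, `train`, `predict`, `evaluate` and `report`
subcommands over the same functions, each run writing a manifest with
its options, seed and package version.

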