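---
title: "Methods: feature construction, fusion network, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature construction, fusion network, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tmpatho)
```

# Scope and model

`tmpatho` predicts, for a single amino-acid substitution in a human
transmembrane protein, (a) a pathogenicity probability and (b) fifteen
per-disease association probabilities. The pipeline has three feature
families, a four-module neural network, a training/evaluation suite,
and a synthetic-data generator that makes the whole stack testable at
desk scale. This vignette records the model's assumptions, the
parameters that matter, and the design decisions taken where the design
was genuinely open.

# Data model and filters

A mutation record carries a protein accession, a 1-based position,
wild-type and mutant residues, the set of source databases citing it,
an optional binary pathogenicity label, optional disease labels over a
fixed 15-category vocabulary, the residue-level topology code at the
site (five raw codes: B, H, S, i, o), the protein's transmembrane
segment count, and an optional homology-cluster id. Positions are
1-based throughout; conversion to 0-based indexing happens only at
array boundaries.

Validation drops (with a logged reason, never an error) records whose
position exceeds the sequence length (`INVALID_POSITION`) or whose
stated wild-type residue disagrees with the reference sequence
(`INVALID_WT`). The source filter keeps records cited by at least two
of the five recognised variant databases — the device that counters the
over-representation of cancer annotations in large aggregated variant
sets. Both filters are order-preserving and idempotent.

The five topology codes group into three classes: transmembrane (H and
B), cytoplasmic (i), extracellular (o and S — signal peptides sit at
the N-terminus of the nascent chain and are excised from the mature
protein).

Splitting is either random 8:1:1 (floor-allocated, remainder to train;
unstratified by default, stratification behind a flag) or
homology-grouped: a holdout of whole clusters greedily packed to the
target fraction, the remaining clusters dealt round-robin by descending
size into folds, so no cluster ever spans a partition boundary. The
>40 %-identity clustering itself is consumed as input (cluster ids),
not re-implemented: it is an external tool's output, not part of this
method.

# Feature construction

## Per-residue window representation

Each sequence is truncated to a 101-residue window centred on the
mutation site; flanks beyond the sequence are padded, and pad positions
carry zero feature rows and are masked out of all attention. Each
residue row concatenates a sequence embedding (pluggable backend;
default width 1280) with 213 per-residue physicochemical property
scales, giving 101 × 1493 under the defaults. Wild-type and mutant
matrices differ exactly in the centre row (plus whatever a contextual
embedder changes). Whether a full-scale protein language model should
embed the whole protein or the window is ambiguous; the embedder
contract here embeds the window.

The redundancy filter that reduces a large scale catalogue to an
uncorrelated working set (keep the first scale of any pair correlated
above a threshold) ships as a utility (`prune_correlated_scales()`)
over any correlation matrix, but the pipeline treats the 213-scale
table as a fixed input.

## The 537-dim site vector

Eight blocks, fixed order, widths 213 + 94 + 47 + 3 + 140 + 5 + 5 + 30:

1. per-scale differences `scale(mut) − scale(wt)`;
2. substitution-matrix scores `M[wt, mut]` (94 symmetric matrices;
   triangular storage completed on ingest);
3. contact-potential differences `Σ_nbr [M(mut, nbr) − M(wt, nbr)]`
   over the real residues within ±3 of the site, excluding the site —
   the "region adjacent" is read as this flanking neighbourhood, with
   the radius configurable;
4. the raw PSSM site triplet (wild score, mutant score, difference) —
   the three-component reading is the only one that reconciles the
   block widths to the printed total of 537;
5. the Gaussian-weighted local PSSM profile: the PSSM is normalised
   elementwise by the logistic sigmoid `h(x) = 1/(1+e^{−x})` into
   (0, 1); the 7 rows at offsets −3…3 are each multiplied by
   `w_j = exp(−j²/2)` and flattened (140). The raw standard-normal
   density gives `h(0) ≈ 0.399`, which contradicts the stated anchor
   `w⁰ = 1`; normalising the density by its centre value satisfies both
   the Gaussian shape and the anchor, and is what the package
   implements. Out-of-range offsets contribute zero rows — an absence
   marker, deliberately distinct from sigmoid-of-zero (0.5) rows;
6. –7. hydrophobicity and polarity window deltas
   `ΔP = P(mut) − mean(P over wild window)` at window half-widths
   1–5. Five windows × one scale each is the only reading consistent
   with "ten features in total"; the defaults are Kyte–Doolittle
   hydropathy and Grantham polarity (both configurable — the specific
   scales used at full scale are not recorded anywhere authoritative).
   At sequence boundaries the mean's divisor shrinks to the number of
   residues actually present (the alternative, a fixed divisor of
   2j+1, is one argument away);
8. six-category residue-class distribution deltas (aliphatic GALIV,
   aromatic FYW, sulfur-containing MC, polar NQSTP, negative DE,
   positive RHK) over the same five windows (30). The components of
   each window's delta always sum to zero.

PSSMs are consumed in PSI-BLAST ASCII layout with the canonical
ARNDCQEGHILKMFPSTWYV column order; profile generation itself (iterative
search against a reference database) is out of scope, and the synthetic
module fabricates PSSMs with realistic self-preference instead.

## Transmembrane context text

A fixed sentence frame renders the protein name, sequence, position,
substitution, topology phrase and segment count into natural language;
the five raw topology descriptors are used (e.g. "non-transmembrane,
inside"), not the grouped three classes. The rendered string is
embedded by a pluggable text backend with a fixed output width (768 by
default). Template rendering is injective — every slot value is
recoverable by the inverse pattern.

The shipped stub backend tokenises the text and maps each token to a
fixed seeded-hash Gaussian vector, returning the L2-normalised token
sum. A whole-string hash would also satisfy determinism and
injectivity, but it would make any shared wording between two variants
(notably the topology phrase) contribute nothing shared to their
embeddings — unlike any real text encoder — and would therefore make
the transmembrane modality unlearnable by construction. Token-level
hashing keeps the stub honest as a stand-in: shared phrases produce
shared structure, while full sentences remain pairwise distinct.
Pooling behaviour of a real language-model backend (CLS token vs mean)
is left to the backend; the contract only fixes the output width.

# The fusion network

Four modules, Eqs. numbered as implemented:

- **Protein representation learning.** A shared-weight encoder for the
  wild-type and mutant windows: BiLSTM (512 units per direction at full
  scale → 1024 concatenated), a linear reduction to `d_model`, then
  `n_encoder_layers` transformer encoder layers. Each layer is
  multi-head self-attention — per head
  `softmax(Q_i K_iᵀ / √d_k) V_i`, heads concatenated and mapped by
  `W_O` — wrapped with residual connections, row LayerNorm and a
  position-wise feed-forward block. The bare attention equations do
  not train stably when stacked; the residual/LayerNorm/FFN wrapping is
  the standard encoder construction and is a deliberate design choice
  here. Sinusoidal positional encodings are added before the encoder
  (disabled by a flag); pad positions are masked out of every attention
  row.
- **Protein–disease fusion.** The K disease one-hot codes pass through
  a learnable embedding layer, giving K query rows used for every
  sample: `CrossAttention_dp = softmax(Q_d K_pᵀ/√d_k) V_p` with the
  protein embedding as keys and values, applied separately to the
  wild-type and mutant embeddings. These cross-attentions are
  implemented exactly as written — with no additional learnable
  projection matrices, unlike the encoder's self-attention, whose
  equations carry per-head maps. For the binary task this reading
  means both class queries are always present and the model emits a
  single pathogenicity probability; the alternative (feeding the
  ground-truth one-hot as an input) would leak the label and is not
  implementable as an honest predictor.
- **Wild–mutant fusion.** `CrossAttention_wm = softmax(Q_w K_mᵀ/√d_k)
  V_m` with the wild dis-prot embedding as query and the mutant one as
  key/value, plus the subtraction embedding fixed as wild − mutant
  (downstream layers are sign-agnostic).
- **Transmembrane-environment encoder.** The text embedding passes
  through a linear (global) branch and 1-D convolution branches
  (kernels 3 and 5, global max-pool per channel), concatenated.
- **Classification.** The flattened fusion embeddings and the
  transmembrane embedding — plus, in the binary task only, the 537-dim
  site vector — feed a sigmoid MLP: one output (binary) or fifteen
  independent sigmoid outputs (multi-label). Supplying the site vector
  in multi-label mode is a configuration error.

Training follows the published protocol: BCE loss, Adam, learning rate
0.001 with batch 128 (binary) / 0.0001 with batch 256 (multi-label),
100 epochs, dropout 0.2, no early stopping, best checkpoint by
validation F1 ("validation performance" is read as the task's F1; the
threshold is 0.5 and configurable). Encoder depth, width, head count
and the convolution/head widths are not recorded authoritative
full-scale values; they are explicit configuration with declared
defaults.

Because no deep-learning framework exists in this package's dependency
footprint, the network runs on a compact reverse-mode autodiff tape
written in R: matrix-level operations record backward closures; the
three hot paths (BiLSTM, batched multi-head self-attention, the whole
fusion stage) are fused single-node operations with hand-written
backward passes. Every gradient path is verified against
central-difference numeric gradients in the test suite, and the fused
attention ops are additionally checked value-for-value against the
plain-matrix implementations exported as `multihead_self_attention()`,
`fuse_disease_protein()` and `fuse_wild_mutant()`.

# Evaluation suite

Binary metrics come from confusion counts at the threshold (ACC, MCC,
F1, recall, precision, specificity) plus rank-based AUC; with
single-class labels, AUC and MCC are reported as undefined markers,
not numbers. Multi-label metrics are **sample-averaged** precision,
recall and F1 over predicted label sets plus Hamming loss; the exact
averaging convention at full scale is not visible in the main record,
so the convention is declared in every report and macro-averaging is
available behind a flag. An all-zero predicted set contributes
precision 0. Per-disease curves treat records not associated with a
class as that class's negatives; AUC and AUPR are computed per class
(average-precision step integration). Bootstrap confidence intervals
resample evaluation rows with replacement (default 1000 iterations,
95 % percentile interval); resamples on which the metric is undefined
are redrawn and counted. The label co-occurrence matrix holds joint
label fractions, symmetric, with marginal prevalences on the diagonal
(the diagonal convention is this package's choice).

# Synthetic data and what passing tests show

The generator emulates every input the pipeline reads, in the same
file formats: proteins (sequences from a fixed background composition;
topology strings from alternating loop/TM runs with occasional beta
strands and signal peptides; segment counts consistent by
construction), PSSMs (integer log-odds, noise plus a +5 bonus on the
observed residue), property tables at the stated cardinalities
(213/94/47, matrices symmetric, values standardised), and mutation
records.

Pathogenicity follows a latent-logistic threshold rule:
`label = 1[β₀ + β₁·ΔKD-hydropathy + β₂·1(site in H/B) + ε > 0]`,
`ε ~ Logistic(0, noise_scale)`. Defaults — β₀ = 0, β₁ = 0.8, β₂ = 1.0,
noise scale 1 — put the Bayes AUC high but not at 1, a realistic
planted regime: with intercept only the prevalence is `plogis(β₀)`,
and with zero noise the labels are a deterministic function of the
planted score (both properties are tested). Disease labels of
pathogenic records are thresholded noisy projections of the computed
537-dim site vector onto sparse per-disease direction vectors, with
per-class prevalence targets; every pathogenic record is guaranteed at
least one label, and overlap arises naturally. The directions load
only on the substitution-dependent blocks (per-scale differences and
window features), never on the PSSM blocks: the multi-label head does
not receive the site vector, so PSSM-supported signal would be
unrecoverable by construction and would turn an honest end-to-end test
into a guaranteed failure. The first four classes ("well-separated":
zero projection noise, prevalence 0.35) are the recovery benchmarks;
the remaining eleven add projection noise.

Because the planted effects are functions of features the pipeline
itself computes — the hydropathy delta sits in the window blocks, the
topology indicator reaches the model only through the text template,
the disease directions live in the residue-level property blocks —
held-out recovery is a test of the full stack, not of the generator.
What passing does **not** show: anything about real mutation spectra,
real disease prevalences, linkage structure between real diseases, or
the representational quality of real protein/text language models. The
stub embedders are deterministic hashes; a full-scale run would plug
real backends into the same contracts.

# Numerical choices and problem sizes

Attention masking uses an additive −10⁹ on pad columns; softmax rows
are max-shifted before exponentiation; BCE is computed from logits in
its numerically stable form. LayerNorm uses ε = 10⁻⁵. Adam uses the
conventional β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸. All randomness flows
through explicit seeds (child seeds are derived by hashing a parent
seed with a purpose tag, all below 2³¹); no function disturbs the
caller's RNG state.

The end-to-end experiments run a compact configuration
(`tiny_model_config()`: 16 LSTM units per direction, d_model 32, 2
heads, 1 encoder layer, 16-wide stub sequence embedder) on 2000
training and 500 test mutations, 6 epochs for the binary task and 18
for the multi-label task at learning rate 10⁻³ — sizes chosen so a
single CPU core completes the full experiment in a few minutes while
leaving the planted signal clearly recoverable. The published
full-scale hyperparameters remain the package defaults
(`model_config()`, `train_config()`).

# Known limitations

- The multi-label averaging convention and several full-scale
  architecture dimensions are declared defaults, not reproductions of
  authoritative values.
- Exact-duplicate removal is the only deduplication implemented;
  conservation-based deduplication of homologous records is consumed
  via cluster ids, not recomputed.
- The stub embedders carry no biology beyond determinism and shared
  token structure; results with them quantify pipeline correctness,
  not real-data performance.
- Training is single-threaded CPU R; the implementation favours
  clarity and verifiable gradients over throughput, and full-scale
  (1493-wide, 512-unit) training is expressible but not the intended
  use at desk scale.
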