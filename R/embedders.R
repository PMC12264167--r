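# Pluggable embedder backends. The defaults are deterministic seeded
# stubs so the whole pipeline builds and tests without model downloads;
# real protein/text language models can be dropped in behind the same
# contracts.

hash_gauss_vector <- function(key, width, seed) {
  with_seed(derive_seed(seed, key), stats::rnorm(width))
}

#' Deterministic stub sequence embedder
#'
#' Implements the sequence-embedder contract: `embed(window)` returns a
#' `window length x width` matrix, deterministically. Each (residue
#' identity, window offset) pair maps to a fixed pseudo-random Gaussian
#' vector derived from the seed by hashing, and pad positions embed to
#' zero rows. The default width (1280) matches the per-residue width of
#' the protein language model the full-scale pipeline would plug in
#' here.
#'
#' @param width embedding width per residue.
#' @param seed integer seed fixing the hash table.
#' @return an object of class `seq_embedder` with fields `name`,
#'   `width` and `embed(window)`.
#' @export
seq_embedder_stub <- function(width = 1280L, seed = 1L) {
  abort_if(width < 1L, "width must be positive")
  cache <- new.env(parent = emptyenv())
  row_for <- function(residue, offset) {
    key <- paste0(residue, "@", offset)
    val <- cache[[key]]
    if (is.null(val)) {
      val <- hash_gauss_vector(paste0("seqstub:", key), width, seed)
      cache[[key]] <- val
    }
    val
  }
  embed <- function(window) {
    res <- strsplit(window$residues, "")[[1]]
    out <- matrix(0, nrow = length(res), ncol = width)
    for (i in which(window$pad_mask)) out[i, ] <- row_for(res[i], i)
    out
  }
  structure(list(name = sprintf("stub-hash-%d", width),
                 width = as.integer(width), embed = embed),
            class = "seq_embedder")
}

#' Deterministic stub text embedder
#'
#' Implements the text-embedder contract: `embed(text)` returns a fixed-
#' width vector, deterministically. The text is lower-cased and split
#' into alphanumeric tokens; each token maps to a fixed seeded-hash
#' Gaussian vector and the embedding is the L2-normalised token sum.
#' Token-level hashing keeps distinct templates distinct while letting
#' shared wording (for example the topology phrase) contribute shared
#' structure, as a real text encoder's representations would. The
#' default width (768) matches the sentence-embedding width of the
#' biomedical language model the full-scale pipeline would plug in.
#'
#' @param width embedding width.
#' @param seed integer seed fixing the token hash table.
#' @return an object of class `text_embedder` with fields `name`,
#'   `width` and `embed(text)`.
#' @export
text_embedder_stub <- function(width = 768L, seed = 1L) {
  abort_if(width < 1L, "width must be positive")
  cache <- new.env(parent = emptyenv())
  vec_for <- function(token) {
    val <- cache[[token]]
    if (is.null(val)) {
      val <- hash_gauss_vector(paste0("textstub:", token), width, seed)
      cache[[token]] <- val
    }
    val
  }
  embed <- function(text) {
    abort_if(!is.character(text) || length(text) != 1L,
             "embed() expects a single string")
    tokens <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    v <- numeric(width)
    for (tk in tokens) v <- v + vec_for(tk)
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    v
  }
  structure(list(name = sprintf("stub-token-hash-%d", width),
                 width = as.integer(width), embed = embed),
            class = "text_embedder")
}

#' Embed a rendered template with a text backend
#'
#' @param text rendered transmembrane-context template.
#' @param backend a `text_embedder`.
#' @return numeric vector of length `backend$width`.
#' @export
embed_text <- function(text, backend) {
  out <- tryCatch(backend$embed(text), error = function(e) {
    stop(sprintf("text embedder '%s' failed: %s",
                 backend$name %||% "unnamed", conditionMessage(e)),
         call. = FALSE)
  })
  abort_if(length(out) != backend$width,
           sprintf("text embedder '%s' returned width %d, expected %d",
                   backend$name, length(out), backend$width))
  out
}
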