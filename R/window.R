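# Mutation-centred sequence windows and the per-residue feature matrix.

#' Extract the mutation-centred sequence window
#'
#' Truncates the protein to `2 * half_width + 1` residues (101 by
#' default) with the mutation site at the centre. Flanks extending past
#' either end of the sequence are filled with the pad symbol `-` and
#' flagged in `pad_mask`.
#'
#' @param sequence protein sequence string.
#' @param position 1-based mutation position (must be validated).
#' @param half_width number of residues kept on each side.
#' @return a `sequence_window`: list with `residues` (character string of
#'   length `2*half_width+1`), `pad_mask` (logical, `TRUE` = real
#'   residue), `center` (1-based index of the mutation site in the
#'   window) and `source_range` (1-based range in the source sequence).
#' @export
extract_window <- function(sequence, position, half_width = 50L) {
  L <- nchar(sequence)
  abort_if(position < 1L || position > L,
           sprintf("position %d outside sequence of length %d", position, L))
  lo <- position - half_width; hi <- position + half_width
  lo_c <- max(1L, lo); hi_c <- min(L, hi)
  core <- substr(sequence, lo_c, hi_c)
  left <- lo_c - lo; right <- hi - hi_c
  res <- paste0(strrep("-", left), core, strrep("-", right))
  w <- 2L * half_width + 1L
  mask <- rep(TRUE, w)
  if (left > 0L) mask[seq_len(left)] <- FALSE
  if (right > 0L) mask[seq.int(w - right + 1L, w)] <- FALSE
  structure(list(residues = res, pad_mask = mask,
                 center = half_width + 1L,
                 source_range = c(lo_c, hi_c)),
            class = "sequence_window")
}

#' Substitute the centre residue of a window
#'
#' @param window a `sequence_window`.
#' @param mut one-letter mutant residue.
#' @return the mutated `sequence_window`.
#' @export
mutate_window <- function(window, mut) {
  check_residue_letters(mut)
  substr(window$residues, window$center, window$center) <- mut
  window
}

#' Per-residue physicochemical property block of a window
#'
#' Row r holds the property values of window residue r over all scales
#' in the table (213 under the default catalogue); pad positions and
#' nonstandard residues contribute all-zero rows (the latter with a
#' warning).
#'
#' @param window a `sequence_window`.
#' @param scales an `aa_scales` matrix (scales x 20).
#' @return numeric matrix, `length(window)` x `nrow(scales)`.
#' @export
aaindex1_block <- function(window, scales) {
  res <- strsplit(window$residues, "")[[1]]
  out <- matrix(0, nrow = length(res), ncol = nrow(scales),
                dimnames = list(NULL, rownames(scales)))
  known <- res %in% aa_alphabet()
  odd <- window$pad_mask & !known
  if (any(odd)) {
    warning(sprintf("nonstandard residue(s) %s in window: zero property rows",
                    paste(unique(res[odd]), collapse = ",")))
  }
  out[known, ] <- t(scales[, res[known], drop = FALSE])
  out
}

#' Assemble the per-residue feature matrix
#'
#' Column-wise concatenation of the sequence-embedding block and the
#' physicochemical property block, in that order (1280 + 213 = 1493
#' columns under the default widths).
#'
#' @param embedding_block numeric matrix (window length x embed width).
#' @param property_block numeric matrix (window length x n scales).
#' @return a `residue_feature_matrix` with a `block_layout` attribute.
#' @export
assemble_residue_matrix <- function(embedding_block, property_block) {
  abort_if(nrow(embedding_block) != nrow(property_block),
           "embedding and property blocks must have the same number of rows")
  m <- cbind(embedding_block, property_block)
  structure(m,
            block_layout = list(sequence_embedding = ncol(embedding_block),
                                aaindex1_properties = ncol(property_block)),
            class = c("residue_feature_matrix", "matrix"))
}

#' Build the wild-type and mutant feature matrices for one mutation
#'
#' @param sequence reference protein sequence.
#' @param position 1-based mutation position.
#' @param mut mutant residue.
#' @param scales an `aa_scales` matrix.
#' @param embedder a sequence embedder (see [seq_embedder_stub()]).
#' @param half_width window half-width.
#' @return list with `wild`, `mutant` (feature matrices), `window`
#'   (wild-type window) and `pad_mask`.
#' @export
residue_matrices <- function(sequence, position, mut, scales, embedder,
                             half_width = 50L) {
  w_wild <- extract_window(sequence, position, half_width)
  w_mut <- mutate_window(w_wild, mut)
  wild <- assemble_residue_matrix(embedder$embed(w_wild),
                                  aaindex1_block(w_wild, scales))
  mutant <- assemble_residue_matrix(embedder$embed(w_mut),
                                    aaindex1_block(w_mut, scales))
  list(wild = wild, mutant = mutant, window = w_wild,
       pad_mask = w_wild$pad_mask)
}
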