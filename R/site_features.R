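# The 537-dimensional mutation-site feature vector: AAIndex property
# differences, substitution-matrix scores, contact-potential differences,
# PSSM blocks and sliding-window property/category deltas.

#' Per-scale property difference between mutant and wild-type residue
#'
#' Component k is `scale_k(mut) - scale_k(wt)` over the scale catalogue
#' (213 components under the defaults).
#'
#' @param wt,mut standard residue letters.
#' @param scales an `aa_scales` matrix.
#' @return numeric vector, one component per scale.
#' @export
aaindex1_diff <- function(wt, mut, scales) {
  abort_if(!(wt %in% aa_alphabet()) || !(mut %in% aa_alphabet()),
           "aaindex1_diff requires standard residues")
  out <- scales[, mut] - scales[, wt]
  names(out) <- rownames(scales)
  out
}

#' Substitution-matrix scores for a residue exchange
#'
#' Component m is `matrix_m[wt, mut]` over the substitution-matrix
#' collection (94 components under the defaults). Triangular source
#' matrices must have been completed to full symmetric form on ingest.
#'
#' @param wt,mut standard residue letters.
#' @param matrices an `aa_matrix_set`.
#' @return numeric vector, one component per matrix.
#' @export
aaindex2_scores <- function(wt, mut, matrices) {
  abort_if(!(wt %in% aa_alphabet()) || !(mut %in% aa_alphabet()),
           "aaindex2_scores requires standard residues")
  out <- vapply(matrices, function(m) {
    v <- m[wt, mut]
    abort_if(is.na(v), sprintf("missing matrix entry (%s,%s)", wt, mut))
    v
  }, numeric(1))
  out
}

#' Contact-potential difference over the site neighbourhood
#'
#' For each pairwise contact-potential matrix, sums
#' `potential(mut, nbr) - potential(wt, nbr)` over the real (non-pad,
#' standard) residues within `radius` of the mutation site, excluding
#' the site itself (47 components under the defaults). An empty
#' neighbourhood yields a zero vector with a warning.
#'
#' @param wt,mut standard residue letters.
#' @param sequence protein sequence string.
#' @param position 1-based mutation position.
#' @param matrices an `aa_matrix_set` of contact potentials.
#' @param radius neighbourhood half-width.
#' @return numeric vector, one component per matrix.
#' @export
aaindex3_contact_diff <- function(wt, mut, sequence, position, matrices,
                                  radius = 3L) {
  abort_if(!(wt %in% aa_alphabet()) || !(mut %in% aa_alphabet()),
           "aaindex3_contact_diff requires standard residues")
  L <- nchar(sequence)
  nbr_pos <- setdiff(seq.int(max(1L, position - radius),
                             min(L, position + radius)), position)
  nbrs <- strsplit(substr(sequence, 1L, L), "")[[1]][nbr_pos]
  nbrs <- nbrs[nbrs %in% aa_alphabet()]
  if (length(nbrs) == 0L) {
    warning("empty neighbourhood: contact-potential difference is zero")
    return(stats::setNames(numeric(length(matrices)), names(matrices)))
  }
  vapply(matrices, function(m) {
    sum(m[mut, nbrs]) - sum(m[wt, nbrs])
  }, numeric(1))
}

#' Sliding-window property delta at the mutation site
#'
#' The mutant residue's property value minus the mean property over the
#' wild-type residues in the window `[position - j, position + j]`
#' (window sizes 3, 5, 7, 9, 11 for half-widths j = 1..5). At sequence
#' boundaries the mean is taken over the residues that exist (the
#' divisor shrinks to the real-residue count).
#'
#' @param sequence protein sequence string.
#' @param position 1-based mutation position.
#' @param mut mutant residue letter.
#' @param scale named numeric property vector over the 20 residues.
#' @param half_width_j window half-width (1..5).
#' @return scalar delta.
#' @export
window_property_delta <- function(sequence, position, mut, scale,
                                  half_width_j) {
  L <- nchar(sequence)
  win <- seq.int(max(1L, position - half_width_j),
                 min(L, position + half_width_j))
  res <- strsplit(sequence, "")[[1]][win]
  res <- res[res %in% names(scale)]
  abort_if(length(res) == 0L, "no standard residues in window")
  unname(scale[mut] - mean(scale[res]))
}

#' Window category-distribution delta
#'
#' Difference between the six-category residue-class distributions of
#' the mutant and wild-type windows `[position - j, position + j]`. The
#' two windows are identical except for the centre residue, and the six
#' components always sum to zero.
#'
#' @inheritParams window_property_delta
#' @return numeric vector of length 6 in [aa_category_levels()] order.
#' @export
category_distribution_delta <- function(sequence, position, mut,
                                        half_width_j) {
  L <- nchar(sequence)
  win <- seq.int(max(1L, position - half_width_j),
                 min(L, position + half_width_j))
  res <- strsplit(sequence, "")[[1]][win]
  mres <- res
  mres[win == position] <- mut
  lv <- aa_category_levels()
  frac <- function(r) {
    r <- r[r %in% names(aa_category())]
    tabulate(factor(aa_category(r), levels = lv), nbins = length(lv)) /
      length(r)
  }
  stats::setNames(frac(mres) - frac(res), lv)
}

#' Default site-vector block layout
#'
#' @return named integer vector of block widths summing to 537.
#' @export
site_vector_layout <- function() {
  c(aaindex1_diff = 213L, aaindex2_scores = 94L, aaindex3_contact_diff = 47L,
    pssm_site_triplet = 3L, local_pssm = 140L,
    window_hydro = 5L, window_polar = 5L, category_delta = 30L)
}

#' Assemble the pathogenicity-sensitive site feature vector
#'
#' Concatenates the eight feature blocks in the fixed layout
#' (213 + 94 + 47 + 3 + 140 + 5 + 5 + 30 = 537 under the defaults): the
#' per-scale property differences, substitution-matrix scores,
#' neighbourhood contact-potential differences, the raw PSSM site
#' triplet, the Gaussian-weighted local profile of the sigmoid-
#' normalised PSSM, hydrophobicity and polarity window deltas at the
#' five window sizes, and the six-category distribution deltas at the
#' same five windows.
#'
#' @param sequence protein sequence string.
#' @param position 1-based mutation position.
#' @param wt,mut residue letters.
#' @param pssm raw L x 20 PSSM for the protein.
#' @param tables list with components `scales` (`aa_scales`, 213 rows),
#'   `subst` (`aa_matrix_set`, 94 matrices) and `contact`
#'   (`aa_matrix_set`, 47 matrices).
#' @param hydro_scale,polarity_scale property vectors for the window
#'   deltas; default Kyte-Doolittle hydropathy and Grantham polarity.
#' @param window_half_widths half-widths of the sliding windows.
#' @return a named numeric vector with a `block_layout` attribute.
#' @export
site_feature_vector <- function(sequence, position, wt, mut, pssm, tables,
                                hydro_scale = kd_hydropathy(),
                                polarity_scale = grantham_polarity(),
                                window_half_widths = 1:5) {
  abort_if(substr(sequence, position, position) != wt,
           "wild-type residue does not match the sequence")
  b1 <- aaindex1_diff(wt, mut, tables$scales)
  b2 <- aaindex2_scores(wt, mut, tables$subst)
  b3 <- aaindex3_contact_diff(wt, mut, sequence, position, tables$contact)
  b4 <- pssm_site_triplet(pssm, position, wt, mut)
  b5 <- local_pssm_features(normalize_pssm(pssm), position)
  b6 <- vapply(window_half_widths, function(j)
    window_property_delta(sequence, position, mut, hydro_scale, j), numeric(1))
  names(b6) <- paste0("hydro_j", window_half_widths)
  b7 <- vapply(window_half_widths, function(j)
    window_property_delta(sequence, position, mut, polarity_scale, j), numeric(1))
  names(b7) <- paste0("polar_j", window_half_widths)
  b8 <- unlist(lapply(window_half_widths, function(j) {
    v <- category_distribution_delta(sequence, position, mut, j)
    names(v) <- paste0("cat_j", j, "_", names(v))
    v
  }))
  blocks <- list(aaindex1_diff = b1, aaindex2_scores = b2,
                 aaindex3_contact_diff = b3, pssm_site_triplet = b4,
                 local_pssm = b5, window_hydro = b6, window_polar = b7,
                 category_delta = b8)
  widths <- vapply(blocks, length, 1L)
  layout <- site_vector_layout()
  layout[c("window_hydro", "window_polar")] <- length(window_half_widths)
  layout["category_delta"] <- 6L * length(window_half_widths)
  layout["aaindex1_diff"] <- nrow(tables$scales)
  layout["aaindex2_scores"] <- length(tables$subst)
  layout["aaindex3_contact_diff"] <- length(tables$contact)
  abort_if(!identical(unname(widths), unname(layout[names(widths)])),
           "site-vector block has unexpected width")
  out <- unlist(blocks)
  structure(out, block_layout = widths)
}
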