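# Evolutionary (PSSM-derived) features: sigmoid normalisation, Gaussian
# positional decay, the weighted local profile and the site score triplet.

#' Sigmoid-normalise a PSSM to the (0,1) interval
#'
#' Applies `h(x) = 1 / (1 + exp(-x))` elementwise to the raw log-odds
#' scores; shape and attributes are preserved.
#'
#' @param pssm L x 20 matrix of raw log-odds.
#' @return matrix of the same shape with entries strictly in (0,1).
#' @export
normalize_pssm <- function(pssm) {
  out <- 1 / (1 + exp(-pssm))
  attributes(out) <- attributes(pssm)
  out
}

#' Gaussian positional decay weights
#'
#' Weights for window offsets `-half_width .. half_width`, proportional
#' to the standard normal density and anchored so the centre weight is
#' exactly 1: `w_j = exp(-j^2 / 2)`. Weights are symmetric and strictly
#' decreasing in |j|.
#'
#' @param half_width window half-width (3 gives the 7-residue profile).
#' @return named numeric vector of length `2 * half_width + 1`.
#' @export
gaussian_weights <- function(half_width = 3L) {
  j <- seq.int(-half_width, half_width)
  stats::setNames(exp(-j^2 / 2), as.character(j))
}

#' Gaussian-weighted local PSSM feature block
#'
#' Takes the 7 rows of the sigmoid-normalised PSSM centred on the
#' mutation site (offsets -3..3), multiplies the 20 values of each row
#' by the Gaussian decay weight of its offset, and flattens offset-major
#' into a 140-vector. Offsets falling outside the sequence contribute
#' zero rows (an explicit absence marker).
#'
#' @param norm_pssm sigmoid-normalised PSSM (see [normalize_pssm()]).
#' @param position 1-based mutation position.
#' @param half_width local window half-width.
#' @return numeric vector of length `(2*half_width+1) * 20`.
#' @export
local_pssm_features <- function(norm_pssm, position, half_width = 3L) {
  w <- gaussian_weights(half_width)
  offs <- seq.int(-half_width, half_width)
  L <- nrow(norm_pssm)
  block <- matrix(0, nrow = length(offs), ncol = 20L)
  for (k in seq_along(offs)) {
    p <- position + offs[k]
    if (p >= 1L && p <= L) block[k, ] <- w[k] * norm_pssm[p, ]
  }
  out <- as.vector(t(block))
  names(out) <- paste0("lpssm_", rep(offs, each = 20L), "_",
                       rep(aa_alphabet(), times = length(offs)))
  out
}

#' Site-level PSSM score triplet
#'
#' Raw log-odds of the wild-type and mutant residues at the mutation
#' site, plus their difference (mutant minus wild-type).
#'
#' @param pssm raw L x 20 PSSM.
#' @param position 1-based mutation position.
#' @param wt,mut residue letters.
#' @return numeric vector `c(score_wt, score_mut, score_mut - score_wt)`.
#' @export
pssm_site_triplet <- function(pssm, position, wt, mut) {
  abort_if(position < 1L || position > nrow(pssm),
           "position outside the PSSM")
  check_residue_letters(c(wt, mut))
  s_wt <- pssm[position, wt]
  s_mut <- pssm[position, mut]
  c(pssm_wt = unname(s_wt), pssm_mut = unname(s_mut),
    pssm_diff = unname(s_mut - s_wt))
}
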