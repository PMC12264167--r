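# Natural-language transmembrane-context template and its embedding.

#' Natural-language phrase for a topology code
#'
#' Uses the five raw descriptors (not the grouped three classes):
#' B = "transmembrane beta strand", H = "transmembrane alpha helix",
#' S = "signal peptide", i = "non-transmembrane, inside",
#' o = "non-transmembrane, outside".
#'
#' @param code character vector of topology codes.
#' @return character vector of phrases.
#' @export
topology_phrase <- function(code) {
  map <- c(B = "transmembrane beta strand",
           H = "transmembrane alpha helix",
           S = "signal peptide",
           i = "non-transmembrane, inside",
           o = "non-transmembrane, outside")
  bad <- setdiff(unique(code), names(map))
  abort_if(length(bad) > 0L,
           sprintf("unknown topology code(s): %s", paste(bad, collapse = ",")))
  unname(map[code])
}

#' Render the transmembrane-context text template
#'
#' Produces the fixed sentence frame describing one mutation in its
#' transmembrane context: protein name, sequence, 1-based mutation
#' position, wild-type and mutant residue, topology phrase of the site
#' and the number of transmembrane segments of the protein.
#'
#' @param protein_name protein name string.
#' @param sequence protein sequence string.
#' @param position 1-based mutation position.
#' @param wt,mut residue letters.
#' @param topology_code raw topology code of the mutation site.
#' @param n_tm_segments number of transmembrane segments.
#' @return a single rendered string.
#' @export
render_tm_template <- function(protein_name, sequence, position, wt, mut,
                               topology_code, n_tm_segments) {
  fields <- list(protein_name, sequence, position, wt, mut, topology_code,
                 n_tm_segments)
  abort_if(any(vapply(fields, function(x) is.null(x) || is.na(x) ||
                        !nzchar(as.character(x)), TRUE)),
           "all template fields must be present")
  sprintf(paste0(
    "Transmembrane protein %s, the protein sequence is %s, ",
    "the residue at position %d is mutated from %s to %s, ",
    "the topology of the mutation site is %s, ",
    "and the number of transmembrane fragments of this transmembrane ",
    "protein is %d"),
    protein_name, sequence, as.integer(position), wt, mut,
    topology_phrase(topology_code), as.integer(n_tm_segments))
}

#' Recover the slot values from a rendered template
#'
#' Inverse of [render_tm_template()]; errors if the string does not
#' match the sentence frame.
#'
#' @param text a rendered template string.
#' @return list of the slot values (with `topology_code` mapped back
#'   from the phrase).
#' @export
parse_tm_template <- function(text) {
  pat <- paste0(
    "^Transmembrane protein (.+), the protein sequence is ([A-Za-z-]+), ",
    "the residue at position ([0-9]+) is mutated from ([A-Z]) to ([A-Z]), ",
    "the topology of the mutation site is (.+), ",
    "and the number of transmembrane fragments of this transmembrane ",
    "protein is ([0-9]+)$")
  m <- regmatches(text, regexec(pat, text))[[1]]
  abort_if(length(m) != 8L, "string does not match the template frame")
  phrases <- topology_phrase(topology_codes())
  code <- topology_codes()[match(m[7], phrases)]
  abort_if(is.na(code), sprintf("unknown topology phrase: %s", m[7]))
  list(protein_name = m[2], sequence = m[3], position = as.integer(m[4]),
       wt = m[5], mut = m[6], topology_code = code,
       n_tm_segments = as.integer(m[8]))
}

#' Render and embed the transmembrane context of one mutation
#'
#' @inheritParams render_tm_template
#' @param backend a `text_embedder` (default stub of width 768).
#' @return list with `template_text` and `embedding`.
#' @export
tm_context_feature <- function(protein_name, sequence, position, wt, mut,
                               topology_code, n_tm_segments,
                               backend = text_embedder_stub()) {
  txt <- render_tm_template(protein_name, sequence, position, wt, mut,
                            topology_code, n_tm_segments)
  list(template_text = txt, embedding = embed_text(txt, backend))
}
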