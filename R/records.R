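# Mutation-record data model: vocabularies, validation, source filtering,
# topology grouping and dataset construction.

#' Controlled vocabularies for mutation records
#'
#' `source_db_vocab()` lists the variant databases a record may cite.
#' `disease_vocab()` returns the fixed 15-category disease vocabulary in
#' its canonical vector order; `disease_codes()` the matching short codes
#' used in label strings.
#'
#' @return character vector.
#' @export
source_db_vocab <- function() {
  c("Humsavar", "SwissVar", "1000Genomes", "COSMIC", "ClinVar")
}

#' @rdname source_db_vocab
#' @export
disease_codes <- function() {
  c("NSD", "DSD", "OCD", "CDM", "RSD", "CD", "RD", "ISD",
    "EMD", "MD", "USD", "SD", "CN", "NP", "UNK")
}

#' @rdname source_db_vocab
#' @export
disease_vocab <- function() {
  c(NSD = "nervous system diseases",
    DSD = "digestive system diseases",
    OCD = "other congenital disorders",
    CDM = "congenital disorders of metabolism",
    RSD = "reproductive system diseases",
    CD  = "cardiovascular diseases",
    RD  = "respiratory diseases",
    ISD = "immune system diseases",
    EMD = "endocrine and metabolic diseases",
    MD  = "musculoskeletal diseases",
    USD = "urinary system diseases",
    SD  = "skin diseases",
    CN  = "cancers",
    NP  = "not provided",
    UNK = "unknown")
}

#' Topology codes and their three-way grouping
#'
#' Residue-level topology uses five raw codes: transmembrane beta strand
#' (`B`), transmembrane alpha helix (`H`), signal peptide (`S`),
#' non-transmembrane inside (`i`) and non-transmembrane outside (`o`).
#' `map_topology()` groups them into three classes: transmembrane
#' (H and B), cytoplasmic (i) and extracellular (o and S; signal
#' peptides sit at the N-terminus of the nascent chain and are excised
#' from the mature protein).
#'
#' @param code character vector of topology codes.
#' @return character vector of class names.
#' @export
map_topology <- function(code) {
  map <- c(H = "transmembrane", B = "transmembrane",
           i = "cytoplasmic",
           o = "extracellular", S = "extracellular")
  bad <- setdiff(unique(code), names(map))
  abort_if(length(bad) > 0L,
           sprintf("unknown topology code(s): %s", paste(bad, collapse = ",")))
  unname(map[code])
}

#' @rdname map_topology
#' @export
topology_codes <- function() c("B", "H", "S", "i", "o")

#' Construct a table of mutation records
#'
#' The record schema is a plain data frame with one row per missense
#' variant: `protein_id`, `protein_name`, `position` (1-based),
#' `wt`, `mut` (one-letter residues), `sources` (semicolon-separated
#' subset of [source_db_vocab()]), `patho_label` (1 pathogenic /
#' 0 neutral / `NA` unlabelled), `disease_labels` (semicolon-separated
#' subset of [disease_codes()], pathogenic records only), `topology`
#' (raw code at the mutation site), `n_tm_segments`, `cluster_id`.
#'
#' @param protein_id,position,wt,mut required record fields.
#' @param protein_name,sources,patho_label,disease_labels,topology,n_tm_segments,cluster_id
#'   optional fields (recycled as usual).
#' @return a `mutation_table` data frame.
#' @export
mutation_table <- function(protein_id, position, wt, mut,
                           protein_name = protein_id, sources = "",
                           patho_label = NA_integer_, disease_labels = "",
                           topology = NA_character_,
                           n_tm_segments = NA_integer_,
                           cluster_id = NA_character_) {
  d <- data.frame(protein_id = protein_id, protein_name = protein_name,
                  position = as.integer(position), wt = wt, mut = mut,
                  sources = sources, patho_label = as.integer(patho_label),
                  disease_labels = disease_labels, topology = topology,
                  n_tm_segments = as.integer(n_tm_segments),
                  cluster_id = cluster_id,
                  stringsAsFactors = FALSE)
  check_residue_letters(c(d$wt, d$mut))
  abort_if(any(d$wt == d$mut),
           "wild-type and mutant residues must differ")
  src <- parse_semicolon_field(d$sources)
  bad <- setdiff(unique(unlist(src)), source_db_vocab())
  abort_if(length(bad) > 0L,
           sprintf("unknown source database(s): %s", paste(bad, collapse = ",")))
  dis <- parse_semicolon_field(d$disease_labels)
  badd <- setdiff(unique(unlist(dis)), disease_codes())
  abort_if(length(badd) > 0L,
           sprintf("unknown disease label(s): %s", paste(badd, collapse = ",")))
  has_dis <- vapply(dis, length, 1L) > 0L
  abort_if(any(has_dis & (is.na(d$patho_label) | d$patho_label != 1L)),
           "disease labels are only allowed on pathogenic (label 1) records")
  class(d) <- c("mutation_table", "data.frame")
  d
}

check_residue_letters <- function(x) {
  x <- x[!is.na(x)]
  abort_if(!all(grepl("^[A-Z]$", x)),
           "malformed residue letter (expected a single uppercase letter)")
  invisible(TRUE)
}

parse_semicolon_field <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Validate records against their reference sequences
#'
#' A record is `VALID` when its position lies inside the reference
#' sequence and the sequence letter at that (1-based) position equals the
#' stated wild-type residue; otherwise the verdict is `INVALID_POSITION`
#' or `INVALID_WT`. Invalid records are meant to be dropped (and logged),
#' not raised.
#'
#' @param records a `mutation_table`.
#' @param sequences named character vector (or list) of reference
#'   sequences keyed by `protein_id`.
#' @return character vector of verdicts, one per record.
#' @export
validate_records <- function(records, sequences) {
  sequences <- unlist(sequences)
  abort_if(!all(records$protein_id %in% names(sequences)),
           "reference sequence missing for some protein_id")
  check_residue_letters(c(records$wt, records$mut))
  seqs <- sequences[records$protein_id]
  abort_if(any(!nzchar(seqs)), "empty reference sequence")
  len <- nchar(seqs)
  verdict <- rep("VALID", nrow(records))
  out_of_range <- records$position < 1L | records$position > len
  verdict[out_of_range] <- "INVALID_POSITION"
  at <- substr(seqs, records$position, records$position)
  verdict[!out_of_range & at != records$wt] <- "INVALID_WT"
  verdict
}

#' @rdname validate_records
#' @param quiet suppress the per-reason drop counts.
#' @return `drop_invalid_records()` returns the surviving subset.
#' @export
drop_invalid_records <- function(records, sequences, quiet = FALSE) {
  v <- validate_records(records, sequences)
  if (!quiet && any(v != "VALID")) {
    tab <- table(v[v != "VALID"])
    log_msg("dropping %d invalid record(s): %s", sum(v != "VALID"),
            paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "))
  }
  records[v == "VALID", , drop = FALSE]
}

#' Keep records present in at least `min_sources` databases
#'
#' Order-preserving filter on the number of distinct source databases a
#' record cites; mirrors the dataset-construction rule of requiring
#' support from at least two of the five variant databases.
#'
#' @param records a `mutation_table`.
#' @param min_sources minimum number of distinct source databases.
#' @return the surviving subset, original order preserved.
#' @export
filter_min_sources <- function(records, min_sources = 2L) {
  src <- parse_semicolon_field(records$sources)
  bad <- setdiff(unique(unlist(src)), source_db_vocab())
  abort_if(length(bad) > 0L,
           sprintf("unknown source database(s): %s", paste(bad, collapse = ",")))
  n <- vapply(src, function(v) length(unique(v)), 1L)
  records[n >= min_sources, , drop = FALSE]
}

#' Build the binary pathogenicity dataset
#'
#' Retains records with a binary pathogenicity label (1 pathogenic /
#' 0 neutral); unlabelled records are excluded with a logged count.
#'
#' @param records a validated, source-filtered `mutation_table`.
#' @param quiet suppress exclusion messages.
#' @return the labelled subset.
#' @export
build_patho_dataset <- function(records, quiet = FALSE) {
  if (nrow(records) == 0L) {
    warning("empty input: pathogenicity dataset has no records")
    return(records)
  }
  keep <- !is.na(records$patho_label)
  if (!quiet && any(!keep)) {
    log_msg("excluding %d record(s) without a pathogenicity label", sum(!keep))
  }
  out <- records[keep, , drop = FALSE]
  abort_if(!all(out$patho_label %in% c(0L, 1L)),
           "pathogenicity labels must be 0 or 1")
  out
}

#' Build the multi-label disease dataset
#'
#' Keeps only pathogenic records and exposes their disease annotations as
#' an N x 15 binary matrix (a record may carry several active labels).
#'
#' @param records a `mutation_table`.
#' @return list with elements `records` (the pathogenic subset) and
#'   `labels` (N x 15 binary matrix, columns in [disease_codes()] order).
#' @export
build_disease_dataset <- function(records) {
  patho <- records[!is.na(records$patho_label) & records$patho_label == 1L, ,
                   drop = FALSE]
  labels <- disease_label_matrix(patho$disease_labels)
  list(records = patho, labels = labels)
}

#' Expand semicolon-separated disease labels to a binary matrix
#'
#' @param x character vector of semicolon-separated disease codes.
#' @return N x 15 binary matrix with columns in [disease_codes()] order.
#' @export
disease_label_matrix <- function(x) {
  codes <- disease_codes()
  lst <- parse_semicolon_field(x)
  bad <- setdiff(unique(unlist(lst)), codes)
  abort_if(length(bad) > 0L,
           sprintf("unknown disease label(s): %s", paste(bad, collapse = ",")))
  m <- matrix(0L, nrow = length(lst), ncol = length(codes),
              dimnames = list(NULL, codes))
  for (i in seq_along(lst)) m[i, lst[[i]]] <- 1L
  m
}

#' Collapse a binary disease matrix back to label strings
#'
#' @param m N x 15 binary matrix.
#' @return character vector of semicolon-separated codes.
#' @export
disease_label_strings <- function(m) {
  codes <- disease_codes()
  apply(m, 1L, function(r) paste(codes[r > 0], collapse = ";"))
}
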