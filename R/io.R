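# File formats: FASTA sequences, PSI-BLAST ASCII PSSMs, mutation tables.

#' Read protein sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` that joins wrapped
#' records and enforces unique identifiers (the first whitespace-
#' delimited token of each header).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  abort_if(length(set) == 0L, sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0L,
           sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ",")))
  seqs <- as.character(set)
  abort_if(!all(grepl("^[A-Za-z]+$", seqs)),
           "illegal characters in FASTA sequence")
  stats::setNames(toupper(seqs), ids)
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::AAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the 20-column log-odds block of PSI-BLAST ASCII output
#' (position, residue letter, 20 integers, possibly followed by the
#' weighted-percentage columns, which are ignored). Columns are kept in
#' the canonical ARNDCQEGHILKMFPSTWYV order.
#'
#' @param path PSSM file path.
#' @param sequence optional reference sequence; residue letters are
#'   cross-checked and mismatches produce a positional warning.
#' @return a `pssm`: L x 20 numeric matrix with a `residues` attribute.
#' @export
read_pssm_ascii <- function(path, sequence = NULL) {
  lines <- readLines(path)
  # locate the header carrying the 20 residue letters
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)[1]
  abort_if(is.na(hdr), sprintf("no PSSM header found in %s", path))
  cols <- strsplit(trimws(lines[hdr]), "\\s+")[[1]][seq_len(20L)]
  abort_if(!identical(sort(cols), sort(aa_alphabet())),
           "PSSM header does not list the 20 standard residues")
  rows <- list(); residues <- character(0)
  for (ln in lines[(hdr + 1L):length(lines)]) {
    t <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(t) < 22L || !grepl("^[0-9]+$", t[1])) {
      if (length(residues) > 0L) break else next
    }
    v <- suppressWarnings(as.numeric(t[3:22]))
    abort_if(anyNA(v), sprintf("non-numeric PSSM cell at position %s", t[1]))
    rows[[length(rows) + 1L]] <- v
    residues <- c(residues, t[2])
  }
  abort_if(length(rows) == 0L, sprintf("no PSSM rows found in %s", path))
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  m <- m[, aa_alphabet(), drop = FALSE]
  if (!is.null(sequence)) {
    ref <- strsplit(sequence, "")[[1]]
    bad <- which(residues != ref[seq_along(residues)])
    if (length(bad) > 0L) {
      warning(sprintf("PSSM residue letters differ from FASTA at position(s) %s",
                      paste(utils::head(bad, 5L), collapse = ",")))
    }
  }
  structure(m, residues = residues, class = c("pssm", "matrix"))
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' @param pssm L x 20 matrix (a `pssm` or plain matrix).
#' @param path output path.
#' @param residues residue letter per row; defaults to the `residues`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(pssm, path, residues = NULL) {
  residues <- residues %||% attr(pssm, "residues")
  abort_if(is.null(residues) || length(residues) != nrow(pssm),
           "need one residue letter per PSSM row")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("            ", paste(sprintf("%3s", aa_alphabet()),
                                          collapse = "")), con)
  for (i in seq_len(nrow(pssm))) {
    writeLines(paste0(sprintf("%5d %s  ", i, residues[i]),
                      paste(sprintf("%3d", as.integer(round(pssm[i, ]))),
                            collapse = "")), con)
  }
  invisible(path)
}

#' Read / write a mutation table as TSV
#'
#' The on-disk layout has one row per record with columns `protein_id`,
#' `protein_name`, `position`, `wt`, `mut`, `sources`, `patho_label`,
#' `disease_labels`, `topology`, `n_tm_segments`, `cluster_id`;
#' `sources` and `disease_labels` are semicolon-separated lists and
#' optional columns may be empty.
#'
#' @param path TSV file path.
#' @return a `mutation_table`.
#' @export
read_mutation_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""),
                         colClasses = "character")
  req <- c("protein_id", "position", "wt", "mut")
  abort_if(!all(req %in% names(d)),
           sprintf("mutation table must have columns: %s",
                   paste(req, collapse = ", ")))
  blank <- function(x) ifelse(is.na(x), "", x)
  mutation_table(
    protein_id = d$protein_id,
    position = as.integer(d$position),
    wt = d$wt, mut = d$mut,
    protein_name = if ("protein_name" %in% names(d))
      ifelse(is.na(d$protein_name), d$protein_id, d$protein_name) else d$protein_id,
    sources = if ("sources" %in% names(d)) blank(d$sources) else "",
    patho_label = if ("patho_label" %in% names(d))
      as.integer(d$patho_label) else NA_integer_,
    disease_labels = if ("disease_labels" %in% names(d))
      blank(d$disease_labels) else "",
    topology = if ("topology" %in% names(d)) d$topology else NA_character_,
    n_tm_segments = if ("n_tm_segments" %in% names(d))
      as.integer(d$n_tm_segments) else NA_integer_,
    cluster_id = if ("cluster_id" %in% names(d)) d$cluster_id else NA_character_)
}

#' @rdname read_mutation_table
#' @param records a `mutation_table`.
#' @export
write_mutation_table <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
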