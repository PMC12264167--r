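# Amino-acid alphabets, reference property scales, and AAIndex-style
# property-table ingestion.

#' The 20 standard amino acids in PSI-BLAST column order
#'
#' All position-specific scoring matrices and property tables in the
#' package use this fixed residue order (ARNDCQEGHILKMFPSTWYV), the
#' de facto layout of PSI-BLAST ASCII output.
#'
#' @return character vector of 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Reference hydrophobicity scale used by the sliding-window property
#' deltas (positive = hydrophobic).
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
kd_hydropathy <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Grantham polarity scale
#'
#' Reference polarity scale used by the sliding-window property deltas.
#'
#' @return named numeric vector over the 20 standard residues.
#' @export
grantham_polarity <- function() {
  c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
    G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
    P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9)
}

#' Physicochemical category of each standard residue
#'
#' The six classes used by the window category-distribution features:
#' aliphatic (G,A,L,I,V), aromatic (F,Y,W), sulfur-containing (M,C),
#' polar (N,Q,S,T,P), negatively charged (D,E) and positively charged
#' (R,H,K).
#'
#' @param residues optional character vector of one-letter codes; when
#'   omitted the full residue -> category map is returned.
#' @return character vector of category names.
#' @export
aa_category <- function(residues = NULL) {
  map <- c(G = "aliphatic", A = "aliphatic", L = "aliphatic", I = "aliphatic",
           V = "aliphatic",
           F = "aromatic", Y = "aromatic", W = "aromatic",
           M = "sulfur", C = "sulfur",
           N = "polar", Q = "polar", S = "polar", T = "polar", P = "polar",
           D = "negative", E = "negative",
           R = "positive", H = "positive", K = "positive")
  if (is.null(residues)) return(map)
  abort_if(!all(residues %in% names(map)),
           sprintf("nonstandard residue(s): %s",
                   paste(setdiff(residues, names(map)), collapse = ",")))
  unname(map[residues])
}

#' @rdname aa_category
#' @export
aa_category_levels <- function() {
  c("aliphatic", "aromatic", "sulfur", "polar", "negative", "positive")
}

# ---- per-residue scale tables (AAIndex1 style) -------------------------------

new_scales <- function(values) {
  stopifnot(is.matrix(values), ncol(values) == 20L)
  colnames(values) <- aa_alphabet()
  structure(values, class = c("aa_scales", "matrix"))
}

#' Read a per-residue scale table from long-format TSV
#'
#' Expects three columns `scale_id`, `residue`, `value`; each scale must
#' cover the 20 standard residues.
#'
#' @param path path to a TSV file.
#' @return an `aa_scales` matrix (scales x 20 residues).
#' @export
read_scales_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  abort_if(!all(c("scale_id", "residue", "value") %in% names(d)),
           "scale TSV must have columns scale_id, residue, value")
  ids <- unique(d$scale_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = 20L,
              dimnames = list(ids, aa_alphabet()))
  idx <- cbind(match(d$scale_id, ids), match(d$residue, aa_alphabet()))
  abort_if(anyNA(idx[, 2]), "scale TSV contains a nonstandard residue code")
  m[idx] <- d$value
  abort_if(anyNA(m), "scale TSV does not cover all 20 residues for every scale")
  new_scales(m)
}

#' Write a per-residue scale table as long-format TSV
#'
#' @param scales an `aa_scales` matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scales_tsv <- function(scales, path) {
  d <- data.frame(
    scale_id = rep(rownames(scales), each = 20L),
    residue = rep(aa_alphabet(), times = nrow(scales)),
    value = sprintf("%.17g", as.vector(t(scales))))  # exact double round-trip
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-residue scales from the native AAIndex1 flat-file layout
#'
#' Parses `H` accession lines and the two `I`-block value rows laid out
#' over the residue order A/L, R/K, N/M, D/F, C/P, Q/S, E/T, G/W, H/Y, I/V.
#'
#' @param path path to an AAIndex1-style flat file.
#' @return an `aa_scales` matrix.
#' @export
read_scales_flat <- function(path) {
  lines <- readLines(path)
  # native column order of the two I rows
  row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ids <- character(0); vals <- list()
  i <- 1L; cur <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "H ")) {
      cur <- trimws(sub("^H ", "", ln))
    } else if (startsWith(ln, "I ")) {
      abort_if(is.null(cur), "AAIndex1 flat file: I block before any H line")
      v1 <- as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]])
      v2 <- as.numeric(strsplit(trimws(lines[i + 2L]), "\\s+")[[1]])
      abort_if(length(v1) != 10L || length(v2) != 10L || anyNA(c(v1, v2)),
               sprintf("AAIndex1 flat file: malformed value rows for %s", cur))
      v <- numeric(20L); names(v) <- aa_alphabet()
      v[row1] <- v1; v[row2] <- v2
      ids <- c(ids, cur); vals[[length(vals) + 1L]] <- v
      i <- i + 2L
    }
    i <- i + 1L
  }
  abort_if(length(ids) == 0L, "AAIndex1 flat file: no entries found")
  m <- do.call(rbind, vals)
  rownames(m) <- ids
  new_scales(m)
}

# ---- 20x20 matrix collections (AAIndex2/3 style) -----------------------------

new_matrix_set <- function(mats) {
  stopifnot(is.list(mats), length(mats) > 0L)
  for (m in mats) {
    stopifnot(is.matrix(m), nrow(m) == 20L, ncol(m) == 20L)
  }
  mats <- lapply(mats, function(m) {
    dimnames(m) <- list(aa_alphabet(), aa_alphabet()); m
  })
  structure(mats, class = "aa_matrix_set")
}

#' Complete a triangular 20x20 matrix to a full symmetric one
#'
#' @param m 20x20 matrix with `NA` above (or below) the diagonal.
#' @return full symmetric matrix.
#' @export
complete_symmetric <- function(m) {
  stopifnot(nrow(m) == 20L, ncol(m) == 20L)
  miss <- is.na(m)
  m[miss] <- t(m)[miss]
  abort_if(anyNA(m), "matrix entry missing after symmetric completion")
  m
}

#' Read a collection of 20x20 matrices from long-format TSV
#'
#' Expects columns `matrix_id`, `row`, `col`, `value`; triangular storage
#' is completed symmetrically.
#'
#' @param path path to a TSV file.
#' @return an `aa_matrix_set` (named list of 20x20 matrices).
#' @export
read_matrix_set_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  abort_if(!all(c("matrix_id", "row", "col", "value") %in% names(d)),
           "matrix TSV must have columns matrix_id, row, col, value")
  aa <- aa_alphabet()
  abort_if(!all(d$row %in% aa) || !all(d$col %in% aa),
           "matrix TSV contains a nonstandard residue code")
  mats <- lapply(split(d, d$matrix_id), function(dd) {
    m <- matrix(NA_real_, 20L, 20L, dimnames = list(aa, aa))
    m[cbind(match(dd$row, aa), match(dd$col, aa))] <- dd$value
    complete_symmetric(m)
  })
  new_matrix_set(mats[unique(d$matrix_id)])
}

#' Write a collection of 20x20 matrices as long-format TSV
#'
#' @param mats an `aa_matrix_set`.
#' @param path output path.
#' @param triangular write only the lower triangle (including diagonal).
#' @return `path`, invisibly.
#' @export
write_matrix_set_tsv <- function(mats, path, triangular = TRUE) {
  aa <- aa_alphabet()
  rows <- lapply(names(mats), function(id) {
    m <- mats[[id]]
    keep <- if (triangular) row(m) >= col(m) else matrix(TRUE, 20L, 20L)
    data.frame(matrix_id = id,
               row = aa[row(m)[keep]], col = aa[col(m)[keep]],
               value = sprintf("%.17g", m[keep]))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read 20x20 matrices from the native AAIndex2/3 flat-file layout
#'
#' Parses `H` accession lines and `M rows = ..., cols = ...` blocks with
#' lower-triangular value rows.
#'
#' @param path path to an AAIndex-style flat file.
#' @return an `aa_matrix_set`.
#' @export
read_matrix_set_flat <- function(path) {
  lines <- readLines(path)
  ids <- character(0); mats <- list()
  i <- 1L; cur <- NULL
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "H ")) {
      cur <- trimws(sub("^H ", "", ln))
    } else if (startsWith(ln, "M ")) {
      abort_if(is.null(cur), "AAIndex flat file: M block before any H line")
      spec <- sub("^M ", "", ln)
      rows_order <- strsplit(sub(".*rows = ([A-Z]+).*", "\\1", spec), "")[[1]]
      cols_order <- strsplit(sub(".*cols = ([A-Z]+).*", "\\1", spec), "")[[1]]
      abort_if(length(rows_order) != 20L || length(cols_order) != 20L,
               sprintf("AAIndex flat file: bad row/col spec for %s", cur))
      m <- matrix(NA_real_, 20L, 20L, dimnames = list(rows_order, cols_order))
      for (r in seq_len(20L)) {
        v <- as.numeric(strsplit(trimws(lines[i + r]), "\\s+")[[1]])
        abort_if(anyNA(v) || length(v) > 20L,
                 sprintf("AAIndex flat file: malformed value row for %s", cur))
        m[r, seq_along(v)] <- v
      }
      i <- i + 20L
      m <- m[aa_alphabet(), aa_alphabet()]
      ids <- c(ids, cur)
      mats[[length(mats) + 1L]] <- complete_symmetric(m)
    }
    i <- i + 1L
  }
  abort_if(length(ids) == 0L, "AAIndex flat file: no matrices found")
  names(mats) <- ids
  new_matrix_set(mats)
}

#' Prune correlated scales, keeping the first occurrence
#'
#' Given a correlation matrix over scale identifiers (in their catalogue
#' order), walks the identifiers in order and keeps a scale only if its
#' absolute correlation with every already-kept scale is below the
#' threshold. This is the keep-first-of-a-correlated-pair redundancy
#' filter used to reduce a large per-residue property catalogue to an
#' uncorrelated working set.
#'
#' @param cor_matrix square correlation matrix with dimnames.
#' @param threshold absolute-correlation cutoff.
#' @return character vector of retained scale identifiers.
#' @export
prune_correlated_scales <- function(cor_matrix, threshold = 0.9) {
  stopifnot(is.matrix(cor_matrix), nrow(cor_matrix) == ncol(cor_matrix))
  ids <- rownames(cor_matrix) %||% as.character(seq_len(nrow(cor_matrix)))
  kept <- integer(0)
  for (i in seq_along(ids)) {
    if (length(kept) == 0L ||
        all(abs(cor_matrix[i, kept]) < threshold, na.rm = TRUE)) {
      kept <- c(kept, i)
    }
  }
  ids[kept]
}
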