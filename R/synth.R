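# Seeded synthetic-data generation: proteins with topology annotations,
# PSSMs, property tables of the stated cardinalities, and mutation
# records whose labels follow a planted, recoverable effect model.

aa_background_freq <- function() {
  f <- c(A = 8.3, R = 5.5, N = 4.0, D = 5.4, C = 1.4, Q = 3.9, E = 6.7,
         G = 7.1, H = 2.2, I = 5.9, L = 9.6, K = 5.8, M = 2.4, F = 3.8,
         P = 4.7, S = 6.6, T = 5.3, W = 1.1, Y = 2.9, V = 6.8)
  f / sum(f)
}

#' Synthetic-data configuration
#'
#' Defines the study conditions the generator emulates. The planted
#' pathogenicity model is a latent-logistic threshold rule
#' `pathogenic = 1[b0 + b_hydro * dHydropathy + b_tm * 1(site in a TM
#' segment) + eps > 0]` with `eps ~ Logistic(0, noise_scale)`, so with
#' zero effect coefficients the prevalence is `plogis(b0)` and with
#' zero noise the labels are a deterministic function of the planted
#' score. Disease labels of pathogenic records are thresholded noisy
#' projections of the 537-dim site vector onto per-disease direction
#' vectors; the directions are supported on the substitution-dependent
#' blocks (per-scale differences and window features), so the signal
#' is recoverable from sequence context alone. The first
#' `n_separated` classes use zero projection noise and higher
#' prevalence (well-separated classes); the rest add Gaussian
#' projection noise.
#'
#' @param n_proteins number of synthetic proteins.
#' @param len_range min/max protein length.
#' @param n_mutations number of mutation records.
#' @param b0,b_hydro,b_tm planted effect coefficients (intercept,
#'   Kyte-Doolittle hydropathy-delta weight, transmembrane-site weight).
#' @param noise_scale scale of the logistic noise in the threshold rule.
#' @param n_separated number of well-separated disease classes.
#' @param disease_prevalence per-class target label prevalence.
#' @param disease_noise per-class projection noise (as a fraction of the
#'   projection's standard deviation).
#' @param n_direction_terms nonzero coordinates per disease direction.
#' @param p_singleton probability a record cites a single source
#'   database (such records are removed by the standard source filter).
#' @param seed mandatory integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_proteins = 40L, len_range = c(120L, 400L),
                         n_mutations = 1000L,
                         b0 = 0, b_hydro = 0.8, b_tm = 1.0,
                         noise_scale = 1,
                         n_separated = 4L,
                         disease_prevalence = c(rep(0.35, n_separated),
                                                rep(0.15, 15L - n_separated)),
                         disease_noise = c(rep(0, n_separated),
                                           rep(0.3, 15L - n_separated)),
                         n_direction_terms = 8L,
                         p_singleton = 0,
                         seed) {
  abort_if(missing(seed), "seed is mandatory")
  abort_if(length(disease_prevalence) != 15L ||
             any(disease_prevalence <= 0 | disease_prevalence >= 1),
           "disease_prevalence must be 15 values in (0,1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 len_range = as.integer(len_range),
                 n_mutations = as.integer(n_mutations),
                 b0 = b0, b_hydro = b_hydro, b_tm = b_tm,
                 noise_scale = noise_scale,
                 n_separated = as.integer(n_separated),
                 disease_prevalence = disease_prevalence,
                 disease_noise = disease_noise,
                 n_direction_terms = as.integer(n_direction_terms),
                 p_singleton = p_singleton,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# one topology string of length L built from alternating loop/TM runs,
# with an optional N-terminal signal peptide and occasional beta TMs
gen_topology_string <- function(L) {
  parts <- character(0)
  if (stats::runif(1) < 0.3) {
    parts <- c(parts, strrep("S", sample(12:20, 1L)))
  }
  side <- sample(c("i", "o"), 1L)
  repeat {
    if (sum(nchar(parts)) >= L) break
    parts <- c(parts, strrep(side, sample(5:40, 1L)))
    if (sum(nchar(parts)) >= L) break
    tm <- if (stats::runif(1) < 0.15) strrep("B", sample(8:12, 1L))
          else strrep("H", sample(17:25, 1L))
    parts <- c(parts, tm)
    side <- if (side == "i") "o" else "i"
  }
  substr(paste(parts, collapse = ""), 1L, L)
}

count_tm_segments <- function(topology) {
  runs <- rle(strsplit(chartr("BH", "TT", topology), "")[[1]])
  sum(runs$values == "T")
}

#' Generate synthetic transmembrane proteins
#'
#' Sequences drawn from a fixed background residue composition, with
#' residue-level topology strings built from alternating runs of
#' inside/outside loops and transmembrane segments (mostly helices,
#' occasionally beta strands), plus occasional N-terminal signal
#' peptides. The stored segment count equals the number of H/B runs in
#' the topology string by construction.
#'
#' @param config a [synth_config()].
#' @return data frame with `protein_id`, `protein_name`, `sequence`,
#'   `topology`, `n_tm_segments`, `cluster_id`.
#' @export
gen_proteins <- function(config) {
  with_seed(derive_seed(config$seed, "proteins"), {
    n <- config$n_proteins
    freq <- aa_background_freq()
    lens <- sample(seq.int(config$len_range[1], config$len_range[2]), n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(names(freq), L, replace = TRUE, prob = freq),
            collapse = ""), "")
    topo <- vapply(lens, gen_topology_string, "")
    data.frame(protein_id = sprintf("SYNP%04d", seq_len(n)),
               protein_name = sprintf("synthetic membrane protein %d",
                                      seq_len(n)),
               sequence = seqs, topology = topo,
               n_tm_segments = vapply(topo, count_tm_segments, 1L),
               cluster_id = sprintf("CL%03d", ceiling(seq_len(n) / 2)),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic PSSM for a sequence
#'
#' Integer log-odds drawn as rounded Gaussian baseline noise plus a
#' positive bonus on the observed residue's column, giving the
#' self-preference of real evolutionary profiles.
#'
#' @param sequence protein sequence string.
#' @param seed integer seed.
#' @param bonus self-preference bonus added to the observed residue.
#' @return a `pssm` (L x 20 matrix with a `residues` attribute).
#' @export
gen_pssm <- function(sequence, seed, bonus = 5) {
  with_seed(derive_seed(seed, paste0("pssm:", sequence)), {
    res <- strsplit(sequence, "")[[1]]
    L <- length(res)
    m <- matrix(round(stats::rnorm(L * 20L, 0, 2)), L, 20L,
                dimnames = list(NULL, aa_alphabet()))
    obs <- match(res, aa_alphabet())
    keep <- !is.na(obs)
    m[cbind(which(keep), obs[keep])] <- m[cbind(which(keep), obs[keep])] + bonus
    structure(m, residues = res, class = c("pssm", "matrix"))
  })
}

#' Generate synthetic property tables of the stated cardinalities
#'
#' 213 per-residue scales plus 94 and 47 symmetric 20 x 20 matrices,
#' all standardised, mirroring the cardinalities of the curated
#' AAIndex working sets the real pipeline ingests.
#'
#' @param seed integer seed.
#' @return list with `scales` (`aa_scales`), `subst` and `contact`
#'   (`aa_matrix_set`s).
#' @export
gen_property_tables <- function(seed) {
  with_seed(derive_seed(seed, "tables"), {
    sc <- matrix(stats::rnorm(213L * 20L), 213L, 20L)
    sc <- (sc - rowMeans(sc)) / apply(sc, 1L, stats::sd)
    rownames(sc) <- sprintf("SC%03d", seq_len(213L))
    sym <- function(id) {
      a <- matrix(stats::rnorm(400L), 20L, 20L)
      m <- (a + t(a)) / 2
      (m - mean(m)) / stats::sd(m)
    }
    subst <- new_matrix_set(stats::setNames(lapply(seq_len(94L), sym),
                                            sprintf("SM%02d", seq_len(94L))))
    contact <- new_matrix_set(stats::setNames(lapply(seq_len(47L), sym),
                                              sprintf("CP%02d", seq_len(47L))))
    list(scales = new_scales(sc), subst = subst, contact = contact)
  })
}

# indices of the site-vector blocks the disease directions may load on:
# the per-scale difference block and the window property/category blocks
# (all functions of the substitution and its sequence context)
disease_direction_support <- function() {
  layout <- site_vector_layout()
  ends <- cumsum(layout)
  starts <- ends - layout + 1L
  c(seq.int(starts["aaindex1_diff"], ends["aaindex1_diff"]),
    seq.int(starts["window_hydro"], ends["category_delta"]))
}

#' Generate mutation records with planted pathogenicity and disease labels
#'
#' Samples (protein, site, substitution) triplets, assigns pathogenicity
#' by the planted latent-logistic threshold rule, and labels pathogenic
#' records with diseases by thresholding noisy projections of the site
#' feature vector onto per-disease direction vectors (guaranteeing at
#' least one active label; overlap between classes arises naturally).
#'
#' @param proteins output of [gen_proteins()].
#' @param config a [synth_config()].
#' @param pssms named list of PSSMs (defaults to [gen_pssm()] per
#'   protein).
#' @param tables property tables (defaults to [gen_property_tables()]).
#' @return list with `records` (a `mutation_table`), `planted` (data
#'   frame with the latent scores) and `disease_model` (directions and
#'   thresholds actually used).
#' @export
gen_labeled_mutations <- function(proteins, config,
                                  pssms = NULL, tables = NULL) {
  if (is.null(tables)) tables <- gen_property_tables(config$seed)
  if (is.null(pssms)) {
    pssms <- stats::setNames(lapply(proteins$sequence, gen_pssm,
                                    seed = config$seed),
                             proteins$protein_id)
  }
  kd <- kd_hydropathy()
  with_seed(derive_seed(config$seed, "mutations"), {
    n <- config$n_mutations
    pidx <- sample.int(nrow(proteins), n, replace = TRUE,
                       prob = nchar(proteins$sequence))
    pos <- vapply(pidx, function(i)
      sample.int(nchar(proteins$sequence[i]), 1L), 1L)
    wt <- substr(proteins$sequence[pidx], pos, pos)
    mut <- vapply(wt, function(w)
      sample(setdiff(aa_alphabet(), w), 1L), "")
    topo <- substr(proteins$topology[pidx], pos, pos)
    in_tm <- topo %in% c("H", "B")
    linear <- config$b0 + config$b_hydro * (kd[mut] - kd[wt]) +
      config$b_tm * in_tm
    eps <- if (config$noise_scale > 0)
      stats::rlogis(n, 0, config$noise_scale) else numeric(n)
    patho <- as.integer(linear + eps > 0)
    if (all(patho == 1L) || all(patho == 0L)) {
      warning("degenerate planted configuration: single-class labels")
    }
    n_src <- ifelse(stats::runif(n) < config$p_singleton, 1L,
                    sample(2:3, n, replace = TRUE))
    sources <- vapply(n_src, function(k)
      paste(sample(source_db_vocab(), k), collapse = ";"), "")
    # disease labels for pathogenic records: thresholded site-vector
    # projections onto sparse per-disease directions
    is_p <- which(patho == 1L)
    dis_str <- rep("", n)
    support <- disease_direction_support()
    D537 <- sum(site_vector_layout())
    dirs <- matrix(0, 15L, D537, dimnames = list(disease_codes(), NULL))
    for (c in seq_len(15L)) {
      ix <- sample(support, config$n_direction_terms)
      w <- stats::rnorm(config$n_direction_terms)
      dirs[c, ix] <- w / sqrt(sum(w^2))
    }
    taus <- rep(NA_real_, 15L)
    if (length(is_p) > 1L) {
      S <- t(vapply(is_p, function(i) {
        as.numeric(site_feature_vector(proteins$sequence[pidx[i]], pos[i],
                                       wt[i], mut[i],
                                       pssms[[proteins$protein_id[pidx[i]]]],
                                       tables))
      }, numeric(D537)))
      Z <- S %*% t(dirs)                              # n_p x 15
      lab <- matrix(0L, length(is_p), 15L)
      margin <- matrix(0, length(is_p), 15L)
      for (c in seq_len(15L)) {
        z <- Z[, c]
        taus[c] <- stats::quantile(z, 1 - config$disease_prevalence[c],
                                   names = FALSE)
        nz <- if (config$disease_noise[c] > 0)
          stats::rnorm(length(z), 0, config$disease_noise[c] * stats::sd(z))
        else 0
        lab[, c] <- as.integer(z + nz > taus[c])
        margin[, c] <- (z - taus[c]) / max(stats::sd(z), 1e-12)
      }
      none <- rowSums(lab) == 0L
      if (any(none)) {
        pick <- max.col(margin[none, , drop = FALSE], ties.method = "first")
        lab[cbind(which(none), pick)] <- 1L
      }
      dis_str[is_p] <- disease_label_strings(lab)
    }
    records <- mutation_table(
      protein_id = proteins$protein_id[pidx],
      protein_name = proteins$protein_name[pidx],
      position = pos, wt = wt, mut = mut, sources = sources,
      patho_label = patho, disease_labels = dis_str,
      topology = topo, n_tm_segments = proteins$n_tm_segments[pidx],
      cluster_id = proteins$cluster_id[pidx])
    list(records = records,
         planted = data.frame(linear = as.numeric(linear),
                              in_tm = in_tm,
                              dhydro = as.numeric(kd[mut] - kd[wt])),
         disease_model = list(directions = dirs, thresholds = taus))
  })
}

#' Generate a complete synthetic dataset in memory
#'
#' Convenience orchestrator: proteins, PSSMs, property tables and
#' labelled mutations under one configuration.
#'
#' @param config a [synth_config()].
#' @return list with `proteins`, `sequences`, `pssms`, `tables`,
#'   `records`, `planted`, `disease_model`, `config`.
#' @export
gen_dataset <- function(config) {
  proteins <- gen_proteins(config)
  tables <- gen_property_tables(config$seed)
  pssms <- stats::setNames(lapply(proteins$sequence, gen_pssm,
                                  seed = config$seed),
                           proteins$protein_id)
  lm <- gen_labeled_mutations(proteins, config, pssms, tables)
  list(proteins = proteins,
       sequences = stats::setNames(proteins$sequence, proteins$protein_id),
       pssms = pssms, tables = tables,
       records = lm$records, planted = lm$planted,
       disease_model = lm$disease_model, config = config)
}

#' Write a synthetic workspace to disk / read it back
#'
#' Emits exactly the formats the real pipeline reads: FASTA sequences,
#' a TSV mutation table, PSI-BLAST-style ASCII PSSMs, long-format
#' property-table TSVs and a JSON manifest. `load_workspace()` reads
#' everything back through the package's own readers.
#'
#' @param dataset output of [gen_dataset()].
#' @param dir workspace directory (created if needed).
#' @return `dir` (writer) / a dataset-like list (reader).
#' @export
write_workspace <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  write_fasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  write_mutation_table(dataset$records, file.path(dir, "mutations.tsv"))
  topo <- data.frame(protein_id = dataset$proteins$protein_id,
                     topology = dataset$proteins$topology,
                     n_tm_segments = dataset$proteins$n_tm_segments)
  utils::write.table(topo, file.path(dir, "topology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (id in names(dataset$pssms)) {
    write_pssm_ascii(dataset$pssms[[id]], file.path(dir, "pssm",
                                                    paste0(id, ".pssm")))
  }
  write_scales_tsv(dataset$tables$scales, file.path(dir, "aaindex1.tsv"))
  write_matrix_set_tsv(dataset$tables$subst, file.path(dir, "aaindex2.tsv"))
  write_matrix_set_tsv(dataset$tables$contact, file.path(dir, "aaindex3.tsv"))
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_workspace
#' @export
load_workspace <- function(dir) {
  sequences <- read_fasta(file.path(dir, "sequences.fasta"))
  records <- read_mutation_table(file.path(dir, "mutations.tsv"))
  topo <- utils::read.delim(file.path(dir, "topology.tsv"),
                            stringsAsFactors = FALSE)
  pssms <- stats::setNames(lapply(names(sequences), function(id) {
    read_pssm_ascii(file.path(dir, "pssm", paste0(id, ".pssm")),
                    sequence = sequences[[id]])
  }), names(sequences))
  tables <- list(scales = read_scales_tsv(file.path(dir, "aaindex1.tsv")),
                 subst = read_matrix_set_tsv(file.path(dir, "aaindex2.tsv")),
                 contact = read_matrix_set_tsv(file.path(dir, "aaindex3.tsv")))
  proteins <- data.frame(protein_id = names(sequences),
                         sequence = unname(sequences),
                         stringsAsFactors = FALSE)
  proteins <- merge(proteins, topo, by = "protein_id", sort = FALSE)
  list(proteins = proteins, sequences = sequences, pssms = pssms,
       tables = tables, records = records)
}
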