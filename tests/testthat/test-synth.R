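test_that("generated proteins have consistent topology bookkeeping", {
  cfg <- synth_config(n_proteins = 30L, n_mutations = 10L, seed = 41L)
  pr <- gen_proteins(cfg)
  expect_equal(nrow(pr), 30L)
  expect_equal(nchar(pr$sequence), nchar(pr$topology))
  # stored segment count equals the number of H/B runs by construction
  for (i in seq_len(nrow(pr))) {
    runs <- rle(strsplit(chartr("BH", "TT", pr$topology[i]), "")[[1]])
    expect_equal(pr$n_tm_segments[i], sum(runs$values == "T"))
  }
  expect_identical(gen_proteins(cfg), pr)  # seed determinism
})

test_that("residue frequencies track the generating composition", {
  cfg <- synth_config(n_proteins = 300L, len_range = c(300L, 380L),
                      n_mutations = 10L, seed = 42L)
  pr <- gen_proteins(cfg)
  res <- unlist(strsplit(pr$sequence, ""))
  n <- length(res)
  expect_gt(n, 9e4)
  freq <- asNamespace("tmpatho")$aa_background_freq()
  obs <- table(factor(res, levels = names(freq)))
  for (aa in names(freq)) {
    sd3 <- 3 * sqrt(n * freq[[aa]] * (1 - freq[[aa]]))
    expect_lt(abs(obs[[aa]] - n * freq[[aa]]), sd3 + 1e-9)
  }
})

test_that("synthetic PSSMs prefer the observed residue", {
  set.seed(1)
  seq <- paste(sample(aa_alphabet(), 400, replace = TRUE), collapse = "")
  p <- gen_pssm(seq, seed = 5L)
  expect_equal(dim(p), c(400L, 20L))
  expect_identical(unclass(gen_pssm(seq, seed = 5L)), unclass(p))
  res <- strsplit(seq, "")[[1]]
  obs_scores <- p[cbind(seq_len(400), match(res, aa_alphabet()))]
  expect_gte(mean(obs_scores > rowMeans(p)), 0.95)
})

test_that("property tables have the stated cardinalities and symmetry", {
  tb <- gen_property_tables(6L)
  expect_equal(dim(tb$scales), c(213L, 20L))
  expect_length(tb$subst, 94L)
  expect_length(tb$contact, 47L)
  for (m in c(tb$subst[seq(1, 94, by = 13)], tb$contact[seq(1, 47, by = 11)])) {
    expect_equal(m, t(m))
  }
  expect_identical(gen_property_tables(6L)$scales, tb$scales)
})

test_that("intercept-only prevalence matches the logistic link", {
  cfg <- synth_config(n_mutations = 4000L, b0 = -0.6, b_hydro = 0,
                      b_tm = 0, seed = 43L)
  pr <- gen_proteins(cfg)
  lm <- gen_labeled_mutations(pr, cfg, tables = gen_property_tables(43L))
  prev <- mean(lm$records$patho_label)
  p0 <- stats::plogis(-0.6)
  sd3 <- 3 * sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(prev - p0), sd3)
})

test_that("zero noise makes labels a deterministic threshold of the score", {
  cfg <- synth_config(n_mutations = 400L, b_hydro = 2, b_tm = 1.5,
                      noise_scale = 0, seed = 44L)
  pr <- gen_proteins(cfg)
  lm <- gen_labeled_mutations(pr, cfg, tables = gen_property_tables(44L))
  expect_identical(lm$records$patho_label,
                   as.integer(lm$planted$linear > 0))
  expect_equal(auc_score(lm$records$patho_label, lm$planted$linear), 1)
})

test_that("disease labels respect prevalence targets and the >=1 guarantee", {
  cfg <- synth_config(n_mutations = 800L, seed = 45L)
  ds <- gen_dataset(cfg)
  dd <- build_disease_dataset(ds$records)
  expect_true(all(rowSums(dd$labels) >= 1L))
  prev <- colMeans(dd$labels)
  # the four well-separated classes target a prevalence of 0.35
  expect_true(all(abs(prev[1:4] - 0.35) < 0.1))
  # multi-label overlap arises (some records carry several labels)
  expect_gt(mean(rowSums(dd$labels) >= 2L), 0.1)
})

test_that("a workspace round-trips through its own readers bit-exactly", {
  cfg <- synth_config(n_mutations = 25L, n_proteins = 6L,
                      len_range = c(60L, 120L), seed = 46L)
  ds <- gen_dataset(cfg)
  dir <- withr::local_tempdir()
  write_workspace(ds, dir)
  back <- load_workspace(dir)
  expect_identical(back$sequences, ds$sequences)
  expect_equal(as.data.frame(back$records), as.data.frame(ds$records))
  expect_equal(unclass(back$pssms[[3]]), unclass(ds$pssms[[3]]),
               ignore_attr = TRUE)
  expect_identical(unclass(back$tables$scales), unclass(ds$tables$scales))
  expect_identical(back$tables$contact[[10]], ds$tables$contact[[10]])
})
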