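test_that("per-scale differences are antisymmetric lookups", {
  tb <- fixture_tables()
  d <- aaindex1_diff("A", "V", tb$scales)
  expect_length(d, 213L)
  expect_equal(d, tb$scales[, "V"] - tb$scales[, "A"], ignore_attr = TRUE)
  expect_equal(aaindex1_diff("V", "A", tb$scales), -d)
  expect_equal(unname(aaindex1_diff("A", "A", tb$scales)), rep(0, 213L))
  fake <- tb$scales; fake["SC001", "A"] <- 1; fake["SC001", "V"] <- 3
  expect_equal(unname(aaindex1_diff("A", "V", fake)["SC001"]), 2)
  expect_error(aaindex1_diff("X", "V", tb$scales), "standard")
})

test_that("substitution-matrix scores read the symmetric matrices", {
  tb <- fixture_tables()
  s <- aaindex2_scores("A", "V", tb$subst)
  expect_length(s, 94L)
  expect_equal(s, aaindex2_scores("V", "A", tb$subst))
  diagv <- aaindex2_scores("W", "W", tb$subst)
  expect_equal(unname(diagv[5]), tb$subst[[5]]["W", "W"])
  fake <- tb$subst; fake[[1]]["A", "V"] <- fake[[1]]["V", "A"] <- -1.5
  expect_equal(unname(aaindex2_scores("A", "V", fake)[1]), -1.5)
})

test_that("contact-potential differences sum over the +/-3 neighbourhood", {
  tb <- fixture_tables()
  seq <- "MKTAYIAKQR"
  # middle site: six neighbours; compare with a brute-force double loop
  v <- aaindex3_contact_diff("A", "W", seq, 5L, tb$contact)
  expect_length(v, 47L)
  res <- strsplit(seq, "")[[1]]
  nbrs <- res[c(2:4, 6:8)]
  oracle <- vapply(tb$contact, function(m)
    sum(vapply(nbrs, function(nb) m["W", nb] - m["A", nb], numeric(1))),
    numeric(1))
  expect_equal(v, oracle)
  # antisymmetry and the identity control
  expect_equal(aaindex3_contact_diff("W", "A", seq, 5L, tb$contact), -v)
  expect_equal(unname(aaindex3_contact_diff("A", "A", seq, 5L, tb$contact)),
               rep(0, 47L))
  # single neighbour at the N-terminus of a 2-residue chain
  v2 <- aaindex3_contact_diff("M", "V", "MK", 1L, tb$contact)
  expect_equal(unname(v2[3]),
               tb$contact[[3]]["V", "K"] - tb$contact[[3]]["M", "K"])
  expect_warning(aaindex3_contact_diff("M", "V", "M", 1L, tb$contact),
                 "empty neighbourhood")
})

test_that("window property delta follows the local-mean formula", {
  sc <- c(A = 1, K = 2, V = 3)
  sc <- c(sc, setNames(rep(0, 17), setdiff(aa_alphabet(), names(sc))))
  # hand-evaluated example: P(V) - mean(P over AKV)
  expect_equal(window_property_delta("AKV", 2L, "V", sc, 1L), 3 - 2)
  # homopolymer control
  kd <- kd_hydropathy()
  expect_equal(window_property_delta("AAAAA", 3L, "A", kd, 2L), 0)
})

test_that("window property delta equals the loop oracle on 1000 random cases", {
  kd <- kd_hydropathy()
  set.seed(17)
  for (case in 1:1000) {
    L <- sample(4:60, 1L)
    seq <- paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
    pos <- sample(L, 1L)
    j <- sample(1:5, 1L)
    mut <- sample(aa_alphabet(), 1L)
    got <- window_property_delta(seq, pos, mut, kd, j)
    res <- strsplit(seq, "")[[1]]
    acc <- 0; cnt <- 0
    for (q in (pos - j):(pos + j)) {
      if (q >= 1 && q <= L) { acc <- acc + kd[[res[q]]]; cnt <- cnt + 1 }
    }
    expect_equal(got, kd[[mut]] - acc / cnt)
  }
})

test_that("category distribution deltas move mass between two classes only", {
  # same category: nothing moves
  expect_equal(unname(category_distribution_delta("GAVLI", 3L, "L", 2L)),
               rep(0, 6L))
  # aliphatic centre to aromatic mutant in a full 5-window
  d <- category_distribution_delta("GAVLI", 3L, "W", 2L)
  expect_equal(unname(d[c("aliphatic", "aromatic")]), c(-1 / 5, 1 / 5))
  expect_equal(unname(d[c("sulfur", "polar", "negative", "positive")]),
               rep(0, 4L))
  # conservation of total fraction, random cases
  set.seed(4)
  for (case in 1:50) {
    L <- sample(3:40, 1L)
    seq <- paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
    d <- category_distribution_delta(seq, sample(L, 1L),
                                     sample(aa_alphabet(), 1L),
                                     sample(1:5, 1L))
    expect_equal(sum(d), 0, tolerance = 1e-12)
  }
})

test_that("site vector assembles the eight blocks into 537 components", {
  tb <- fixture_tables()
  fx <- fixture_protein()
  p <- gen_pssm(fx$sequence, seed = 12L)
  pos <- 20L
  wt <- substr(fx$sequence, pos, pos)
  v <- site_feature_vector(fx$sequence, pos, wt, "D", p, tb)
  expect_length(v, 537L)
  layout <- attr(v, "block_layout")
  expect_equal(unname(layout),
               c(213L, 94L, 47L, 3L, 140L, 5L, 5L, 30L))
  expect_equal(sum(site_vector_layout()), 537L)
  # the window blocks contribute 10 property features and 30 category ones
  expect_equal(unname(layout["window_hydro"] + layout["window_polar"]), 10L)
  expect_equal(unname(layout["category_delta"]), 30L)
  expect_error(site_feature_vector(fx$sequence, pos, "W", "D", p, tb),
               "does not match")
})

test_that("difference blocks negate when wild and mutant swap", {
  tb <- fixture_tables()
  fx <- fixture_protein()
  p <- gen_pssm(fx$sequence, seed = 13L)
  pos <- 30L
  wt <- substr(fx$sequence, pos, pos)
  mut <- setdiff(aa_alphabet(), wt)[1]
  v <- site_feature_vector(fx$sequence, pos, wt, mut, p, tb)
  # forward/backward substitution on a sequence carrying the mutant residue
  seq2 <- fx$sequence
  substr(seq2, pos, pos) <- mut
  v2 <- site_feature_vector(seq2, pos, mut, wt, p, tb)
  expect_equal(unname(v2[1:213]), unname(-v[1:213]))            # scale diffs
  expect_equal(unname(v2[357]), unname(-v[357]))                # pssm diff
})
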