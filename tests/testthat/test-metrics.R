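test_that("binary metrics come from the confusion counts", {
  # perfect separation
  m <- binary_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(m$mcc, 1); expect_equal(m$f1, 1); expect_equal(m$auc, 1)
  expect_equal(m$acc, 1); expect_equal(m$specificity, 1)
  # fixed counts: TP=40 FP=10 TN=35 FN=15, MCC from the closed form
  labels <- rep(c(1, 1, 0, 0), c(40, 15, 10, 35))
  probs <- rep(c(0.9, 0.1, 0.9, 0.1), c(40, 15, 10, 35))
  m2 <- binary_metrics(labels, probs)
  expect_equal(unname(m2$counts), c(40, 10, 35, 15))
  mcc_closed <- (40 * 35 - 10 * 15) /
    sqrt((40 + 10) * (40 + 15) * (35 + 10) * (35 + 15))
  expect_equal(m2$mcc, mcc_closed)
  expect_equal(m2$precision, 40 / 50)
  expect_equal(m2$recall, 40 / 55)
  expect_equal(m2$f1, 2 * (40 / 50) * (40 / 55) / (40 / 50 + 40 / 55))
  # single-class labels: undefined markers, not numbers
  m3 <- binary_metrics(rep(1, 5), runif(5))
  expect_true(is.na(m3$auc))
  expect_true(is.na(m3$mcc))
})

test_that("AUC equals the pairwise concordance fraction", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # ties on purpose
    conc <- 0; tot <- 0
    for (i in which(y == 1)) {
      for (j in which(y == 0)) {
        tot <- tot + 1
        conc <- conc + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
      }
    }
    expect_equal(auc_score(y, s), conc / tot)
  }
})

test_that("average precision respects the known PR properties", {
  y <- c(1, 1, 0, 0, 0, 0)
  expect_equal(aupr_score(y, c(0.9, 0.8, 0.4, 0.3, 0.2, 0.1)), 1)
  # constant scores: precision at full recall equals the prevalence
  expect_equal(aupr_score(y, rep(0.5, 6)), 2 / 6)
  set.seed(10)
  for (rep in 1:20) {
    y <- rbinom(40, 1, 0.3)
    if (sum(y) == 0 || sum(y) == 40) next
    expect_gte(aupr_score(y, runif(40)) + 1e-12, 0)
    # all-positive predictions floor at the prevalence
    expect_gte(aupr_score(y, rep(1, 40)), mean(y) - 1e-12)
  }
})

test_that("multi-label metrics follow the sample-averaged convention", {
  Y <- matrix(0L, 3, 15); P <- matrix(0.1, 3, 15)
  Y[1, 1:2] <- 1L; Y[2, 3] <- 1L; Y[3, c(4, 5, 6)] <- 1L
  P[1, 1:2] <- 0.9          # exact
  P[2, c(3, 4)] <- 0.9      # one spurious
  P[3, 4] <- 0.9            # partial
  m <- multilabel_metrics(Y, P)
  # hand computation per sample: P = (1, 1/2, 1), R = (1, 1, 1/3)
  expect_equal(m$precision_ml, mean(c(1, 1 / 2, 1)))
  expect_equal(m$recall_ml, mean(c(1, 1, 1 / 3)))
  f1s <- c(1, 2 * 0.5 * 1 / 1.5, 2 * 1 * (1 / 3) / (1 + 1 / 3))
  expect_equal(m$f1_ml, mean(f1s))
  # Hamming loss counts wrong bits: spurious 4 on row 2, missed 5,6 on row 3
  expect_equal(m$hamming_loss, 3 / (3 * 15))
  # perfect prediction
  expect_equal(multilabel_metrics(Y, Y)$hamming_loss, 0)
  # exactly one wrong bit in an N x 15 matrix
  P2 <- Y; P2[2, 7] <- 1
  expect_equal(multilabel_metrics(Y, P2)$hamming_loss, 1 / (3 * 15))
  # all-zero predicted set contributes precision zero
  m0 <- multilabel_metrics(matrix(1, 1, 15), matrix(0, 1, 15))
  expect_equal(m0$precision_ml, 0)
})

test_that("per-disease curves use not-associated records as negatives", {
  set.seed(11)
  n <- 300
  Y <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  P <- matrix(runif(n * 3), n, 3)
  P[, 1] <- Y[, 1] * 0.5 + runif(n) * 0.5   # separable class
  P[, 1][Y[, 1] == 1] <- 0.6 + 0.4 * runif(sum(Y[, 1]))
  P[, 1][Y[, 1] == 0] <- 0.5 * runif(sum(Y[, 1] == 0))
  out <- per_disease_curves(Y, P)
  expect_equal(out$class, c("c1", "c2", "c3"))
  expect_equal(out$n_pos, colSums(Y), ignore_attr = TRUE)
  expect_equal(out$auc[1], 1)
  expect_equal(out$aupr[1], 1)
  # random scores on a balanced class sit near one half
  expect_lt(abs(out$auc[2] - 0.5), 0.12)
  # a class with no positives is an undefined marker
  Y0 <- Y; Y0[, 3] <- 0
  expect_true(is.na(per_disease_curves(Y0, P)$auc[3]))
})

test_that("bootstrap intervals behave as percentile intervals should", {
  set.seed(12)
  y <- rbinom(150, 1, 0.5)
  p <- ifelse(y == 1, runif(150, 0.3, 1), runif(150, 0, 0.7))
  ci <- bootstrap_ci(y, p, function(l, s) auc_score(l, s),
                     n_boot = 200L, seed = 3L)
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
  # reproducible under the same seed
  ci2 <- bootstrap_ci(y, p, function(l, s) auc_score(l, s),
                      n_boot = 200L, seed = 3L)
  expect_identical(ci[c("lower", "upper")], ci2[c("lower", "upper")])
  # degenerate constant metric: zero-width interval
  cid <- bootstrap_ci(y, p, function(l, s) 0.7, n_boot = 50L, seed = 1L)
  expect_equal(cid$lower, 0.7); expect_equal(cid$upper, 0.7)
  # endpoints monotone in the level
  ci80 <- bootstrap_ci(y, p, function(l, s) auc_score(l, s),
                       n_boot = 200L, level = 0.8, seed = 3L)
  expect_gte(ci80$lower, ci$lower - 1e-12)
  expect_lte(ci80$upper, ci$upper + 1e-12)
})

test_that("bootstrap coverage is near nominal for a binomial proportion", {
  set.seed(13)
  hits <- 0L
  for (rep in 1:500) {
    y <- rbinom(60, 1, 0.3)
    ci <- bootstrap_ci(y, y, function(l, s) mean(l), n_boot = 120L,
                       seed = rep)
    if (ci$lower <= 0.3 && 0.3 <= ci$upper) hits <- hits + 1L
  }
  expect_gt(hits / 500, 0.85)
  expect_lt(hits / 500, 0.99)
})

test_that("co-occurrence matrix counts joint label fractions", {
  Y <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(1, 1, 0))
  co <- cooccurrence_matrix(Y)
  expect_equal(co, t(co))
  expect_equal(diag(co), colMeans(Y), ignore_attr = TRUE)
  expect_equal(co[1, 2], 2 / 4)
  expect_equal(co[1, 3], 0)
  # disjoint labels: off-diagonal zeros
  Yd <- diag(3)
  expect_equal(cooccurrence_matrix(Yd) - diag(diag(cooccurrence_matrix(Yd))),
               matrix(0, 3, 3))
})
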