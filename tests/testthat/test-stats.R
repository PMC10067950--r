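test_that("Mann-Whitney AUC handles separation, ties and the worked case", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  # 4 pairs: 3 wins, 1 loss
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # complement identity for tie-free scores
  set.seed(201)
  for (i in 1:20) {
    s <- rnorm(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1)
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(202)
  for (i in 1:10) {
    y <- rep(0:1, each = 15)
    s <- rnorm(30) + y
    expect_equal(roc_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("DeLong interval brackets the point estimate and matches pROC", {
  set.seed(203)
  y <- rep(0:1, each = 20)
  s <- rnorm(40) + 1.2 * y
  ci <- delong_ci(s, y)
  expect_equal(ci$auc, roc_auc(s, y))
  expect_lte(ci$lo, ci$auc); expect_gte(ci$hi, ci$auc)
  # alpha monotonicity: 99% interval contains the 95% one
  ci99 <- delong_ci(s, y, alpha = 0.01)
  expect_lte(ci99$lo, ci$lo); expect_gte(ci99$hi, ci$hi)
  skip_if_not_installed("pROC")
  pc <- as.numeric(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                                method = "delong"))
  expect_equal(c(ci$lo, ci$auc, ci$hi), pc, tolerance = 1e-8)
})

test_that("DeLong variance agrees with a jackknife oracle", {
  set.seed(204)
  y <- rep(0:1, each = 20)
  s <- rnorm(40) + y
  v <- delong_ci(s, y)$se^2
  # leave-one-out jackknife variance of the AUC
  n <- length(y)
  theta <- vapply(seq_len(n), function(i) roc_auc(s[-i], y[-i]), numeric(1))
  vjack <- (n - 1) / n * sum((theta - mean(theta))^2)
  expect_lt(abs(v - vjack) / vjack, 0.10)
})

test_that("one-sided paired DeLong test behaves under symmetry and swap", {
  set.seed(205)
  y <- rep(0:1, each = 25)
  a <- rnorm(50) + y
  b <- 0.7 * a + rnorm(50, sd = 0.5)
  expect_equal(delong_compare_one_sided(a, a, y)$p, 0.5)
  pab <- delong_compare_one_sided(a, b, y)$p
  pba <- delong_compare_one_sided(b, a, y)$p
  expect_equal(pab + pba, 1)
  expect_error(delong_compare_one_sided(a[-1], b, y), "equal length")
  skip_if_not_installed("pROC")
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  pref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE,
                         alternative = "greater")$p.value
  expect_equal(pab, pref, tolerance = 1e-8)
})

test_that("one-sided DeLong p agrees with a sign-flip permutation oracle", {
  set.seed(206)
  y <- rep(0:1, each = 30)
  base <- rnorm(60) + 1.1 * y
  a <- base + rnorm(60, sd = 0.4)
  b <- base + rnorm(60, sd = 0.55)
  p_delong <- delong_compare_one_sided(a, b, y)$p
  # permutation oracle: under H0 the two correlated scores are
  # exchangeable within each subject; swap the (a, b) scores per subject
  # with probability 1/2 and recompute the AUC difference
  nperm <- 10000
  d_obs <- roc_auc(a, y) - roc_auc(b, y)
  set.seed(207)
  d_perm <- numeric(nperm)
  for (k in seq_len(nperm)) {
    flip <- runif(60) < 0.5
    ak <- ifelse(flip, b, a)
    bk <- ifelse(flip, a, b)
    d_perm[k] <- roc_auc(ak, y) - roc_auc(bk, y)
  }
  p_perm <- mean(d_perm >= d_obs)
  expect_lt(abs(p_delong - p_perm), 0.02)
})

test_that("Clopper-Pearson intervals reproduce the published table values", {
  # printed sensitivity/specificity rows: point and 95% CI in percent
  cases <- list(
    list(k = 125, n = 130, point = 96.2, lo = 91.3, hi = 98.7),
    list(k = 137, n = 172, point = 79.7, lo = 72.9, hi = 85.4),
    list(k = 122, n = 172, point = 70.9, lo = 63.5, hi = 77.6),
    list(k = 108, n = 172, point = 62.8, lo = 55.1, hi = 70.0),
    list(k = 129, n = 130, point = 99.2, lo = 95.8, hi = 100.0),
    list(k = 133, n = 172, point = 77.3, lo = 70.3, hi = 83.4))
  for (cs in cases) {
    ci <- clopper_pearson(cs$k, cs$n)
    expect_equal(round(100 * ci$point, 1), cs$point)
    expect_equal(round(100 * ci$lo, 1), cs$lo)
    expect_equal(round(100 * ci$hi, 1), cs$hi)
  }
})

test_that("Clopper-Pearson edges, bracketing and monotonicity hold", {
  expect_identical(clopper_pearson(0, 10)$lo, 0)
  expect_identical(clopper_pearson(10, 10)$hi, 1)
  # agreement with the exact binomial test implementation in stats
  for (k in c(0, 3, 7, 10)) {
    ci <- clopper_pearson(k, 10)
    ref <- stats::binom.test(k, 10)$conf.int
    expect_equal(c(ci$lo, ci$hi), as.numeric(ref))
  }
  prev <- -1
  for (k in 0:20) {
    ci <- clopper_pearson(k, 20)
    expect_lte(ci$lo, ci$point); expect_gte(ci$hi, ci$point)
    expect_gt(ci$lo, prev - 1e-12)
    prev <- ci$lo
  }
  expect_error(clopper_pearson(5, 4), "k <= n")
})

test_that("McNemar test: exact tail, symmetry, and degenerate cases", {
  expect_equal(mcnemar_discordant(10, 0)$p, 2 * 0.5^10)
  expect_equal(mcnemar_discordant(3, 8)$p, mcnemar_discordant(8, 3)$p)
  expect_equal(mcnemar_discordant(6, 6)$p, 1)
  expect_warning(res <- mcnemar_discordant(0, 0), "degenerate")
  expect_equal(res$p, 1)
  # large discordance switches to the continuity-corrected chi-square
  res <- mcnemar_discordant(20, 15, verbose = TRUE)
  expect_identical(res$method, "chisq")
  expect_equal(res$p_chisq,
               stats::mcnemar.test(matrix(c(0, 15, 20, 0), 2, 2))$p.value)
})

test_that("evaluate reproduces a hand-computed 8-ear report", {
  # 4 subjects, 8 ears; probabilities chosen so dichotomization is forced
  preds <- list(
    list(right_probs = c(0.8, 0.1, 0.1), left_probs = c(0.1, 0.7, 0.2),
         symmetry_probs = c(0.2, 0.6, 0.2)),  # R neg, L mild
    list(right_probs = c(0.2, 0.2, 0.6), left_probs = c(0.6, 0.3, 0.1),
         symmetry_probs = c(0.1, 0.2, 0.7)),  # R severe, L neg
    list(right_probs = c(0.5, 0.3, 0.2), left_probs = c(0.3, 0.4, 0.3),
         symmetry_probs = c(0.7, 0.2, 0.1)),  # R neg, L mild
    list(right_probs = c(0.1, 0.6, 0.3), left_probs = c(0.45, 0.3, 0.25),
         symmetry_probs = c(0.6, 0.3, 0.1)))  # R mild, L neg
  labels <- data.frame(subject_id = c("a", "b", "c", "d"),
                       right = c(0L, 2L, 1L, 1L),
                       left = c(1L, 0L, 0L, 0L))
  rep <- evaluate(preds, labels)
  # hand count: truth pos ears = a.L, b.R, c.R, d.R (4); neg = 4
  # predicted pos: a.L, b.R, c.L, d.R
  expect_equal(rep$sensitivity$k, 3); expect_equal(rep$sensitivity$n, 4)
  expect_equal(rep$specificity$k, 3); expect_equal(rep$specificity$n, 4)
  # confusion: diag = true 0 pred 0 (3), true 1 pred 1 (2), true 2 pred 2 (1)
  expect_equal(sum(rep$confusion), 8)
  expect_equal(unname(diag(rep$confusion)), c(3, 2, 1))
  expect_equal(rep$accuracy$point, 6 / 8)
  expect_equal(rep$accuracy$point,
               sum(diag(rep$confusion)) / sum(rep$confusion))
  # AUC from 1 - p(normal): hand-enumerated over the 16 pairs
  scores <- c(0.2, 0.9, 0.8, 0.4, 0.5, 0.7, 0.9, 0.55)
  truth <- c(0, 1, 1, 0, 1, 0, 1, 0)
  expect_equal(rep$auc, roc_auc(scores, truth))
  # invariance to subject ordering
  rep2 <- evaluate(preds[c(3, 1, 4, 2)], labels[c(3, 1, 4, 2), ])
  expect_equal(rep2$auc, rep$auc)
  expect_equal(rep2$confusion, rep$confusion)
})

test_that("evaluate validates alignment and exclusions", {
  preds <- list(list(right_probs = c(1, 0, 0), left_probs = c(1, 0, 0),
                     symmetry_probs = c(1, 0, 0)))
  expect_error(evaluate(preds, data.frame(subject_id = c("a", "b"),
                                          right = c(0L, 0L), left = c(0L, 0L))),
               "misaligned")
  expect_error(evaluate(preds, data.frame(subject_id = "a", right = 3L,
                                          left = 0L)),
               "excluded")
})
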