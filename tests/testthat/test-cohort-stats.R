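test_that("Spearman correlation: monotone invariance, sign, ties, NA policy", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1.0)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1.0)
  # tie case against the direct Pearson-on-mid-ranks oracle
  x <- c(1, 2, 2, 3, 5, 6)
  y <- c(2, 1, 4, 4, 6, 7)
  oracle <- stats::cor(rank(x), rank(y))
  expect_equal(spearman_cor(x, y)$rho, oracle, tolerance = 1e-12)
  # pairwise deletion and n reporting
  res <- spearman_cor(c(1, 2, NA, 4, 5), c(2, NA, 3, 8, 10))
  expect_equal(res$n, 3)
  expect_error(spearman_cor(c(1, 2), c(3, 4)), "at least 3")
  # p from the t-approximation
  set.seed(2)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  r <- spearman_cor(x, y)
  tt <- r$rho * sqrt((20 - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * stats::pt(-abs(tt), 18), tolerance = 1e-12)
})

test_that("two-group comparisons agree with exhaustive permutation", {
  res0 <- rank_tests(list(c(1, 2, 3), c(1, 2, 3)))
  expect_identical(res0$test, "wilcoxon")
  expect_equal(res0$p.value, 1.0)
  # exact permutation oracle over all C(6,3) splits of {1..6}
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  pooled <- c(g1, g2)
  stat <- function(idx) sum(rank(pooled)[idx])  # rank sum of group 1
  obs <- stat(1:3)
  splits <- combn(6, 3)
  perm <- apply(splits, 2, stat)
  p_exact <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)) - 1e-9)
  res <- rank_tests(list(g1, g2))
  expect_lt(abs(res$p.value - p_exact), 0.02)
  expect_error(rank_tests(list(c(1, 2), numeric(0))), "0 observations")
})

test_that("Kruskal-Wallis with Dunn-Bonferroni flags only shifted pairs", {
  set.seed(31)
  g1 <- rnorm(15); g2 <- rnorm(15); g3 <- rnorm(15) + 4
  res <- rank_tests(list(g1, g2, g3))
  expect_identical(res$test, "kruskal-wallis")
  expect_lt(res$p.value, 0.01)
  ph <- res$posthoc
  flagged <- ph[ph$p_adj < 0.05, ]
  expect_setequal(paste(flagged$group1, flagged$group2),
                  c("1 3", "2 3"))
  # Dunn z against a direct recomputation for one pair
  pooled <- c(g1, g2, g3); rk <- rank(pooled)
  rb <- tapply(rk, rep(1:3, each = 15), mean)
  N <- 45
  se <- sqrt((N * (N + 1) / 12) * (2 / 15))
  z12 <- (rb[1] - rb[2]) / se
  expect_equal(ph$z[ph$group1 == 1 & ph$group2 == 2], unname(z12),
               tolerance = 1e-10)
})

test_that("AUC equals the tie-aware concordance oracle and is rank-invariant", {
  set.seed(13)
  for (i in 1:20) {
    n <- 30
    scores <- sample(rnorm(12), n, replace = TRUE)  # forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    r <- roc_delong(scores, labels)
    x <- scores[labels]; y <- scores[!labels]
    oracle <- mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_identical(r$auc, oracle)
    # strictly increasing transform leaves the AUC unchanged
    r2 <- roc_delong(exp(2 * scores), labels)
    expect_identical(r2$auc, r$auc)
  }
  expect_equal(roc_delong(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1.0)
  expect_equal(roc_delong(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_delong(1:5, rep(TRUE, 5)), "both classes")
})

test_that("DeLong variance and CI match the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- rnorm(60)
  labels <- c(rep(TRUE, 25), rep(FALSE, 35))
  scores[labels] <- scores[labels] + 1
  r <- roc_delong(scores, labels)
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$delong_variance, as.numeric(pROC::var(pr)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci95[1], max(0, ci[1]), tolerance = 1e-6)
  expect_equal(r$ci95[2], min(1, ci[3]), tolerance = 1e-6)
})

test_that("paired DeLong comparison: conventions, invariance, reference", {
  set.seed(5)
  scores <- rnorm(40); labels <- c(rep(TRUE, 15), rep(FALSE, 25))
  scores[labels] <- scores[labels] + 0.8
  self <- delong_compare(scores, scores, labels)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$p, 1.0)
  mono <- delong_compare(scores, 3 * scores - 7, labels)
  expect_equal(mono$delta_auc, 0)
  other <- rnorm(40)
  res <- delong_compare(scores, other, labels)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, other, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
})

test_that("DeLong covariance matches direct structural components at n = 12", {
  set.seed(123)
  labels <- c(rep(TRUE, 5), rep(FALSE, 7))
  a <- rnorm(12); b <- 0.5 * a + rnorm(12)
  res <- delong_compare(a, b, labels)
  # direct V10/V01 computation
  comp <- function(s) {
    x <- s[labels]; y <- s[!labels]
    psi <- outer(x, y, function(p, q) (p > q) + 0.5 * (p == q))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  ca <- comp(a); cb <- comp(b)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / 5 +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / 7
  expect_equal(res$z, (ca$auc - cb$auc) / sqrt(vd), tolerance = 1e-12)
})

test_that("marker combination: identity, noise robustness, bi-normal oracle", {
  set.seed(99)
  n <- 500
  y <- rbinom(n, 1, 0.5) == 1
  m1 <- rnorm(n) + y * 1.2
  tab <- tibble::tibble(m1 = m1, m1b = m1, noise = rnorm(n),
                        ph_status = y)
  # a marker combined with itself scores rank-identically to the marker
  cm_self <- combine_markers(tab, c("m1", "m1b"))
  expect_equal(cm_self$roc$auc, roc_delong(m1, y)$auc, tolerance = 1e-9)
  # adding pure noise must not cost more than 0.02 AUC
  cm_noise <- combine_markers(tab, c("m1", "noise"))
  expect_gte(cm_noise$roc$auc, roc_delong(m1, y)$auc - 0.02)
  # two independent unit-shift markers: optimal linear AUC = Phi(sqrt(2)/sqrt(2))
  n2 <- 2000
  y2 <- rbinom(n2, 1, 0.5) == 1
  tab2 <- tibble::tibble(a = rnorm(n2) + y2, b = rnorm(n2) + y2,
                         ph_status = y2)
  cm2 <- combine_markers(tab2, c("a", "b"))
  expect_lt(abs(cm2$roc$auc - stats::pnorm(1)), 0.03)
  expect_error(combine_markers(tab[1:5, ], c("m1", "noise")), "at least 10")
})

test_that("perfect separation falls back to a penalized fit, flagged", {
  set.seed(1)
  n <- 40
  y <- c(rep(FALSE, 20), rep(TRUE, 20))
  sep <- c(rnorm(20, -3), rnorm(20, 3))
  tab <- tibble::tibble(sep = sep, other = rnorm(n), ph_status = y)
  cm <- combine_markers(tab, c("sep", "other"))
  expect_true(cm$penalized)
  expect_gt(cm$roc$auc, 0.95)
})

test_that("the accuracy exclusion rule is strictly below 0.80", {
  tab <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                        av_accuracy = c(0.75, 0.80, 0.90, NA))
  res <- apply_exclusions(tab)
  expect_setequal(res$av_subcohort$patient_id, c("b", "c"))
  expect_equal(nrow(res$table), 4)
  expect_setequal(res$log$row, c(1, 4))
  all_good <- tibble::tibble(av_accuracy = c(0.8, 0.9, 1.0))
  res2 <- apply_exclusions(all_good)
  expect_equal(nrow(res2$av_subcohort), 3)
  expect_equal(nrow(res2$log), 0)
})
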