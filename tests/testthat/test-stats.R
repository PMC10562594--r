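test_that("one-sample chance test matches the textbook formula and t.test", {
  x <- c(0.6, 0.7, 0.55, 0.65, 0.6)
  cr <- one_sample_vs_chance(x)
  m <- mean(x); s <- sd(x)
  expect_equal(cr$statistic, (m - 0.5) / (s / sqrt(5)))
  ref <- t.test(x, mu = 0.5, alternative = "greater")
  expect_equal(cr$p, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(cr$ci[1], unname(ref$conf.int[1]), tolerance = 1e-12)
  expect_equal(cr$effect, (m - 0.5) / s)

  expect_error(one_sample_vs_chance(rep(0.5, 5)), "zero variance")
  expect_error(one_sample_vs_chance(0.6), "at least 2")
})

test_that("welch_t reproduces Welch-Satterthwaite df and Bonferroni caps", {
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:30, 1), 0.3, sd = runif(1, 0.5, 3))
    cr <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(cr$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(unname(cr$df), unname(ref$parameter), tolerance = 1e-10)
    expect_equal(cr$p, unname(ref$p.value), tolerance = 1e-10)
    cr2 <- welch_t(a, b, bonferroni_m = 2L)
    expect_equal(cr2$p, min(1, 2 * cr$p))
    expect_gte(cr2$p, cr$p)  # adjustment never decreases p
  }
  # equal variances, equal n: df approaches the pooled nA + nB - 2
  set.seed(11)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(unname(welch_t(a, b)$df), 398, tolerance = 0.05 * 398)
  expect_error(welch_t(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("mixed 2x2 ANOVA agrees with aov(Error(subject)) on 50 datasets", {
  set.seed(12)
  for (rep in 1:50) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    n <- n1 + n2
    dat <- data.frame(
      subject_id = rep(sprintf("s%02d", 1:n), each = 2),
      condition = rep(c("A", "B"), n),
      condition_order = rep(c(rep(1L, n1), rep(2L, n2)), each = 2),
      score = rnorm(2 * n) +
        rep(rnorm(n), each = 2) +             # subject effects
        runif(1) * (rep(c(0, 1), n)) +        # condition effect
        runif(1) * rep(c(rep(0, n1), rep(1, n2)), each = 2)
    )
    mine <- mixed_anova_2x2(dat)
    ref <- summary(aov(score ~ condition_order * condition +
                         Error(subject_id),
                       data = transform(dat,
                                        condition_order = factor(condition_order),
                                        subject_id = factor(subject_id))))
    btw <- ref[["Error: subject_id"]][[1]]
    wth <- ref[["Error: Within"]][[1]]
    rownames(btw) <- trimws(rownames(btw))
    rownames(wth) <- trimws(rownames(wth))
    get <- function(eff) mine[mine$effect == eff, ]
    expect_equal(get("order")$F, btw["condition_order", "F value"],
                 tolerance = 1e-8)
    expect_equal(get("order")$p, btw["condition_order", "Pr(>F)"],
                 tolerance = 1e-8)
    expect_equal(get("condition")$F, wth["condition", "F value"],
                 tolerance = 1e-8)
    expect_equal(get("condition:order")$F,
                 wth["condition_order:condition", "F value"],
                 tolerance = 1e-8)
    expect_equal(get("condition")$df2, wth["Residuals", "Df"])
  }
})

test_that("mixed ANOVA handles constructed cases and listwise deletion", {
  # pure condition effect, balanced orders: interaction F ~ 0
  n <- 20L
  dat <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:n), each = 2),
    condition = rep(c("A", "B"), n),
    condition_order = rep(rep(1:2, each = n / 2), each = 2),
    score = rep(c(0, 1), n) + rep(seq(0, 1, length.out = n), each = 2)
  )
  an <- mixed_anova_2x2(dat)
  expect_lt(an$F[an$effect == "condition:order"], 1e-20)
  expect_gt(an$F[an$effect == "condition"], 1e6)

  # subjects missing one condition are dropped listwise
  dat2 <- dat
  dat2$score[dat2$subject_id == "s01" & dat2$condition == "B"] <- NA
  expect_identical(attr(mixed_anova_2x2(dat2), "n"), n - 1L)

  expect_error(
    mixed_anova_2x2(dat[dat$condition_order == 1, ]),
    "order group")
})

test_that("paired permutation test behaves at its exact tails", {
  expect_equal(paired_permutation(rep(0.3, 10), rep(0.3, 10))$p, 1)

  set.seed(13)
  d <- abs(rnorm(20)) + 0.01  # all same sign
  p <- paired_permutation(d, n_perm = 10000, seed = 1)$p
  expect_lte(p, 2 * (1 / 2)^19 + 20 / 10001)

  # invariance under translation-free positive scaling of differences
  p1 <- paired_permutation(d * 3, n_perm = 500, seed = 7)$p
  p2 <- paired_permutation(d, n_perm = 500, seed = 7)$p
  expect_identical(p1, p2)

  x <- rnorm(10); y <- rnorm(10)
  p3 <- paired_permutation(x, y, n_perm = 500, seed = 8)$p
  p4 <- paired_permutation((x + 5) * 2, (y + 5) * 2, n_perm = 500,
                           seed = 8)$p
  expect_identical(p3, p4)

  expect_error(paired_permutation(1:3, 3:1), "at least 6")
})

test_that("permutation and chance tests are calibrated under the null", {
  set.seed(14)
  rej_perm <- mean(replicate(300, {
    d <- rnorm(24)
    paired_permutation(d, n_perm = 300)$p < 0.05
  }))
  expect_lt(abs(rej_perm - 0.05), 0.035)
  rej_t <- mean(replicate(1000, {
    x <- 0.5 + rnorm(30, sd = 0.1)
    one_sample_vs_chance(x)$p < 0.05
  }))
  expect_lt(abs(rej_t - 0.05), 0.02)
})

test_that("recall-organization correlation matches cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(recall_organization_correlation(x, 2 * x + 1)$statistic, 1)

  set.seed(15)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    a <- rnorm(n); b <- 0.3 * a + rnorm(n)
    cr <- recall_organization_correlation(a, b)
    ref <- cor.test(a, b)
    expect_equal(cr$statistic, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(cr$p, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(cr$ci, as.vector(ref$conf.int), tolerance = 1e-10)
  }
  expect_error(recall_organization_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("correlation CI covers the true null value ~95% of the time", {
  set.seed(16)
  cover <- mean(replicate(400, {
    a <- rnorm(40); b <- rnorm(40)
    ci <- recall_organization_correlation(a, b)$ci
    ci[1] < 0 && 0 < ci[2]
  }))
  expect_lt(abs(cover - 0.95), 0.03)
})

test_that("repeated-measures ANOVA and GG epsilon agree with dual routes", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(8:20, 1); k <- 4
    mat <- matrix(rnorm(n * k), n, k) + rnorm(n)
    res <- one_way_rm_anova(mat, gg = FALSE)
    long <- data.frame(y = as.vector(t(mat)),
                       cond = factor(rep(1:k, n)),
                       subj = factor(rep(1:n, each = k)))
    ref <- summary(aov(y ~ cond + Error(subj), data = long))
    wth <- ref[["Error: Within"]][[1]]
    rownames(wth) <- trimws(rownames(wth))
    expect_equal(res$F, wth["cond", "F value"], tolerance = 1e-8)
    expect_equal(res$p, wth["cond", "Pr(>F)"], tolerance = 1e-8)

    # epsilon via the eigenvalue route on orthonormal contrasts
    C <- t(qr.Q(qr(cbind(1, contr.helmert(k))))[, -1])
    lam <- eigen(C %*% cov(mat) %*% t(C), only.values = TRUE)$values
    eps_ref <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    expect_equal(gg_epsilon(mat), eps_ref, tolerance = 1e-10)
    expect_gte(gg_epsilon(mat), 1 / (k - 1) - 1e-12)
    expect_lte(gg_epsilon(mat), 1 + 1e-12)
  }
  # two-level factor: epsilon identically 1
  mat2 <- matrix(rnorm(20), 10, 2)
  expect_equal(gg_epsilon(mat2), 1, tolerance = 1e-12)
})
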