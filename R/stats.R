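#' @title Condition-contrast containers
#' @description Every statistical operation returns a `contrast_result`,
#'   a light container holding the descriptives, test statistic, degrees
#'   of freedom (possibly fractional), p-value, effect size and adjustment
#'   label, so stage outputs serialise uniformly to the contrasts CSV.
#' @param measure character label of the measure tested.
#' @param means,sds,ns named numeric vectors of per-group descriptives.
#' @param statistic,df,p,effect,effect_type,adjustment,n_perm,ci test
#'   results; `df` may be length 2 for F tests, `ci` a length-2 vector.
#' @return object of class `contrast_result`.
#' @keywords internal
contrast_result <- function(measure, means, sds, ns, statistic, df, p,
                            effect = NA_real_, effect_type = NA_character_,
                            adjustment = "none", n_perm = NA_integer_,
                            ci = c(NA_real_, NA_real_)) {
  stopifnot(p >= 0, p <= 1)
  structure(list(measure = measure, means = means, sds = sds, ns = ns,
                 statistic = statistic, df = df, p = p, effect = effect,
                 effect_type = effect_type, adjustment = adjustment,
                 n_perm = n_perm, ci = ci),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("<contrast_result> %s: stat = %.4g, df = (%s), p = %.4g",
              x$measure, x$statistic, dfs, x$p))
  if (!is.na(x$effect)) cat(sprintf(", %s = %.3g", x$effect_type, x$effect))
  if (x$adjustment != "none") cat(sprintf(" [%s]", x$adjustment))
  cat("\n")
  invisible(x)
}

#' One-sample t test against chance
#'
#' Tests whether a set of factor scores exceeds the chance level 0.5 (by
#' default one-tailed, with a one-sided confidence interval).
#'
#' @param scores numeric scores; `NA`s are dropped.
#' @param mu0 null value (default [chance_level()]).
#' @param tail `"greater"` (default), `"less"` or `"two.sided"`.
#' @param conf confidence level (default 0.95).
#' @param measure label for the result.
#' @return a `contrast_result` with Cohen's d and the one-sided CI bound.
#' @export
one_sample_vs_chance <- function(scores, mu0 = chance_level(),
                                 tail = c("greater", "less", "two.sided"),
                                 conf = 0.95, measure = "score_vs_chance") {
  tail <- match.arg(tail)
  x <- scores[!is.na(scores)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 defined scores")
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: all scores identical")
  m <- mean(x)
  se <- s / sqrt(n)
  tstat <- (m - mu0) / se
  df <- n - 1L
  p <- switch(tail,
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df),
              two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
  q <- stats::qt(conf, df)
  ci <- switch(tail,
               greater = c(m - q * se, Inf),
               less = c(-Inf, m + q * se),
               two.sided = m + c(-1, 1) * stats::qt((1 + conf) / 2, df) * se)
  contrast_result(measure, means = c(sample = m), sds = c(sample = s),
                  ns = c(sample = n), statistic = tstat, df = df, p = p,
                  effect = (m - mu0) / s, effect_type = "cohens_d",
                  ci = ci)
}

#' Welch two-sample t test with optional Bonferroni adjustment
#'
#' Unpaired comparison of two groups without assuming equal variances:
#' the degrees of freedom are adjusted by the Welch-Satterthwaite
#' approximation. The p-value is multiplied by `bonferroni_m` (capped at
#' 1) when the comparison is one of a family.
#'
#' @param a,b numeric score vectors (`NA`s dropped).
#' @param bonferroni_m number of comparisons in the family (default 1 =
#'   no adjustment).
#' @param conf confidence level for the two-sided CI on the mean
#'   difference.
#' @param measure label for the result.
#' @return a `contrast_result` (Cohen's d uses the pooled SD).
#' @export
welch_t <- function(a, b, bonferroni_m = 1L, conf = 0.95,
                    measure = "group_contrast") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need at least 2 scores per group")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("zero variance in both groups")
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p_raw <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p <- min(1, p_raw * bonferroni_m)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  q <- stats::qt((1 + conf) / 2, df)
  contrast_result(measure,
                  means = c(a = mean(a), b = mean(b)),
                  sds = c(a = sqrt(va), b = sqrt(vb)),
                  ns = c(a = na, b = nb),
                  statistic = tstat, df = df, p = p,
                  effect = (mean(a) - mean(b)) / sp,
                  effect_type = "cohens_d",
                  adjustment = if (bonferroni_m > 1L) "bonferroni" else "none",
                  ci = (mean(a) - mean(b)) + c(-1, 1) * q * sqrt(se2))
}

#' 2 (within) x 2 (between) split-plot ANOVA
#'
#' The mixed design used for condition contrasts: context condition as a
#' two-level within-subject factor crossed with condition order as a
#' two-level between-subject factor. Sums of squares are computed
#' stratum-wise (between-subject stratum for the order effect,
#' within-subject stratum for condition and the interaction), which for
#' this design coincides with `aov(score ~ order * condition +
#' Error(subject))`. Subjects missing either condition score are dropped
#' listwise. Partial eta squared is `SS_effect / (SS_effect + SS_error)`
#' within the effect's stratum.
#'
#' @param data long data.frame with columns `subject_id`, `condition`
#'   (exactly 2 levels), `condition_order` (2 levels) and the score column
#'   named by `score`.
#' @param score name of the score column (default `"score"`).
#' @return data.frame of class `anova_2x2` with one row per effect
#'   (`condition`, `order`, `condition:order`): `df1`, `df2`, `F`, `p`,
#'   `pes` (partial eta squared); attribute `n` gives the subjects kept.
#' @export
mixed_anova_2x2 <- function(data, score = "score") {
  stopifnot(all(c("subject_id", "condition", "condition_order") %in%
                  names(data)), score %in% names(data))
  conds <- sort(unique(as.character(data$condition)))
  if (length(conds) != 2L) stop("condition must have exactly 2 levels")
  wide <- stats::reshape(
    data[, c("subject_id", "condition", "condition_order", score)],
    idvar = "subject_id", timevar = "condition", direction = "wide"
  )
  y1 <- wide[[paste0(score, ".", conds[1L])]]
  y2 <- wide[[paste0(score, ".", conds[2L])]]
  keep <- !is.na(y1) & !is.na(y2)
  wide <- wide[keep, ]; y1 <- y1[keep]; y2 <- y2[keep]
  g <- factor(wide[[grep("^condition_order", names(wide))[1L]]])
  if (nlevels(g) != 2L || any(table(g) < 2L)) {
    stop("need at least 2 complete subjects per order group")
  }
  n <- length(y1)

  tt <- (y2 - y1) / sqrt(2)  # within-subject stratum coordinates
  ss <- (y1 + y2) / sqrt(2)  # between-subject stratum coordinates
  ss_cond <- sum(tt)^2 / n
  tbar_g <- tapply(tt, g, mean)
  n_g <- tabulate(g)
  ss_int <- sum(n_g * tbar_g^2) - ss_cond
  ss_werr <- sum((tt - tbar_g[g])^2)
  sbar_g <- tapply(ss, g, mean)
  ss_order <- sum(n_g * (sbar_g - mean(ss))^2)
  ss_berr <- sum((ss - sbar_g[g])^2)

  df_err <- n - 2L
  eff <- function(ssq, sserr) {
    F <- (ssq / 1) / (sserr / df_err)
    c(F = F, p = stats::pf(F, 1, df_err, lower.tail = FALSE),
      pes = ssq / (ssq + sserr))
  }
  rows <- rbind(condition = eff(ss_cond, ss_werr),
                order = eff(ss_order, ss_berr),
                `condition:order` = eff(ss_int, ss_werr))
  out <- data.frame(effect = rownames(rows), df1 = 1L, df2 = df_err,
                    F = rows[, "F"], p = rows[, "p"], pes = rows[, "pes"],
                    row.names = NULL)
  structure(out, n = n, conditions = conds,
            class = c("anova_2x2", "data.frame"))
}

#' Sign-flipping permutation test for paired scores
#'
#' Nonparametric companion to the within-subject contrasts: the signs of
#' the per-subject condition differences are flipped at random and the
#' two-sided p-value is `(1 + #{|perm mean| >= |obs mean|}) / (n_perm + 1)`.
#' Invariant to translation and positive rescaling of the scores.
#'
#' @param x,y paired score vectors (or `y = NULL` and `x` the
#'   differences); pairs with any `NA` are dropped.
#' @param n_perm number of random sign assignments (default 10000).
#' @param seed optional RNG seed.
#' @param measure label for the result.
#' @return a `contrast_result`; the statistic is the observed mean
#'   difference.
#' @export
paired_permutation <- function(x, y = NULL, n_perm = 10000L, seed = NULL,
                               measure = "paired_permutation") {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 6L) stop("need at least 6 complete pairs")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(d)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm <- as.vector(signs %*% d) / n
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  contrast_result(measure, means = c(diff = obs),
                  sds = c(diff = stats::sd(d)), ns = c(pairs = n),
                  statistic = obs, df = NA_real_, p = p,
                  n_perm = as.integer(n_perm))
}

#' Pearson correlation between recall and organization
#'
#' Linear association between correct-recall counts and a clustering
#' factor score, with the two-sided t test on `df = n - 2` and a 95%
#' Fisher-z confidence interval.
#'
#' @param n_correct,factor_scores paired numeric vectors; incomplete
#'   pairs are dropped.
#' @param conf confidence level (default 0.95).
#' @param measure label for the result.
#' @return a `contrast_result`; the statistic is Pearson's r, `effect`
#'   repeats r.
#' @export
recall_organization_correlation <- function(n_correct, factor_scores,
                                            conf = 0.95,
                                            measure = "recall_x_organization") {
  keep <- !is.na(n_correct) & !is.na(factor_scores)
  x <- n_correct[keep]; y <- factor_scores[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  z <- atanh(r)
  zse <- 1 / sqrt(n - 3)
  q <- stats::qnorm((1 + conf) / 2)
  contrast_result(measure, means = c(r = r), sds = c(r = NA_real_),
                  ns = c(pairs = n), statistic = r, df = df, p = p,
                  effect = r, effect_type = "pearson_r",
                  ci = tanh(z + c(-1, 1) * q * zse))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Used for the binned serial-position analysis, where the within factor
#' has four levels and sphericity is rarely tenable. The
#' Greenhouse-Geisser epsilon is estimated from the double-centred
#' covariance matrix of the conditions and multiplies both F-test degrees
#' of freedom; for a two-level factor epsilon is identically 1.
#'
#' @param mat numeric matrix, one row per subject, one column per level of
#'   the within factor; rows with `NA` are dropped.
#' @param gg apply the Greenhouse-Geisser correction (default `TRUE`).
#' @return list with `F`, `df1`, `df2`, `p`, `pes`, `epsilon`, `n`.
#' @export
one_way_rm_anova <- function(mat, gg = TRUE) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 levels")
  grand <- mean(mat)
  col_m <- colMeans(mat)
  row_m <- rowMeans(mat)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_err <- sum((mat - outer(row_m, col_m, `+`) + grand)^2)
  eps <- if (gg) gg_epsilon(mat) else 1
  df1 <- (k - 1) * eps
  df2 <- (n - 1) * (k - 1) * eps
  F <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE),
       pes = ss_cond / (ss_cond + ss_err), epsilon = eps, n = n)
}

#' Greenhouse-Geisser epsilon
#'
#' @param mat subjects-by-levels score matrix.
#' @return epsilon in [1/(k-1), 1].
#' @export
gg_epsilon <- function(mat) {
  S <- stats::cov(as.matrix(mat))
  k <- ncol(S)
  D <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
  sum(diag(D))^2 / ((k - 1) * sum(D^2))
}
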