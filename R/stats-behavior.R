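# The study's statistical tests, with its reporting conventions (ranksum
# of the first sample plus z value, Yates-corrected chi-square on
# proportions), and behavioral scoring (discrimination index, exploration
# exclusion rule).

#' Wilcoxon rank-sum test (ranksum / zval reporting convention)
#'
#' The statistic is the sum of ranks of `x` in the pooled sample. The z
#' value uses the normal approximation with tie correction and a 0.5
#' continuity correction; the p value is taken from the exact distribution
#' when `min(n) <= 10` and the pooled sample has no ties, otherwise from
#' the normal approximation.
#'
#' @param x,y numeric samples.
#' @return list with `ranksum`, `zval`, `p`, `n` (`c(nx, ny)`) and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_ranksum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  ranksum <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))
  sigma2 <- nx * ny / 12 * (nx + ny + 1 - tie_term)
  dev <- ranksum - mu
  z <- if (sigma2 > 0) (dev - sign(dev) * 0.5) / sqrt(sigma2) else 0
  has_ties <- any(ties > 1)
  if (min(nx, ny) <= 10 && !has_ties) {
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(ranksum = ranksum, zval = z, p = min(1, p), n = c(nx, ny),
       method = method)
}

#' One-way ANOVA across groups
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return list with `F`, `df` (`c(between, within)`) and `p`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2)
    ln_stop("need at least two groups", "lfpnet_error_stats")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::aov(y ~ g))
  list(F = a$`F value`[1], df = c(a$Df[1], a$Df[2]), p = a$`Pr(>F)`[1])
}

#' Paired t test
#'
#' @param x_pre,x_post paired samples (t is computed for `x_pre - x_post`).
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x_pre, x_post) {
  tt <- stats::t.test(x_pre, x_post, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Chi-square test on a 2 x 2 table
#'
#' Yates continuity correction by default (the convention that reproduces
#' the proportion comparisons of responder counts); set `yates = FALSE`
#' for the uncorrected statistic.
#'
#' @param a,b,c,d cell counts, rows = groups: `(a, b)` and `(c, d)`.
#' @param yates apply the continuity correction.
#' @return list with `chi`, `df` (= 1) and `p`.
#' @export
chisq_2x2 <- function(a, b, c, d, yates = TRUE) {
  m <- matrix(c(a, c, b, d), 2, 2)
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(chi = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Chi-square comparison of two proportions k1/n1 vs k2/n2
#'
#' Convenience wrapper around [chisq_2x2()] for responder counts.
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @param yates apply the continuity correction.
#' @export
chisq_proportions <- function(k1, n1, k2, n2, yates = TRUE) {
  chisq_2x2(k1, n1 - k1, k2, n2 - k2, yates = yates)
}

#' Discrimination index
#'
#' `(t_novel - t_familiar) / (t_novel + t_familiar)`; for the
#' object-location task "novel" is the displaced object. Chance level 0.
#'
#' @param t_novel,t_familiar interaction times, s (vectorized).
#' @return DI in `[-1, 1]`.
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  tot <- t_novel + t_familiar
  if (any(tot <= 0))
    ln_stop("total interaction time must be positive", "lfpnet_error_stats")
  (t_novel - t_familiar) / tot
}

#' Exclude animals with low exploration
#'
#' Animals with velocity strictly below the threshold (default 20 cm/min)
#' are excluded from further analysis.
#'
#' @param trials behavior data.frame with a `velocity_cm_min` column.
#' @param threshold_cm_min exclusion threshold.
#' @return list with `kept`, `excluded` (data.frames) and `n_excluded`.
#' @export
exclusion_filter <- function(trials, threshold_cm_min = 20) {
  low <- trials$velocity_cm_min < threshold_cm_min
  list(kept = trials[!low, , drop = FALSE],
       excluded = trials[low, , drop = FALSE],
       n_excluded = sum(low))
}

#' Two-group comparison with the variance-homogeneity gate
#'
#' Screens the two samples with an F test on their variances (the study's
#' normality screen, which in practice acts as a variance-homogeneity
#' gate — an unconventional use, applied here for fidelity to the original
#' analysis chain): when the gate passes (p >= alpha) a one-way ANOVA is
#' used, otherwise the Wilcoxon rank-sum test.
#'
#' @param x,y numeric samples.
#' @param alpha gate level.
#' @return list with `test` (`"anova"` or `"ranksum"`), `gate_p` and
#'   `result` (the chosen test's output).
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  gate <- stats::var.test(x, y)$p.value
  if (gate >= alpha) {
    list(test = "anova", gate_p = gate, result = oneway_anova(list(x, y)))
  } else {
    list(test = "ranksum", gate_p = gate, result = wilcoxon_ranksum(x, y))
  }
}
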