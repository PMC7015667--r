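#' D'Agostino K-squared normality test
#'
#' Omnibus test combining the standardized sample skewness (D'Agostino 1970
#' transformation) and kurtosis (Anscombe-Glynn transformation); the
#' statistic `K2 = Z_skew^2 + Z_kurt^2` is referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x numeric sample with at least 8 observations.
#' @return a one-row data frame: `statistic`, `z_skew`, `z_kurt`, `raw_p`,
#'   `method`, `n`.
#' @export
normality_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino's K2 test needs at least 8 observations")
  if (sd(x) == 0) stop("sample has zero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  g2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  data.frame(statistic = k2, z_skew = z1, z_kurt = z2,
             raw_p = pchisq(k2, df = 2, lower.tail = FALSE),
             method = "D'Agostino K2", n = n)
}

#' Compare groups with the study's testing scheme
#'
#' Two groups: Student's t-test (paired or unpaired) with Bonferroni
#' adjustment `min(1, p * n_comparisons)`. More than two groups: one-way
#' ANOVA followed by Tukey's multiple comparison test.
#'
#' @param samples named list of numeric vectors (>= 2 groups).
#' @param paired paired comparison (two groups only; equal lengths required).
#' @param n_comparisons Bonferroni family size for the t-test p-value
#'   (default 1).
#' @return for two groups, a one-row data frame (`statistic`, `raw_p`,
#'   `adjusted_p`, `method`, `n1`, `n2`); for more, a list with `anova`
#'   (one-row data frame with the F statistic) and `tukey` (pairwise data
#'   frame with adjusted p-values).
#' @export
compare_groups <- function(samples, paired = FALSE, n_comparisons = 1) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  if (length(samples) == 2) {
    a <- samples[[1]]; b <- samples[[2]]
    if (paired && length(a) != length(b))
      stop("paired comparison requires equal group sizes")
    if (paired && all(a == b))      # degenerate: no difference at all
      return(data.frame(statistic = 0, raw_p = 1, adjusted_p = 1,
                        method = "paired t-test (Bonferroni)",
                        n1 = length(a), n2 = length(b)))
    tt <- t.test(a, b, paired = paired, var.equal = TRUE)
    return(data.frame(statistic = unname(tt$statistic),
                      raw_p = tt$p.value,
                      adjusted_p = min(1, tt$p.value * n_comparisons),
                      method = if (paired) "paired t-test (Bonferroni)"
                               else "t-test (Bonferroni)",
                      n1 = length(a), n2 = length(b)))
  }
  if (paired) stop("paired comparisons are defined for two groups only")
  df <- data.frame(
    value = unlist(samples, use.names = FALSE),
    group = factor(rep(names(samples), lengths(samples))))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(anova = data.frame(statistic = an$`F value`[1],
                          raw_p = an$`Pr(>F)`[1],
                          adjusted_p = an$`Pr(>F)`[1],
                          method = "one-way ANOVA",
                          n = nrow(df)),
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          adjusted_p = tk[, "p adj"],
                          row.names = NULL))
}

#' Sample size for comparing two means
#'
#' Smallest integer `n1` (with `n2 = ratio * n1`) achieving the requested
#' power for a two-sided comparison of two means, by the normal
#' approximation:
#' `n1 = (z_{1-alpha/2} + z_{power})^2 * sigma^2 * (1 + 1/ratio) / delta^2`,
#' rounded up, with a floor of 1.
#'
#' @param mu1,mu2 group means (must differ).
#' @param sigma common SD (> 0).
#' @param alpha two-sided type-I error rate (default 0.05).
#' @param power target power 1 - beta (default 0.8).
#' @param ratio allocation ratio n2/n1 (default 1).
#' @return integer `n1`.
#' @export
sample_size_two_means <- function(mu1, mu2, sigma, alpha = 0.05,
                                  power = 0.8, ratio = 1) {
  stop_if_not_scalar_pos(sigma, "sigma")
  stop_if_not_scalar_pos(ratio, "ratio")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  delta <- mu1 - mu2
  if (delta == 0) stop("mu1 and mu2 must differ")
  n <- (qnorm(1 - alpha / 2) + qnorm(power))^2 * sigma^2 *
    (1 + 1 / ratio) / delta^2
  max(1L, as.integer(ceiling(n - 1e-9)))
}
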