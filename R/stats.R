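#' @importFrom stats fisher.test pnorm prop.test qnorm quantile rnorm runif
NULL

#' Fisher's exact test with base-2 log-odds
#'
#' Enrichment statistic used throughout: the two-sided Fisher exact p-value
#' on the raw 2x2 table, and the base-2 log odds ratio. When any cell is
#' zero, 0.5 is added to all four cells for the log-odds only
#' (Haldane-Anscombe); the p-value always comes from the uncorrected counts.
#'
#' @param a,b,c,d the 2x2 counts, laid out as rows (feature present, feature
#'   absent) by columns (outcome, no outcome): \code{a} present+outcome,
#'   \code{b} present+no outcome, \code{c} absent+outcome, \code{d} absent+no
#'   outcome.
#' @param alternative passed to [stats::fisher.test()] (default two-sided).
#' @return list with elements \code{table} (the four counts),
#'   \code{log2_odds} and \code{p_value}.
#' @examples
#' fetLogOdds(30, 70, 10, 390)$log2_odds  # log2(16.71) ~ 4.06
#' @export
fetLogOdds <- function(a, b, c, d, alternative = "two.sided") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("fetLogOdds: counts must be non-negative")
  if (sum(cells) == 0) stop("fetLogOdds: empty table")
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  lor <- log2((cc["a"] * cc["d"]) / (cc["b"] * cc["c"]))
  p <- fisher.test(matrix(cells, 2, 2, byrow = TRUE),
                   alternative = alternative)$p.value
  list(table = unname(cells), log2_odds = unname(lor), p_value = p)
}

#' Random-set (RS) enrichment test
#'
#' Compares the mean feature value in a site set against its sampling
#' distribution over random sets of the same size drawn from the population,
#' using the standardized statistic
#' Z = (Xbar - mu) / (sigma/sqrt(m) * sqrt((N-m)/(N-1)))
#' (finite-population correction included). The p-value is one-sided
#' (enrichment): it is small only when the set has higher values than random
#' sets.
#'
#' @param values numeric feature per site (population).
#' @param members logical set indicator, same length; at least one TRUE and
#'   at least one FALSE.
#' @param B optional number of Monte-Carlo resamples; when > 0 an empirical
#'   p-value over B random size-m sets is added as \code{p_mc}.
#' @param fpc include the finite-population correction (default TRUE).
#' @return list with m, N, Xbar, mu, sigma, Z, p_value (and p_mc when
#'   requested).
#' @export
rsTest <- function(values, members, B = 0, fpc = TRUE) {
  stopifnot(length(values) == length(members))
  members <- as.logical(members)
  m <- sum(members)
  N <- length(values)
  if (m < 1 || m >= N) stop("rsTest: need 1 <= m < N")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2) * N / (N - 1))
  xbar <- mean(values[members])
  if (sigma == 0) {
    z <- 0
    p <- 0.5
  } else {
    se <- sigma / sqrt(m) * if (fpc) sqrt((N - m) / (N - 1)) else 1
    z <- (xbar - mu) / se
    p <- pnorm(z, lower.tail = FALSE)
  }
  out <- list(m = m, N = N, Xbar = xbar, mu = mu, sigma = sigma,
              Z = z, p_value = p)
  if (B > 0) {
    null_means <- vapply(seq_len(B), function(i)
      mean(values[sample.int(N, m)]), 0)
    out$p_mc <- (sum(null_means >= xbar) + 1) / (B + 1)
  }
  out
}

#' Wilson 95% confidence interval for a proportion
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return list with k, n, estimate, ci_low, ci_high.
#' @examples
#' proportionCI(8, 10)  # ci ~ (0.490, 0.943)
#' @export
proportionCI <- function(k, n, conf = 0.95) {
  if (n < 1) stop("proportionCI: n must be >= 1")
  if (k < 0 || k > n) stop("proportionCI: need 0 <= k <= n")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(k = k, n = n, estimate = p,
       ci_low = max(0, center - half), ci_high = min(1, center + half))
}

#' Compare two proportions (score test)
#'
#' Two-sided chi-square score test without continuity correction, plus the
#' Wilson interval of each proportion.
#'
#' @param k1,n1 successes/trials in group 1.
#' @param k2,n2 successes/trials in group 2.
#' @return list with the two estimates, their Wilson CIs, and p_value.
#' @export
compareProportions <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("compareProportions: n must be >= 1")
  p <- suppressWarnings(
    prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$p.value)
  if (is.na(p)) p <- 1  # degenerate table (all successes or all failures)
  c1 <- proportionCI(k1, n1)
  c2 <- proportionCI(k2, n2)
  list(estimate1 = c1$estimate, ci1 = c(c1$ci_low, c1$ci_high),
       estimate2 = c2$estimate, ci2 = c(c2$ci_low, c2$ci_high),
       p_value = p)
}

#' Matthews correlation coefficient
#'
#' @param truth logical (or 0/1) observed labels.
#' @param pred logical (or 0/1) predicted labels.
#' @return MCC in [-1, 1]; 0 when a marginal is degenerate.
#' @export
mcc <- function(truth, pred) {
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  tp <- sum(truth & pred)
  tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param labels logical outcome.
#' @param scores numeric scores.
#' @return AUC in [0, 1].
#' @export
aucROC <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
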