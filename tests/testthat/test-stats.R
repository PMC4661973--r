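# independent oracle: odds ratio by direct arithmetic, two-sided exact p by
# enumerating the hypergeometric distribution of the top-left cell
.oracleFET <- function(a, b, c, d) {
  lor <- if (any(c(a, b, c, d) == 0))
    log2(((a + .5) * (d + .5)) / ((b + .5) * (c + .5)))
  else log2((a * d) / (b * c))
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p <- sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  list(lor = lor, p = p)
}

test_that("Fisher log2-odds matches direct arithmetic on worked examples", {
  r <- fetLogOdds(30, 70, 10, 390)
  expect_equal(r$log2_odds, log2((30 * 390) / (70 * 10)), tolerance = 1e-12)
  expect_equal(r$log2_odds, 4.0632, tolerance = 1e-4)

  r0 <- fetLogOdds(10, 10, 10, 10)
  expect_equal(r0$log2_odds, 0)
  expect_equal(r0$p_value, 1)

  # zero-cell policy: corrected finite LOR, exact p from uncorrected counts
  rz <- fetLogOdds(5, 0, 3, 7)
  expect_true(is.finite(rz$log2_odds))
  expect_equal(rz$log2_odds, log2((5.5 * 7.5) / (0.5 * 3.5)))
  expect_equal(rz$p_value, fisher.test(matrix(c(5, 0, 3, 7), 2, 2,
                                              byrow = TRUE))$p.value)
  expect_error(fetLogOdds(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher results agree with the brute-force oracle on random tables", {
  set.seed(42)
  for (i in 1:300) {
    cells <- rpois(4, sample(c(3, 12, 40), 1)) + sample(0:1, 4, TRUE)
    r <- fetLogOdds(cells[1], cells[2], cells[3], cells[4])
    o <- .oracleFET(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$log2_odds, o$lor, tolerance = 1e-10)
    expect_equal(r$p_value, o$p, tolerance = 1e-7)
  }
})

test_that("RS statistic handles degenerate and monotone cases", {
  expect_error(rsTest(1:10, rep(TRUE, 10)), "1 <= m < N")
  r <- rsTest(rep(3, 100), c(rep(TRUE, 10), rep(FALSE, 90)))
  expect_equal(r$Z, 0)
  expect_equal(r$p_value, 0.5)

  v <- sort(rnorm(200))
  top <- seq_along(v) > 180
  r2 <- rsTest(v, top)
  expect_gt(r2$Z, 0)
  expect_lt(r2$p_value, 0.5)
})

test_that("RS enrichment of a set implies depletion of its complement", {
  set.seed(1)
  v <- rnorm(500)
  mem <- seq_along(v) %in% sample(500, 60)
  z1 <- rsTest(v, mem)$Z
  z2 <- rsTest(v, !mem)$Z
  expect_lt(z1 * z2, 0)   # opposite signs
  # with the finite-population correction the relation is exactly antisymmetric
  expect_equal(z1, -z2, tolerance = 1e-10)
})

test_that("Monte-Carlo and analytic RS p-values agree", {
  set.seed(2)
  v <- rnorm(1500)
  mem <- seq_along(v) %in% sample(1500, 100)
  B <- 2000
  r <- rsTest(v, mem, B = B)
  tol <- 3 * sqrt(r$p_value * (1 - r$p_value) / B) + 2 / B
  expect_lt(abs(r$p_mc - r$p_value), max(tol, 0.02))
})

test_that("Wilson intervals match the closed form", {
  r <- proportionCI(8, 10)
  expect_equal(r$estimate, 0.8)
  expect_equal(r$ci_low, 0.490, tolerance = 1e-3)
  expect_equal(r$ci_high, 0.943, tolerance = 1e-3)

  r0 <- proportionCI(0, 10)
  expect_equal(r0$estimate, 0)
  expect_equal(r0$ci_low, 0)
  expect_gt(r0$ci_high, 0)
  expect_error(proportionCI(3, 0), ">= 1")
  expect_error(proportionCI(11, 10), "0 <= k <= n")
})

test_that("two-proportion comparison is calibrated at the null and detects differences", {
  same <- compareProportions(20, 100, 40, 200)
  expect_equal(same$p_value, 1, tolerance = 1e-10)
  diff <- compareProportions(40, 100, 10, 100)
  expect_lt(diff$p_value, 1e-4)
})

test_that("MCC and AUC agree with reference implementations", {
  set.seed(3)
  y <- runif(300) < 0.3
  score <- rnorm(300) + 2 * y
  pred <- score > 0.5
  tp <- sum(y & pred); tn <- sum(!y & !pred)
  fp <- sum(!y & pred); fn <- sum(y & !pred)
  ref <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mcc(y, pred), ref)
  expect_equal(mcc(y, rep(TRUE, 300)), 0)   # degenerate marginal
  ref_auc <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, score, quiet = TRUE))))
  expect_equal(aucROC(y, score), ref_auc, tolerance = 1e-10)
})
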