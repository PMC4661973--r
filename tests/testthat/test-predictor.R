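test_that("a separable feature gives perfect held-out performance", {
  x <- c(rnorm(200, -3), rnorm(200, 3))
  y <- rep(c(FALSE, TRUE), each = 200)
  r <- fitLogistic(matrix(x, dimnames = list(NULL, "f")), y, seed = 1)
  expect_equal(aucTest(r), 1)
  expect_equal(mccTest(r), 1)
  expect_gt(modelSlopes(r)["f"], 0)
})

test_that("a label-independent feature scores at chance", {
  set.seed(9)
  x <- rnorm(5000)
  y <- runif(5000) < 0.2
  r <- suppressWarnings(
    fitLogistic(matrix(x, dimnames = list(NULL, "noise")), y, seed = 2))
  expect_lt(abs(aucTest(r) - 0.5), 0.05)
  expect_error(fitLogistic(matrix(x, ncol = 1), rep(TRUE, 5000)),
               "both classes")
})

test_that("planted generative slopes are recovered", {
  set.seed(21)
  n <- 10000
  code3 <- rnorm(n)
  motif <- runif(n) < 0.074
  y <- runif(n) < plogis(1.5 * code3 + 0.86 * motif - 3)
  r <- fitLogistic(cbind(code3 = code3, mot = as.numeric(motif)), y,
                   seed = 1)
  s <- modelSlopes(r)
  expect_lt(abs(s["code3"] - 1.5) / 1.5, 0.2)
  expect_gt(s["mot"], 0)
  expect_gt(aucTest(r), 0.75)
})

test_that("the tuned cut-off never loses training MCC versus 0.5 and reports are seed-deterministic", {
  set.seed(4)
  n <- 3000
  x <- rnorm(n)
  y <- runif(n) < plogis(1.2 * x - 2.5)
  X <- matrix(x, dimnames = list(NULL, "x"))
  r1 <- fitLogistic(X, y, seed = 7)
  r2 <- fitLogistic(X, y, seed = 7)
  expect_identical(modelSlopes(r1), modelSlopes(r2))
  expect_identical(r1@pc, r2@pc)
  # recompute train MCC at 0.5 with the same split and model
  expect_gte(r1@mccTrain + 1e-12, {
    set.seed(7)
    test_idx <- unlist(lapply(c(0L, 1L), function(cls) {
      idx <- which(as.integer(y) == cls)
      sample(idx, max(1, round(0.2 * length(idx))))
    }))
    tr <- setdiff(seq_len(n), test_idx)
    fit <- glmnet::glmnet(cbind(x = scale(x)[, 1], .dummy = 0)[tr, ],
                          as.integer(y)[tr], family = "binomial",
                          alpha = 1, lambda = 1 / (r1@C * length(tr)),
                          standardize = FALSE)
    pr <- as.numeric(predict(fit, cbind(scale(x)[, 1], 0)[tr, ],
                             type = "response"))
    mcc(y[tr], pr >= 0.5)
  })
})

test_that("the single-mark grid ranks the informative mark first", {
  set.seed(31)
  n <- 6000
  signal <- abs(rnorm(n, 0, 0.2))
  y <- runif(n) < plogis(4 * signal - 2.5)
  V <- cbind(h3k4me1 = pmin(signal, 1),
             h3k27ac = runif(n, 0, 0.5),
             h3k27me3 = runif(n, 0, 0.5))
  rownames(V) <- paste0("s", 1:n)
  motif <- runif(n) < 0.3
  grid <- suppressWarnings(   # chance-level marks may fall back to p_c = 0.5
    table1Grid(MarkMatrix(V), motif, y, siteClass = "dist_s1", seed = 1))
  singles <- grid[grid$model %in% colnames(V), ]
  expect_equal(singles$model[which.max(singles$auc_test)], "h3k4me1")
  # adding an informative mark to the motif never hurts much
  mot_auc <- grid$auc_test[grid$model == "mot"]
  expect_gte(grid$auc_test[grid$model == "h3k4me1 + mot"], mot_auc - 0.02)
  # constant mark scores at chance
  V2 <- cbind(flat = rep(0.5, n), h3k4me1 = pmin(signal, 1))
  rownames(V2) <- rownames(V)
  g2 <- suppressWarnings(table1Grid(MarkMatrix(V2), motif, y, seed = 1))
  expect_lt(abs(g2$auc_test[g2$model == "flat"] - 0.5), 0.06)
  expect_equal(g2$delta_mot[g2$model == "h3k4me1 + mot"],
               g2$auc_test[g2$model == "h3k4me1 + mot"] -
                 g2$auc_test[g2$model == "h3k4me1"])
})

test_that("drop-one robustness flags collinear features", {
  set.seed(41)
  n <- 4000
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  y <- runif(n) < plogis(a + 0.5 * b - 1)
  # orthogonal features: slopes barely move
  r <- dropOneRobustness(cbind(a = a, b = b, c = c_), y)
  expect_true(all(r[, "sd"] < 0.1))
  expect_equal(r["a", "mean"], r["a", "full"], tolerance = 0.1)
  # duplicated feature: its slope swings wildly across refits
  dup <- a + rnorm(n, 0, 0.01)
  r2 <- dropOneRobustness(cbind(a = a, dup = dup, b = b), y)
  expect_gt(r2["a", "sd"], 5 * r["a", "sd"])
  expect_error(dropOneRobustness(matrix(a, ncol = 1), y), "at least 2")
})
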