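# small hand-made occupancy table
.makeOcc <- function(X, p65, stage = NULL) {
  X <- X == 1
  occ <- as.integer(rowSums(
    X[, setdiff(colnames(X), c("CTCF", "RAD21")), drop = FALSE]))
  if (is.null(stage)) stage <- rep("dist_s2", nrow(X))
  new("OccupancyTable", matrix = X, p65 = as.logical(p65),
      occupancy = occ, stage = stage,
      siteIDs = sprintf("s%04d", seq_len(nrow(X))))
}

test_that("the occupancy curve equals a brute-force group-by", {
  t <- testOccupancy()
  oc <- occupancyCurve(t)
  ref <- tapply(t@p65, t@occupancy, mean)
  expect_equal(oc$p65_fraction, as.numeric(ref[as.character(oc$occupancy)]))
  expect_equal(sum(oc$n_sites), length(t@p65))
  # trivial case: no p65 anywhere
  t0 <- .makeOcc(matrix(0, 5, 2, dimnames = list(NULL, c("A", "B"))),
                 rep(FALSE, 5))
  oc0 <- occupancyCurve(t0)
  expect_equal(oc0$p65_fraction, 0)
  expect_equal(oc0$n_sites, 5)
})

test_that("the planted occupancy effect yields a monotone p65 curve", {
  s <- testSites()
  acc <- s[mcols(s)$accessibility == "accessible"]
  oc <- occupancyCurve(occupancyTable(acc))
  oc <- oc[oc$n_sites >= 20, ]
  expect_gt(cor(oc$occupancy, oc$p65_fraction, method = "spearman"), 0.9)
})

test_that("per-TF enrichment matches brute-force tables", {
  X <- matrix(0, 8, 3, dimnames = list(NULL, c("A", "B", "CTCF")))
  X[1:4, "A"] <- 1
  X[c(1, 5), "B"] <- 1
  X[, "CTCF"] <- 1
  t <- .makeOcc(X, c(1, 1, 1, 0, 0, 0, 0, 0))
  e <- tfEnrichment(t, "all")
  a_row <- e[e$tf == "A", ]
  ref <- fetLogOdds(3, 1, 0, 4)
  expect_equal(a_row$log2_odds, ref$log2_odds)
  expect_equal(a_row$p_value, ref$p_value)
  # TF present everywhere has no contrast and is flagged
  expect_true(e$degenerate[e$tf == "CTCF"])
  expect_error(tfEnrichment(t, "prox_s1"), "fewer than 2")
})

test_that("a planted high-propensity TF is recovered at stage-1 enhancers", {
  # BCL3-like: 3.4x odds for p65 at single-TF sites
  set.seed(13)
  n <- 10000
  X <- matrix(0, n, 2, dimnames = list(NULL, c("BCL3", "OTHER")))
  has <- seq_len(n) <= 3000
  X[has, "BCL3"] <- 1
  X[!has, "OTHER"] <- 1
  base_odds <- 0.08
  p <- ifelse(has, 3.4 * base_odds / (1 + 3.4 * base_odds),
              base_odds / (1 + base_odds))
  t <- .makeOcc(X, runif(n) < p, stage = rep("dist_s1", n))
  e <- tfEnrichment(t, "dist_s1")
  expect_lt(abs(e$log2_odds[e$tf == "BCL3"] - log2(3.4)), 0.3)
})

test_that("the cooperativity matrix is symmetric and detects planted synergy", {
  set.seed(17)
  n <- 6000
  X <- matrix(runif(n * 4) < 0.25, n, 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  pj <- ifelse(X[, "A"] & X[, "B"], 0.45,
               ifelse(X[, "A"] | X[, "B"], 0.06, 0.05))
  t <- .makeOcc(X * 1, runif(n) < pj)
  cm <- cooperativityMatrix(t, "dist_s2")
  expect_equal(cm$log2_odds, t(cm$log2_odds))
  expect_gt(cm$log2_odds["A", "B"], 1)
  expect_lt(cm$p_value["A", "B"], 1e-5)
  expect_equal(cm$direction["A", "B"], 1)
  # uncapped because highly significant
  expect_equal(cm$display["A", "B"], cm$log2_odds["A", "B"])
  # independent pair: usually masked; display capping only affects display
  if (!is.na(cm$p_value["C", "D"]) && cm$p_value["C", "D"] >= 0.05)
    expect_true(is.na(cm$display["C", "D"]))
})

test_that("null cooperativity entries are masked at alpha = 0.05", {
  set.seed(19)
  masked <- 0
  for (i in 1:40) {
    n <- 2000
    X <- matrix(runif(n * 2) < 0.3, n, 2, dimnames = list(NULL, c("A", "B")))
    t <- .makeOcc(X * 1, runif(n) < 0.1)
    cm <- cooperativityMatrix(t, "dist_s2")
    if (is.na(cm$display["A", "B"])) masked <- masked + 1
  }
  expect_gte(masked / 40, 0.9)
})

test_that("greedy cluster chains obey the per-step gain rule", {
  cl <- tgcSearch(testOccupancy(), "dist_s2")
  expect_gt(nrow(cl), 0)
  for (i in seq_len(nrow(cl))) {
    lors <- as.numeric(sub(".*:", "",
                           strsplit(cl$expansion_chain[i], ";")[[1]]))
    steps <- diff(lors)
    if (cl$direction[i] == "enriched") expect_true(all(steps >= 0.2 - 1e-9))
    else expect_true(all(steps <= -0.2 + 1e-9))
    expect_gte(cl$support[i], 40)
  }
})

test_that("cluster support and confidence equal brute-force recounts", {
  t <- testOccupancy()
  cl <- tgcSearch(t, "dist_s2")
  for (i in seq_len(min(5, nrow(cl)))) {
    tfs <- strsplit(cl$cluster[i], "\\+")[[1]]
    ind <- rep(TRUE, nrow(t@matrix))
    for (tf in tfs) ind <- ind & t@matrix[, tf]
    expect_equal(cl$support[i], sum(ind))
    expect_equal(cl$confidence[i], mean(t@p65[ind]))
  }
})

test_that("greedy search is deterministic and beats its own seed", {
  t <- testOccupancy()
  c1 <- tgcSearch(t, "dist_s2")
  c2 <- tgcSearch(t, "dist_s2")
  expect_identical(c1, c2)
  # certified optimum on a small panel: greedy never beats exhaustive,
  # and the greedy result improves on every single-TF seed it grew from
  keep <- c("CREB1", "FOXA2", "JUND", "RAD21", "MAX", "SP1", "YY1", "GATA3")
  sub <- new("OccupancyTable",
             matrix = t@matrix[, keep],
             p65 = t@p65,
             occupancy = as.integer(rowSums(
               t@matrix[, setdiff(keep, c("CTCF", "RAD21"))])),
             stage = t@stage, siteIDs = t@siteIDs)
  g <- tgcSearch(sub, "dist_s2")
  best <- bestClusterExhaustive(sub, "dist_s2", minSupport = 40,
                                maxSize = 4)
  expect_gte(best$log2_odds + 1e-9, max(g$log2_odds))
  top <- g[which.max(g$log2_odds), ]
  seed_tf <- sub("[:].*", "", strsplit(top$expansion_chain, ";")[[1]][1])
  seed_ind <- sub@matrix[sub@stage == "dist_s2", seed_tf]
  y <- sub@p65[sub@stage == "dist_s2"]
  seed_lor <- fetLogOdds(sum(seed_ind & y), sum(seed_ind & !y),
                         sum(!seed_ind & y), sum(!seed_ind & !y))$log2_odds
  expect_gte(top$log2_odds, seed_lor)
})

test_that("the planted TF cluster is recovered exactly", {
  cl <- tgcSearch(testOccupancy(), "dist_s2")
  expect_true("CREB1+FOXA2+JUND+RAD21" %in% cl$cluster)
  hit <- cl[cl$cluster == "CREB1+FOXA2+JUND+RAD21", ]
  # within 3 binomial MC SDs of the planted confidence
  expect_lt(abs(hit$confidence - 0.75),
            3 * sqrt(0.75 * 0.25 / hit$support))
  expect_lt(hit$p_value, 1e-10)
})

test_that("rule redundancy pruning keeps only informative antecedents", {
  # one perfectly predictive TF: every superset rule is redundant
  set.seed(23)
  n <- 2000
  X <- matrix(runif(n * 3) < 0.5, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  p65 <- X[, "A"]
  t <- .makeOcc(X * 1, p65)
  rules <- tnrSearch(t, minSupport = 40, k = 100, maxSize = 3)
  with_a <- grepl("A", rules$cluster)
  expect_true("A" %in% rules$cluster)
  expect_false(any(with_a & rules$n_tfs > 1))
  # k = 1 returns the single best admissible rule
  r1 <- tnrSearch(t, minSupport = 40, k = 1, maxSize = 3)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$cluster, "A")
  expect_equal(r1$confidence, 1)
})

test_that("significant greedy clusters appear among top non-redundant rules", {
  t <- testOccupancy()
  cl <- tgcSearch(t, "dist_s2")
  strong <- cl[cl$direction == "enriched" & cl$p_value < 1e-5 &
                 cl$n_tfs <= 4, ]
  rules <- tnrSearch(t, k = 5000, maxSize = 4)
  expect_gt(nrow(strong), 0)
  expect_true(all(strong$cluster %in% rules$cluster))
})
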