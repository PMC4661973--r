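test_that("overlapping and abutting peaks merge transitively into one site", {
  tf <- list(A = gr("chr1", 101, 200), B = gr("chr1", 151, 250))
  s <- buildSites(tf)
  expect_equal(length(s), 1)
  expect_equal(start(s), 101)
  expect_equal(end(s), 250)
  expect_setequal(as.list(mcols(s)$tfs)[[1]], c("A", "B"))

  # directly adjacent (no gap): 0-based [100,200) + [200,300)
  tf2 <- list(A = gr("chr1", 101, 200), B = gr("chr1", 201, 300))
  s2 <- buildSites(tf2)
  expect_equal(length(s2), 1)
  expect_equal(c(start(s2), end(s2)), c(101, 300))

  # a 1-bp gap keeps sites separate
  tf3 <- list(A = gr("chr1", 101, 200), B = gr("chr1", 202, 300))
  expect_equal(length(buildSites(tf3)), 2)
})

test_that("p65-only regions become inaccessible sites", {
  s <- buildSites(list(A = gr("chr1", 101, 200)),
                  p65Peaks = gr("chr1", c(150, 501), c(180, 600)),
                  dhsPeaks = gr("chr1", 1000, 1100))
  expect_equal(length(s), 3)
  m <- mcols(s)
  inacc <- m$accessibility == "inaccessible"
  expect_equal(sum(inacc), 1)
  expect_equal(start(s)[inacc], 501)
  expect_true(all(m$p65[inacc]))
  expect_equal(lengths(m$tfs)[inacc], 0L)
  expect_false(any(m$dhs[inacc]))
})

test_that("merging is idempotent on site intervals", {
  s <- testSites()
  again <- buildSites(list(X = granges(s)))
  expect_equal(start(again), start(s))
  expect_equal(end(again), end(s))
})

test_that("occupancy never counts CTCF, RAD21 or DHS", {
  set.seed(7)
  pool <- c("CTCF", "RAD21", "JUND", "MAX", "SP1", "YY1", "CREB1")
  for (i in 1:25) {
    tfs <- sample(pool, sample(1:6, 1))
    peaks <- lapply(tfs, function(x) gr("chr1", 101, 200))
    names(peaks) <- tfs
    s <- buildSites(peaks, dhsPeaks = gr("chr1", 120, 180))
    expect_equal(mcols(s)$occupancy,
                 length(setdiff(tfs, c("CTCF", "RAD21"))))
  }
})

test_that("stage labels follow the occupancy rules", {
  tss <- gr("chr1", 150, 150)
  # proximal site with JUND + CTCF: occupancy 1 -> prox_s1
  s <- classifySites(buildSites(list(JUND = gr("chr1", 101, 200),
                                     CTCF = gr("chr1", 101, 200))), tss)
  expect_equal(mcols(s)$occupancy, 1)
  expect_equal(mcols(s)$stage, "prox_s1")

  mk <- function(n) {
    peaks <- lapply(seq_len(n), function(i) gr("chr1", 1001, 1100))
    names(peaks) <- paste0("TF", seq_len(n))
    classifySites(buildSites(peaks), tss)
  }
  expect_equal(mcols(mk(1))$stage, "dist_s1")
  expect_equal(mcols(mk(3))$stage, "dist_s2")
  expect_equal(mcols(mk(4))$stage, "dist_s2")
  expect_equal(mcols(mk(5))$stage, "other")
})

test_that("stage and accessibility labels partition the sites", {
  m <- mcols(testSites())
  expect_equal(sum(table(m$stage)), length(testSites()))
  expect_equal(sum(m$accessibility == "accessible") +
                 sum(m$accessibility == "inaccessible"),
               length(testSites()))
  # inaccessible implies p65, no TFs, no DHS
  inacc <- m$accessibility == "inaccessible"
  expect_true(all(m$p65[inacc]))
  expect_true(all(lengths(m$tfs)[inacc] == 0))
  expect_false(any(m$dhs[inacc]))
})

test_that("CGI calls require agreement of both definitions", {
  sites <- buildSites(list(A = gr("chr1", c(101, 1001, 2001),
                                  c(200, 1100, 2100))))
  cgiA <- gr("chr1", c(110, 1010), c(150, 1050))  # sites 1 and 2
  cgiB <- gr("chr1", 110, 150)                    # site 1 only
  meth <- data.frame(chrom = character(), position = numeric(),
                     cov1 = numeric(), pct1 = numeric(),
                     cov2 = numeric(), pct2 = numeric())
  s <- classifyCgiMethylation(sites, cgiA, cgiB, meth)
  expect_equal(mcols(s)$cgi, c("CGI", "unclassified", "nonCGI"))
  expect_equal(mcols(s)$methylation, rep("none", 3))
})

test_that("methylation levels use both-replicate coverage and 25/75 bins", {
  sites <- buildSites(list(A = gr("chr1", 101, 300)))
  meth <- data.frame(
    chrom = "chr1",
    position = c(120, 150, 200),
    cov1 = c(12, 15, 9),          # third CpG under-covered in rep1
    pct1 = c(80, 90, 0),
    cov2 = c(15, 12, 30),
    pct2 = c(80, 90, 0))
  s <- classifyCgiMethylation(sites, GRanges(), GRanges(), meth)
  expect_equal(mcols(s)$meth_mean, 85)   # mean of 80 and 90 only
  expect_equal(mcols(s)$methylation, "high")

  # boundary arithmetic: 25 and 75 are medium, just outside are not
  for (pct in list(c(20, "low"), c(25, "medium"), c(75, "medium"),
                   c(76, "high"))) {
    m2 <- data.frame(chrom = "chr1", position = 120, cov1 = 20,
                     pct1 = as.numeric(pct[1]), cov2 = 20,
                     pct2 = as.numeric(pct[1]))
    s2 <- classifyCgiMethylation(sites, GRanges(), GRanges(), m2)
    expect_equal(mcols(s2)$methylation, pct[2])
  }
})

test_that("methylation enrichment matches direct 2x2 arithmetic", {
  # constructed stratum: 100 high sites (40 p65) vs 100 low sites (10 p65)
  n <- 200
  sites <- buildSites(list(A = gr("chr1", seq(1, by = 200, length.out = n),
                                  seq(100, by = 200, length.out = n))))
  m <- mcols(sites)
  m$tss_proximal <- rep(FALSE, n)
  m$cgi <- rep("nonCGI", n)
  m$methylation <- rep(c("high", "low"), each = 100)
  m$p65 <- c(rep(c(TRUE, FALSE), c(40, 60)), rep(c(TRUE, FALSE), c(10, 90)))
  mcols(sites) <- m
  res <- methylationEnrichment(sites, levels = c("low", "high"))
  hi <- res[res$methylation == "high", ]
  expect_equal(hi$log2_odds, log2(6), tolerance = 1e-12)
  expect_equal(hi$localization, "distal")
  # balanced p65 across levels gives zero log-odds
  m$p65 <- rep(c(TRUE, FALSE), 100)
  mcols(sites) <- m
  res0 <- methylationEnrichment(sites, levels = c("low", "high"))
  expect_true(all(abs(res0$log2_odds) < 1e-12))
})

test_that("planted hyper-methylation enrichment is recovered in sign", {
  s <- testSites()
  acc <- s[mcols(s)$accessibility == "accessible"]
  res <- methylationEnrichment(acc)
  hit <- res[res$localization == "distal" & res$cgi == "nonCGI" &
               res$methylation == "high", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$log2_odds, 0)
  # the planted effect itself, checked at full power via the truth flags
  ts <- testBundle()$truthSites
  bg <- !ts$inaccessible & !ts$proximal & !ts$cgi & !ts$hyper
  cmp <- compareProportions(sum(ts$p65[ts$hyper]), sum(ts$hyper),
                            sum(ts$p65[bg]), sum(bg))
  expect_gt(cmp$estimate1, cmp$estimate2)
  expect_lt(cmp$p_value, 0.01)
})
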