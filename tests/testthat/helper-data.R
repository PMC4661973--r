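suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# shared fixtures, built once per test run
.testCache <- new.env(parent = emptyenv())

testBundle <- function() {
  if (is.null(.testCache$bundle))
    .testCache$bundle <- simulateBundle(nSites = 6000, nGenes = 2000,
                                        seed = 101)
  .testCache$bundle
}

testSites <- function() {
  if (is.null(.testCache$sites)) {
    b <- testBundle()
    s <- buildSites(b$tfPeaks, b$p65Peaks, b$dhsPeaks)
    s <- classifySites(s, b$tss, b$motifPeaks)
    .testCache$sites <- classifyCgiMethylation(s, b$cgiA, b$cgiB,
                                               b$methylation)
  }
  .testCache$sites
}

testOccupancy <- function() {
  if (is.null(.testCache$occ))
    .testCache$occ <- occupancyTable(testSites())
  .testCache$occ
}

# 1-based GRanges shorthand
gr <- function(chrom, start, end, ...) {
  GRanges(chrom, IRanges(start, end), ...)
}

writeLinesTo <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
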