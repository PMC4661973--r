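.linkFixture <- function() {
  # proximal site at TSS; distal sites at increasing distances
  tfA <- gr("chr1", c(99951, 120001, 180001, 240001, 301001, 350001, 400001),
            c(100051, 120100, 180100, 240100, 301100, 350100, 400100))
  tfB <- gr("chr1", c(99951, 120001), c(100051, 120100))
  sites <- buildSites(list(A = tfA, B = tfB))
  tss <- gr("chr1", 100001, 100001, name = "g1")
  list(sites = classifySites(sites, tss), tss = tss)
}

test_that("links respect the 100 kb limit and the 3-site cap", {
  fx <- .linkFixture()
  links <- linkSites(fx$tss, fx$sites)
  expect_equal(sum(links$type == "proximal"), 1)
  distal <- links[links$type == "distal", ]
  expect_lte(nrow(distal), 3)
  expect_true(all(distal$distance <= 1e5))
  # the 300 kb+ sites are never linked
  far_ids <- mcols(fx$sites)$site_id[start(fx$sites) > 250000]
  expect_false(any(far_ids %in% links$site_id))
})

test_that("link scores decay with distance and peak for identical TF sets", {
  fx <- .linkFixture()
  links <- linkSites(fx$tss, fx$sites)
  distal <- links[links$type == "distal", ]
  # identical TF set at the shortest distance scores highest
  expect_equal(distal$site_id[which.max(distal$link_score)],
               distal$site_id[which.min(distal$distance)])
  ord <- order(distal$distance)
  same_sim <- distal[distal$similarity == distal$similarity[ord[2]], ]
  if (nrow(same_sim) > 1) {
    o <- order(same_sim$distance)
    expect_true(all(diff(same_sim$link_score[o]) <= 0))
  }
  # zero distance + identical TF sets would give score 1: check the kernel
  expect_equal(distal$link_score,
               distal$similarity * exp(-distal$distance / 5e4))
})

test_that("no gene receives more than 1 proximal or 3 distal links", {
  b <- testBundle()
  links <- linkSites(b$tss, testSites())
  per_gene <- split(links$type, links$gene_id)
  expect_true(all(vapply(per_gene, function(x) sum(x == "proximal"), 0) <= 1))
  expect_true(all(vapply(per_gene, function(x) sum(x == "distal"), 0) <= 3))
})

test_that("up-regulation fractions equal brute-force group-bys", {
  b <- testBundle()
  links <- linkSites(b$tss, testSites())
  res <- upregulationByOccupancy(links, b$expression)
  tab <- res$byOccupancy
  up_genes <- b$expression$gene_id[b$expression$label == "up"]
  for (i in sample(nrow(tab), min(8, nrow(tab)))) {
    sel <- links$type == tab$type[i] & links$occupancy == tab$occupancy[i]
    if (tab$group[i] == "p65") sel <- sel & links$p65
    expect_equal(tab$n[i], sum(sel))
    expect_equal(tab$frac_up[i], mean(links$gene_id[sel] %in% up_genes))
  }
})

test_that("the planted promoter occupancy effect on up-regulation is recovered", {
  # promoter-focused draw: every gene linked to a p65-rich promoter set
  truth <- syntheticTruth(fracProximal = 0.55, baseLogit = qlogis(0.25),
                          occupancyEffect = 0.25, fracInaccessible = 0.02)
  b <- simulateBundle(truth, nSites = 12000, nGenes = 5000, seed = 303)
  s <- classifySites(buildSites(b$tfPeaks, b$p65Peaks, b$dhsPeaks), b$tss,
                     b$motifPeaks)
  links <- linkSites(b$tss, s)
  res <- upregulationByOccupancy(links, b$expression)
  ctr <- res$contrasts
  hit <- ctr[ctr$group == "p65" & ctr$type == "proximal", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$frac_low, hit$frac_high)
  expect_lt(hit$p_value, 1e-3)
  expect_lt(abs(hit$frac_low - 0.16), 0.05)
  expect_lt(abs(hit$frac_high - 0.05), 0.04)
})

test_that("expression labels independent of p65 give a null contrast", {
  b <- testBundle()
  links <- linkSites(b$tss, testSites())
  set.seed(5)
  shuffled <- b$expression
  shuffled$label <- sample(shuffled$label)
  res <- upregulationByOccupancy(links, shuffled)
  ctr <- res$contrasts
  expect_true(all(ctr$p_value > 1e-4))
})
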