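# Synthetic data generator: emits a full input bundle (peaks, marks,
# methylation, CGIs, TSS, expression labels) with planted, serialized ground
# truth so every pipeline stage can be validated against known parameters.

#' @importFrom stats plogis qlogis rpois rexp rbeta rbinom
NULL

.MARKS <- c("H2A.Z", "H3K27ac", "H3K27me3", "H3K4me1", "H3K4me2", "H3K4me3",
            "H3K79me2", "H3K9ac")

.TF_PANEL <- c("ATF3", "BCL3", "BHLHE40", "CEBPB", "CREB1", "CTCF", "E2F6",
               "ELF1", "FOSL1", "FOXA1", "FOXA2", "GABP", "GATA3", "GR",
               "JUN", "JUND", "MAX", "MYC", "NRF1", "P300", "POL2", "RAD21",
               "SIX5", "SP1", "TAF1", "TCF12", "TEAD4", "USF1", "YY1",
               "ZBTB33")

.plantedCodes <- function() {
  H <- matrix(0, 4, length(.MARKS), dimnames = list(
    paste0("code", 1:4), .MARKS))
  # active promoter: tied acetylation / K4me3 / H2A.Z
  H["code1", c("H3K4me3", "H3K9ac", "H3K27ac", "H2A.Z")] <-
    c(1.0, 0.8, 0.7, 0.6)
  # repressive
  H["code2", "H3K27me3"] <- 1.0
  H["code2", "H2A.Z"] <- 0.15
  # primed enhancer: K4me1-led
  H["code3", c("H3K4me1", "H3K4me2", "H2A.Z")] <- c(1.0, 0.6, 0.4)
  # elongation
  H["code4", c("H3K79me2", "H3K4me1")] <- c(1.0, 0.5)
  H
}

#' Planted ground truth for the synthetic generator
#'
#' The defaults encode the study conditions the analyses assume: a base p65
#' rate anchored so sites bound by 12 TFs recruit p65 ~75\% of the time
#' while stage-2 background sits near 8\%; a motif log-odds of 0.86 applying
#' to 7.4\% of sites; four non-negative chromatin codes with per-code
#' logistic effects (code 3, the H3K4me1-led code, at +1.5); a planted
#' 4-protein cluster (CREB1/RAD21/JUND/FOXA2) with p65 confidence 0.75 and a
#' depleted cluster (GATA3/TCF12/USF1) at 0.01; a hyper-methylation bonus at
#' distal non-CGI sites; and up-regulation probabilities of 16\% (p65-bound,
#' low occupancy) falling to 5\% (high occupancy).
#'
#' @param ... override any default by name.
#' @return named list of planted parameters (YAML-serializable).
#' @export
syntheticTruth <- function(...) {
  defaults <- list(
    marks = .MARKS,
    tfPanel = .TF_PANEL,
    plantedCodes = .plantedCodes(),
    codeEffects = c(code1 = 0.3, code2 = -0.3, code3 = 0.8, code4 = -0.4),
    motifEffect = 0.86,
    motifPrevalence = 0.074,
    baseLogit = -4.30,
    occupancyEffect = 0.46,
    methylationEffect = 0.9,
    plantedCluster = list(tfs = c("CREB1", "RAD21", "JUND", "FOXA2"),
                          confidence = 0.75, fraction = 0.012,
                          partialFraction = 0.03),
    depletedCluster = list(tfs = c("GATA3", "TCF12", "USF1"),
                           confidence = 0.01, fraction = 0.008,
                           partialFraction = 0.02),
    expressionEffect = list(p65_low = 0.16, p65_high = 0.05,
                            no_p65 = 0.04, unlinked = 0.03, down = 0.05),
    fracInaccessible = 0.03,
    fracProximal = 0.30,
    chroms = paste0("chr", 1:5),
    chromLength = 1e7,
    densityScale = 0.05,
    weightMean = 0.25,
    weightSparsity = 0.55,
    dhsBase = -0.5,
    dhsOccSlope = 0.4,
    cgiFracProximal = 0.25,
    cgiFracDistal = 0.08,
    cgiDisagreement = 0.05,
    hyperFracDistalNonCgi = 0.15
  )
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad))
    stop("unknown truth parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  stopifnot(all(defaults$plantedCodes >= 0),
            defaults$motifPrevalence >= 0, defaults$motifPrevalence <= 1,
            defaults$plantedCluster$confidence >= 0,
            defaults$plantedCluster$confidence <= 1)
  defaults
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# place n site intervals of given lengths on the toy genome, non-overlapping
# with gaps >= 20 bp; returns chrom, start (1-based), end
.placeSites <- function(n, lengths, chroms, chromLength) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- integer(n); end <- integer(n)
  for (ch in chroms) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    avail <- 0.90 * chromLength - sum(lengths[idx])
    if (avail <= 20 * length(idx))
      stop("simulateBundle: sites do not fit on the toy genome")
    gaps <- 20 + round(rexp(length(idx), length(idx) / avail))
    s <- cumsum(gaps + c(0, lengths[idx][-length(idx)])) + 1
    if (s[length(s)] + lengths[idx][length(idx)] > chromLength)
      stop("simulateBundle: sites do not fit on the toy genome")
    start[idx] <- s
    end[idx] <- s + lengths[idx] - 1
  }
  data.frame(chrom = chrom, start = start, end = end)
}

#' Generate a full synthetic input bundle
#'
#' Produces every file the pipeline consumes, drawn from the planted model
#' in \code{truth}: TF peak sets with planted cluster co-occurrence, DHS
#' and post-stimulation p65 peaks, motif occurrences, mark read counts
#' (Poisson around length x planted code reconstruction), an RRBS-style
#' methylation table with CGI structure, two CGI definitions, gene TSS
#' positions, and expression labels coupled to p65 and promoter occupancy.
#'
#' @param truth list from [syntheticTruth()].
#' @param nSites total number of regulatory sites (>= 100).
#' @param nGenes number of genes.
#' @param seed RNG seed; the bundle is a deterministic function of
#'   (truth, nSites, nGenes, seed).
#' @return list with elements tfPeaks (named list of GRanges), dhsPeaks,
#'   p65Peaks, motifPeaks, tss, cgiA, cgiB (GRanges), markCounts (matrix),
#'   lengths, methylation, expression (data.frames), truthSites (per-site
#'   planted attributes) and truth.
#' @export
simulateBundle <- function(truth = syntheticTruth(), nSites = 20000,
                           nGenes = 5000, seed = 7) {
  if (nSites < 100)
    stop("simulateBundle: nSites must be >= 100 (site classes too sparse)")
  set.seed(seed)
  n_inacc <- round(truth$fracInaccessible * nSites)
  n_acc <- nSites - n_inacc
  inaccessible <- c(rep(FALSE, n_acc), rep(TRUE, n_inacc))

  # --- site class skeleton -------------------------------------------------
  proximal <- logical(nSites)
  proximal[!inaccessible] <- runif(n_acc) < truth$fracProximal
  proximal[inaccessible] <- runif(n_inacc) < 0.10
  occ <- integer(nSites)
  acc_idx <- which(!inaccessible)
  is_prox <- proximal[acc_idx]
  occ[acc_idx[is_prox]] <- pmin(rpois(sum(is_prox), 2.5), 12L)
  nd <- sum(!is_prox)
  hot <- runif(nd) < 0.07
  occ_d <- ifelse(hot, pmin(5L + rpois(nd, 2.5), 12L),
                  pmin(rpois(nd, 1.8), 12L))
  occ[acc_idx[!is_prox]] <- occ_d

  countable <- setdiff(truth$tfPanel, c("CTCF", "RAD21"))
  tf_w <- rep(1, length(countable))
  names(tf_w) <- countable
  tf_w[c("POL2", "SP1", "MAX", "YY1")] <- 2.5
  tf_sets <- vector("list", nSites)
  for (i in acc_idx) {
    k <- occ[i]
    tf_sets[[i]] <- if (k > 0)
      sample(countable, k, prob = tf_w) else character()
  }
  has_ctcf <- !inaccessible & runif(nSites) < 0.15
  has_rad21 <- !inaccessible & runif(nSites) < 0.20

  # planted clusters live at accessible distal sites. Fully assembled sites
  # get the override confidence; "partial" sites carry a random proper
  # subset of the cluster TFs at the background p65 rate, so each TF of the
  # cluster is individually informative (successive intersections improve
  # enrichment, as at partially assembled enhancers).
  taken <- integer()
  plant <- function(cl) {
    pool <- setdiff(acc_idx[!proximal[acc_idx]], taken)
    n_full <- round(cl$fraction * nSites)
    n_part <- round((cl$partialFraction %||% 0) * nSites)
    pick <- sample(pool, min(n_full + n_part, length(pool)))
    full <- pick[seq_len(min(n_full, length(pick)))]
    part <- setdiff(pick, full)
    taken <<- c(taken, pick)
    assign_tfs <- function(i, tfs) {
      tf_sets[[i]] <<- setdiff(tfs, c("CTCF", "RAD21"))
      occ[i] <<- length(tf_sets[[i]])
      has_rad21[i] <<- "RAD21" %in% tfs
      has_ctcf[i] <<- "CTCF" %in% tfs
    }
    for (i in full) assign_tfs(i, cl$tfs)
    for (i in part) {
      sz <- sample(2:(length(cl$tfs) - 1), 1)
      assign_tfs(i, sample(cl$tfs, sz))
    }
    full
  }
  idx_cluster <- plant(truth$plantedCluster)
  idx_depleted <- plant(truth$depletedCluster)
  for (i in which(has_ctcf)) tf_sets[[i]] <- union(tf_sets[[i]], "CTCF")
  for (i in which(has_rad21)) tf_sets[[i]] <- union(tf_sets[[i]], "RAD21")

  dhs <- logical(nSites)
  dhs[acc_idx] <- ifelse(occ[acc_idx] == 0, TRUE,
                         runif(length(acc_idx)) <
                           plogis(truth$dhsBase +
                                    truth$dhsOccSlope * occ[acc_idx]))

  # --- genome placement ----------------------------------------------------
  lengths <- round(runif(nSites, 300, 1500))
  pos <- .placeSites(nSites, lengths, truth$chroms, truth$chromLength)
  ord <- order(pos$chrom, pos$start)
  # reorder everything into (chrom, start) order so site ids match the
  # sites the pipeline will rebuild from the peak files
  pos <- pos[ord, ]
  lengths <- lengths[ord]
  inaccessible <- inaccessible[ord]
  proximal <- proximal[ord]
  occ <- occ[ord]
  tf_sets <- tf_sets[ord]
  dhs <- dhs[ord]
  remap <- match(seq_len(nSites), ord)
  idx_cluster <- remap[idx_cluster]
  idx_depleted <- remap[idx_depleted]
  site_id <- sprintf("site_%06d", seq_len(nSites))

  # --- CGI and methylation -------------------------------------------------
  cgi <- runif(nSites) < ifelse(proximal, truth$cgiFracProximal,
                                truth$cgiFracDistal)
  disagree <- runif(nSites) < truth$cgiDisagreement
  hyper <- !cgi & !proximal & !inaccessible &
    runif(nSites) < truth$hyperFracDistalNonCgi
  site_pct <- numeric(nSites)
  site_pct[cgi] <- 100 * rbeta(sum(cgi), 0.6, 8)
  site_pct[hyper] <- 100 * rbeta(sum(hyper), 12, 1)
  rest <- !cgi & !hyper
  u <- runif(sum(rest))
  site_pct[rest] <- 100 * ifelse(u < 0.62, rbeta(sum(rest), 0.8, 8),
                                 ifelse(u < 0.88, rbeta(sum(rest), 5, 5),
                                        rbeta(sum(rest), 10, 1)))
  n_cpg <- 1 + rpois(nSites, ifelse(cgi, 8, 2))
  si <- rep(seq_len(nSites), n_cpg)
  n_tot <- length(si)
  p1 <- 100 * .clamp01((site_pct[si] + rnorm(n_tot, 0, 8)) / 100)
  p2 <- 100 * .clamp01((p1 + rnorm(n_tot, 0, 4)) / 100)
  at <- pos$start[si] + floor(runif(n_tot) * lengths[si])
  methylation <- data.frame(
    chrom = pos$chrom[si], position = at - 1L,  # 0-based in the table
    cov1 = rpois(n_tot, 25) + 1L, pct1 = round(p1, 1),
    cov2 = rpois(n_tot, 25) + 1L, pct2 = round(p2, 1))
  methylation <- methylation[order(methylation$chrom,
                                   methylation$position), ]
  rownames(methylation) <- NULL

  # --- marks ---------------------------------------------------------------
  H <- truth$plantedCodes
  k <- nrow(H)
  W <- matrix(rexp(nSites * k, 1 / truth$weightMean), nSites, k,
              dimnames = list(site_id, rownames(H)))
  W[matrix(runif(nSites * k) > truth$weightSparsity, nSites, k)] <- 0
  W[inaccessible, ] <- W[inaccessible, ] * 0.1
  V <- W %*% H
  lambda <- lengths * (truth$densityScale * V + 0.002)
  markCounts <- matrix(rpois(length(lambda), lambda), nSites,
                       ncol(H), dimnames = list(site_id, colnames(H)))

  # --- p65 -----------------------------------------------------------------
  motif <- runif(nSites) < truth$motifPrevalence
  Wz <- scale(W)
  Wz[is.nan(Wz)] <- 0
  eta <- truth$baseLogit + truth$occupancyEffect * occ +
    truth$motifEffect * motif +
    as.vector(Wz %*% truth$codeEffects) +
    truth$methylationEffect * hyper
  p65 <- runif(nSites) < plogis(eta)
  p65[idx_cluster] <- runif(length(idx_cluster)) <
    truth$plantedCluster$confidence
  p65[idx_depleted] <- runif(length(idx_depleted)) <
    truth$depletedCluster$confidence
  p65[inaccessible] <- TRUE

  # --- genes, TSS, expression ----------------------------------------------
  prox_sites <- which(proximal)
  n_linked <- min(nGenes, length(prox_sites))
  linked_sites <- if (n_linked > 0) sort(sample(prox_sites, n_linked)) else
    integer()
  gene_id <- sprintf("gene_%05d", seq_len(nGenes))
  tss_chrom <- character(nGenes)
  tss_pos <- integer(nGenes)
  tss_chrom[seq_len(n_linked)] <- pos$chrom[linked_sites]
  tss_pos[seq_len(n_linked)] <-
    floor((pos$start[linked_sites] + pos$end[linked_sites]) / 2)
  if (nGenes > n_linked) {
    extra <- (n_linked + 1):nGenes
    tss_chrom[extra] <- sample(truth$chroms, length(extra), replace = TRUE)
    # drop extra TSS into inter-site space: positions near the chromosome
    # end, past every placed site
    for (i in extra)
      tss_pos[i] <- round(runif(1, 0.96 * truth$chromLength,
                                truth$chromLength - 1))
  }
  ee <- truth$expressionEffect
  p_up <- rep(ee$unlinked, nGenes)
  if (n_linked > 0) {
    so <- occ[linked_sites]
    sp <- p65[linked_sites]
    pu <- ifelse(so <= 2, ee$p65_low,
                 ifelse(so >= 5, ee$p65_high,
                        ee$p65_low + (so - 2) *
                          (ee$p65_high - ee$p65_low) / 3))
    p_up[seq_len(n_linked)] <- ifelse(sp, pu, ee$no_p65)
  }
  up <- runif(nGenes) < p_up
  down <- !up & runif(nGenes) < ee$down
  label <- ifelse(up, "up", ifelse(down, "down", "none"))

  # --- assemble GRanges ----------------------------------------------------
  mkgr <- function(sel) GRanges(pos$chrom[sel],
                                IRanges(pos$start[sel], pos$end[sel]))
  tfPeaks <- list()
  membership <- lapply(tf_sets, function(x) x)
  for (tf in truth$tfPanel) {
    sel <- vapply(membership, function(x) tf %in% x, TRUE)
    if (any(sel)) tfPeaks[[tf]] <- mkgr(which(sel))
  }
  dhsPeaks <- mkgr(which(dhs))
  p65_sel <- which(p65)
  p65Peaks <- mkgr(p65_sel)
  p65Peaks$summit <- floor((pos$start[p65_sel] + pos$end[p65_sel]) / 2)
  mot_sel <- which(motif)
  mot_mid <- floor((pos$start[mot_sel] + pos$end[mot_sel]) / 2)
  motifPeaks <- GRanges(pos$chrom[mot_sel],
                        IRanges(mot_mid - 5, mot_mid + 4))
  cgiA <- mkgr(which(cgi | (disagree & !cgi)))
  cgiB <- mkgr(which(cgi & !disagree))
  tss <- GRanges(tss_chrom, IRanges(tss_pos, tss_pos), name = gene_id)

  truthSites <- data.frame(
    site_id = site_id, chrom = pos$chrom, start = pos$start - 1L,
    end = pos$end, length = lengths, inaccessible = inaccessible,
    proximal = proximal, occupancy = occ, dhs = dhs, p65 = p65,
    motif = motif, cgi = cgi, hyper = hyper,
    cluster = seq_len(nSites) %in% idx_cluster,
    depleted = seq_len(nSites) %in% idx_depleted,
    tfs = vapply(membership, function(x) paste(sort(x), collapse = ","), ""))

  list(tfPeaks = tfPeaks, dhsPeaks = dhsPeaks, p65Peaks = p65Peaks,
       motifPeaks = motifPeaks, tss = tss, cgiA = cgiA, cgiB = cgiB,
       markCounts = markCounts, lengths = lengths,
       methylation = methylation,
       expression = data.frame(gene_id = gene_id, label = label),
       truthSites = truthSites, trueWeights = W, truth = truth,
       seed = seed)
}

#' Simulate a planted-code mark matrix (no counting noise)
#'
#' Direct matrix-level draw from the code model: sparse exponential weights
#' times the planted codes plus Gaussian noise, clipped to [0,1]. Used for
#' controlled factorization-recovery experiments.
#'
#' @param nSites number of rows.
#' @param truth list from [syntheticTruth()].
#' @param noiseSd Gaussian noise SD (default 0.05).
#' @param seed RNG seed.
#' @return list with V (matrix in [0,1]), W, H.
#' @export
simulateCodeMatrix <- function(nSites, truth = syntheticTruth(),
                               noiseSd = 0.05, seed = 1) {
  set.seed(seed)
  H <- truth$plantedCodes
  k <- nrow(H)
  W <- matrix(rexp(nSites * k, 1 / truth$weightMean), nSites, k)
  W[matrix(runif(nSites * k) > truth$weightSparsity, nSites, k)] <- 0
  V <- W %*% H + matrix(rnorm(nSites * ncol(H), 0, noiseSd), nSites)
  V <- .clamp01(V)
  colnames(V) <- colnames(H)
  rownames(V) <- sprintf("site_%06d", seq_len(nSites))
  list(V = V, W = W, H = H)
}

#' Tiny deterministic fixture bundle
#'
#' A 200-site bundle with boosted rates (so every site class carries both
#' outcome labels), one planted 3-TF cluster (CREB1/JUND/MAX at confidence
#' 0.9) and the standard planted codes; small enough to audit by hand and
#' fast enough for end-to-end smoke tests.
#'
#' @return bundle list as from [simulateBundle()].
#' @export
smallFixture <- function() {
  truth <- syntheticTruth(
    baseLogit = qlogis(0.30),
    occupancyEffect = 0.15,
    plantedCluster = list(tfs = c("CREB1", "JUND", "MAX"),
                          confidence = 0.9, fraction = 0.10),
    depletedCluster = list(tfs = c("GATA3", "TCF12", "USF1"),
                           confidence = 0.0, fraction = 0.0),
    fracInaccessible = 0.10)
  simulateBundle(truth, nSites = 200, nGenes = 60, seed = 42)
}

#' Write a bundle to disk in the standard formats
#'
#' TF peaks as BED3 under \code{tfs/}, DHS and CGI definitions as BED3, p65
#' as narrowPeak (absolute summit encoded as the column-10 offset), motif
#' occurrences and TSS as BED, mark counts / methylation / expression as
#' TSV, and the planted truth as YAML.
#'
#' @param bundle list from [simulateBundle()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(file.path(dir, "tfs"), recursive = TRUE, showWarnings = FALSE)
  for (tf in names(bundle$tfPeaks))
    writeBed(bundle$tfPeaks[[tf]], file.path(dir, "tfs", paste0(tf, ".bed")))
  writeBed(bundle$dhsPeaks, file.path(dir, "dhs.bed"))
  g <- bundle$p65Peaks
  np <- data.frame(chrom = as.character(seqnames(g)),
                   start = start(g) - 1L, end = end(g), name = ".",
                   score = 0L, strand = ".", signal = 1, p = -1, q = -1,
                   peak = g$summit - (start(g) - 1L) - 1L)
  write.table(np, file.path(dir, "p65.narrowPeak"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeBed(bundle$motifPeaks, file.path(dir, "motif.bed"))
  writeBed(bundle$tss, file.path(dir, "tss.bed"))
  writeBed(bundle$cgiA, file.path(dir, "cgi_a.bed"))
  writeBed(bundle$cgiB, file.path(dir, "cgi_b.bed"))
  counts <- data.frame(site_id = rownames(bundle$markCounts),
                       length = bundle$lengths,
                       bundle$markCounts, check.names = FALSE)
  writeTable(counts, file.path(dir, "marks_counts.tsv"))
  writeTable(bundle$methylation, file.path(dir, "methylation.tsv"))
  writeTable(bundle$expression, file.path(dir, "expression.tsv"))
  writeTable(bundle$truthSites, file.path(dir, "truth_sites.tsv"))
  tr <- bundle$truth
  tr$plantedCodes <- apply(tr$plantedCodes, 1, as.list, simplify = FALSE)
  yaml::write_yaml(c(tr, list(seed = bundle$seed)),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a bundle directory written by [writeBundle()]
#' @param dir bundle directory.
#' @return list with the same elements as [simulateBundle()] (minus the
#'   in-memory-only truth matrices).
#' @export
readBundle <- function(dir) {
  tf_files <- list.files(file.path(dir, "tfs"), pattern = "\\.bed$",
                         full.names = TRUE)
  tfPeaks <- lapply(tf_files, readBed)
  names(tfPeaks) <- sub("\\.bed$", "", basename(tf_files))
  counts <- readTable(file.path(dir, "marks_counts.tsv"))
  markCounts <- as.matrix(counts[, setdiff(colnames(counts),
                                           c("site_id", "length"))])
  rownames(markCounts) <- counts$site_id
  list(tfPeaks = tfPeaks,
       dhsPeaks = readBed(file.path(dir, "dhs.bed")),
       p65Peaks = readPeaks(file.path(dir, "p65.narrowPeak"), "p65"),
       motifPeaks = readBed(file.path(dir, "motif.bed")),
       tss = readBed(file.path(dir, "tss.bed")),
       cgiA = readBed(file.path(dir, "cgi_a.bed")),
       cgiB = readBed(file.path(dir, "cgi_b.bed")),
       markCounts = markCounts,
       lengths = counts$length,
       methylation = readTable(file.path(dir, "methylation.tsv")),
       expression = readTable(file.path(dir, "expression.tsv")),
       truthSites = readTable(file.path(dir, "truth_sites.tsv")),
       truth = yaml::read_yaml(file.path(dir, "truth.yaml")))
}
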