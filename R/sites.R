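#' @importFrom GenomicRanges GRanges reduce findOverlaps start end width seqnames resize
#' @importFrom IRanges IRanges overlapsAny CharacterList
#' @importFrom S4Vectors queryHits subjectHits
NULL

.TF_EXCLUDED <- c("CTCF", "RAD21")

.siteOccupancy <- function(tf_list) {
  vapply(tf_list, function(x) length(setdiff(x, .TF_EXCLUDED)), 0L)
}

#' Build regulatory sites from TF, DHS and p65 peaks
#'
#' Merges all pre-stimulation TF peaks and DHS peaks that overlap or are
#' directly adjacent (no gap) into maximal "regulatory sites". Post-stimulation
#' p65 peaks falling entirely outside these sites are emitted as additional
#' sites labeled \code{inaccessible}; every other site is \code{accessible}.
#' Each site records the set of pre-bound TFs, DHS and p65 flags, and its
#' occupancy (number of bound TFs, never counting CTCF, RAD21 or DHS).
#'
#' @param tfPeaks named list of \link[GenomicRanges]{GRanges}, one per TF
#'   (names are the TF labels), or a single GRanges with a \code{factor}
#'   metadata column.
#' @param p65Peaks GRanges of post-stimulation p65 peaks (may be empty).
#' @param dhsPeaks GRanges of DHS peaks (may be empty).
#' @return GRanges of sites sorted by (chrom, start) with metadata columns
#'   \code{site_id}, \code{tfs} (CharacterList), \code{dhs}, \code{p65},
#'   \code{occupancy}, \code{accessibility}.
#' @export
buildSites <- function(tfPeaks, p65Peaks = GRanges(), dhsPeaks = GRanges()) {
  if (is.list(tfPeaks) || is(tfPeaks, "GRangesList")) {
    labs <- names(tfPeaks)
    if (is.null(labs) || any(!nzchar(labs)))
      stop("buildSites: tfPeaks list must be named by TF label")
    tf_all <- GRanges()
    for (i in seq_along(tfPeaks)) {
      g <- tfPeaks[[i]]
      if (!length(g)) next
      mcols(g) <- NULL
      g$factor <- labs[i]
      suppressWarnings(tf_all <- c(tf_all, g))
    }
  } else {
    tf_all <- tfPeaks
    if (length(tf_all) && is.null(tf_all$factor))
      stop("buildSites: GRanges input needs a 'factor' metadata column")
  }
  pre <- GRanges()
  if (length(tf_all)) {
    g <- tf_all; mcols(g) <- NULL
    pre <- g
  }
  if (length(dhsPeaks)) {
    g <- dhsPeaks; mcols(g) <- NULL
    suppressWarnings(pre <- c(pre, g))
  }
  accessible <- reduce(pre)  # merges overlapping and abutting peaks
  p65r <- reduce({g <- p65Peaks; mcols(g) <- NULL; g})
  inacc <- p65r[!overlapsAny(p65r, accessible)]
  suppressWarnings(sites <- c(accessible, inacc))
  acc_flag <- rep(c("accessible", "inaccessible"),
                  c(length(accessible), length(inacc)))
  ord <- order(as.character(seqnames(sites)), start(sites))
  sites <- sites[ord]
  acc_flag <- acc_flag[ord]

  tfs <- CharacterList(rep(list(character()), length(sites)))
  if (length(tf_all)) {
    ov <- findOverlaps(sites, tf_all)
    if (length(ov)) {
      got <- split(tf_all$factor[subjectHits(ov)],
                   factor(queryHits(ov), levels = seq_along(sites)))
      tfs <- CharacterList(unname(lapply(got, function(x) sort(unique(x)))))
    }
  }
  mcols(sites)$site_id <- sprintf("site_%06d", seq_along(sites))
  mcols(sites)$tfs <- tfs
  mcols(sites)$dhs <- if (length(dhsPeaks))
    overlapsAny(sites, dhsPeaks) else rep(FALSE, length(sites))
  mcols(sites)$p65 <- if (length(p65Peaks))
    overlapsAny(sites, p65Peaks) else rep(FALSE, length(sites))
  mcols(sites)$occupancy <- .siteOccupancy(as.list(tfs))
  mcols(sites)$accessibility <- acc_flag
  sites
}

#' Classify regulatory sites by TSS proximity and occupancy stage
#'
#' A site is TSS-proximal iff it overlaps a TSS (optionally flanked by
#' \code{config@tssFlank} bp). Stages follow the occupancy rule:
#' proximal sites bound by 1-2 TFs are \code{prox_s1}; distal sites bound by
#' exactly one TF are \code{dist_s1}; distal sites bound by 2-4 TFs are
#' \code{dist_s2}; everything else is \code{other}. CTCF, RAD21 and DHS never
#' count toward occupancy.
#'
#' @param sites GRanges from [buildSites()].
#' @param tss GRanges of TSS positions (1-bp intervals or wider).
#' @param motifPeaks optional GRanges of NF-kB motif occurrences; sets the
#'   per-site binary \code{motif} flag.
#' @param config a \linkS4class{RunConfig}.
#' @return The sites with metadata columns \code{tss_proximal}, \code{stage}
#'   and \code{motif} filled in.
#' @export
classifySites <- function(sites, tss, motifPeaks = NULL,
                          config = runConfig()) {
  tssq <- tss
  if (config@tssFlank > 0)
    tssq <- suppressWarnings(
      resize(tss, width(tss) + 2 * config@tssFlank, fix = "center"))
  prox <- overlapsAny(sites, tssq)
  occ <- mcols(sites)$occupancy
  stage <- rep("other", length(sites))
  stage[prox & occ >= 1 & occ <= 2] <- "prox_s1"
  stage[!prox & occ == 1] <- "dist_s1"
  stage[!prox & occ >= 2 & occ <= 4] <- "dist_s2"
  mcols(sites)$tss_proximal <- prox
  mcols(sites)$stage <- stage
  mcols(sites)$motif <- if (!is.null(motifPeaks))
    overlapsAny(sites, motifPeaks) else rep(FALSE, length(sites))
  sites
}

#' Classify sites by CpG-island and DNA-methylation context
#'
#' A site is \code{CGI} when it overlaps islands in both definitions,
#' \code{nonCGI} when in neither, and \code{unclassified} when the two
#' definitions disagree. CpGs are used only when their coverage reaches
#' \code{config@minCoverage} in both replicates; a site's methylation is the
#' mean over retained CpGs of the replicate-mean percent, binned as
#' low [0,25), medium [25,75], high (75,100]. Sites with no retained CpG get
#' \code{none}.
#'
#' @param sites classified sites GRanges.
#' @param cgiA,cgiB GRanges of the two CGI definitions.
#' @param meth data.frame from [readMethylation()].
#' @param config a \linkS4class{RunConfig}.
#' @return The sites with metadata columns \code{cgi}, \code{methylation} and
#'   \code{meth_mean} (NA when no CpG) filled in.
#' @export
classifyCgiMethylation <- function(sites, cgiA, cgiB, meth,
                                   config = runConfig()) {
  inA <- overlapsAny(sites, cgiA)
  inB <- overlapsAny(sites, cgiB)
  cgi <- ifelse(inA & inB, "CGI", ifelse(!inA & !inB, "nonCGI",
                                         "unclassified"))
  keep <- meth[meth$cov1 >= config@minCoverage &
                 meth$cov2 >= config@minCoverage, , drop = FALSE]
  meth_mean <- rep(NA_real_, length(sites))
  if (nrow(keep)) {
    cpg <- GRanges(keep$chrom, IRanges(keep$position + 1, keep$position + 1))
    pct <- (keep$pct1 + keep$pct2) / 2
    ov <- findOverlaps(cpg, sites)
    if (length(ov)) {
      sums <- tapply(pct[queryHits(ov)], subjectHits(ov), mean)
      meth_mean[as.integer(names(sums))] <- as.numeric(sums)
    }
  }
  lvl <- rep("none", length(sites))
  lvl[!is.na(meth_mean) & meth_mean < config@methLow] <- "low"
  lvl[!is.na(meth_mean) & meth_mean >= config@methLow &
        meth_mean <= config@methHigh] <- "medium"
  lvl[!is.na(meth_mean) & meth_mean > config@methHigh] <- "high"
  mcols(sites)$cgi <- cgi
  mcols(sites)$methylation <- lvl
  mcols(sites)$meth_mean <- meth_mean
  sites
}

#' p65 enrichment by localization, CGI status and methylation level
#'
#' For each stratum (TSS-proximal/distal crossed with CGI/nonCGI) and each
#' methylation level, tests whether p65 binding is enriched at sites of that
#' level versus the other methylation levels in the stratum (2x2 Fisher test,
#' base-2 log-odds). Sites with no methylation call are excluded; strata with
#' no contrast are omitted.
#'
#' @param sites sites with methylation labels filled in.
#' @param levels methylation levels to report (default low/medium/high).
#' @return data.frame with columns localization, cgi, methylation, n_level,
#'   n_other, log2_odds, p_value.
#' @export
methylationEnrichment <- function(sites,
                                  levels = c("low", "medium", "high")) {
  m <- mcols(sites)
  rows <- list()
  for (loc in c("proximal", "distal")) {
    locmask <- if (loc == "proximal") m$tss_proximal else !m$tss_proximal
    for (cg in c("CGI", "nonCGI")) {
      mask <- locmask & m$cgi == cg & m$methylation != "none"
      if (!any(mask)) next
      p65 <- m$p65[mask]
      lv <- m$methylation[mask]
      for (l in levels) {
        sel <- lv == l
        if (!any(sel) || all(sel)) next
        fe <- fetLogOdds(sum(sel & p65), sum(sel & !p65),
                         sum(!sel & p65), sum(!sel & !p65))
        rows[[length(rows) + 1]] <- data.frame(
          localization = loc, cgi = cg, methylation = l,
          n_level = sum(sel), n_other = sum(!sel),
          log2_odds = fe$log2_odds, p_value = fe$p_value)
      }
    }
  }
  if (!length(rows))
    return(data.frame(localization = character(), cgi = character(),
                      methylation = character(), n_level = integer(),
                      n_other = integer(), log2_odds = numeric(),
                      p_value = numeric()))
  do.call(rbind, rows)
}

#' Flatten classified sites into a data.frame
#'
#' TF sets become comma-separated strings so the table can round-trip
#' through [writeTable()]/[readTable()].
#'
#' @param sites classified sites GRanges.
#' @return data.frame, one row per site.
#' @export
sitesAsDataFrame <- function(sites) {
  m <- mcols(sites)
  df <- data.frame(
    site_id = m$site_id,
    chrom = as.character(seqnames(sites)),
    start = start(sites) - 1L,   # BED convention in flat tables
    end = end(sites),
    tfs = vapply(as.list(m$tfs), paste, "", collapse = ","),
    dhs = m$dhs, p65 = m$p65, occupancy = m$occupancy,
    accessibility = m$accessibility,
    stringsAsFactors = FALSE)
  for (col in c("tss_proximal", "stage", "motif", "cgi", "methylation",
                "meth_mean"))
    if (!is.null(m[[col]])) df[[col]] <- m[[col]]
  df
}

#' Rebuild a sites GRanges from its flat table
#' @param df data.frame from [sitesAsDataFrame()].
#' @return GRanges with the same metadata columns.
#' @export
sitesFromDataFrame <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr)$site_id <- df$site_id
  mcols(gr)$tfs <- CharacterList(lapply(strsplit(df$tfs, ","), function(x)
    x[nzchar(x)]))
  for (col in c("dhs", "p65", "occupancy", "accessibility", "tss_proximal",
                "stage", "motif", "cgi", "methylation", "meth_mean"))
    if (!is.null(df[[col]])) mcols(gr)[[col]] <- df[[col]]
  gr
}

#' Build the binary TF occupancy table from classified sites
#'
#' @param sites classified sites GRanges.
#' @param tfLabels TF panel (default: all TFs observed in the sites).
#' @return An \linkS4class{OccupancyTable}.
#' @export
occupancyTable <- function(sites, tfLabels = NULL) {
  m <- mcols(sites)
  tf_list <- as.list(m$tfs)
  if (is.null(tfLabels)) tfLabels <- sort(unique(unlist(tf_list)))
  X <- matrix(FALSE, length(sites), length(tfLabels),
              dimnames = list(m$site_id, tfLabels))
  idx <- cbind(rep(seq_along(tf_list), lengths(tf_list)),
               match(unlist(tf_list), tfLabels))
  idx <- idx[!is.na(idx[, 2]), , drop = FALSE]
  X[idx] <- TRUE
  new("OccupancyTable", matrix = X, p65 = m$p65,
      occupancy = as.integer(m$occupancy),
      stage = as.character(m$stage), siteIDs = m$site_id)
}
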