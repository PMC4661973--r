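#' @importFrom GenomicRanges distance
NULL

.jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(0)
  length(intersect(a, b)) / length(u)
}

#' Link genes to TSS-proximal and TSS-distal regulatory sites
#'
#' Each gene gets at most one proximal site (the site overlapping its TSS;
#' nearest midpoint wins when several overlap) and at most
#' \code{config@maxDistalLinks} distal sites within
#' \code{config@linkDistance} bp of the TSS. Distal candidates are scored
#' \code{jaccard(TF sets of distal and proximal site) * exp(-distance /
#' config@linkKernelScale)}; genes with no proximal site use a uniform TF
#' similarity of 0.5. The top-scoring candidates are kept.
#'
#' @param genes GRanges of TSS positions with a \code{name} metadata column
#'   holding gene ids.
#' @param sites classified sites GRanges (from [classifySites()]).
#' @return data.frame with one row per link: gene_id, site_id, type
#'   (proximal/distal), distance, similarity, link_score, p65, occupancy.
#' @param config a \linkS4class{RunConfig}.
#' @export
linkSites <- function(genes, sites, config = runConfig()) {
  m <- mcols(sites)
  tf_list <- as.list(m$tfs)
  names(tf_list) <- m$site_id
  site_mid <- floor((start(sites) + end(sites)) / 2)

  ov <- findOverlaps(genes, sites)
  prox_for_gene <- rep(NA_integer_, length(genes))
  if (length(ov)) {
    qh <- queryHits(ov); sh <- subjectHits(ov)
    dmid <- abs(site_mid[sh] - start(genes)[qh])
    o <- order(qh, dmid)
    first <- !duplicated(qh[o])
    prox_for_gene[qh[o][first]] <- sh[o][first]
  }

  near <- findOverlaps(genes, sites, maxgap = config@linkDistance)
  rows <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    gene_id <- genes$name[g]
    pi <- prox_for_gene[g]
    prox_tfs <- if (!is.na(pi)) tf_list[[pi]] else NULL
    out <- NULL
    if (!is.na(pi)) {
      out <- data.frame(gene_id = gene_id, site_id = m$site_id[pi],
                        type = "proximal", distance = 0,
                        similarity = 1, link_score = 1,
                        p65 = m$p65[pi], occupancy = m$occupancy[pi])
    }
    cand <- subjectHits(near)[queryHits(near) == g]
    cand <- setdiff(cand, pi)
    cand <- cand[!m$tss_proximal[cand]]
    if (length(cand)) {
      d <- distance(genes[g], sites[cand])
      keep <- !is.na(d) & d <= config@linkDistance
      cand <- cand[keep]; d <- d[keep]
    }
    if (length(cand)) {
      sim <- if (!is.null(prox_tfs))
        vapply(cand, function(i) .jaccard(tf_list[[i]], prox_tfs), 0)
      else rep(0.5, length(cand))
      score <- sim * exp(-d / config@linkKernelScale)
      o <- order(-score, d)
      take <- o[seq_len(min(config@maxDistalLinks, length(o)))]
      out <- rbind(out, data.frame(
        gene_id = gene_id, site_id = m$site_id[cand[take]],
        type = "distal", distance = d[take], similarity = sim[take],
        link_score = score[take], p65 = m$p65[cand[take]],
        occupancy = m$occupancy[cand[take]]))
    }
    rows[[g]] <- out
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(), site_id = character(),
                      type = character(), distance = numeric(),
                      similarity = numeric(), link_score = numeric(),
                      p65 = logical(), occupancy = integer())
  rownames(out) <- NULL
  out
}

#' Up-regulation fraction of linked sites by occupancy
#'
#' For p65-bound sites and for all sites, split by proximal/distal link
#' type and occupancy, computes the fraction of linked sites whose gene is
#' up-regulated, with Wilson 95\% CIs, plus the low- versus high-occupancy
#' two-proportion contrast (low: occupancy <= \code{config@lowOcc}; high:
#' >= \code{config@highOcc}).
#'
#' @param links data.frame from [linkSites()].
#' @param expression data.frame with columns gene_id and label (one of
#'   "up", "down", "none").
#' @param config a \linkS4class{RunConfig}.
#' @return list with \code{byOccupancy} (group, type, occupancy, n,
#'   frac_up, ci_low, ci_high) and \code{contrasts} (group, type, low/high
#'   counts and fractions, p_value).
#' @export
upregulationByOccupancy <- function(links, expression,
                                    config = runConfig()) {
  up <- links$gene_id %in% expression$gene_id[expression$label == "up"]
  rows <- list()
  contrasts <- list()
  for (grp in c("p65", "all")) {
    gmask <- if (grp == "p65") links$p65 else rep(TRUE, nrow(links))
    for (ty in c("proximal", "distal")) {
      sel <- gmask & links$type == ty
      if (!any(sel)) next
      occ <- links$occupancy[sel]
      u <- up[sel]
      for (o in sort(unique(occ))) {
        s <- occ == o
        ci <- proportionCI(sum(u[s]), sum(s))
        rows[[length(rows) + 1]] <- data.frame(
          group = grp, type = ty, occupancy = o, n = ci$n,
          frac_up = ci$estimate, ci_low = ci$ci_low, ci_high = ci$ci_high)
      }
      lo <- occ <= config@lowOcc
      hi <- occ >= config@highOcc
      if (any(lo) && any(hi)) {
        cmp <- compareProportions(sum(u[lo]), sum(lo), sum(u[hi]), sum(hi))
        contrasts[[length(contrasts) + 1]] <- data.frame(
          group = grp, type = ty,
          n_low = sum(lo), frac_low = cmp$estimate1,
          n_high = sum(hi), frac_high = cmp$estimate2,
          p_value = cmp$p_value)
      }
    }
  }
  list(byOccupancy = if (length(rows)) do.call(rbind, rows) else
         data.frame(group = character(), type = character(),
                    occupancy = integer(), n = integer(),
                    frac_up = numeric(), ci_low = numeric(),
                    ci_high = numeric()),
       contrasts = if (length(contrasts)) do.call(rbind, contrasts) else
         data.frame(group = character(), type = character(),
                    n_low = integer(), frac_low = numeric(),
                    n_high = integer(), frac_high = numeric(),
                    p_value = numeric()))
}
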