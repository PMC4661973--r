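# Occupancy analysis, per-TF enrichment, pairwise cooperativity, and the two
# combinatorial TF-cluster searches (greedy TGC and top-k non-redundant
# association rules).

# base-2 log odds ratio with Haldane-Anscombe correction on zero cells;
# fast path used inside the greedy search (no exact p-value).
.lor2 <- function(a, b, c, d) {
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  log2((a * d) / (b * c))
}

.classLOR <- function(ind, y) {
  a <- sum(ind & y); b <- sum(ind & !y)
  c <- sum(!ind & y); d <- sum(!ind & !y)
  .lor2(a, b, c, d)
}

#' p65 recruitment probability as a function of occupancy
#'
#' @param t an \linkS4class{OccupancyTable}.
#' @return data.frame with one row per observed occupancy: n_sites,
#'   p65_fraction and its Wilson 95\% CI.
#' @export
occupancyCurve <- function(t) {
  occ <- t@occupancy
  lev <- sort(unique(occ))
  rows <- lapply(lev, function(o) {
    sel <- occ == o
    ci <- proportionCI(sum(t@p65[sel]), sum(sel))
    data.frame(occupancy = o, n_sites = ci$n, p65_fraction = ci$estimate,
               ci_low = ci$ci_low, ci_high = ci$ci_high)
  })
  do.call(rbind, rows)
}

#' Per-TF p65 enrichment within a site class
#'
#' 2x2 Fisher test of p65 binding for sites bound versus not bound by each
#' TF, with all sites of the class as background. TFs absent from the class
#' are omitted; TFs present at every class site carry no contrast and are
#' flagged.
#'
#' @param t an \linkS4class{OccupancyTable}.
#' @param siteClass stage label selecting the class (e.g. "dist_s1");
#'   "all" uses every site.
#' @return data.frame with columns tf, n_with, n_without, log2_odds,
#'   p_value, degenerate.
#' @export
tfEnrichment <- function(t, siteClass = "all") {
  mask <- if (siteClass == "all") rep(TRUE, length(t@p65)) else
    t@stage == siteClass
  if (sum(mask) < 2) stop("tfEnrichment: class has fewer than 2 sites")
  X <- t@matrix[mask, , drop = FALSE]
  y <- t@p65[mask]
  rows <- list()
  for (tf in colnames(X)) {
    v <- X[, tf]
    if (!any(v)) next
    degenerate <- all(v)
    if (degenerate) {
      rows[[length(rows) + 1]] <- data.frame(
        tf = tf, n_with = sum(v), n_without = 0L,
        log2_odds = NA_real_, p_value = NA_real_, degenerate = TRUE)
      next
    }
    fe <- fetLogOdds(sum(v & y), sum(v & !y), sum(!v & y), sum(!v & !y))
    rows[[length(rows) + 1]] <- data.frame(
      tf = tf, n_with = sum(v), n_without = sum(!v),
      log2_odds = fe$log2_odds, p_value = fe$p_value, degenerate = FALSE)
  }
  do.call(rbind, rows)
}

#' Pairwise TF cooperativity matrix
#'
#' For each TF pair, compares p65 frequency at sites co-occupied by both TFs
#' (foreground) against sites occupied by exactly one of the two (baseline)
#' within the class. Direction is positive iff the joint p65 probability
#' exceeds both single-TF probabilities. Entries with Fisher p >= 0.05, or
#' with foreground support below \code{config@coopMinSupport}, are masked in
#' the display matrix; entries with p >= 1e-5 are display-capped at +2 / -1.
#' Stored statistics are never capped. A secondary statistic compares each
#' pair's joint odds to the mean joint odds over all pairs ("two random
#' proteins" baseline).
#'
#' @param t an \linkS4class{OccupancyTable}.
#' @param siteClass stage label (default "dist_s2").
#' @param config a \linkS4class{RunConfig}.
#' @return list of symmetric TF x TF matrices: log2_odds, p_value,
#'   direction (+1/-1), display (masked and capped), pair_vs_random.
#' @export
cooperativityMatrix <- function(t, siteClass = "dist_s2",
                                config = runConfig()) {
  mask <- if (siteClass == "all") rep(TRUE, length(t@p65)) else
    t@stage == siteClass
  X <- t@matrix[mask, , drop = FALSE]
  y <- t@p65[mask]
  tfs <- colnames(X)
  p <- length(tfs)
  lor <- pv <- dir <- disp <- pvr <- matrix(
    NA_real_, p, p, dimnames = list(tfs, tfs))
  odds <- function(k, n) (k + 0.5) / (n - k + 0.5)
  joint_odds <- c()
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    both <- X[, i] & X[, j]
    joint_odds <- c(joint_odds, odds(sum(both & y), sum(both)))
  }
  mean_odds <- mean(joint_odds, na.rm = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    both <- X[, i] & X[, j]
    onlyA <- X[, i] & !X[, j]
    onlyB <- !X[, i] & X[, j]
    base <- onlyA | onlyB
    if (sum(both) < config@coopMinSupport || !any(base)) next
    fe <- fetLogOdds(sum(both & y), sum(both & !y),
                     sum(base & y), sum(base & !y))
    pj <- mean(y[both])
    pa <- if (any(onlyA)) mean(y[onlyA]) else 0
    pb <- if (any(onlyB)) mean(y[onlyB]) else 0
    d <- if (pj > max(pa, pb)) 1 else -1
    dv <- if (fe$p_value >= 0.05) NA_real_
      else if (fe$p_value >= 1e-5) {
        if (fe$log2_odds > 0) min(fe$log2_odds, 2) else max(fe$log2_odds, -1)
      } else fe$log2_odds
    vr <- log2(odds(sum(both & y), sum(both)) / mean_odds)
    lor[i, j] <- lor[j, i] <- fe$log2_odds
    pv[i, j] <- pv[j, i] <- fe$p_value
    dir[i, j] <- dir[j, i] <- d
    disp[i, j] <- disp[j, i] <- dv
    pvr[i, j] <- pvr[j, i] <- vr
  }
  list(log2_odds = lor, p_value = pv, direction = dir, display = disp,
       pair_vs_random = pvr)
}

# genome-wide support and confidence of a TF set
.clusterSupport <- function(X, y, tfs) {
  ind <- rep(TRUE, nrow(X))
  for (tf in tfs) ind <- ind & X[, tf]
  list(ind = ind, support = sum(ind),
       confidence = if (any(ind)) mean(y[ind]) else NA_real_)
}

#' Greedy TF-cluster search (TGC)
#'
#' Starting from every single TF, greedily adds the TF that most improves
#' the cluster's base-2 log-odds of p65 enrichment within the site class,
#' accepting an addition only when the gain is at least \code{delta} AND the
#' expanded cluster still has at least \code{minSupport} co-occupied sites
#' genome-wide. A second pass searches for depleted clusters (each step must
#' decrease the log-odds by at least \code{delta}). Identical final TF sets
#' are deduplicated; only clusters that expanded beyond their seed are
#' reported. Support and confidence are genome-wide over all sites;
#' enrichment and its exact p-value are computed within the class. Ties in
#' the greedy step are broken lexicographically by TF label.
#'
#' @param t an \linkS4class{OccupancyTable} over all regulatory sites.
#' @param siteClass stage label for the enrichment (default "dist_s2").
#' @param delta minimum per-step log2-odds gain (default from config, 0.2).
#' @param minSupport minimum genome-wide support (default from config, 40).
#' @param config a \linkS4class{RunConfig}.
#' @return data.frame with columns cluster, direction, n_tfs, log2_odds,
#'   p_value, support, confidence, expansion_chain (steps as
#'   "tf:log2odds" separated by ";").
#' @export
tgcSearch <- function(t, siteClass = "dist_s2", delta = NULL,
                      minSupport = NULL, config = runConfig()) {
  if (is.null(delta)) delta <- config@tgcDelta
  if (is.null(minSupport)) minSupport <- config@tgcMinSupport
  mask <- if (siteClass == "all") rep(TRUE, length(t@p65)) else
    t@stage == siteClass
  if (!any(mask))
    return(data.frame(cluster = character(), direction = character(),
                      n_tfs = integer(), log2_odds = numeric(),
                      p_value = numeric(), support = integer(),
                      confidence = numeric(),
                      expansion_chain = character()))
  X <- t@matrix
  Xc <- X[mask, , drop = FALSE]
  yc <- t@p65[mask]
  y <- t@p65
  tfs <- sort(colnames(X))
  found <- list()
  for (direction in c("enriched", "depleted")) {
    sgn <- if (direction == "enriched") 1 else -1
    for (seed_tf in tfs) {
      cur <- seed_tf
      cur_c <- Xc[, seed_tf]
      cur_g <- X[, seed_tf]
      if (sum(cur_g) < minSupport || !any(cur_c)) next
      cur_lor <- .classLOR(cur_c, yc)
      chain <- sprintf("%s:%.4f", seed_tf, cur_lor)
      repeat {
        best_gain <- -Inf; best_tf <- NULL
        for (cand in setdiff(tfs, cur)) {
          new_g <- cur_g & X[, cand]
          if (sum(new_g) < minSupport) next
          new_c <- cur_c & Xc[, cand]
          gain <- sgn * (.classLOR(new_c, yc) - cur_lor)
          if (gain > best_gain + 1e-12) {   # ties keep first (lexicographic)
            best_gain <- gain; best_tf <- cand
          }
        }
        if (is.null(best_tf) || best_gain < delta) break
        cur <- c(cur, best_tf)
        cur_g <- cur_g & X[, best_tf]
        cur_c <- cur_c & Xc[, best_tf]
        cur_lor <- cur_lor + sgn * best_gain
        chain <- c(chain, sprintf("%s:%.4f", best_tf, cur_lor))
      }
      if (length(cur) < 2) next
      key <- paste(sort(cur), collapse = "+")
      if (!is.null(found[[key]])) next
      cs <- .clusterSupport(X, y, cur)
      ind_c <- cur_c
      fe <- fetLogOdds(sum(ind_c & yc), sum(ind_c & !yc),
                       sum(!ind_c & yc), sum(!ind_c & !yc))
      found[[key]] <- data.frame(
        cluster = key, direction = direction, n_tfs = length(cur),
        log2_odds = fe$log2_odds, p_value = fe$p_value,
        support = cs$support, confidence = cs$confidence,
        expansion_chain = paste(chain, collapse = ";"))
    }
  }
  if (!length(found))
    return(data.frame(cluster = character(), direction = character(),
                      n_tfs = integer(), log2_odds = numeric(),
                      p_value = numeric(), support = integer(),
                      confidence = numeric(),
                      expansion_chain = character()))
  out <- do.call(rbind, unname(found))
  out[order(-abs(out$log2_odds)), , drop = FALSE]
}

#' Top-k non-redundant association rules (TNR)
#'
#' Enumerates TF itemsets up to \code{maxSize} with genome-wide support at
#' least \code{minSupport} (level-wise, Apriori-pruned), forms rules
#' (itemset -> p65), ranks them by confidence then support, and drops a rule
#' as redundant when any proper subset of its antecedent reaches at least
#' the same confidence. The top k survivors are returned.
#'
#' @param t an \linkS4class{OccupancyTable} over all regulatory sites.
#' @param minSupport minimum genome-wide support (default from config, 40).
#' @param k number of rules to return (default from config, 50).
#' @param maxSize maximum antecedent size (default from config, 4).
#' @param config a \linkS4class{RunConfig}.
#' @return data.frame with columns cluster, n_tfs, support, confidence,
#'   log2_odds, p_value.
#' @export
tnrSearch <- function(t, minSupport = NULL, k = NULL, maxSize = NULL,
                      config = runConfig()) {
  if (is.null(minSupport)) minSupport <- config@tgcMinSupport
  if (is.null(k)) k <- config@tnrK
  if (is.null(maxSize)) maxSize <- config@tnrMaxSize
  X <- t@matrix
  y <- t@p65
  tfs <- colnames(X)
  conf_of <- new.env(parent = emptyenv())
  items <- list()   # each: list(tfs=integer indices, ind=logical, support, conf)
  level <- list()
  for (i in seq_along(tfs)) {
    ind <- X[, i]
    s <- sum(ind)
    if (s < minSupport) next
    it <- list(tfs = i, ind = ind, support = s, conf = mean(y[ind]))
    assign(paste(i, collapse = "+"), it$conf, envir = conf_of)
    level[[length(level) + 1]] <- it
    items[[length(items) + 1]] <- it
  }
  size <- 1L
  while (size < maxSize && length(level)) {
    nxt <- list()
    for (it in level) {
      last <- it$tfs[length(it$tfs)]
      for (j in seq_along(tfs)) {
        if (j <= last) next
        ind <- it$ind & X[, j]
        s <- sum(ind)
        if (s < minSupport) next
        new_it <- list(tfs = c(it$tfs, j), ind = ind, support = s,
                       conf = mean(y[ind]))
        assign(paste(new_it$tfs, collapse = "+"), new_it$conf,
               envir = conf_of)
        nxt[[length(nxt) + 1]] <- new_it
        items[[length(items) + 1]] <- new_it
      }
    }
    level <- nxt
    size <- size + 1L
  }
  if (!length(items))
    return(data.frame(cluster = character(), n_tfs = integer(),
                      support = integer(), confidence = numeric(),
                      log2_odds = numeric(), p_value = numeric()))
  conf <- vapply(items, `[[`, 0, "conf")
  supp <- vapply(items, `[[`, 0, "support")
  ord <- order(-conf, -supp)
  out_rows <- list()
  subsets_of <- function(v) {
    subs <- list()
    for (m in seq_len(length(v) - 1))
      subs <- c(subs, utils::combn(v, m, simplify = FALSE))
    subs
  }
  for (idx in ord) {
    if (length(out_rows) >= k) break
    it <- items[[idx]]
    redundant <- FALSE
    if (length(it$tfs) > 1) {
      for (sub in subsets_of(it$tfs)) {
        sc <- get0(paste(sub, collapse = "+"), envir = conf_of,
                   ifnotfound = NA_real_)
        if (!is.na(sc) && sc >= it$conf) { redundant <- TRUE; break }
      }
    }
    if (redundant) next
    fe <- fetLogOdds(sum(it$ind & y), sum(it$ind & !y),
                     sum(!it$ind & y), sum(!it$ind & !y))
    out_rows[[length(out_rows) + 1]] <- data.frame(
      cluster = paste(sort(tfs[it$tfs]), collapse = "+"),
      n_tfs = length(it$tfs), support = it$support, confidence = it$conf,
      log2_odds = fe$log2_odds, p_value = fe$p_value)
  }
  if (!length(out_rows))
    return(data.frame(cluster = character(), n_tfs = integer(),
                      support = integer(), confidence = numeric(),
                      log2_odds = numeric(), p_value = numeric()))
  do.call(rbind, out_rows)
}

#' Exhaustive best cluster (certification oracle for small TF panels)
#'
#' Enumerates every TF subset up to \code{maxSize} with the given genome-wide
#' support and returns the one maximizing the class log2-odds. Exponential;
#' intended for <= 12 TFs.
#'
#' @param t an \linkS4class{OccupancyTable}.
#' @param siteClass stage label.
#' @param minSupport minimum genome-wide support.
#' @param maxSize maximum subset size.
#' @return list with tfs and log2_odds of the certified optimum.
#' @export
bestClusterExhaustive <- function(t, siteClass = "dist_s2",
                                  minSupport = 40, maxSize = 4) {
  if (ncol(t@matrix) > 14)
    stop("bestClusterExhaustive: too many TFs for exhaustive enumeration")
  mask <- if (siteClass == "all") rep(TRUE, length(t@p65)) else
    t@stage == siteClass
  X <- t@matrix; Xc <- X[mask, , drop = FALSE]; yc <- t@p65[mask]
  tfs <- colnames(X)
  best <- list(tfs = character(), log2_odds = -Inf)
  for (m in seq_len(min(maxSize, length(tfs)))) {
    for (comb in utils::combn(seq_along(tfs), m, simplify = FALSE)) {
      ind_g <- rep(TRUE, nrow(X))
      for (i in comb) ind_g <- ind_g & X[, i]
      if (sum(ind_g) < minSupport) next
      ind_c <- rep(TRUE, nrow(Xc))
      for (i in comb) ind_c <- ind_c & Xc[, i]
      lor <- .classLOR(ind_c, yc)
      if (lor > best$log2_odds) best <- list(tfs = tfs[comb], log2_odds = lor)
    }
  }
  best
}
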