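#' @importFrom GenomicRanges coverage
NULL

#' Scale raw mark counts to [0,1]
#'
#' Per-site read counts are converted to densities d = count / length and
#' scaled per mark with the saturating sigmoid s(d) = tanh(c * d / q), where
#' q is the \code{sigmoidQuantile} (default 95th) percentile of that mark's
#' nonzero densities and c = \code{sigmoidC} (default 0.5). The map is
#' within 4\% of linear on [0, q] and bounded by 1; s(0) = 0 and s is
#' monotone. Scaling one mark's counts by a constant leaves the result
#' unchanged (q rescales with the data).
#'
#' @param rawCounts non-negative sites x marks count matrix with rownames
#'   (site ids) and colnames (marks).
#' @param lengths site lengths in bp (> 0), recycled along rows.
#' @param config a \linkS4class{RunConfig}.
#' @return A \linkS4class{MarkMatrix}. An all-zero mark column stays zero,
#'   with a warning.
#' @export
scaleCounts <- function(rawCounts, lengths, config = runConfig()) {
  rawCounts <- as.matrix(rawCounts)
  if (any(rawCounts < 0)) stop("scaleCounts: counts must be non-negative")
  if (any(lengths <= 0)) stop("scaleCounts: lengths must be positive")
  if (length(lengths) != nrow(rawCounts))
    stop("scaleCounts: one length per site required")
  if (is.null(rownames(rawCounts)))
    rownames(rawCounts) <- sprintf("site_%06d", seq_len(nrow(rawCounts)))
  if (is.null(colnames(rawCounts)))
    colnames(rawCounts) <- sprintf("mark_%02d", seq_len(ncol(rawCounts)))
  dens <- rawCounts / lengths
  scaled <- dens
  for (j in seq_len(ncol(dens))) {
    nz <- dens[, j][dens[, j] > 0]
    if (!length(nz)) {
      warning("scaleCounts: mark '", colnames(dens)[j],
              "' has no signal; column left at zero")
      scaled[, j] <- 0
      next
    }
    q <- quantile(nz, config@sigmoidQuantile, names = FALSE)
    scaled[, j] <- tanh(config@sigmoidC * dens[, j] / q)
  }
  MarkMatrix(scaled)
}

#' Positional enrichment profile around anchors
#'
#' Averages a genomic signal in fixed-width bins around a set of anchor
#' positions (typically peak summits). Bin b covers offsets
#' [-flank + b*bin, -flank + (b+1)*bin). Anchors truncated at chromosome
#' bounds contribute only the bins they cover.
#'
#' @param signal GRanges with a numeric \code{score} metadata column
#'   (piecewise-constant coverage); uncovered positions count as 0.
#' @param anchors GRanges of anchor positions (midpoints are used for wider
#'   ranges).
#' @param flank half-window in bp (default 2000).
#' @param bin bin width in bp (default 20); must divide flank.
#' @return data.frame with columns offset (bin start relative to anchor) and
#'   mean_signal.
#' @export
enrichmentProfile <- function(signal, anchors, flank = 2000, bin = 20) {
  if (!length(anchors)) stop("enrichmentProfile: anchors must be non-empty")
  if (flank %% bin != 0)
    stop("enrichmentProfile: flank must be divisible by bin")
  score <- signal$score
  if (is.null(score)) stop("enrichmentProfile: signal needs a 'score' column")
  cov <- coverage(signal, weight = score)
  nb <- 2 * flank / bin
  sums <- numeric(nb)
  cnts <- numeric(nb)
  mid <- floor((start(anchors) + end(anchors)) / 2)
  chr <- as.character(seqnames(anchors))
  for (i in seq_along(anchors)) {
    if (!chr[i] %in% names(cov)) next
    rle <- cov[[chr[i]]]
    lo <- mid[i] - flank
    hi <- mid[i] + flank - 1
    wlo <- max(1L, lo)                        # truncate at chromosome start
    if (hi < wlo) next
    # positions past the end of the coverage vector are uncovered (zero)
    vals <- numeric(hi - wlo + 1)
    whi <- min(length(rle), hi)
    if (whi >= wlo) vals[seq_len(whi - wlo + 1)] <- as.numeric(rle[wlo:whi])
    offs <- (wlo:hi) - mid[i]                 # in [-flank, flank-1]
    b <- (offs + flank) %/% bin + 1L
    sums <- sums + as.numeric(tapply(vals, factor(b, levels = seq_len(nb)),
                                     sum, default = 0))
    cnts <- cnts + as.numeric(tapply(rep(1, length(b)),
                                     factor(b, levels = seq_len(nb)),
                                     sum, default = 0))
  }
  mean_signal <- ifelse(cnts > 0, sums / cnts, NA_real_)
  data.frame(offset = seq(-flank, flank - bin, by = bin),
             mean_signal = mean_signal)
}

#' Geometric-mean interaction of two marks
#'
#' Joint magnitude of a mark pair at each site: GM = sqrt(v_i * v_j). The
#' result stays in [0,1] and is zero wherever either mark is zero.
#'
#' @param m a \linkS4class{MarkMatrix}.
#' @param i,j mark names.
#' @return list with \code{pair} and per-site \code{values}.
#' @export
gmInteraction <- function(m, i, j) {
  v <- markValues(m)
  if (!all(c(i, j) %in% colnames(v)))
    stop("gmInteraction: mark not present in matrix")
  list(pair = c(i, j), values = sqrt(v[, i] * v[, j]))
}
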