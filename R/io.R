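#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom utils read.table write.table
NULL

# Split whitespace-delimited lines into a character matrix with a fixed
# minimum column count, reporting 1-based line numbers on failure.
.parseDelim <- function(path, min_cols, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    bad <- which(nf < min_cols)[1]
    stop(sprintf("%s: line %d of %s has %d field(s), need at least %d",
                 what, bad, path, nf[bad], min_cols))
  }
  fields
}

.numOrStop <- function(x, path, what, col) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop(sprintf("%s: line %d of %s: column %d is not numeric ('%s')",
                 what, bad, path, col, x[bad]))
  }
  v
}

#' Read a BED3+/narrowPeak file of peaks
#'
#' Accepts plain BED (3+ columns) or ENCODE narrowPeak (10 columns). BED
#' coordinates are 0-based half-open and converted to the 1-based GRanges
#' convention. For narrowPeak input the column-10 summit offset is converted
#' to an absolute 1-based position (-1 offsets yield NA).
#'
#' @param path path to the peak file.
#' @param factor track label attached to every record (TF name, "DHS",
#'   "p65", "MOT").
#' @return A \link[GenomicRanges]{GRanges} sorted by (chrom, start) with
#'   metadata columns \code{factor}, \code{summit} (1-based absolute position
#'   or NA) and \code{score} (NA when absent).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr2\t0\t10", f)
#' readPeaks(f, "JUND")
#' @export
readPeaks <- function(path, factor) {
  if (!nzchar(factor)) stop("factor label must be non-empty")
  fields <- .parseDelim(path, 3L, "readPeaks")
  if (is.null(fields))
    return(GRanges(factor = character(), summit = numeric(),
                   score = numeric()))
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- .numOrStop(vapply(fields, `[`, "", 2L), path, "readPeaks", 2L)
  end0 <- .numOrStop(vapply(fields, `[`, "", 3L), path, "readPeaks", 3L)
  if (any(start0 < 0)) {
    bad <- which(start0 < 0)[1]
    stop(sprintf("readPeaks: line %d of %s: negative start", bad, path))
  }
  if (any(end0 <= start0)) {
    bad <- which(end0 <= start0)[1]
    stop(sprintf("readPeaks: line %d of %s: end (%d) <= start (%d)",
                 bad, path, end0[bad], start0[bad]))
  }
  nf <- lengths(fields)
  score <- rep(NA_real_, length(chrom))
  has5 <- nf >= 5L
  if (any(has5)) {
    s <- vapply(fields[has5], `[`, "", 5L)
    score[has5] <- suppressWarnings(as.numeric(s))
  }
  summit <- rep(NA_real_, length(chrom))
  is_np <- nf >= 10L
  if (any(is_np)) {
    off <- .numOrStop(vapply(fields[is_np], `[`, "", 10L),
                      path, "readPeaks", 10L)
    abs0 <- ifelse(off < 0, NA_real_, start0[is_np] + off)
    bad <- !is.na(abs0) & (abs0 < start0[is_np] | abs0 >= end0[is_np])
    if (any(bad)) {
      i <- which(is_np)[which(bad)[1]]
      stop(sprintf("readPeaks: line %d of %s: summit outside peak", i, path))
    }
    summit[is_np] <- abs0 + 1  # to 1-based
  }
  gr <- GRanges(factor(chrom, levels = sort(unique(chrom))),
                IRanges(start0 + 1, end0),
                factor = factor, summit = summit, score = score)
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr))]
}

#' Read a BED file of plain intervals
#'
#' Convenience reader for interval-only inputs (CGI definitions, TSS lists).
#' The BED name column, when present, is kept as metadata column \code{name}.
#'
#' @param path path to a BED3+ file.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
readBed <- function(path) {
  fields <- .parseDelim(path, 3L, "readBed")
  if (is.null(fields)) return(GRanges(name = character()))
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- .numOrStop(vapply(fields, `[`, "", 2L), path, "readBed", 2L)
  end0 <- .numOrStop(vapply(fields, `[`, "", 3L), path, "readBed", 3L)
  if (any(end0 <= start0)) {
    bad <- which(end0 <= start0)[1]
    stop(sprintf("readBed: line %d of %s: end <= start", bad, path))
  }
  name <- rep(NA_character_, length(chrom))
  has4 <- lengths(fields) >= 4L
  name[has4] <- vapply(fields[has4], `[`, "", 4L)
  GRanges(factor(chrom, levels = sort(unique(chrom))),
          IRanges(start0 + 1, end0), name = name)
}

#' Read an RRBS methylation table
#'
#' Fixed six-column TSV dialect: chrom, 0-based CpG position, coverage and
#' percent methylation for replicate 1, then coverage and percent for
#' replicate 2. Two replicates are required. Percents outside [0,100] or
#' negative coverages are rejected.
#'
#' @param path path to the TSV (a header line starting with "chrom" is
#'   allowed and skipped).
#' @return data.frame with columns chrom, position (0-based), cov1, pct1,
#'   cov2, pct2. Empty file gives a zero-row frame.
#' @export
readMethylation <- function(path) {
  empty <- data.frame(chrom = character(), position = numeric(),
                      cov1 = numeric(), pct1 = numeric(),
                      cov2 = numeric(), pct2 = numeric())
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^chrom\\b", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- which(nf < 6L)[1]
    stop(sprintf(paste0("readMethylation: line %d of %s has %d column(s); ",
                        "6 required (both replicates must be present)"),
                 bad, path, nf[bad]))
  }
  num <- function(i) .numOrStop(vapply(fields, `[`, "", i),
                                path, "readMethylation", i)
  out <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    position = num(2L), cov1 = num(3L), pct1 = num(4L),
                    cov2 = num(5L), pct2 = num(6L))
  if (any(out$cov1 < 0 | out$cov2 < 0))
    stop("readMethylation: negative coverage in ", path)
  bad <- out$pct1 < 0 | out$pct1 > 100 | out$pct2 < 0 | out$pct2 > 100
  if (any(bad))
    stop(sprintf("readMethylation: line %d of %s: percent outside [0,100]",
                 which(bad)[1], path))
  out
}

#' Write an internal result table as TSV
#'
#' Header + tab-separated values, deterministic column order (as given),
#' doubles rounded to 6 significant digits. Writing then reading a table
#' returns the same values (after the one-time rounding).
#'
#' @param records data.frame (zero rows allowed: a header-only file is
#'   written).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeTable <- function(records, path) {
  records <- as.data.frame(records)
  for (j in seq_along(records))
    if (is.double(records[[j]])) records[[j]] <- signif(records[[j]], 6)
  ok <- tryCatch({
    write.table(records, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("writeTable: cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a TSV written by [writeTable()]
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "")
}

#' Write a GRanges as BED (0-based half-open)
#'
#' @param gr a GRanges; metadata column \code{name} (when present) becomes
#'   BED column 4.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
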