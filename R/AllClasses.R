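#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Run configuration
#'
#' Container for every tunable threshold and parameter of the pipeline, with
#' the published defaults. All stages take a \code{RunConfig} so a run is
#' fully described by one object plus a seed.
#'
#' @slot seed integer RNG seed.
#' @slot minCoverage minimum RRBS read coverage required in both replicates
#'   for a CpG to be used (default 10).
#' @slot methLow,methHigh percent-methylation cut points separating
#'   low/medium/high site methylation (defaults 25 and 75).
#' @slot tssFlank bp added around each TSS when testing TSS proximity
#'   (default 0: a site is proximal iff it overlaps the TSS point).
#' @slot sigmoidC,sigmoidQuantile parameters of the signal scaling sigmoid
#'   \code{tanh(sigmoidC * d / q)} where \code{q} is the
#'   \code{sigmoidQuantile} quantile of nonzero densities (defaults 0.5, 0.95).
#' @slot nmfRank NMF rank (number of chromatin codes, default 4).
#' @slot nmfRestarts,nmfTol,nmfMaxIter NMF fitting controls.
#' @slot cGrid inverse-regularization grid for the logistic models.
#' @slot cvFolds cross-validation folds (default 10).
#' @slot testFraction held-out test fraction (default 0.2).
#' @slot pcStep step of the classification cut-off scan (default 0.01).
#' @slot tgcDelta minimum log2-odds gain to accept a TF added to a cluster
#'   (default 0.2).
#' @slot tgcMinSupport minimum genome-wide support of a cluster (default 40).
#' @slot tnrK,tnrMaxSize top-k and maximum antecedent size for the
#'   association-rule search (defaults 50 and 4).
#' @slot coopMinSupport minimum co-occupied foreground for a cooperativity
#'   matrix entry (default 10).
#' @slot linkDistance maximum TSS-to-enhancer distance in bp (default 100000).
#' @slot maxDistalLinks maximum distal sites linked per gene (default 3).
#' @slot linkKernelScale distance-kernel scale in bp for link scores
#'   (default 50000).
#' @slot lowOcc,highOcc occupancy bounds defining the low (<=) and high (>=)
#'   occupancy groups of the up-regulation contrast (defaults 2 and 5).
#'
#' @seealso [runConfig()]
#' @export
setClass("RunConfig", representation(
  seed = "integer",
  minCoverage = "numeric",
  methLow = "numeric",
  methHigh = "numeric",
  tssFlank = "numeric",
  sigmoidC = "numeric",
  sigmoidQuantile = "numeric",
  nmfRank = "integer",
  nmfRestarts = "integer",
  nmfTol = "numeric",
  nmfMaxIter = "integer",
  cGrid = "numeric",
  cvFolds = "integer",
  testFraction = "numeric",
  pcStep = "numeric",
  tgcDelta = "numeric",
  tgcMinSupport = "integer",
  tnrK = "integer",
  tnrMaxSize = "integer",
  coopMinSupport = "integer",
  linkDistance = "numeric",
  maxDistalLinks = "integer",
  linkKernelScale = "numeric",
  lowOcc = "integer",
  highOcc = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@minCoverage < 0) msg <- c(msg, "minCoverage must be >= 0")
  if (!(object@methLow >= 0 && object@methLow < object@methHigh &&
        object@methHigh <= 100))
    msg <- c(msg, "need 0 <= methLow < methHigh <= 100")
  if (object@nmfRank < 1) msg <- c(msg, "nmfRank must be >= 1")
  if (object@testFraction <= 0 || object@testFraction >= 1)
    msg <- c(msg, "testFraction must be in (0,1)")
  if (object@tgcDelta < 0) msg <- c(msg, "tgcDelta must be >= 0")
  if (object@tgcMinSupport < 1) msg <- c(msg, "tgcMinSupport must be >= 1")
  if (object@linkDistance <= 0) msg <- c(msg, "linkDistance must be > 0")
  if (object@maxDistalLinks < 0) msg <- c(msg, "maxDistalLinks must be >= 0")
  if (object@lowOcc >= object@highOcc)
    msg <- c(msg, "lowOcc must be < highOcc")
  if (length(msg)) msg else TRUE
})

#' Create a run configuration
#'
#' @param seed integer RNG seed.
#' @param ... any \linkS4class{RunConfig} slot to override its default.
#' @return A \linkS4class{RunConfig}.
#' @examples
#' cfg <- runConfig(seed = 1, tgcDelta = 0.3)
#' @export
runConfig <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    seed = as.integer(seed),
    minCoverage = 10,
    methLow = 25,
    methHigh = 75,
    tssFlank = 0,
    sigmoidC = 0.5,
    sigmoidQuantile = 0.95,
    nmfRank = 4L,
    nmfRestarts = 10L,
    nmfTol = 1e-5,
    nmfMaxIter = 2000L,
    cGrid = c(0.01, 0.1, 1, 10, 100),
    cvFolds = 10L,
    testFraction = 0.2,
    pcStep = 0.01,
    tgcDelta = 0.2,
    tgcMinSupport = 40L,
    tnrK = 50L,
    tnrMaxSize = 4L,
    coopMinSupport = 10L,
    linkDistance = 1e5,
    maxDistalLinks = 3L,
    linkKernelScale = 5e4,
    lowOcc = 2L,
    highOcc = 5L
  )
  bad <- setdiff(names(args), names(defaults))
  if (length(bad))
    stop("unknown RunConfig parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  int_slots <- c("seed", "nmfRank", "nmfRestarts", "nmfMaxIter", "cvFolds",
                 "tgcMinSupport", "tnrK", "tnrMaxSize", "coopMinSupport",
                 "maxDistalLinks", "lowOcc", "highOcc")
  for (s in int_slots) defaults[[s]] <- as.integer(defaults[[s]])
  do.call(new, c(list("RunConfig"), defaults))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig (seed ", object@seed, ")\n", sep = "")
  for (s in setdiff(slotNames(object), "seed"))
    cat("  ", s, ": ", paste(slot(object, s), collapse = ", "), "\n", sep = "")
})

#' Convert a RunConfig to a named list
#' @param config a \linkS4class{RunConfig}.
#' @return Named list of all parameters.
#' @export
configAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}

#' Scaled histone-mark matrix
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"scaled"}
#' holds length-normalized, sigmoid-scaled mark signals in [0,1]; rows are
#' regulatory sites, columns are marks.
#'
#' @export
setClass("MarkMatrix", contains = "SummarizedExperiment")

setValidity("MarkMatrix", function(object) {
  if (!"scaled" %in% names(assays(object)))
    return("MarkMatrix needs an assay named 'scaled'")
  v <- assay(object, "scaled")
  if (anyNA(v)) return("scaled values must not contain NA")
  if (any(v < 0 | v > 1)) return("scaled values must lie in [0,1]")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("scaled matrix must carry site ids (rownames) and marks (colnames)")
  TRUE
})

#' Construct a MarkMatrix
#' @param values numeric matrix in [0,1]; rownames are site ids, colnames marks.
#' @return A \linkS4class{MarkMatrix}.
#' @export
MarkMatrix <- function(values) {
  new("MarkMatrix", SummarizedExperiment(assays = list(scaled = values)))
}

#' @describeIn MarkMatrix the scaled sites-by-marks matrix.
#' @param x a \code{MarkMatrix}.
#' @export
markValues <- function(x) assay(x, "scaled")

#' @describeIn MarkMatrix mark labels (columns).
#' @export
markNames <- function(x) colnames(assay(x, "scaled"))

#' @describeIn MarkMatrix site identifiers (rows).
#' @export
siteIDs <- function(x) rownames(assay(x, "scaled"))

setMethod("show", "MarkMatrix", function(object) {
  v <- assay(object, "scaled")
  cat("MarkMatrix:", nrow(v), "sites x", ncol(v), "marks\n")
  cat("  marks:", paste(colnames(v), collapse = ", "), "\n")
  cat("  range: [", format(min(v), digits = 3), ",",
      format(max(v), digits = 3), "]\n")
})

#' Non-negative chromatin-code factorization
#'
#' Result of decomposing a scaled mark matrix V (sites x marks) into
#' non-negative per-site weights W (sites x k) and codes H (k x marks),
#' V ~ W H. Code rows are max-normalized (the free scale lives in W) and
#' ordered by descending total weight mass.
#'
#' @slot V,W,H the factorization matrices.
#' @slot k rank.
#' @slot reconError Frobenius norm of V - W H.
#' @slot siteClass site class the matrix came from (free-text label).
#' @export
setClass("CodeFactorization", representation(
  V = "matrix", W = "matrix", H = "matrix",
  k = "integer", reconError = "numeric", siteClass = "character"
))

setValidity("CodeFactorization", function(object) {
  msg <- character()
  if (any(object@W < 0) || any(object@H < 0))
    msg <- c(msg, "W and H must be non-negative")
  if (nrow(object@H) != object@k || ncol(object@W) != object@k)
    msg <- c(msg, "W/H dimensions inconsistent with rank k")
  if (ncol(object@H) != ncol(object@V) || nrow(object@W) != nrow(object@V))
    msg <- c(msg, "W/H dimensions inconsistent with V")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CodeFactorization", function(object) {
  cat("CodeFactorization (", object@siteClass, "): ",
      nrow(object@V), " sites x ", ncol(object@V), " marks, rank ",
      object@k, "\n", sep = "")
  cat("  reconstruction error (Frobenius):",
      format(object@reconError, digits = 5), "\n")
})

#' @describeIn CodeFactorization the k x marks code matrix.
#' @param x a \code{CodeFactorization}.
#' @export
codes <- function(x) x@H

#' @describeIn CodeFactorization the Frobenius reconstruction error.
#' @export
reconError <- function(x) x@reconError

#' Logistic model report
#'
#' Summary of one regularized logistic model of p65 binding: selected penalty
#' and C, MCC-tuned cut-off, held-out AUC and MCC, and standardized slopes.
#'
#' @slot features predictor names.
#' @slot penalty "L1" or "L2".
#' @slot C selected inverse regularization strength.
#' @slot pc tuned classification cut-off.
#' @slot aucTest,mccTest held-out performance.
#' @slot mccTrain training MCC at the tuned cut-off.
#' @slot slopes named standardized coefficients (natural-log odds ratios).
#' @slot intercept model intercept.
#' @slot slopeRobustness matrix with columns mean/sd of each slope across
#'   drop-one-covariate refits (empty until computed).
#' @export
setClass("ModelReport", representation(
  features = "character", penalty = "character", C = "numeric",
  pc = "numeric", aucTest = "numeric", mccTest = "numeric",
  mccTrain = "numeric", slopes = "numeric", intercept = "numeric",
  slopeRobustness = "matrix"
))

setValidity("ModelReport", function(object) {
  msg <- character()
  if (!object@penalty %in% c("L1", "L2")) msg <- c(msg, "penalty must be L1/L2")
  if (object@pc <= 0 || object@pc >= 1) msg <- c(msg, "pc must be in (0,1)")
  if (object@aucTest < 0 || object@aucTest > 1) msg <- c(msg, "auc in [0,1]")
  if (object@mccTest < -1 || object@mccTest > 1) msg <- c(msg, "mcc in [-1,1]")
  if (any(!is.finite(object@slopes))) msg <- c(msg, "slopes must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModelReport", function(object) {
  cat("ModelReport: ", paste(object@features, collapse = " + "), "\n", sep = "")
  cat(sprintf("  penalty %s, C = %g, tuned p_c = %.2f\n",
              object@penalty, object@C, object@pc))
  cat(sprintf("  test AUC = %.3f, test MCC = %.3f\n",
              object@aucTest, object@mccTest))
  cat("  standardized slopes:\n")
  print(round(object@slopes, 3))
})

#' @describeIn ModelReport held-out area under the ROC curve.
#' @param x a \code{ModelReport}.
#' @export
aucTest <- function(x) x@aucTest

#' @describeIn ModelReport held-out Matthews correlation coefficient.
#' @export
mccTest <- function(x) x@mccTest

#' @describeIn ModelReport named standardized slopes.
#' @export
modelSlopes <- function(x) x@slopes

#' Binary TF occupancy table
#'
#' Sites-by-TFs binary pre-stimulation occupancy with the p65 outcome,
#' occupancy counts and stage labels; the substrate of all combinatorial
#' analyses.
#'
#' @slot matrix logical sites x TFs matrix.
#' @slot p65 logical outcome per site.
#' @slot occupancy integer occupancy per site (CTCF/RAD21/DHS excluded).
#' @slot stage character stage label per site.
#' @slot siteIDs site identifiers.
#' @export
setClass("OccupancyTable", representation(
  matrix = "matrix", p65 = "logical", occupancy = "integer",
  stage = "character", siteIDs = "character"
))

setValidity("OccupancyTable", function(object) {
  msg <- character()
  n <- nrow(object@matrix)
  if (!is.logical(object@matrix)) msg <- c(msg, "matrix must be logical")
  if (length(object@p65) != n || length(object@occupancy) != n ||
      length(object@stage) != n || length(object@siteIDs) != n)
    msg <- c(msg, "per-site vectors must match matrix rows")
  excl <- intersect(colnames(object@matrix), c("CTCF", "RAD21", "DHS"))
  keep <- setdiff(colnames(object@matrix), excl)
  if (length(keep) &&
      !all(object@occupancy ==
             rowSums(object@matrix[, keep, drop = FALSE])))
    msg <- c(msg, "occupancy must equal row sums excluding CTCF/RAD21/DHS")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OccupancyTable", function(object) {
  cat("OccupancyTable:", nrow(object@matrix), "sites x",
      ncol(object@matrix), "TFs;",
      sum(object@p65), "p65-positive\n")
})
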