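# Non-negative matrix factorization of scaled mark matrices into
# "chromatin codes" (rows of H) and per-site weights (W).

.frob <- function(M) sqrt(sum(M * M))

# NNDSVD initialization (non-negative double SVD): deterministic,
# well-suited to sparse non-negative data.
.nndsvd <- function(V, k) {
  s <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k)
  H <- matrix(0, k, ncol(V))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      if (nup * nvp > 0) {
        W[, j] <- sqrt(s$d[j] * nup * nvp) * up / nup
        H[j, ] <- sqrt(s$d[j] * nup * nvp) * vp / nvp
      }
    } else {
      W[, j] <- sqrt(s$d[j] * nun * nvn) * un / nun
      H[j, ] <- sqrt(s$d[j] * nun * nvn) * vn / nvn
    }
  }
  eps <- mean(V) * 1e-4 + 1e-12
  W[W <= 0] <- eps
  H[H <= 0] <- eps
  list(W = W, H = H)
}

# Multiplicative updates for the Frobenius loss (Lee & Seung). The loss is
# non-increasing under each update by construction.
.nmfMU <- function(V, W, H, tol, maxIter) {
  eps <- 1e-12
  err <- .frob(V - W %*% H)
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_err <- .frob(V - W %*% H)
    if (err > 0 && (err - new_err) / err < tol && it > 5) {
      err <- new_err
      break
    }
    err <- new_err
  }
  list(W = W, H = H, err = err)
}

#' Fit non-negative chromatin codes (NMF)
#'
#' Decomposes a scaled mark matrix V (sites x marks, values in [0,1]) into
#' non-negative per-site weights W and k code rows H minimizing the
#' Frobenius loss, via multiplicative updates. The first start is the
#' deterministic NNDSVD initialization; the remaining restarts are random,
#' and the fit with the lowest reconstruction error wins. Code rows are then
#' max-normalized (scale moved into W) and reordered by descending total
#' weight mass, giving a canonical, reproducible factorization.
#'
#' @param m a \linkS4class{MarkMatrix} or a numeric matrix in [0,1] with
#'   dimnames.
#' @param k rank (number of codes); must be < number of marks.
#' @param seed RNG seed for the random restarts.
#' @param nRestarts total number of starts (default from config, 10).
#' @param siteClass free-text class label stored in the result.
#' @param config a \linkS4class{RunConfig} (tolerance and iteration cap).
#' @return A \linkS4class{CodeFactorization}.
#' @export
fitNMF <- function(m, k = 4, seed = 1, nRestarts = NULL,
                   siteClass = "all", config = runConfig()) {
  V <- if (is(m, "MarkMatrix")) markValues(m) else as.matrix(m)
  if (anyNA(V) || any(V < 0)) stop("fitNMF: V must be non-negative, no NA")
  if (k >= ncol(V)) stop("fitNMF: rank k must be < number of marks")
  if (all(V == 0)) stop("fitNMF: all-zero matrix")
  if (is.null(nRestarts)) nRestarts <- config@nmfRestarts
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- if (r == 1) .nndsvd(V, k) else {
      list(W = matrix(runif(nrow(V) * k, 0, max(V)), ncol = k),
           H = matrix(runif(k * ncol(V), 0, 1), nrow = k))
    }
    fit <- .nmfMU(V, init$W, init$H, config@nmfTol, config@nmfMaxIter)
    if (is.null(best) || fit$err < best$err) best <- fit
  }
  W <- best$W
  H <- best$H
  # canonical form: unit-max code rows, codes ordered by total weight mass
  for (r in seq_len(k)) {
    mx <- max(H[r, ])
    if (mx > 0) {
      H[r, ] <- H[r, ] / mx
      W[, r] <- W[, r] * mx
    }
  }
  ord <- order(colSums(W), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  rownames(H) <- colnames(W) <- paste0("code", seq_len(k))
  colnames(H) <- colnames(V)
  rownames(W) <- rownames(V)
  new("CodeFactorization", V = V, W = W, H = H, k = as.integer(k),
      reconError = best$err, siteClass = siteClass)
}

#' Per-site code weights
#'
#' @param f a \linkS4class{CodeFactorization}.
#' @param standardized also return z-scored copies (columns suffixed
#'   \code{_z}) for use as regression covariates.
#' @return data.frame of weights, rownames are site ids.
#' @export
codeWeights <- function(f, standardized = TRUE) {
  W <- f@W
  out <- as.data.frame(W)
  if (standardized) {
    for (j in colnames(W)) {
      s <- stats::sd(W[, j])
      out[[paste0(j, "_z")]] <- if (s > 0) (W[, j] - mean(W[, j])) / s else
        rep(0, nrow(W))
    }
  }
  out
}

.cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .permutations(n - 1)
    for (p in rest) out[[length(out) + 1]] <- c(i, setdiff(seq_len(n), i)[p])
  }
  out
}

#' Match codes between two factorizations
#'
#' Finds the one-to-one assignment of code rows maximizing the total cosine
#' similarity (exhaustive over permutations; ranks here are small).
#'
#' @param f1,f2 \linkS4class{CodeFactorization} objects over the same marks.
#' @return data.frame with columns code1, code2, cosine.
#' @export
compareCodes <- function(f1, f2) {
  if (!identical(colnames(f1@H), colnames(f2@H)))
    stop("compareCodes: factorizations use different mark sets")
  k1 <- nrow(f1@H); k2 <- nrow(f2@H)
  if (k1 != k2) stop("compareCodes: ranks differ")
  S <- matrix(0, k1, k2)
  for (i in seq_len(k1)) for (j in seq_len(k2))
    S[i, j] <- .cosine(f1@H[i, ], f2@H[j, ])
  best <- NULL; best_sum <- -Inf
  for (p in .permutations(k1)) {
    s <- sum(S[cbind(seq_len(k1), p)])
    if (s > best_sum) { best_sum <- s; best <- p }
  }
  data.frame(code1 = rownames(f1@H),
             code2 = rownames(f2@H)[best],
             cosine = S[cbind(seq_len(k1), best)])
}

#' Reconstruction-error scree over ranks
#'
#' Diagnostic only: refits at each rank and reports the Frobenius error.
#'
#' @param m matrix or \linkS4class{MarkMatrix}.
#' @param ranks ranks to scan (default 2:6).
#' @param seed RNG seed.
#' @param config a \linkS4class{RunConfig}.
#' @return data.frame with columns k and recon_error.
#' @export
nmfScree <- function(m, ranks = 2:6, seed = 1, config = runConfig()) {
  data.frame(k = ranks, recon_error = vapply(ranks, function(k)
    reconError(fitNMF(m, k = k, seed = seed, config = config)), 0))
}
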