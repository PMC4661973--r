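#' @importFrom glmnet glmnet
#' @importFrom stats glm binomial coef predict sd
NULL

.isBinaryCol <- function(x) all(x %in% c(0, 1))

# z-score continuous columns, leave binary 0/1 columns untouched
.standardizeFeatures <- function(X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    if (.isBinaryCol(X[, j])) next
    s <- sd(X[, j])
    X[, j] <- if (s > 0) (X[, j] - mean(X[, j])) / s else X[, j] * 0
  }
  X
}

# stratified fold assignment: positives and negatives split separately
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.glmnetFit <- function(X, y, penalty, C) {
  if (all(apply(X, 2, function(v) length(unique(v)) < 2))) {
    # every predictor constant: intercept-only model
    return(list(null = TRUE, p = mean(y), features = colnames(X)))
  }
  added_dummy <- FALSE
  if (ncol(X) == 1) {          # glmnet needs >= 2 columns
    X <- cbind(X, .dummy = 0)
    added_dummy <- TRUE
  }
  lambda <- 1 / (C * nrow(X))
  fit <- glmnet(X, y, family = "binomial",
                alpha = if (penalty == "L1") 1 else 0,
                lambda = lambda, standardize = FALSE)
  list(fit = fit, lambda = lambda, added_dummy = added_dummy)
}

.glmnetPredict <- function(model, X) {
  if (isTRUE(model$null)) return(rep(model$p, nrow(X)))
  if (model$added_dummy) X <- cbind(X, .dummy = 0)
  as.numeric(predict(model$fit, newx = X, type = "response",
                     s = model$lambda))
}

.glmnetCoefs <- function(model) {
  if (isTRUE(model$null)) {
    co <- c(qlogis(min(max(model$p, 1e-12), 1 - 1e-12)),
            rep(0, length(model$features)))
    names(co) <- c("(Intercept)", model$features)
    return(co)
  }
  co <- as.numeric(coef(model$fit, s = model$lambda))
  names(co) <- rownames(coef(model$fit, s = model$lambda))
  co
}

#' Fit an MCC-tuned regularized logistic model of p65 binding
#'
#' Protocol: a stratified 20\% test split is withheld; on the training set a
#' grid over penalty (L1, L2) and inverse regularization C is scored by mean
#' 10-fold cross-validated MCC at cut-off 0.5; the winning model is refit on
#' the full training set and the classification cut-off p_c is scanned on a
#' fine grid to maximize training MCC; test AUC and MCC at the tuned p_c are
#' reported. Continuous features are z-scored (so slopes are standardized
#' natural-log odds ratios); binary 0/1 features are left as is.
#'
#' @param features sites x p numeric matrix with column names.
#' @param labels logical p65 outcome; both classes must be present.
#' @param seed RNG seed (split and folds).
#' @param penalties penalties to scan (default L1 and L2).
#' @param config a \linkS4class{RunConfig} (C grid, folds, test fraction,
#'   p_c step).
#' @return A \linkS4class{ModelReport}.
#' @export
fitLogistic <- function(features, labels, seed = 1,
                        penalties = c("L1", "L2"),
                        config = runConfig()) {
  X <- as.matrix(features)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2)
    stop("fitLogistic: both classes must be present in labels")
  X <- .standardizeFeatures(X)
  set.seed(seed)
  # stratified train/test split
  test_idx <- unlist(lapply(c(0L, 1L), function(cls) {
    idx <- which(y == cls)
    sample(idx, max(1, round(config@testFraction * length(idx))))
  }))
  tr <- setdiff(seq_along(y), test_idx)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xte <- X[test_idx, , drop = FALSE]; yte <- y[test_idx]

  folds <- .stratifiedFolds(ytr, config@cvFolds)
  grid <- expand.grid(C = config@cGrid, penalty = penalties,
                      stringsAsFactors = FALSE)
  cv_mcc <- vapply(seq_len(nrow(grid)), function(g) {
    scores <- vapply(seq_len(config@cvFolds), function(f) {
      hold <- folds == f
      if (length(unique(ytr[!hold])) < 2) return(NA_real_)
      mod <- .glmnetFit(Xtr[!hold, , drop = FALSE], ytr[!hold],
                        grid$penalty[g], grid$C[g])
      pr <- .glmnetPredict(mod, Xtr[hold, , drop = FALSE])
      mcc(ytr[hold] == 1, pr >= 0.5)
    }, 0)
    mean(scores, na.rm = TRUE)
  }, 0)
  # among grid points whose CV MCC is within epsilon of the best, prefer the
  # weakest regularization (largest C): MCC is threshold-based and nearly
  # flat in C, and weaker penalties give less biased slopes
  near <- which(cv_mcc >= max(cv_mcc) - 0.005)
  best_g <- near[which.max(grid$C[near])]
  penalty <- grid$penalty[best_g]
  C <- grid$C[best_g]

  final <- .glmnetFit(Xtr, ytr, penalty, C)
  pr_tr <- .glmnetPredict(final, Xtr)
  pc_grid <- seq(config@pcStep, 1 - config@pcStep, by = config@pcStep)
  mcc_scan <- vapply(pc_grid, function(pc) mcc(ytr == 1, pr_tr >= pc), 0)
  pc <- pc_grid[which.max(mcc_scan)]
  pred_tr <- pr_tr >= pc
  if (all(pred_tr) || !any(pred_tr)) {
    warning("fitLogistic: degenerate cut-off scan; falling back to p_c = 0.5")
    pc <- 0.5
  }
  mcc_train <- mcc(ytr == 1, pr_tr >= pc)

  pr_te <- .glmnetPredict(final, Xte)
  co <- .glmnetCoefs(final)
  slopes <- co[setdiff(names(co), c("(Intercept)", ".dummy"))]
  do.call(new, list(Class = "ModelReport",
      features = colnames(X), penalty = penalty, C = C, pc = pc,
      aucTest = aucROC(yte == 1, pr_te),
      mccTest = mcc(yte == 1, pr_te >= pc),
      mccTrain = mcc_train,
      slopes = slopes, intercept = unname(co["(Intercept)"]),
      slopeRobustness = matrix(numeric(), 0, 2)))
}

#' Single-mark model grid (with and without motif)
#'
#' Fits, for one site class, a logistic model per mark alone, per mark plus
#' binary motif presence, and motif alone. The delta_mot column is the AUC
#' gain of each mark+motif model over the same mark alone.
#'
#' @param marks a \linkS4class{MarkMatrix} restricted to the class.
#' @param motif logical per-site motif flag.
#' @param labels logical p65 outcome.
#' @param siteClass class label recorded in the output.
#' @param seed RNG seed.
#' @param config a \linkS4class{RunConfig}.
#' @return data.frame with columns class, model, auc_test, mcc_test,
#'   delta_mot; attribute \code{"mean_delta_mot"} holds the average gain.
#' @export
table1Grid <- function(marks, motif, labels, siteClass = "all", seed = 1,
                       config = runConfig()) {
  V <- markValues(marks)
  motif <- as.numeric(motif)
  rows <- list()
  auc_alone <- numeric(0)
  for (mk in colnames(V)) {
    r1 <- fitLogistic(V[, mk, drop = FALSE], labels, seed = seed,
                      config = config)
    X2 <- cbind(V[, mk, drop = FALSE], mot = motif)
    r2 <- fitLogistic(X2, labels, seed = seed, config = config)
    auc_alone[mk] <- aucTest(r1)
    rows[[length(rows) + 1]] <- data.frame(
      class = siteClass, model = mk,
      auc_test = aucTest(r1), mcc_test = mccTest(r1), delta_mot = NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      class = siteClass, model = paste0(mk, " + mot"),
      auc_test = aucTest(r2), mcc_test = mccTest(r2),
      delta_mot = aucTest(r2) - aucTest(r1))
  }
  rmot <- fitLogistic(matrix(motif, ncol = 1,
                             dimnames = list(NULL, "mot")),
                      labels, seed = seed, config = config)
  rows[[length(rows) + 1]] <- data.frame(
    class = siteClass, model = "mot",
    auc_test = aucTest(rmot), mcc_test = mccTest(rmot),
    delta_mot = NA_real_)
  out <- do.call(rbind, rows)
  attr(out, "mean_delta_mot") <- mean(out$delta_mot, na.rm = TRUE)
  out
}

#' Slope robustness under drop-one-covariate refits
#'
#' For each coefficient, refits the (unregularized, standardized) logistic
#' model once per omitted other covariate and reports the mean and SD of the
#' coefficient across those refits: a collinearity-sensitive measure of how
#' stable each slope is to model specification.
#'
#' @param features sites x p matrix, p >= 2.
#' @param labels logical outcome.
#' @param seed RNG seed (unused by the deterministic refits; kept for
#'   interface symmetry).
#' @return matrix with rownames = features and columns mean, sd, full (the
#'   full-model slope).
#' @export
dropOneRobustness <- function(features, labels, seed = 1) {
  X <- .standardizeFeatures(as.matrix(features))
  if (ncol(X) < 2) stop("dropOneRobustness: need at least 2 covariates")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(as.logical(labels))
  fit_slopes <- function(cols) {
    df <- data.frame(y = y, X[, cols, drop = FALSE])
    co <- coef(suppressWarnings(glm(y ~ ., data = df, family = binomial())))
    co[-1]
  }
  full <- fit_slopes(colnames(X))
  p <- ncol(X)
  out <- matrix(NA_real_, p, 3,
                dimnames = list(colnames(X), c("mean", "sd", "full")))
  for (j in seq_len(p)) {
    vals <- vapply(setdiff(seq_len(p), j), function(kdrop) {
      cols <- colnames(X)[setdiff(seq_len(p), kdrop)]
      fit_slopes(cols)[[colnames(X)[j]]]
    }, 0)
    out[j, ] <- c(mean(vals), if (length(vals) > 1) sd(vals) else 0,
                  full[[colnames(X)[j]]])
  }
  out
}
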