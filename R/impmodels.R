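# Pluggable categorical imputation models shared by MICT, MICT-timing and
# FCS: penalised multinomial (softmax) regression with perfect-prediction
# protection, and random forest with tree-vote probabilities.
#
# Predictors are categorical state codes, one-hot expanded against the full
# alphabet (so a category unseen in training maps to an all-zero block and is
# never an error). Optional fixed covariates are appended the same way.

# Internal: one-hot design matrix for an integer code matrix (n x p, codes
# 1..K) plus optional covariate data.frame (factors/characters).
oneHotDesign <- function(X, K, covariates = NULL, covLevels = NULL) {
  n <- nrow(X); p <- ncol(X)
  out <- matrix(0, n, p * K)
  if (n) {
    for (j in seq_len(p)) {
      ok <- which(!is.na(X[, j]))  # NA predictor -> all-zero block
      idx <- cbind(ok, (j - 1L) * K + X[ok, j])
      out[idx] <- 1
    }
  }
  if (!is.null(covLevels) && length(covLevels)) {
    blocks <- lapply(names(covLevels), function(nm) {
      lv <- covLevels[[nm]]
      v <- as.character(covariates[[nm]])
      b <- matrix(0, n, length(lv))
      hit <- match(v, lv)
      ok <- which(!is.na(hit))
      b[cbind(ok, hit[ok])] <- 1
      b
    })
    out <- cbind(out, do.call(cbind, blocks))
  }
  out
}

# Factor coding for the random-forest paths: NA predictors become an
# explicit "0" level so prediction never fails on unseen gaps.
rfFactor <- function(x, K) {
  x[is.na(x)] <- 0L
  factor(x, levels = 0:K)
}

covariateLevels <- function(covariates) {
  if (is.null(covariates) || !ncol(covariates)) return(list())
  lv <- lapply(covariates, function(v) sort(unique(as.character(v))))
  lv
}

#' Fit a multinomial imputation model
#'
#' Softmax regression of a categorical response on one-hot expanded
#' categorical predictors, fitted with \pkg{nnet}. With \code{protect = TRUE}
#' a small ridge penalty (\code{lambda}) keeps every fitted weight finite so
#' predicted probabilities for categories seen in training are strictly
#' inside (0, 1) even under perfect separation. A single-category response
#' yields a degenerate-but-protected distribution (probability
#' \eqn{1 - \epsilon} on the seen category). Categories absent from training
#' receive probability exactly 0 (so imputation can never invent unseen
#' states), except in the degenerate single-category case where the
#' protection epsilon is spread over the rest of the alphabet.
#'
#' @param X integer matrix of predictor state codes (n x p, codes 1..K).
#' @param y integer response codes.
#' @param K alphabet size.
#' @param protect apply perfect-prediction protection.
#' @param lambda ridge penalty when protecting.
#' @param covariates optional data.frame of fixed covariates (one row per
#'   training row).
#' @return a fitted model object with a \code{predictProba} contract.
#' @export
fitMultinomial <- function(X, y, K, protect = TRUE, lambda = 1e-3,
                           covariates = NULL) {
  n <- length(y)
  if (n == 0L) stop("empty training set: caller should fall back")
  seen <- sort(unique(y))
  covLv <- covariateLevels(covariates)
  if (length(seen) == 1L) {
    eps <- if (protect) min(0.005, 1 / (2 * (n + 1))) else 0
    return(structure(list(kind = "multinomial", degenerate = TRUE,
                          seen = seen, K = K, eps = eps,
                          p = ncol(X), covLevels = covLv),
                     class = "seqgapsModel"))
  }
  # collapse duplicate (predictors, response) rows into case weights: the
  # weighted likelihood (and ridge penalty) is identical, fits are much
  # faster for low-order categorical designs
  keyCols <- c(lapply(seq_len(ncol(X)), function(j) X[, j]), list(y))
  if (length(covLv))
    keyCols <- c(keyCols, lapply(covariates, as.character))
  key <- do.call(paste, c(keyCols, list(sep = "\r")))
  first <- which(!duplicated(key))
  g <- match(key, key[first])
  w <- tabulate(g, nbins = length(first))
  Xu <- X[first, , drop = FALSE]
  yu <- y[first]
  cvu <- if (length(covLv)) covariates[first, , drop = FALSE] else NULL
  D <- oneHotDesign(Xu, K, cvu, covLv)
  Yind <- matrix(0, length(yu), length(seen))
  Yind[cbind(seq_along(yu), match(yu, seen))] <- 1
  fit <- nnet::nnet.default(D, Yind, weights = w, size = 0, skip = TRUE,
                            softmax = TRUE, rang = 0,
                            decay = if (protect) lambda else 0,
                            maxit = 200, trace = FALSE, MaxNWts = 1e5)
  structure(list(kind = "multinomial", degenerate = FALSE, fit = fit,
                 seen = seen, K = K, p = ncol(X), covLevels = covLv),
            class = "seqgapsModel")
}

#' Fit a random-forest imputation model
#'
#' Classification forest over the categorical predictors; class probability
#' is the fraction of trees voting for the class. Deterministic under a
#' fixed RNG seed. Defaults follow standard practice: 100 trees, sqrt(p)
#' candidate predictors per split, unlimited depth.
#'
#' @inheritParams fitMultinomial
#' @param nTrees number of trees.
#' @return a fitted model object.
#' @export
fitRandomForest <- function(X, y, K, nTrees = 100, covariates = NULL) {
  n <- length(y)
  if (n == 0L) stop("empty training set: caller should fall back")
  seen <- sort(unique(y))
  covLv <- covariateLevels(covariates)
  if (length(seen) == 1L || n < 2L) {
    return(structure(list(kind = "random_forest", degenerate = TRUE,
                          seen = seen, K = K, eps = 0, p = ncol(X),
                          covLevels = covLv),
                     class = "seqgapsModel"))
  }
  df <- as.data.frame(lapply(seq_len(ncol(X)), function(j)
    rfFactor(X[, j], K)))
  names(df) <- paste0("x", seq_len(ncol(X)))
  if (length(covLv)) {
    for (nm in names(covLv))
      df[[paste0("c_", nm)]] <- factor(as.character(covariates[[nm]]),
                                       levels = covLv[[nm]])
  }
  fit <- randomForest::randomForest(x = df, y = factor(y, levels = seen),
                                    ntree = nTrees)
  structure(list(kind = "random_forest", degenerate = FALSE, fit = fit,
                 seen = seen, K = K, p = ncol(X), covLevels = covLv),
            class = "seqgapsModel")
}

#' Predicted class probabilities over the full alphabet
#'
#' Returns an n x K matrix of probabilities (rows sum to 1); columns of
#' alphabet categories unseen in training are exactly 0, seen categories are
#' strictly positive under protection.
#'
#' @param model a fitted model from \code{\link{fitMultinomial}} or
#'   \code{\link{fitRandomForest}}.
#' @param X integer matrix of predictor codes (n x p).
#' @param covariates optional covariate data.frame aligned with \code{X}.
#' @export
predictProba <- function(model, X, covariates = NULL) {
  n <- nrow(X)
  K <- model$K
  out <- matrix(0, n, K)
  if (model$kind == "marginal")
    return(matrix(model$probs, n, K, byrow = TRUE))
  if (model$degenerate) {
    k <- model$seen
    eps <- model$eps
    out[, k] <- 1 - eps
    if (eps > 0 && K > 1L) out[, -k] <- eps / (K - 1L)
    return(out)
  }
  if (model$kind == "multinomial") {
    D <- oneHotDesign(X, K, covariates, model$covLevels)
    p <- stats::predict(model$fit, D)
    if (is.null(dim(p))) p <- matrix(p, nrow = n, byrow = TRUE)
  } else {
    df <- as.data.frame(lapply(seq_len(ncol(X)), function(j)
      rfFactor(X[, j], K)))
    names(df) <- paste0("x", seq_len(ncol(X)))
    if (length(model$covLevels)) {
      for (nm in names(model$covLevels))
        df[[paste0("c_", nm)]] <- factor(as.character(covariates[[nm]]),
                                         levels = model$covLevels[[nm]])
    }
    p <- stats::predict(model$fit, df, type = "prob")
    if (is.null(dim(p))) p <- matrix(p, nrow = n, byrow = TRUE)
  }
  p <- pmax(p, 0)
  p <- p / rowSums(p)
  out[, model$seen] <- p
  out
}

#' Draw imputed states from a fitted model
#'
#' One random draw per predictor row, according to the model's predicted
#' probabilities.
#'
#' @inheritParams predictProba
#' @param argmax take the most probable state instead of drawing (used by
#'   deterministic-recovery diagnostics).
#' @return integer vector of state codes.
#' @export
drawState <- function(model, X, covariates = NULL, argmax = FALSE) {
  p <- predictProba(model, X, covariates)
  if (argmax) return(max.col(p, ties.method = "first"))
  sampleRows(p)
}

# Internal: one categorical draw per row of a probability matrix.
sampleRows <- function(p) {
  n <- nrow(p)
  cs <- p
  for (j in seq_len(ncol(p))[-1L]) cs[, j] <- cs[, j] + cs[, j - 1L]
  u <- stats::runif(n) * cs[, ncol(p)]
  idx <- as.integer(rowSums(cs < u)) + 1L
  pmin(idx, ncol(p))
}
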