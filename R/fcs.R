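# Fully conditional specification (chained equations) for a univariate
# categorical panel: each time point is one variable.

#' FCS configuration
#'
#' @param predictors predictor set for target time t: \code{"P1"} =
#'   \{t-1\}, \code{"PF1"} = \{t-1, t+1\}, \code{"P5"} = \{t-5..t-1\},
#'   \code{"PF5"} = \{t-5..t-1, t+1..t+5\}, \code{"all"} = every other time
#'   point, \code{"past"} = \{1..t-1\}; indices outside 1..T are dropped.
#' @param model imputation model family.
#' @param nIter number of FCS iterations; 0 means initial (marginal) fill
#'   only.
#' @param minTrainRows degenerate-response guard threshold (training always
#'   uses all rows originally observed at the target).
#' @param protect,lambda,nTrees,useCovariates as in \code{\link{mictConfig}}.
#' @export
fcsConfig <- function(predictors = c("PF5", "P1", "PF1", "P5", "all", "past"),
                      model = c("multinomial", "random_forest"),
                      nIter = 10L, minTrainRows = 1L, protect = TRUE,
                      lambda = 1e-3, nTrees = 100L, useCovariates = TRUE) {
  list(predictors = match.arg(predictors), model = match.arg(model),
       nIter = as.integer(nIter), minTrainRows = as.integer(minTrainRows),
       protect = protect, lambda = lambda, nTrees = as.integer(nTrees),
       useCovariates = useCovariates)
}

# Internal: predictor time indices for target t.
fcsPredictorSet <- function(set, t, T) {
  idx <- switch(set,
    P1 = t - 1L,
    PF1 = c(t - 1L, t + 1L),
    P5 = seq.int(t - 5L, t - 1L),
    PF5 = c(seq.int(t - 5L, t - 1L), seq.int(t + 1L, t + 5L)),
    all = setdiff(seq_len(T), t),
    past = seq_len(t - 1L))
  idx[idx >= 1L & idx <= T]
}

#' Impute gaps with FCS (chained equations)
#'
#' Each missing cell is first filled by a draw from its column's observed
#' marginal. The algorithm then cycles \code{nIter} times over the time
#' points in ascending order; at each visited column with original
#' missingness it fits a model on the rows originally observed there
#' (predictors taken from the current working values) and redraws every
#' originally missing cell of that column. The final iteration is kept, and
#' the whole process is repeated independently M times. An empty predictor
#' set (t = 1 under past-only sets) falls back to a marginal redraw.
#'
#' @param panel an incomplete \linkS4class{SequencePanel}.
#' @param config an \code{\link{fcsConfig}}.
#' @param M number of imputations.
#' @param seed master seed.
#' @return a \linkS4class{MultipleImputation}.
#' @export
fcsImpute <- function(panel, config = fcsConfig(), M = 5L, seed = NULL) {
  stopifnot(M >= 1L)
  checkImputable(panel)
  codes0 <- stateCodes(panel)
  T <- ncol(codes0)
  K <- length(alphabet(panel))
  void <- voidMask(panel)
  missMask <- missingMask(panel)
  missCols <- which(colSums(missMask) > 0L)
  covdf <- if (config$useCovariates && ncol(panel@covariates))
    panel@covariates else NULL
  log <- newFitLog()
  panels <- vector("list", M)
  # column marginals of the observed data (panel-wide fallback for a fully
  # missing column)
  allCounts <- tabulate(codes0[!is.na(codes0)], nbins = K)
  colProbs <- lapply(seq_len(T), function(t) {
    cnt <- tabulate(codes0[!is.na(codes0[, t]), t], nbins = K)
    if (sum(cnt) == 0L) cnt <- allCounts
    cnt / sum(cnt)
  })
  for (m in seq_len(M)) {
    sm <- if (is.null(seed)) NULL else deriveSeed(seed, 100L + m)
    codes <- withSeed(sm, {
      w <- codes0
      for (t in missCols) {
        rows <- which(missMask[, t])
        w[rows, t] <- sampleRows(matrix(colProbs[[t]], length(rows), K,
                                        byrow = TRUE))
      }
      iter <- 0L
      while (iter < config$nIter) {
        iter <- iter + 1L
        for (t in missCols) {
          targetRows <- which(missMask[, t])
          obsRows <- which(!is.na(codes0[, t]))
          pset <- fcsPredictorSet(config$predictors, t, T)
          if (!length(pset) || length(obsRows) < config$minTrainRows) {
            w[targetRows, t] <- sampleRows(
              matrix(colProbs[[t]], length(targetRows), K, byrow = TRUE))
            logFit(log, m, "fcs", NA_integer_, t, 0L, 0L, NULL,
                   length(obsRows), "marginal", "marginal")
            next
          }
          X <- w[obsRows, pset, drop = FALSE]
          cv <- if (!is.null(covdf)) covdf[obsRows, , drop = FALSE] else NULL
          model <- if (config$model == "multinomial")
            fitMultinomial(X, codes0[obsRows, t], K, config$protect,
                           config$lambda, cv)
          else fitRandomForest(X, codes0[obsRows, t], K, config$nTrees, cv)
          logFit(log, m, "fcs", NA_integer_, t,
                 sum(pset < t), sum(pset > t), NULL, length(obsRows),
                 config$model)
          Xnew <- w[targetRows, pset, drop = FALSE]
          cvn <- if (!is.null(covdf)) covdf[targetRows, , drop = FALSE]
            else NULL
          w[targetRows, t] <- drawState(model, Xnew, cvn)
        }
      }
      w
    })
    stopifnot(identical(codes[!missMask & !void], codes0[!missMask & !void]))
    panels[[m]] <- setCodes(panel, codes)
  }
  new("MultipleImputation", panels = panels, method = "fcs",
      config = c(config, list(M = M)),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      fitLog = fitLogTable(log))
}
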