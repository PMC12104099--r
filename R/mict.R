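# MICT: multiple imputation for categorical time series. Gaps are filled
# recursively from their edges, by decreasing remaining gap length, using
# one imputation model per remaining length fitted on displacement windows
# harvested anywhere in the panel. The timing variant (R/timing.R) reuses
# this engine with position-specific models and a time-frame filter.

#' MICT configuration
#'
#' @param np,nf number of past / future predictors (\code{np + nf >= 1}).
#' @param preset optional shorthand overriding \code{np}/\code{nf}:
#'   \code{"P1"} = (1,0), \code{"PF1"} = (1,1), \code{"P5"} = (5,0),
#'   \code{"PF5"} = (5,5).
#' @param model imputation model family.
#' @param minTrainRows below this many training windows the sparse-training
#'   fallback ladder engages (reduced window, then pooled first-order Markov,
#'   then marginal draw).
#' @param protect perfect-prediction protection for the multinomial model.
#' @param lambda ridge penalty used by the protection.
#' @param nTrees random-forest size.
#' @param useCovariates include the panel's fixed covariates as predictors.
#' @param argmax impute the most probable state instead of drawing (for
#'   deterministic-recovery diagnostics only).
#' @export
mictConfig <- function(np = 5L, nf = 5L, preset = NULL,
                       model = c("multinomial", "random_forest"),
                       minTrainRows = 10L, protect = TRUE, lambda = 1e-3,
                       nTrees = 100L, useCovariates = TRUE, argmax = FALSE) {
  if (!is.null(preset)) {
    pn <- resolvePredictorPreset(preset)
    np <- pn[1L]; nf <- pn[2L]
  }
  stopifnot(np >= 0L, nf >= 0L, np + nf >= 1L)
  list(np = as.integer(np), nf = as.integer(nf), model = match.arg(model),
       minTrainRows = as.integer(minTrainRows), protect = protect,
       lambda = lambda, nTrees = as.integer(nTrees),
       useCovariates = useCovariates, argmax = argmax)
}

#' Resolve a predictor-set preset name
#' @param name one of "P1", "PF1", "P5", "PF5".
#' @return integer c(np, nf).
#' @export
resolvePredictorPreset <- function(name) {
  switch(toupper(name),
         P1 = c(1L, 0L), PF1 = c(1L, 1L), P5 = c(5L, 0L), PF5 = c(5L, 5L),
         stop("unknown predictor preset: ", name))
}

# Internal: panel-wide marginal model over observed states.
marginalModel <- function(panel) {
  K <- length(alphabet(panel))
  counts <- tabulate(stateCodes(panel)[!is.na(stateCodes(panel))], nbins = K)
  structure(list(kind = "marginal", probs = counts / sum(counts), K = K,
                 degenerate = FALSE, seen = which(counts > 0)),
            class = "seqgapsModel")
}

# Internal: fit the model for one (stage, G, window, position) with the
# sparse-training fallback ladder. For the timing variant (position +
# radius given) the radius is widened first, one step at a time, until
# minTrainRows is reached or the frame covers the whole axis; only then
# does the MICT ladder engage (reduced window -> pooled first-order Markov
# -> marginal).
fitStageModel <- function(panel, G, np, nf, cfg, position = NULL,
                          radius = NULL, log = NULL, stage = "internal",
                          m = NA_integer_) {
  K <- length(alphabet(panel))
  T <- seqLength(panel)
  covdf <- if (cfg$useCovariates && ncol(panel@covariates))
    panel@covariates else NULL
  build <- function(G, np, nf, rad) {
    filt <- if (!is.null(position) && !is.null(rad))
      seq.int(max(1L, position - rad), min(T, position + rad)) else NULL
    buildTrainingWindows(panel, G, np, nf, positionFilter = filt)
  }
  tryFit <- function(tw, fallback, rad) {
    if (length(tw$y) < cfg$minTrainRows) return(NULL)
    cv <- if (!is.null(covdf)) covdf[tw$seq, , drop = FALSE] else NULL
    model <- tryCatch(
      if (cfg$model == "multinomial")
        fitMultinomial(tw$X, tw$y, K, cfg$protect, cfg$lambda, cv)
      else fitRandomForest(tw$X, tw$y, K, cfg$nTrees, cv),
      error = function(e) NULL)
    if (is.null(model)) return(NULL)
    logFit(log, m, stage, G, position, tw$np, tw$nf, rad, length(tw$y),
           cfg$model, fallback)
    list(model = model, np = tw$np, nf = tw$nf)
  }
  rad <- radius
  tw <- build(G, np, nf, rad)
  if (!is.null(position) && !is.null(rad)) {
    while (length(tw$y) < cfg$minTrainRows &&
           (position - rad > 1L || position + rad < T)) {
      rad <- rad + 1L
      tw <- build(G, np, nf, rad)
    }
  }
  res <- tryFit(tw, if (!is.null(radius) && !identical(rad, radius))
    "radius_widened" else "none", rad)
  if (!is.null(res)) return(res)
  # rung 1: shrink the window to at most one predictor per side
  np1 <- min(np, 1L); nf1 <- min(nf, 1L)
  if (np1 != np || nf1 != nf) {
    res <- tryFit(build(G, np1, nf1, NULL), "window_1", NULL)
    if (!is.null(res)) return(res)
  }
  # rung 2: first-order Markov pooled over all adjacent observed pairs
  npM <- if (np >= 1L) 1L else 0L
  nfM <- 1L - npM
  twM <- buildTrainingWindows(panel, 1L, npM, nfM)
  res <- tryFit(twM, "markov", NULL)
  if (!is.null(res)) return(res)
  # rung 3: marginal distribution of observed states
  logFit(log, m, stage, G, position, 0L, 0L, NULL, 0L, "marginal", "marginal")
  list(model = marginalModel(panel), np = 0L, nf = 0L)
}

# Internal: impute one cell per gap for a set of gaps sharing one fitted
# model. `s` is the current (leftmost remaining) missing position per gap.
drawCells <- function(codes, rows, s, G, fitres, cfg, covdf, argmax) {
  np <- fitres$np; nf <- fitres$nf
  n <- length(rows)
  X <- matrix(integer(), n, np + nf)
  if (np > 0L) for (j in seq_len(np))
    X[, j] <- codes[cbind(rows, s - np + j - 1L)]
  if (nf > 0L) for (j in seq_len(nf))
    X[, np + j] <- codes[cbind(rows, s + G + j - 1L)]
  cv <- if (!is.null(covdf)) covdf[rows, , drop = FALSE] else NULL
  drawState(fitres$model, X, cv, argmax = argmax)
}

# Internal: staged engine shared by MICT and MICT-timing (radius = NULL for
# plain MICT). Returns the completed code matrix.
imputeEngine <- function(panel, cfg, radius = NULL, baseSeed = NULL,
                         log = NULL, m = NA_integer_) {
  codes <- stateCodes(panel)
  T <- ncol(codes)
  lens <- effectiveLengths(panel)
  covdf <- if (cfg$useCovariates && ncol(panel@covariates))
    panel@covariates else NULL
  gaps <- classifyGaps(panel, cfg$np, cfg$nf)
  cache <- new.env(parent = emptyenv())
  getModel <- function(stage, G, np, nf, pos) {
    key <- paste(stage, G, np, nf, pos %||% "", sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- fitStageModel(panel, G, np, nf, cfg, position = pos,
                                  radius = radius, log = log, stage = stage,
                                  m = m)
    cache[[key]]
  }
  timing <- !is.null(radius)

  # -- stage 1: internal gaps, by decreasing remaining length -------------
  processWindowGaps <- function(g, stage) {
    if (!nrow(g)) return(invisible(NULL))
    s <- g$start
    rem <- g$end - g$start + 1L
    while (any(rem > 0L)) {
      G <- max(rem)
      act <- which(rem == G)
      keys <- paste(g$np[act], g$nf[act],
                    if (timing) s[act] else "", sep = "|")
      for (kk in unique(keys)) {
        rows <- act[keys == kk]
        np <- g$np[rows[1L]]; nf <- g$nf[rows[1L]]
        pos <- if (timing) s[rows[1L]] else NULL
        fitres <- getModel(stage, G, np, nf, pos)
        codes[cbind(g$seq[rows], s[rows])] <<-
          drawCells(codes, g$seq[rows], s[rows], G, fitres, cfg, covdf,
                    cfg$argmax)
      }
      rem[act] <- rem[act] - 1L
      s[act] <- s[act] + 1L
    }
  }

  internal <- gaps[gaps$type == "internal", , drop = FALSE]
  internal$np <- rep(cfg$np, nrow(internal))
  internal$nf <- rep(cfg$nf, nrow(internal))
  if (!is.null(baseSeed)) set.seed(deriveSeed(baseSeed, 1L))
  processWindowGaps(internal, "internal")

  # -- stage 2: initial gaps, imputed from the far right to the left ------
  if (!is.null(baseSeed)) set.seed(deriveSeed(baseSeed, 2L))
  kInit <- if (cfg$nf > 0L) cfg$nf else cfg$np
  init <- gaps[gaps$type == "initial", , drop = FALSE]
  if (nrow(init)) {
    for (r in order(init$seq)) {
      i <- init$seq[r]
      for (t in rev(seq_len(init$end[r]))) {
        avail <- 0L
        tt <- t + 1L
        while (tt <= lens[i] && !is.na(codes[i, tt]) && avail < kInit) {
          avail <- avail + 1L; tt <- tt + 1L
        }
        fitres <- if (avail == 0L) {
          logFit(log, m, "initial", 1L, t, 0L, 0L, NULL, 0L, "marginal",
                 "marginal")
          list(model = marginalModel(panel), np = 0L, nf = 0L)
        } else getModel("initial", 1L, 0L, avail, if (timing) t else NULL)
        codes[i, t] <- drawCells(codes, i, t, 1L, fitres, cfg, covdf,
                                 cfg$argmax)
      }
    }
  }

  # -- stage 3: terminal gaps, imputed from the far left to the right -----
  if (!is.null(baseSeed)) set.seed(deriveSeed(baseSeed, 3L))
  kTerm <- if (cfg$np > 0L) cfg$np else cfg$nf
  term <- gaps[gaps$type == "terminal", , drop = FALSE]
  if (nrow(term)) {
    for (r in order(term$seq)) {
      i <- term$seq[r]
      for (t in seq.int(term$start[r], term$end[r])) {
        avail <- 0L
        tt <- t - 1L
        while (tt >= 1L && !is.na(codes[i, tt]) && avail < kTerm) {
          avail <- avail + 1L; tt <- tt - 1L
        }
        fitres <- if (avail == 0L) {
          logFit(log, m, "terminal", 1L, t, 0L, 0L, NULL, 0L, "marginal",
                 "marginal")
          list(model = marginalModel(panel), np = 0L, nf = 0L)
        } else getModel("terminal", 1L, avail, 0L, if (timing) t else NULL)
        codes[i, t] <- drawCells(codes, i, t, 1L, fitres, cfg, covdf,
                                 cfg$argmax)
      }
    }
  }

  # -- stage 4: edge-constrained gaps with reduced windows ----------------
  if (!is.null(baseSeed)) set.seed(deriveSeed(baseSeed, 4L))
  edge <- gaps[gaps$type %in% c("left_hand", "right_hand", "both_hand"), ,
               drop = FALSE]
  if (nrow(edge)) {
    edge$np <- ifelse(edge$type %in% c("left_hand", "both_hand"),
                      edge$n_before, cfg$np)
    edge$nf <- ifelse(edge$type %in% c("right_hand", "both_hand"),
                      edge$n_after, cfg$nf)
    processWindowGaps(edge, "edge")
  }
  codes
}

#' Impute gaps with the MICT algorithm
#'
#' Fills every gap of an incomplete panel M independent times. Internal gaps
#' are imputed first, recursively from their left edge by decreasing
#' remaining length, with one shared model per remaining length; then
#' initial gaps (right to left, future predictors) and terminal gaps (left
#' to right, past predictors); finally the edge-constrained gap types with
#' windows reduced to the cells actually available. Observed cells are never
#' altered. Under past-only presets (nf = 0) initial gaps fall back to
#' future predictors, and symmetrically for terminal gaps when np = 0.
#'
#' @param panel an incomplete \linkS4class{SequencePanel}.
#' @param config a \code{\link{mictConfig}}.
#' @param M number of imputations.
#' @param seed master seed; per-imputation, per-stage sub-streams are
#'   derived deterministically.
#' @return a \linkS4class{MultipleImputation}.
#' @export
mictImpute <- function(panel, config = mictConfig(), M = 5L, seed = NULL) {
  multipleImpute(panel, config, M, seed, radius = NULL, method = "mict")
}

# Internal: shared M-loop for MICT and MICT-timing.
multipleImpute <- function(panel, config, M, seed, radius, method) {
  stopifnot(M >= 1L)
  checkImputable(panel)
  log <- newFitLog()
  obsMask <- !is.na(stateCodes(panel))
  panels <- vector("list", M)
  for (m in seq_len(M)) {
    sm <- if (is.null(seed)) NULL else deriveSeed(seed, 100L + m)
    codes <- imputeEngine(panel, config, radius = radius, baseSeed = sm,
                          log = log, m = m)
    stopifnot(identical(codes[obsMask], stateCodes(panel)[obsMask]))
    if (any(is.na(codes) & !voidMask(panel)))
      stop("internal error: imputation left missing cells")
    panels[[m]] <- setCodes(panel, codes)
  }
  new("MultipleImputation", panels = panels, method = method,
      config = c(config, list(radius = radius, M = M)),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      fitLog = fitLogTable(log))
}
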