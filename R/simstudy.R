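# Simulation engine: resampled repetitions, amputation, multiple
# imputation, Rubin pooling, and performance measures (bias, coverage,
# variance) with Monte Carlo standard errors.

#' Imputation method specifications for a simulation study
#'
#' Each builder returns a named method whose \code{impute} function maps an
#' incomplete panel to a list of M completed panels. \code{methodOracle}
#' returns the true (pre-amputation) resampled panel M times — the
#' calibration reference of the engine; \code{methodMarginal} draws each
#' missing cell independently from its column's observed marginal (an FCS
#' run with zero iterations) — a deliberately poor baseline that breaks
#' spell structure.
#'
#' @param config the corresponding algorithm configuration.
#' @param name label used in the report.
#' @return a list with \code{name} and \code{impute(panel, M, seed, truth)}.
#' @export
methodMict <- function(config = mictConfig(), name = "mict") {
  list(name = name, impute = function(panel, M, seed, truth)
    completedPanels(mictImpute(panel, config, M, seed)))
}

#' @rdname methodMict
#' @export
methodTiming <- function(config = timingConfig(), name = "mict_timing") {
  list(name = name, impute = function(panel, M, seed, truth)
    completedPanels(timingImpute(panel, config, M, seed)))
}

#' @rdname methodMict
#' @export
methodFcs <- function(config = fcsConfig(), name = "fcs") {
  list(name = name, impute = function(panel, M, seed, truth)
    completedPanels(fcsImpute(panel, config, M, seed)))
}

#' @rdname methodMict
#' @export
methodVlmc <- function(config = vlmcConfig(), name = "vlmc") {
  list(name = name, impute = function(panel, M, seed, truth)
    completedPanels(vlmcImpute(panel, config, M, seed)))
}

#' @rdname methodMict
#' @export
methodOracle <- function(name = "oracle") {
  list(name = name, impute = function(panel, M, seed, truth)
    replicate(M, truth, simplify = FALSE))
}

#' @rdname methodMict
#' @export
methodMarginal <- function(name = "marginal") {
  cfg <- fcsConfig(nIter = 0L)
  list(name = name, impute = function(panel, M, seed, truth)
    completedPanels(fcsImpute(panel, cfg, M, seed)))
}

#' Run a simulation study comparing imputation methods
#'
#' Per repetition: resample n sequences with replacement from the complete
#' panel; simulate missingness; for each method impute M times, evaluate
#' the estimands and their bootstrap variances on every completed panel and
#' pool with Rubin's rules. After \code{nRep} repetitions each estimand gets
#' a performance row: bias (mean pooled estimate minus the truth), its
#' Monte Carlo standard error, 95\% interval coverage with its MCSE, the
#' empirical variance of the pooled estimates and the mean model variance.
#' The truth is, by default, the estimand on the original complete panel,
#' fixed across repetitions (\code{truth = "resample"} scores each
#' repetition against its own resampled panel instead). A method failure in
#' a repetition is recorded and the repetition excluded for that method.
#'
#' @param panel a complete \linkS4class{SequencePanel}.
#' @param amputeCfg an \code{\link{amputeConfig}}.
#' @param methods list of method specifications (see
#'   \code{\link{methodMict}}).
#' @param nRep number of repetitions.
#' @param M imputations per repetition.
#' @param bBoot bootstrap replicates for the within-imputation variance.
#' @param seed master seed; every repetition/method/bootstrap stream is
#'   derived from it.
#' @param families estimand families to evaluate.
#' @param truth \code{"full"} or \code{"resample"}.
#' @param rrCap cap for infinite relative risks.
#' @param cacheDir optional directory caching per-repetition results, making
#'   interrupted runs resumable.
#' @return an object of class \code{seqgapsStudy}: list with
#'   \code{performance} (one row per method x estimand), \code{failures},
#'   and the run settings.
#' @export
runStudy <- function(panel, amputeCfg, methods, nRep = 100L, M = 5L,
                     bBoot = 1000L, seed = NULL,
                     families = c("timing", "duration", "sequencing"),
                     truth = c("full", "resample"), rrCap = 100,
                     cacheDir = NULL) {
  truth <- match.arg(truth)
  families <- match.arg(families, several.ok = TRUE)
  if (!isComplete(panel)) stop("the study panel must be complete")
  if (!length(methods)) stop("need at least one method")
  names(methods) <- vapply(methods, `[[`, character(1), "name")
  K <- length(alphabet(panel))
  states <- alphabet(panel)
  n <- nSeq(panel)
  theta <- estimandVectorCodes(stateCodes(panel), K, states, families,
                               rrCap)
  ids <- names(theta)
  if (!is.null(cacheDir) && !dir.exists(cacheDir))
    dir.create(cacheDir, recursive = TRUE)
  repResults <- vector("list", nRep)
  for (r in seq_len(nRep)) {
    cacheFile <- if (!is.null(cacheDir))
      file.path(cacheDir, sprintf("rep_%04d.rds", r)) else NULL
    if (!is.null(cacheFile) && file.exists(cacheFile)) {
      repResults[[r]] <- readRDS(cacheFile)
      next
    }
    sr <- if (is.null(seed)) NULL else deriveSeed(seed, 1L, r)
    idx <- withSeed(sr, sample.int(n, n, replace = TRUE))
    completeRep <- panel[idx]
    amputed <- ampute(completeRep, amputeCfg,
                      if (is.null(seed)) NULL else deriveSeed(seed, 2L, r))
    thetaRep <- if (truth == "resample")
      estimandVectorCodes(stateCodes(completeRep), K, states, families,
                          rrCap) else NULL
    res <- list(theta = thetaRep, methods = list())
    for (mi in seq_along(methods)) {
      meth <- methods[[mi]]
      sm <- if (is.null(seed)) NULL else deriveSeed(seed, 3L, r, mi)
      out <- tryCatch({
        panels <- meth$impute(amputed, M, sm, completeRep)
        Q <- matrix(NA_real_, M, length(ids), dimnames = list(NULL, ids))
        W <- Q
        for (m in seq_len(M)) {
          cm <- stateCodes(panels[[m]])
          Q[m, ] <- estimandVectorCodes(cm, K, states, families, rrCap)
          bv <- bootstrapVarianceCodes(cm, K, states, families, bBoot,
                                       if (is.null(seed)) NULL else
                                         deriveSeed(seed, 4L, r, mi, m),
                                       rrCap)
          W[m, ] <- bv
        }
        pooled <- rubinPoolMatrix(Q, W)
        pooled
      }, error = function(e) structure(conditionMessage(e),
                                       class = "studyFailure"))
      res$methods[[meth$name]] <- out
    }
    if (!is.null(cacheFile)) saveRDS(res, cacheFile)
    repResults[[r]] <- res
  }
  assembleStudy(repResults, methods, theta, ids, truth, nRep, M, families)
}

# Internal: bootstrap variance on a raw code matrix (vector aligned with
# the estimand ids).
bootstrapVarianceCodes <- function(codes, K, states, families, B, seed,
                                   rrCap) {
  n <- nrow(codes)
  point <- estimandVectorCodes(codes, K, states, families, rrCap)
  reps <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      as.numeric(estimandVectorCodes(codes[i, , drop = FALSE], K, states,
                                     families, rrCap))
    }, numeric(length(point)))
  })
  nDef <- rowSums(!is.na(reps))
  vv <- apply(reps, 1L, stats::var, na.rm = TRUE)
  vv[nDef < 2L] <- NA_real_
  vv
}

# Internal: turn per-repetition pooled tables into the performance table.
assembleStudy <- function(repResults, methods, theta, ids, truth, nRep, M,
                          families) {
  perf <- list()
  failures <- list()
  for (meth in methods) {
    nm <- meth$name
    Qbar <- matrix(NA_real_, nRep, length(ids),
                   dimnames = list(NULL, ids))
    lo <- Qbar; hi <- Qbar; Tvar <- Qbar
    thetaMat <- matrix(theta, nRep, length(ids), byrow = TRUE,
                       dimnames = list(NULL, ids))
    nFail <- 0L
    for (r in seq_len(nRep)) {
      out <- repResults[[r]]$methods[[nm]]
      if (inherits(out, "studyFailure")) {
        nFail <- nFail + 1L
        failures[[length(failures) + 1L]] <-
          data.frame(method = nm, rep = r, message = unclass(out),
                     stringsAsFactors = FALSE)
        next
      }
      Qbar[r, ] <- out$Qbar
      lo[r, ] <- out$lo
      hi[r, ] <- out$hi
      Tvar[r, ] <- out$Tvar
      if (truth == "resample")
        thetaMat[r, ] <- repResults[[r]]$theta
    }
    nOk <- colSums(!is.na(Qbar))
    bias <- colMeans(Qbar - thetaMat, na.rm = TRUE)
    mcseBias <- apply(Qbar - thetaMat, 2L, stats::sd, na.rm = TRUE) /
      sqrt(pmax(nOk, 1L))
    covered <- (thetaMat >= lo) & (thetaMat <= hi)
    coverage <- colMeans(covered, na.rm = TRUE)
    nCov <- colSums(!is.na(covered))
    mcseCoverage <- sqrt(coverage * (1 - coverage) / pmax(nCov, 1L))
    perf[[nm]] <- data.frame(
      method = nm, id = ids, family = sub("\\|.*$", "", ids),
      truth = as.numeric(theta)[match(ids, names(theta))],
      bias = bias, mcseBias = mcseBias, coverage = coverage,
      mcseCoverage = mcseCoverage,
      empVar = apply(Qbar, 2L, stats::var, na.rm = TRUE),
      meanTvar = colMeans(Tvar, na.rm = TRUE),
      nRep = nOk, nFail = nFail, stringsAsFactors = FALSE)
  }
  performance <- do.call(rbind, perf)
  # drop estimands never defined (e.g. transitions absent from the panel)
  performance <- performance[!is.na(performance$truth) &
                               performance$nRep > 0L, , drop = FALSE]
  rownames(performance) <- NULL
  structure(list(performance = performance,
                 failures = if (length(failures)) do.call(rbind, failures)
                 else NULL,
                 truth = truth, nRep = nRep, M = M, families = families),
            class = "seqgapsStudy")
}

#' @export
print.seqgapsStudy <- function(x, ...) {
  cat("seqgapsStudy:", x$nRep, "repetitions, M =", x$M, "\n")
  cat("  methods:", paste(unique(x$performance$method), collapse = ", "),
      "\n")
  cat("  estimands:", length(unique(x$performance$id)), "in families",
      paste(x$families, collapse = ", "), "\n")
  if (!is.null(x$failures))
    cat("  failures:", nrow(x$failures), "\n")
  invisible(x)
}

#' Aggregate a performance table
#'
#' Per (method, family): (a) the mean absolute bias over the family's
#' estimands; (b) the proportion of estimands whose Monte Carlo interval
#' \code{bias +/- 1.96 mcseBias} contains 0; (c) the proportion whose
#' interval \code{coverage +/- 1.96 mcseCoverage} contains the nominal
#' 0.95.
#'
#' @param study a \code{seqgapsStudy} or its performance data.frame.
#' @return a tidy data.frame, one row per method x family.
#' @export
summarizeStudy <- function(study) {
  perf <- if (inherits(study, "seqgapsStudy")) study$performance else study
  if (!nrow(perf)) stop("empty performance table")
  sp <- split(perf, list(perf$method, perf$family), drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(method = d$method[1L], family = d$family[1L],
               nEstimands = nrow(d),
               meanAbsBias = mean(abs(d$bias)),
               propBiasZero = mean(d$bias - 1.96 * d$mcseBias <= 0 &
                                     d$bias + 1.96 * d$mcseBias >= 0),
               propCoverageNominal =
                 mean(d$coverage - 1.96 * d$mcseCoverage <= 0.95 &
                        d$coverage + 1.96 * d$mcseCoverage >= 0.95),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$family), , drop = FALSE]
}
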