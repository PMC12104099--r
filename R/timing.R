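# MICT-timing: position-specific imputation models restricted to a time
# frame around the cell being imputed.

#' MICT-timing configuration
#'
#' All \code{\link{mictConfig}} fields plus the time-frame radius. A radius
#' of 0 trains each model only on windows whose target occurs at the same
#' time point as the cell being imputed; a radius of T - 1 reproduces plain
#' MICT.
#'
#' @inheritParams mictConfig
#' @param radius non-negative time-frame half-width.
#' @export
timingConfig <- function(np = 1L, nf = 1L, preset = NULL,
                         model = c("multinomial", "random_forest"),
                         radius = 0L, minTrainRows = 10L, protect = TRUE,
                         lambda = 1e-3, nTrees = 100L, useCovariates = TRUE,
                         argmax = FALSE) {
  cfg <- mictConfig(np = np, nf = nf, preset = preset, model = model,
                    minTrainRows = minTrainRows, protect = protect,
                    lambda = lambda, nTrees = nTrees,
                    useCovariates = useCovariates, argmax = argmax)
  stopifnot(radius >= 0L)
  cfg$radius <- as.integer(radius)
  cfg
}

#' Impute gaps with the MICT-timing algorithm
#'
#' Identical staging to \code{\link{mictImpute}}, except that for each
#' target cell at time t the model is fitted only on training windows whose
#' target position lies within \code{radius} of t, and gaps of equal
#' remaining length at different positions use different models. When a
#' frame holds fewer than \code{minTrainRows} windows the radius is widened
#' one step at a time (logged) before the regular fallback ladder engages.
#'
#' @param panel an incomplete \linkS4class{SequencePanel}.
#' @param config a \code{\link{timingConfig}}.
#' @param M number of imputations.
#' @param seed master seed.
#' @return a \linkS4class{MultipleImputation}.
#' @export
timingImpute <- function(panel, config = timingConfig(), M = 5L,
                         seed = NULL) {
  if (is.null(config$radius)) stop("config must be a timingConfig()")
  if (config$radius > seqLength(panel) - 1L)
    stop("radius must be at most T - 1")
  multipleImpute(panel, config, M, seed, radius = config$radius,
                 method = "mict_timing")
}
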