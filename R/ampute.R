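# Missing-data generators: MAR gaps, attrition, small-sample MAR.
# Hazards are evaluated against the true (pre-amputation) state at the
# previous time point: the generators see complete data.

#' Amputation configuration
#'
#' Defaults are the gap/attrition hazard constants and structural rules of
#' the simulation design this package implements: the probability that a
#' gap starts at the first time point is 0.06; at later time points it is
#' 0.20 after a high-risk state and 0.03 otherwise; an ongoing gap continues
#' with probability 0.66; attrition triggers (from the middle of the
#' sequence onward) with probability 0.10 after a high-risk state and 0.015
#' otherwise; 40\% of sequences are kept fully observed; a sequence may lose
#' at most 75\% of its cells (regenerated otherwise); the small-sample
#' design subsamples 200 cases before amputing.
#'
#' @param mechanism missingness mechanism.
#' @param highRiskStates states whose occurrence raises the hazard at the
#'   next time point (required; the choice should let missingness occur at
#'   any time).
#' @param pInitGap,pStartHi,pStartLo,pContinue MAR gap hazards.
#' @param pAttrHi,pAttrLo attrition trigger hazards.
#' @param completeFraction fraction of sequences protected (kept complete).
#' @param maxMissingFraction per-sequence missingness cap enforced by the
#'   redo rule.
#' @param smallN subsample size for the small-sample mechanism.
#' @param enforceRedo regenerate a sequence's mask while it exceeds the cap.
#' @export
amputeConfig <- function(mechanism = c("mar", "attrition", "small_sample"),
                         highRiskStates, pInitGap = 0.06, pStartHi = 0.20,
                         pStartLo = 0.03, pContinue = 0.66, pAttrHi = 0.10,
                         pAttrLo = 0.015, completeFraction = 0.40,
                         maxMissingFraction = 0.75, smallN = 200L,
                         enforceRedo = TRUE) {
  probs <- c(pInitGap, pStartHi, pStartLo, pContinue, pAttrHi, pAttrLo,
             completeFraction, maxMissingFraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  list(mechanism = match.arg(mechanism),
       highRiskStates = as.character(highRiskStates),
       pInitGap = pInitGap, pStartHi = pStartHi, pStartLo = pStartLo,
       pContinue = pContinue, pAttrHi = pAttrHi, pAttrLo = pAttrLo,
       completeFraction = completeFraction,
       maxMissingFraction = maxMissingFraction, smallN = as.integer(smallN),
       enforceRedo = enforceRedo)
}

# Internal: common preparation and checks.
amputeSetup <- function(panel, config) {
  if (!isComplete(panel)) stop("amputation requires a complete panel")
  hr <- match(config$highRiskStates, alphabet(panel))
  if (anyNA(hr))
    stop("highRiskStates not in the alphabet: ",
         paste(config$highRiskStates[is.na(hr)], collapse = ", "))
  hr
}

# Internal: generate MAR gap masks for a block of sequences (vectorised
# over sequences; one sweep over time). isHi: n x T logical of high-risk
# true states.
marMask <- function(isHi, T, cfg) {
  n <- nrow(isHi)
  m <- matrix(FALSE, n, T)
  inGap <- stats::runif(n) < cfg$pInitGap
  m[, 1L] <- inGap
  for (t in seq_len(T)[-1L]) {
    hz <- ifelse(isHi[, t - 1L], cfg$pStartHi, cfg$pStartLo)
    p <- ifelse(inGap, cfg$pContinue, hz)
    inGap <- stats::runif(n) < p
    m[, t] <- inGap
  }
  m
}

# Internal: attrition masks; first eligible trigger time is ceiling(T/2)+1.
attritionMask <- function(isHi, T, cfg) {
  n <- nrow(isHi)
  m <- matrix(FALSE, n, T)
  t0 <- ceiling(T / 2) + 1L
  trig <- rep(FALSE, n)
  for (t in seq.int(t0, T)) {
    hz <- ifelse(isHi[, t - 1L], cfg$pAttrHi, cfg$pAttrLo)
    trig <- trig | (!trig & stats::runif(n) < hz)
    m[, t] <- trig
  }
  m
}

# Internal: apply the protected-complete and redo rules around a mask
# generator, then return the amputed panel.
runAmputation <- function(panel, config, seed, maskFn) {
  hr <- amputeSetup(panel, config)
  codes <- stateCodes(panel)
  n <- nrow(codes); T <- ncol(codes)
  isHi <- matrix(codes %in% hr, n, T)
  withSeed(seed, {
    nProt <- ceiling(config$completeFraction * n)
    prot <- if (nProt > 0L) sample.int(n, nProt) else integer()
    free <- setdiff(seq_len(n), prot)
    m <- matrix(FALSE, n, T)
    if (length(free)) {
      m[free, ] <- maskFn(isHi[free, , drop = FALSE], T, config)
      if (config$enforceRedo) {
        attempts <- 0L
        repeat {
          bad <- free[rowMeans(m[free, , drop = FALSE]) >
                        config$maxMissingFraction]
          if (!length(bad)) break
          attempts <- attempts + 1L
          if (attempts > 1000L)
            stop("redo rule failed after 1000 attempts for sequence(s) ",
                 paste(seqIDs(panel)[utils::head(bad, 3L)], collapse = ", "))
          m[bad, ] <- maskFn(isHi[bad, , drop = FALSE], T, config)
        }
      }
    }
    out <- codes
    out[m] <- NA_integer_
    out[voidMask(panel)] <- NA_integer_
    setCodes(panel, out)
  })
}

#' Simulate MAR gap missingness
#'
#' A protected fraction of sequences stays complete; in the others a gap
#' starts at t = 1 with probability \code{pInitGap} and at t > 1, when no
#' gap is running, with a hazard depending on the true previous state
#' (\code{pStartHi} for high-risk states, \code{pStartLo} otherwise); an
#' ongoing gap continues with probability \code{pContinue}. A sequence
#' exceeding the missingness cap is regenerated when \code{enforceRedo}.
#'
#' @param panel a complete \linkS4class{SequencePanel}.
#' @param config an \code{\link{amputeConfig}}.
#' @param seed RNG seed.
#' @return the panel with missing cells inserted.
#' @export
amputeMAR <- function(panel, config, seed = NULL) {
  runAmputation(panel, config, seed, marMask)
}

#' Simulate attrition (permanent dropout)
#'
#' From time \code{ceiling(T/2) + 1} onward, each not-yet-triggered
#' sequence drops out with hazard \code{pAttrHi} after a high-risk true
#' state and \code{pAttrLo} otherwise; from the trigger point every later
#' cell is missing. Protection and redo rules as in \code{\link{amputeMAR}}.
#'
#' @inheritParams amputeMAR
#' @export
amputeAttrition <- function(panel, config, seed = NULL) {
  runAmputation(panel, config, seed, attritionMask)
}

#' Simulate MAR missingness in a small subsample
#'
#' Draws \code{smallN} sequences uniformly without replacement, then applies
#' the MAR gap mechanism (protection applies within the subsample).
#'
#' @inheritParams amputeMAR
#' @export
amputeSmallSample <- function(panel, config, seed = NULL) {
  if (nSeq(panel) < config$smallN)
    stop("panel has fewer than smallN sequences")
  sub <- withSeed(if (is.null(seed)) NULL else deriveSeed(seed, 1L),
                  sample.int(nSeq(panel), config$smallN))
  amputeMAR(panel[sub], config,
            if (is.null(seed)) NULL else deriveSeed(seed, 2L))
}

#' Dispatch an amputation mechanism from its configuration
#' @inheritParams amputeMAR
#' @export
ampute <- function(panel, config, seed = NULL) {
  switch(config$mechanism,
         mar = amputeMAR(panel, config, seed),
         attrition = amputeAttrition(panel, config, seed),
         small_sample = amputeSmallSample(panel, config, seed))
}
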