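# Synthetic complete-panel generators: first-order (possibly
# time-heterogeneous) Markov processes emulating six archetypes of
# life-course data — from near-constant civil-status records to volatile
# health-satisfaction scores, strongly age-graded professional careers,
# near-irreversible cohabitational histories and monthly school-to-work
# sequences whose transitions cluster in specific calendar months.

#' Specification of a synthetic sequence panel
#'
#' @param n number of sequences.
#' @param T sequence length.
#' @param states state alphabet.
#' @param init initial state distribution (length K, sums to 1).
#' @param trans a K x K stochastic matrix (time-homogeneous) or a list of
#'   T - 1 such matrices (entry t governs the step from t to t + 1).
#' @param spikePositions,spikePair optional seasonality metadata: time
#'   points at which a designated transition is concentrated, and the
#'   (from, to) pair; used by diagnostics and tests.
#' @export
generatorSpec <- function(n, T, states, init, trans, spikePositions = NULL,
                          spikePair = NULL) {
  K <- length(states)
  stopifnot(n >= 1L, T >= 2L, K >= 2L, length(init) == K,
            abs(sum(init) - 1) < 1e-8, all(init >= 0))
  mats <- if (is.matrix(trans)) list(trans) else trans
  for (P in mats) {
    if (!is.matrix(P) || any(dim(P) != K))
      stop("transition matrices must be K x K")
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
      stop("transition matrix rows must be non-negative and sum to 1")
  }
  if (!is.matrix(trans) && length(trans) != T - 1L)
    stop("need one transition matrix per step (T - 1)")
  structure(list(n = as.integer(n), T = as.integer(T), states = states,
                 init = init / sum(init), trans = trans,
                 spikePositions = spikePositions, spikePair = spikePair),
            class = "generatorSpec")
}

#' Generate a complete panel from a specification
#'
#' Each sequence starts from the initial distribution and evolves by Markov
#' steps with the time-appropriate transition matrix. Deterministic under a
#' fixed seed.
#'
#' @param spec a \code{\link{generatorSpec}}.
#' @param seed RNG seed.
#' @return a complete \linkS4class{SequencePanel}.
#' @export
generatePanel <- function(spec, seed = NULL) {
  n <- spec$n; T <- spec$T; K <- length(spec$states)
  homog <- is.matrix(spec$trans)
  cums <- if (homog) list(rowCumsum(spec$trans))
    else lapply(spec$trans, rowCumsum)
  codes <- withSeed(seed, {
    m <- matrix(NA_integer_, n, T)
    ci <- cumsum(spec$init)
    m[, 1L] <- pmin(findInterval(stats::runif(n), ci) + 1L, K)
    for (t in seq_len(T)[-1L]) {
      cm <- if (homog) cums[[1L]] else cums[[t - 1L]]
      u <- stats::runif(n)
      m[, t] <- pmin(rowSums(cm[m[, t - 1L], , drop = FALSE] < u) + 1L, K)
    }
    m
  })
  p <- sequencePanel(codes, states = spec$states)
  attr(p, "spikePositions") <- spec$spikePositions
  attr(p, "spikePair") <- spec$spikePair
  p
}

rowCumsum <- function(P) {
  out <- P
  for (j in seq_len(ncol(P))[-1L]) out[, j] <- out[, j] + out[, j - 1L]
  out
}

# Internal: stochastic matrix from a named edge list; remaining mass stays.
transMatrix <- function(states, moves) {
  K <- length(states)
  P <- diag(K)
  for (mv in moves) {
    i <- match(mv[[1L]], states); j <- match(mv[[2L]], states)
    P[i, j] <- as.numeric(mv[[3L]])
  }
  for (i in seq_len(K)) {
    off <- sum(P[i, -i])
    P[i, i] <- 1 - off
  }
  if (any(P < 0)) stop("move probabilities exceed 1 for some state")
  P
}

#' Archetype panel presets
#'
#' Named generator specifications emulating the main configurations of
#' univariate life-course data: \code{stable_calendar} (civil-status-like:
#' yearly, very low transition rate ~1.6\%), \code{volatile_calendar}
#' (health-satisfaction-like ordinal process, ~36.5\% transitions),
#' \code{process_time_strong} (career trajectories with strongly age-graded
#' education-to-work moves, ~10\% transitions), \code{seasonal_monthly}
#' (monthly school-to-work sequences, ~3.6\% transitions, school-leaving
#' concentrated at months 12, 24, ..., 72), \code{ordered_irreversible}
#' (cohabitational histories that essentially never revisit a state), and
#' \code{small_template} (a generic moderate-persistence panel for
#' small-sample experiments).
#'
#' @param name preset name.
#' @param n number of sequences (defaults to the archetype's).
#' @return a \code{\link{generatorSpec}}.
#' @export
panelPreset <- function(name = c("stable_calendar", "volatile_calendar",
                                 "process_time_strong", "seasonal_monthly",
                                 "ordered_irreversible", "small_template"),
                        n = NULL) {
  name <- match.arg(name)
  switch(name,
    stable_calendar = {
      st <- c("single", "married", "separated", "divorced", "widowed")
      P <- transMatrix(st, list(
        list("single", "married", 0.014), list("single", "widowed", 0.001),
        list("married", "separated", 0.006),
        list("married", "divorced", 0.004),
        list("married", "widowed", 0.004),
        list("separated", "divorced", 0.10),
        list("separated", "married", 0.02),
        list("divorced", "married", 0.012),
        list("widowed", "married", 0.005)))
      generatorSpec(n %||% 2324L, 21L, st,
                    c(0.30, 0.59, 0.011, 0.068, 0.031), P)
    },
    volatile_calendar = {
      st <- c("low", "average", "high", "very_high")
      P <- transMatrix(st, list(
        list("low", "average", 0.30), list("low", "high", 0.065),
        list("average", "low", 0.10), list("average", "high", 0.235),
        list("average", "very_high", 0.03),
        list("high", "average", 0.12), list("high", "very_high", 0.225),
        list("high", "low", 0.02),
        list("very_high", "high", 0.315), list("very_high", "average", 0.05)))
      generatorSpec(n %||% 1259L, 21L, st, c(0.037, 0.114, 0.493, 0.356), P)
    },
    process_time_strong = {
      st <- c("education", "fulltime", "parttime", "nonworking")
      base <- function(exitHaz) transMatrix(st, list(
        list("education", "fulltime", exitHaz * 0.70),
        list("education", "parttime", exitHaz * 0.15),
        list("education", "nonworking", exitHaz * 0.15),
        list("fulltime", "parttime", 0.04),
        list("fulltime", "nonworking", 0.03),
        list("fulltime", "education", 0.005),
        list("parttime", "fulltime", 0.08),
        list("parttime", "nonworking", 0.03),
        list("nonworking", "fulltime", 0.07),
        list("nonworking", "parttime", 0.05)))
      mats <- lapply(seq_len(25L), function(t)
        base(if (t < 4L) 0.08 else if (t <= 9L) 0.30 else 0.55))
      generatorSpec(n %||% 3382L, 26L, st, c(0.92, 0.06, 0.01, 0.01), mats)
    },
    seasonal_monthly = {
      st <- c("school", "further_education", "higher_education", "training",
              "employment", "joblessness")
      off <- transMatrix(st, list(
        list("school", "joblessness", 0.003),
        list("further_education", "joblessness", 0.003),
        list("higher_education", "joblessness", 0.003),
        list("training", "employment", 0.025),
        list("employment", "joblessness", 0.009),
        list("joblessness", "employment", 0.09),
        list("joblessness", "training", 0.02)))
      spike <- transMatrix(st, list(
        list("school", "employment", 0.35),
        list("school", "further_education", 0.15),
        list("school", "higher_education", 0.10),
        list("school", "training", 0.05),
        list("further_education", "employment", 0.30),
        list("further_education", "higher_education", 0.15),
        list("higher_education", "employment", 0.30),
        list("training", "employment", 0.30),
        list("employment", "joblessness", 0.004),
        list("joblessness", "employment", 0.06),
        list("joblessness", "training", 0.03)))
      spikes <- seq.int(12L, 72L, by = 12L)
      mats <- lapply(seq_len(71L), function(t)
        if ((t + 1L) %in% spikes) spike else off)
      generatorSpec(n %||% 712L, 72L, st,
                    c(0.93, 0.01, 0.01, 0.01, 0.02, 0.02), mats,
                    spikePositions = spikes,
                    spikePair = c("school", "employment"))
    },
    ordered_irreversible = {
      st <- c("with_parents", "with_partner", "with_partner_child", "other")
      P <- transMatrix(st, list(
        list("with_parents", "with_partner", 0.115),
        list("with_parents", "other", 0.02),
        list("with_partner", "with_partner_child", 0.155),
        list("with_partner", "other", 0.01),
        list("with_partner_child", "other", 0.006),
        list("other", "with_partner_child", 0.05)))
      generatorSpec(n %||% 3710L, 26L, st, c(0.95, 0.03, 0.0, 0.02), P)
    },
    small_template = {
      st <- c("A", "B", "C", "D")
      P <- matrix(0.1 / 3, 4L, 4L)
      diag(P) <- 0.9
      generatorSpec(n %||% 1000L, 21L, st, rep(0.25, 4L), P)
    })
}

#' Toy two-sequence panel for window-counting diagnostics
#'
#' Two length-15 sequences over \{A, B\}: sequence 1 with an internal gap
#' at times 4-7 (so, under np = nf = 2, the length-4 window builder
#' harvests exactly one window from it, targeting t = 10 with predictors at
#' 8, 9, 14 and 15) and sequence 2 fully observed (contributing the eight
#' windows t = 3..10).
#'
#' @return an incomplete \linkS4class{SequencePanel}.
#' @export
mictExamplePanel <- function() {
  s1 <- c("A", "A", "B", NA, NA, NA, NA, "B", "A", "B", "A", "A", "B", "B",
          "A")
  s2 <- c("B", "A", "B", "B", "A", "A", "B", "A", "B", "B", "A", "B", "A",
          "A", "B")
  sequencePanel(rbind(s1, s2), states = c("A", "B"), ids = c("s1", "s2"))
}
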