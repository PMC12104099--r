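# Estimands on completed panels: timing (state frequencies per time point),
# duration (mean spell length per state), sequencing (pooled transition
# relative risks), and their bootstrap variances.

# Internal: fast estimand evaluation on a raw code matrix. Returns a named
# numeric vector; undefined estimands are NA. `rrCap` replaces an infinite
# relative risk; capped values are flagged via the "capped" attribute.
estimandVectorCodes <- function(codes, K, states,
                                families = c("timing", "duration",
                                             "sequencing"),
                                rrCap = 100) {
  out <- numeric(0)
  capped <- character(0)
  T <- ncol(codes)
  n <- nrow(codes)
  if ("timing" %in% families) {
    tm <- matrix(NA_real_, K, T)
    for (t in seq_len(T)) {
      cnt <- tabulate(codes[!is.na(codes[, t]), t], nbins = K)
      tot <- sum(cnt)
      if (tot > 0L) tm[, t] <- cnt / tot
    }
    v <- as.vector(tm)
    names(v) <- paste0("timing|", rep(states, T), "|",
                       rep(seq_len(T), each = K))
    out <- c(out, v)
  }
  if ("duration" %in% families) {
    prev <- cbind(NA_integer_, codes[, -T, drop = FALSE])
    isStart <- !is.na(codes) & (is.na(prev) | codes != prev)
    nSpells <- tabulate(codes[isStart], nbins = K)
    totLen <- tabulate(codes[!is.na(codes)], nbins = K)
    v <- ifelse(nSpells > 0L, totLen / pmax(nSpells, 1L), NA_real_)
    names(v) <- paste0("duration|", states)
    out <- c(out, v)
  }
  if ("sequencing" %in% families) {
    a <- codes[, -T, drop = FALSE]
    b <- codes[, -1L, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    trans <- matrix(0, K, K)
    if (any(ok)) {
      tt <- tabulate((a[ok] - 1L) * K + b[ok], nbins = K * K)
      trans <- matrix(tt, K, K, byrow = TRUE)
    }
    fromTot <- rowSums(trans)
    toTot <- colSums(trans)
    allTot <- sum(trans)
    v <- rep(NA_real_, K * (K - 1L))
    nm <- character(K * (K - 1L))
    k <- 0L
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (i == j) next
      k <- k + 1L
      nm[k] <- paste0("sequencing|", states[i], ">", states[j])
      denomN <- allTot - fromTot[i]           # transitions not from i
      if (fromTot[i] == 0 || denomN == 0) next
      p1 <- trans[i, j] / fromTot[i]
      p0 <- (toTot[j] - trans[i, j]) / denomN
      if (p0 == 0) {
        if (p1 > 0) { v[k] <- rrCap; capped <- c(capped, nm[k]) }
        # p1 == p0 == 0: undefined, stays NA
      } else v[k] <- p1 / p0
    }
    names(v) <- nm
    out <- c(out, v)
  }
  attr(out, "capped") <- capped
  out
}

#' Evaluate the life-course estimands of a panel
#'
#' Three families: \emph{timing} — the proportion of sequences in each state
#' at each time point; \emph{duration} — the mean spell length of each state
#' pooled over sequences; \emph{sequencing} — the pooled relative risk of
#' each ordered transition a -> b, \eqn{RR = P(X_{t+1}=b | X_t=a) /
#' P(X_{t+1}=b | X_t \ne a)}. States with no spells, and transition pairs
#' with an undefined denominator, are dropped with a note; an infinite RR is
#' capped at \code{rrCap} and flagged.
#'
#' @param panel a complete \linkS4class{SequencePanel}.
#' @param families subset of the three estimand families.
#' @param rrCap replacement value for an infinite relative risk.
#' @param freqFloor timing estimands with a state frequency below this floor
#'   at a time point are excluded (default 0: keep all).
#' @return data.frame with columns \code{id}, \code{family}, \code{estimate}
#'   and a \code{capped} flag.
#' @export
panelEstimands <- function(panel, families = c("timing", "duration",
                                               "sequencing"),
                           rrCap = 100, freqFloor = 0) {
  families <- match.arg(families, several.ok = TRUE)
  if (!isComplete(panel))
    stop("estimands are defined on complete panels only")
  v <- estimandVectorCodes(stateCodes(panel), length(alphabet(panel)),
                           alphabet(panel), families, rrCap)
  capped <- attr(v, "capped")
  df <- data.frame(id = names(v), family = sub("\\|.*$", "", names(v)),
                   estimate = as.numeric(v),
                   capped = names(v) %in% capped,
                   stringsAsFactors = FALSE)
  if (freqFloor > 0) {
    drop <- df$family == "timing" & !is.na(df$estimate) &
      df$estimate < freqFloor
    df <- df[!drop, , drop = FALSE]
  }
  df <- df[!is.na(df$estimate), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname panelEstimands
#' @export
timingEstimands <- function(panel) panelEstimands(panel, "timing")

#' @rdname panelEstimands
#' @export
durationEstimands <- function(panel) panelEstimands(panel, "duration")

#' @rdname panelEstimands
#' @export
sequencingEstimands <- function(panel, rrCap = 100)
  panelEstimands(panel, "sequencing", rrCap = rrCap)

#' Bootstrap variance of the estimands
#'
#' Resamples sequences (rows) with replacement \code{B} times and returns
#' the sample variance of each estimand across replicates, aligned with the
#' point estimates from the original panel. An estimand undefined in more
#' than half of the replicates is flagged unreliable.
#'
#' @param panel a complete \linkS4class{SequencePanel}.
#' @param families estimand families to evaluate.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param rrCap as in \code{\link{panelEstimands}}.
#' @return data.frame with \code{id}, \code{estimate}, \code{variance},
#'   \code{nDefined}, \code{unreliable}.
#' @export
bootstrapVariance <- function(panel, families = c("timing", "duration",
                                                  "sequencing"),
                              B = 1000L, seed = NULL, rrCap = 100) {
  stopifnot(B >= 2L)
  families <- match.arg(families, several.ok = TRUE)
  codes <- stateCodes(panel)
  K <- length(alphabet(panel))
  states <- alphabet(panel)
  point <- estimandVectorCodes(codes, K, states, families, rrCap)
  n <- nrow(codes)
  reps <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      as.numeric(estimandVectorCodes(codes[idx, , drop = FALSE], K, states,
                                     families, rrCap))
    }, numeric(length(point)))
  })
  nDef <- rowSums(!is.na(reps))
  vv <- apply(reps, 1L, stats::var, na.rm = TRUE)
  vv[nDef < 2L] <- NA_real_
  data.frame(id = names(point), estimate = as.numeric(point), variance = vv,
             nDefined = nDef, unreliable = nDef < B / 2,
             stringsAsFactors = FALSE)
}
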