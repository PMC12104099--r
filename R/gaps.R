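#' Classify missing-data gaps
#'
#' Detects every maximal run of missing cells in each sequence and classifies
#' it into the six-gap typology used by the MICT algorithm, relative to a
#' predictor window of \code{np} past and \code{nf} future cells:
#' \describe{
#'   \item{initial}{the gap starts at the first time point;}
#'   \item{terminal}{the gap ends at the last (effective) time point;}
#'   \item{internal}{at least \code{np} contiguous observed cells before and
#'     \code{nf} after the gap;}
#'   \item{left_hand}{fewer than \code{np} (but >= 1) observed before,
#'     enough after;}
#'   \item{right_hand}{enough before, fewer than \code{nf} after;}
#'   \item{both_hand}{deficient on both sides.}
#' }
#' \code{n_before}/\code{n_after} count contiguous observed cells only (an
#' adjacent gap truncates availability) and are capped at \code{np}/\code{nf}.
#'
#' @param panel a \linkS4class{SequencePanel}.
#' @param np,nf non-negative predictor counts, \code{np + nf >= 1}.
#' @return data.frame with columns \code{seq}, \code{start}, \code{end},
#'   \code{n_before}, \code{n_after}, \code{type} (1-based inclusive time
#'   indices).
#' @export
classifyGaps <- function(panel, np, nf) {
  stopifnot(np >= 0L, nf >= 0L, np + nf >= 1L)
  codes <- stateCodes(panel)
  lens <- effectiveLengths(panel)
  obs <- !is.na(codes)
  if (any(rowSums(obs) == 0L))
    stop("sequence(s) fully missing: ",
         paste(seqIDs(panel)[rowSums(obs) == 0L], collapse = ", "))
  out <- vector("list", nrow(codes))
  for (i in seq_len(nrow(codes))) {
    Ti <- lens[i]
    oi <- obs[i, seq_len(Ti)]
    r <- rle(!oi)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    miss <- which(r$values)
    if (!length(miss)) next
    rows <- lapply(miss, function(k) {
      s <- starts[k]; e <- ends[k]
      # contiguous observed run immediately before / after
      nb <- 0L
      t <- s - 1L
      while (t >= 1L && oi[t] && nb < np) { nb <- nb + 1L; t <- t - 1L }
      na_ <- 0L
      t <- e + 1L
      while (t <= Ti && oi[t] && na_ < nf) { na_ <- na_ + 1L; t <- t + 1L }
      type <-
        if (s == 1L) "initial"
        else if (e == Ti) "terminal"
        else if (nb >= np && na_ >= nf) "internal"
        else if (nb < np && na_ >= nf) "left_hand"
        else if (nb >= np && na_ < nf) "right_hand"
        else "both_hand"
      data.frame(seq = i, start = s, end = e, n_before = nb, n_after = na_,
                 type = type, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seq = integer(), start = integer(), end = integer(),
                      n_before = integer(), n_after = integer(),
                      type = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overall transition rate of a panel
#'
#' Fraction of adjacent time-point pairs (both cells observed) whose states
#' differ, pooled over all sequences.
#'
#' @param panel a \linkS4class{SequencePanel}.
#' @return a fraction in [0, 1].
#' @export
transitionRate <- function(panel) {
  codes <- stateCodes(panel)
  a <- codes[, -ncol(codes), drop = FALSE]
  b <- codes[, -1L, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no adjacent observed pair in the panel")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Average number of visits to visited states (ANV)
#'
#' Per sequence, the mean over distinct visited states of the number of
#' spells (maximal runs) of that state; the panel value is the mean over
#' sequences. Equals 1 when no state is ever revisited and L/2 for strict
#' two-state alternation of length L. Defined on complete panels only.
#'
#' @param panel a complete \linkS4class{SequencePanel}.
#' @return the panel-level ANV.
#' @export
anv <- function(panel) {
  if (!isComplete(panel))
    stop("anv is defined on complete panels only")
  codes <- stateCodes(panel)
  lens <- effectiveLengths(panel)
  K <- length(alphabet(panel))
  n <- nrow(codes)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    x <- codes[i, seq_len(lens[i])]
    nSpells <- 1L + sum(x[-1L] != x[-length(x)])
    nDistinct <- length(unique(x))
    vals[i] <- nSpells / nDistinct
  }
  mean(vals)
}

#' Mean spell length of one state
#'
#' Mean length of the maximal runs of \code{state}, pooled over all
#' sequences of a complete panel. When the state never occurs the result is
#' the "no spells" sentinel \code{NA} (with attribute \code{nSpells = 0}),
#' distinct from a mean of 0.
#'
#' @param panel a complete \linkS4class{SequencePanel}.
#' @param state a state label from the alphabet.
#' @return mean spell length, with attribute \code{nSpells}.
#' @export
spellStats <- function(panel, state) {
  k <- match(state, alphabet(panel))
  if (is.na(k)) stop("state '", state, "' is not in the alphabet")
  if (!isComplete(panel))
    stop("spellStats is defined on complete panels only")
  st <- spellSummary(panel)
  n <- st$nSpells[k]
  if (n == 0L) return(structure(NA_real_, nSpells = 0L))
  structure(st$totalLength[k] / n, nSpells = n)
}

# Internal: pooled spell counts and total cell counts per state, vectorised.
# Mean spell length of state s = totalLength[s] / nSpells[s].
spellSummary <- function(panel) {
  codes <- stateCodes(panel)
  K <- length(alphabet(panel))
  lens <- effectiveLengths(panel)
  T <- ncol(codes)
  # a spell starts where the state differs from the previous cell (or at t=1)
  prev <- cbind(NA_integer_, codes[, -T, drop = FALSE])
  isStart <- !is.na(codes) & (is.na(prev) | codes != prev)
  starts <- codes[isStart]
  nSpells <- tabulate(starts, nbins = K)
  totalLength <- tabulate(codes[!is.na(codes)], nbins = K)
  list(nSpells = nSpells, totalLength = totalLength)
}
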