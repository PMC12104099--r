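# Displacement-window training sets for MICT / MICT-timing.

#' Build the training windows for a given remaining gap length
#'
#' A window targets time \code{t} and uses predictors at offsets
#' \code{-np..-1} (past) and \code{+G..+G+nf-1} (future beyond the gap's far
#' edge). One row is harvested per (sequence, t) with every predictor cell
#' and the target cell observed in the source panel and the window inside
#' \code{1..T}. With \code{positionFilter}, only targets \code{t} in the
#' given set are kept (the MICT-timing restriction).
#'
#' @param panel a \linkS4class{SequencePanel} (the source of observed
#'   windows; imputed values never enter training).
#' @param G remaining gap length (>= 1).
#' @param np,nf past / future predictor counts.
#' @param positionFilter optional integer set of admissible target times.
#' @return list with \code{X} (integer predictor matrix, past columns then
#'   future), \code{y} (target codes), \code{seq}, \code{t}, and the window
#'   geometry.
#' @export
buildTrainingWindows <- function(panel, G, np, nf, positionFilter = NULL) {
  stopifnot(G >= 1L, np >= 0L, nf >= 0L)
  codes <- stateCodes(panel)
  T <- ncol(codes)
  obs <- !is.na(codes)
  tMin <- np + 1L
  tMax <- T - G - nf + 1L
  ts <- if (tMin > tMax) integer() else seq.int(tMin, tMax)
  if (!is.null(positionFilter)) ts <- intersect(ts, as.integer(positionFilter))
  p <- np + nf
  Xs <- vector("list", length(ts))
  ys <- vector("list", length(ts))
  seqs <- vector("list", length(ts))
  tt <- vector("list", length(ts))
  for (k in seq_along(ts)) {
    t <- ts[k]
    colsPast <- if (np > 0L) seq.int(t - np, t - 1L) else integer()
    colsFut <- if (nf > 0L) seq.int(t + G, t + G + nf - 1L) else integer()
    need <- c(colsPast, t, colsFut)
    ok <- rowSums(obs[, need, drop = FALSE]) == length(need)
    if (!any(ok)) next
    Xs[[k]] <- codes[ok, c(colsPast, colsFut), drop = FALSE]
    ys[[k]] <- codes[ok, t]
    seqs[[k]] <- which(ok)
    tt[[k]] <- rep.int(t, sum(ok))
  }
  keep <- !vapply(Xs, is.null, logical(1))
  X <- if (any(keep)) do.call(rbind, Xs[keep]) else
    matrix(integer(), 0L, p)
  list(X = X,
       y = if (any(keep)) unlist(ys[keep], use.names = FALSE) else integer(),
       seq = if (any(keep)) unlist(seqs[keep], use.names = FALSE) else
         integer(),
       t = if (any(keep)) unlist(tt[keep], use.names = FALSE) else integer(),
       G = G, np = np, nf = nf)
}

#' Count training windows inside a time frame
#'
#' Number of windows \code{\link{buildTrainingWindows}} harvests for target
#' position \code{t} when training is restricted to targets within
#' \code{radius} of \code{t}. Exposed for diagnostics and testing of the
#' MICT-timing restriction; non-decreasing in \code{radius}.
#'
#' @inheritParams buildTrainingWindows
#' @param t target time point.
#' @param radius non-negative time-frame half-width.
#' @export
countWindowsInFrame <- function(panel, G, np, nf, t, radius) {
  T <- seqLength(panel)
  filt <- seq.int(max(1L, t - radius), min(T, t + radius))
  length(buildTrainingWindows(panel, G, np, nf, positionFilter = filt)$y)
}
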