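# Rubin's rules for combining M imputed-data estimates.

#' Pool M estimates with Rubin's rules
#'
#' Combines M per-imputation estimates and their (within) variances:
#' \eqn{\bar Q} is the mean estimate, \eqn{\bar W} the mean within variance,
#' B the between variance (sample variance over imputations), total variance
#' \eqn{T = \bar W + (1 + 1/M) B}, degrees of freedom
#' \eqn{(M-1)(1 + \bar W / ((1+1/M)B))^2} (infinite when B = 0), and a 95\%
#' t interval. With M = 1 the between component cannot be estimated: the
#' within variance is returned alone with \code{mOne = TRUE}.
#'
#' @param estimates numeric vector of M estimates.
#' @param variances numeric vector of M non-negative variances.
#' @return list with \code{Qbar}, \code{Wbar}, \code{B}, \code{Tvar},
#'   \code{df}, \code{ci95}, \code{M}, \code{mOne}.
#' @export
rubinPool <- function(estimates, variances) {
  M <- length(estimates)
  stopifnot(M >= 1L, length(variances) == M)
  if (any(variances < 0, na.rm = TRUE)) stop("variances must be >= 0")
  Qbar <- mean(estimates)
  Wbar <- mean(variances)
  if (M == 1L) {
    ci <- Qbar + c(-1, 1) * stats::qnorm(0.975) * sqrt(Wbar)
    return(list(Qbar = Qbar, Wbar = Wbar, B = NA_real_, Tvar = Wbar,
                df = Inf, ci95 = ci, M = M, mOne = TRUE))
  }
  B <- stats::var(estimates)
  Tvar <- Wbar + (1 + 1 / M) * B
  df <- if (B == 0) Inf else (M - 1) * (1 + Wbar / ((1 + 1 / M) * B))^2
  ci <- Qbar + c(-1, 1) * stats::qt(0.975, df) * sqrt(Tvar)
  list(Qbar = Qbar, Wbar = Wbar, B = B, Tvar = Tvar, df = df, ci95 = ci,
       M = M, mOne = FALSE)
}

# Internal: vectorised pooling over K estimands. Q, W are M x K matrices
# (NA allowed; an estimand pools over its defined imputations). Returns a
# data.frame: Qbar, Wbar, B, Tvar, df, lo, hi, nImp.
rubinPoolMatrix <- function(Q, W) {
  M <- nrow(Q)
  nImp <- colSums(!is.na(Q))
  Qbar <- colMeans(Q, na.rm = TRUE)
  Wbar <- colMeans(W, na.rm = TRUE)
  B <- apply(Q, 2L, stats::var, na.rm = TRUE)
  B[nImp < 2L] <- 0
  Tvar <- Wbar + (1 + 1 / pmax(nImp, 1L)) * B
  df <- ifelse(B > 0,
               (pmax(nImp, 2L) - 1) *
                 (1 + Wbar / ((1 + 1 / pmax(nImp, 1L)) * B))^2, Inf)
  half <- stats::qt(0.975, df) * sqrt(Tvar)
  data.frame(id = colnames(Q), Qbar = Qbar, Wbar = Wbar, B = B,
             Tvar = Tvar, df = df, lo = Qbar - half, hi = Qbar + half,
             nImp = nImp, stringsAsFactors = FALSE)
}
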