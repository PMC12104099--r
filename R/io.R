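#' Read a sequence panel from CSV
#'
#' Wide format: a header row of time labels, one row per individual, first
#' column the identifier. Long format: columns \code{id}, \code{time},
#' \code{state}. Cells equal to one of \code{missingTokens} (empty cells and
#' \code{"NA"} by default) are read as missing; \code{voidToken} (default
#' \code{"*"}) marks trailing structural padding for ragged panels. Panels
#' containing a fully missing sequence are rejected with a diagnostic naming
#' the sequence.
#'
#' @param path CSV file path.
#' @param format \code{"wide"} or \code{"long"}.
#' @param states optional alphabet (inferred otherwise).
#' @param missingTokens labels read as missing.
#' @param voidToken label read as structural padding.
#' @param covariates optional data.frame of fixed covariates (wide only).
#' @return a \linkS4class{SequencePanel}.
#' @export
readSequencePanel <- function(path, format = c("wide", "long"), states = NULL,
                              missingTokens = c("", "NA"), voidToken = "*",
                              covariates = NULL) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (format == "long") {
    need <- c("id", "time", "state")
    if (!all(need %in% names(df)))
      stop("long format needs columns id, time, state")
    ids <- unique(df$id)
    times <- sort(unique(as.integer(df$time)))
    m <- matrix(NA_character_, length(ids), length(times),
                dimnames = NULL)
    i <- match(df$id, ids)
    j <- match(as.integer(df$time), times)
    m[cbind(i, j)] <- df$state
  } else {
    ids <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    dimnames(m) <- NULL
  }
  void <- !is.na(m) & m == voidToken
  m[void | (!is.na(m) & m %in% missingTokens)] <- NA_character_
  panel <- sequencePanel(m, states = states, ids = ids,
                         covariates = covariates, void = void,
                         missingToken = missingTokens[1L])
  nObs <- rowSums(!is.na(stateCodes(panel)))
  if (any(nObs == 0L))
    stop("rejected at load, sequence(s) fully missing: ",
         paste(seqIDs(panel)[nObs == 0L], collapse = ", "))
  panel
}

#' Write a sequence panel to wide CSV
#'
#' Inverse of \code{\link{readSequencePanel}} (wide format); round-trips are
#' byte-stable for the state labels.
#'
#' @param panel a \linkS4class{SequencePanel}.
#' @param path output file.
#' @param missingToken token written for missing cells (defaults to the
#'   panel's own).
#' @param voidToken token written for structural padding.
#' @export
writeSequencePanel <- function(panel, path, missingToken = NULL,
                               voidToken = "*") {
  mt <- missingToken %||% panel@missingToken
  m <- stateLabels(panel)
  m[is.na(m)] <- mt
  m[voidMask(panel)] <- voidToken
  df <- data.frame(id = seqIDs(panel), m, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("id", paste0("t", seq_len(seqLength(panel))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
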