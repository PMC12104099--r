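#' @import methods
NULL

#' SequencePanel: a panel of categorical state sequences
#'
#' The central container of the package: an n x T matrix of integer state
#' codes (rows are individuals, columns are equally spaced time points),
#' together with the state alphabet, sequence identifiers, optional fixed
#' (time-constant) covariates and an optional structural-padding mask for
#' ragged panels. Missing cells are stored as \code{NA}; structural padding
#' (cells beyond an individual's true sequence length) is flagged in
#' \code{void} and excluded from every statistic and from imputation.
#'
#' @slot codes integer matrix, values in \code{1..length(states)} or \code{NA}.
#' @slot states character vector of distinct state labels; the missing token
#'   is never part of the alphabet.
#' @slot ids character vector of sequence identifiers, one per row.
#' @slot covariates data.frame of fixed per-sequence covariates (0 columns
#'   when absent); categorical columns are used as extra predictors by the
#'   imputation models.
#' @slot void logical matrix marking structural padding; only trailing runs
#'   are allowed.
#' @slot missingToken character scalar used when writing CSV.
#'
#' @export
setClass("SequencePanel",
  representation(codes = "matrix", states = "character", ids = "character",
                 covariates = "data.frame", void = "matrix",
                 missingToken = "character"))

setValidity("SequencePanel", function(object) {
  msg <- character()
  K <- length(object@states)
  if (K < 1L) msg <- c(msg, "alphabet must contain at least one state")
  if (anyDuplicated(object@states))
    msg <- c(msg, "state labels must be distinct")
  if (length(object@missingToken) != 1L)
    msg <- c(msg, "missingToken must be a single string")
  if (object@missingToken %in% object@states)
    msg <- c(msg, "missing token must not be a state label")
  d <- dim(object@codes)
  if (d[1] < 1L || d[2] < 2L)
    msg <- c(msg, "panel needs >= 1 sequence and >= 2 time points")
  if (!is.integer(object@codes))
    msg <- c(msg, "codes must be an integer matrix")
  v <- object@codes[!is.na(object@codes)]
  if (length(v) && (min(v) < 1L || max(v) > K))
    msg <- c(msg, "state codes out of alphabet range")
  if (length(object@ids) != d[1])
    msg <- c(msg, "ids length must equal the number of sequences")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (nrow(object@covariates) && nrow(object@covariates) != d[1])
    msg <- c(msg, "covariates must have one row per sequence")
  if (!identical(dim(object@void), d))
    msg <- c(msg, "void mask must match the panel dimensions")
  if (any(object@void & !is.na(object@codes)))
    msg <- c(msg, "void cells cannot carry a state")
  # only trailing padding is allowed
  if (any(object@void[, 1L])) {
    msg <- c(msg, "a sequence cannot be entirely structural padding")
  } else if (ncol(object@void) > 1L &&
             any(object@void[, -ncol(object@void), drop = FALSE] &
                 !object@void[, -1L, drop = FALSE])) {
    msg <- c(msg, "structural padding must be a trailing run")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SequencePanel
#'
#' @param data matrix or data.frame of state labels (character/factor) or
#'   integer codes; \code{NA} marks missingness.
#' @param states alphabet; inferred from the observed labels when NULL.
#' @param ids sequence identifiers (default \code{"s1"..}).
#' @param covariates optional data.frame of fixed covariates.
#' @param void optional logical matrix of structural padding.
#' @param missingToken token used for missing cells on write.
#' @return a \linkS4class{SequencePanel}.
#' @export
sequencePanel <- function(data, states = NULL, ids = NULL, covariates = NULL,
                          void = NULL, missingToken = "") {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (is.factor(data)) stop("data must be a matrix")
  if (is.character(data)) {
    if (is.null(states)) states <- sort(unique(data[!is.na(data)]))
    codes <- matrix(match(data, states), nrow(data), ncol(data))
    bad <- !is.na(data) & is.na(codes)
    if (any(bad))
      stop("labels not in the alphabet: ",
           paste(unique(data[bad]), collapse = ", "))
  } else {
    codes <- data
    if (is.null(states)) {
      K <- suppressWarnings(max(codes, na.rm = TRUE))
      states <- paste0("S", seq_len(max(K, 1L)))
    }
  }
  storage.mode(codes) <- "integer"
  dimnames(codes) <- NULL
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(codes)))
  if (is.null(covariates))
    covariates <- data.frame(matrix(nrow = nrow(codes), ncol = 0L))
  if (is.null(void)) void <- matrix(FALSE, nrow(codes), ncol(codes))
  codes[void] <- NA_integer_
  new("SequencePanel", codes = codes, states = states,
      ids = as.character(ids), covariates = covariates, void = void,
      missingToken = missingToken)
}

setMethod("show", "SequencePanel", function(object) {
  n <- nrow(object@codes); T <- ncol(object@codes)
  miss <- sum(is.na(object@codes) & !object@void)
  eff <- sum(!object@void)
  cat("SequencePanel:", n, "sequences x", T, "time points\n")
  cat("  alphabet (", length(object@states), "): ",
      paste(object@states, collapse = ", "), "\n", sep = "")
  cat(sprintf("  missing cells: %d (%.1f%%)\n", miss, 100 * miss / eff))
  if (ncol(object@covariates))
    cat("  covariates:", paste(names(object@covariates), collapse = ", "),
        "\n")
  if (any(object@void)) cat("  structural padding present\n")
})

#' MultipleImputation: M completed panels from one incomplete panel
#'
#' @slot panels list of complete \linkS4class{SequencePanel} objects.
#' @slot method character, the imputation algorithm used.
#' @slot config list, the resolved configuration.
#' @slot seed integer master seed (NA when the global stream was used).
#' @slot fitLog data.frame of model fits and fallbacks.
#' @export
setClass("MultipleImputation",
  representation(panels = "list", method = "character", config = "list",
                 seed = "integer", fitLog = "data.frame"))

setValidity("MultipleImputation", function(object) {
  if (!length(object@panels)) return("needs at least one completed panel")
  ok <- vapply(object@panels, function(p) is(p, "SequencePanel"), logical(1))
  if (!all(ok)) return("panels must be SequencePanel objects")
  TRUE
})

setMethod("show", "MultipleImputation", function(object) {
  cat("MultipleImputation:", length(object@panels), "completed panels",
      "(method:", paste0(object@method, ")"), "\n")
  cat("  seed:", object@seed, " model fits:", nrow(object@fitLog), "\n")
})

setMethod("length", "MultipleImputation", function(x) length(x@panels))

#' @export
setMethod("[[", "MultipleImputation", function(x, i) x@panels[[i]])
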