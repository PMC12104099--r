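# Accessor generics and methods for the core classes.

#' Number of sequences in a panel
#' @param x a SequencePanel
#' @export
setGeneric("nSeq", function(x) standardGeneric("nSeq"))
#' @export
setMethod("nSeq", "SequencePanel", function(x) nrow(x@codes))

#' Number of time points (columns) in a panel
#' @param x a SequencePanel
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @export
setMethod("seqLength", "SequencePanel", function(x) ncol(x@codes))

#' State alphabet
#' @param x a SequencePanel
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @export
setMethod("alphabet", "SequencePanel", function(x) x@states)

#' Sequence identifiers
#' @param x a SequencePanel
#' @export
setGeneric("seqIDs", function(x) standardGeneric("seqIDs"))
#' @export
setMethod("seqIDs", "SequencePanel", function(x) x@ids)

#' Integer state-code matrix (NA = missing)
#' @param x a SequencePanel
#' @export
setGeneric("stateCodes", function(x) standardGeneric("stateCodes"))
#' @export
setMethod("stateCodes", "SequencePanel", function(x) x@codes)

#' Character state-label matrix
#' @param x a SequencePanel
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @export
setMethod("stateLabels", "SequencePanel", function(x) {
  m <- matrix(x@states[x@codes], nrow(x@codes), ncol(x@codes))
  m
})

#' Logical mask of missing cells (structural padding excluded)
#' @param x a SequencePanel
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @export
setMethod("missingMask", "SequencePanel", function(x)
  is.na(x@codes) & !x@void)

#' Structural-padding mask
#' @param x a SequencePanel
#' @export
setGeneric("voidMask", function(x) standardGeneric("voidMask"))
#' @export
setMethod("voidMask", "SequencePanel", function(x) x@void)

#' Fixed per-sequence covariates
#' @param x a SequencePanel
#' @export
setGeneric("panelCovariates", function(x) standardGeneric("panelCovariates"))
#' @export
setMethod("panelCovariates", "SequencePanel", function(x) x@covariates)

#' Is every (non-padding) cell observed?
#' @param x a SequencePanel
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))
#' @export
setMethod("isComplete", "SequencePanel", function(x) !any(missingMask(x)))

#' Effective sequence length per row (padding excluded)
#' @param x a SequencePanel
#' @export
setGeneric("effectiveLengths", function(x) standardGeneric("effectiveLengths"))
#' @export
setMethod("effectiveLengths", "SequencePanel", function(x)
  ncol(x@void) - rowSums(x@void))

#' Completed panels of a MultipleImputation
#' @param x a MultipleImputation
#' @export
setGeneric("completedPanels", function(x) standardGeneric("completedPanels"))
#' @export
setMethod("completedPanels", "MultipleImputation", function(x) x@panels)

#' Model-fit log of a MultipleImputation
#' @param x a MultipleImputation
#' @export
setGeneric("fitLog", function(x) standardGeneric("fitLog"))
#' @export
setMethod("fitLog", "MultipleImputation", function(x) x@fitLog)

#' Subset a panel by sequences (rows)
#' @param x a SequencePanel
#' @param i row index
#' @export
setMethod("[", signature(x = "SequencePanel", i = "ANY", j = "missing"),
  function(x, i, j, ..., drop = FALSE) {
    idx <- seq_len(nrow(x@codes))[i]
    cov <- x@covariates[idx, , drop = FALSE]
    rownames(cov) <- NULL
    ids <- x@ids[idx]
    if (anyDuplicated(ids)) ids <- make.unique(ids)
    new("SequencePanel", codes = x@codes[idx, , drop = FALSE],
        states = x@states, ids = ids, covariates = cov,
        void = x@void[idx, , drop = FALSE], missingToken = x@missingToken)
  })

# Internal: replace the code matrix, keeping everything else.
setCodes <- function(panel, codes) {
  storage.mode(codes) <- "integer"
  initialize(panel, codes = codes)
}

# Internal: entry-point guard shared by the imputation algorithms.
checkImputable <- function(panel) {
  mm <- missingMask(panel)
  if (!any(mm)) stop("nothing to impute: the panel is complete")
  obs <- rowSums(!is.na(panel@codes))
  if (any(obs == 0L))
    stop("sequence(s) fully missing: ",
         paste(panel@ids[obs == 0L], collapse = ", "))
  invisible(TRUE)
}
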