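# Internal helpers: seed derivation, fit logging.

# Derive a deterministic 32-bit sub-seed from a master seed and integer tags.
# Linear-congruential mixing keeps every derived seed in [1, 2^31 - 2].
deriveSeed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483563
  for (k in tags) {
    s <- (s * 40014 + as.double(k) + 1) %% 2147483563
  }
  as.integer(s + 1)
}

# Run `expr` under a given seed without disturbing the caller's RNG stream.
# A NULL seed leaves the global stream in charge.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Mutable fit log shared across imputation stages. Records one row per model
# fit (or fallback) so ordering properties and fallback usage are inspectable.
newFitLog <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}

logFit <- function(log, imputation, stage, G, position, np, nf, radius,
                   nRows, kind, fallback = "none") {
  if (is.null(log)) return(invisible(NULL))
  log$rows[[length(log$rows) + 1L]] <- data.frame(
    imputation = imputation, stage = stage, G = G,
    position = if (is.null(position)) NA_integer_ else position,
    np = np, nf = nf,
    radius = if (is.null(radius)) NA_integer_ else radius,
    nRows = nRows, kind = kind, fallback = fallback,
    stringsAsFactors = FALSE)
  invisible(NULL)
}

fitLogTable <- function(log) {
  if (is.null(log) || length(log$rows) == 0L) {
    return(data.frame(imputation = integer(), stage = character(),
                      G = integer(), position = integer(), np = integer(),
                      nf = integer(), radius = integer(), nRows = integer(),
                      kind = character(), fallback = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, log$rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
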