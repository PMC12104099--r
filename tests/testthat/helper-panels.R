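# Fixture builders used across the suite; everything is generated in code.

# Panel from a character matrix (rows = sequences), NA = missing.
chrPanel <- function(..., states = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  sequencePanel(m, states = states)
}

# Single-sequence panel from a character vector.
seqPanel <- function(x, states = NULL) chrPanel(x, states = states)

# Complete stationary first-order Markov panel.
markovPanel <- function(n, T, P, states = NULL, seed = 1,
                        init = rep(1 / nrow(P), nrow(P))) {
  if (is.null(states)) states <- LETTERS[seq_len(nrow(P))]
  generatePanel(generatorSpec(n, T, states, init, P), seed = seed)
}

# Uniform stay-probability matrix.
stayMatrix <- function(K, stay) {
  P <- matrix((1 - stay) / (K - 1), K, K)
  diag(P) <- stay
  P
}

# Deterministic cycle permutation matrix A -> B -> C -> ... -> A.
cycleMatrix <- function(K) {
  P <- matrix(0, K, K)
  for (i in seq_len(K)) P[i, i %% K + 1L] <- 1
  P
}

# Punch missing cells into a complete panel at given (row, col) positions.
punch <- function(panel, rows, cols) {
  codes <- stateCodes(panel)
  codes[cbind(rows, cols)] <- NA_integer_
  seqgaps:::setCodes(panel, codes)
}

# Random MCAR mask (used for structural property tests, not for the
# mechanism-specific generators).
punchRandom <- function(panel, frac, seed) {
  codes <- stateCodes(panel)
  n <- length(codes)
  set.seed(seed)
  drop <- sample.int(n, round(frac * n))
  codes[drop] <- NA_integer_
  # keep every sequence with >= 1 observed cell
  bad <- which(rowSums(!is.na(codes)) == 0L)
  for (i in bad) codes[i, 1L] <- stateCodes(panel)[i, 1L]
  seqgaps:::setCodes(panel, codes)
}
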