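# Variable-length Markov chains: context-tree growing, deviance (context
# algorithm) and probability-ratio (Learn-PSA) pruning, AIC threshold
# selection, and left-to-right gap imputation.
#
# A context is stored most-recent-state-first, so the parent of a node is
# the context with its oldest state dropped (the suffix). Node counts tally
# the next-state distribution given the context; positions without a
# full-depth history contribute to every truncated context they do have.

#' VLMC configuration
#'
#' @param algorithm pruning criterion: \code{"context"} (deviance against a
#'   chi-square quantile) or \code{"learn_psa"} (conditional-probability
#'   ratios).
#' @param thresholds candidate thresholds scanned by AIC selection; defaults
#'   are the quantiles 0.1, 0.05, 0.04, 0.03, 0.02, 0.01, 0.001 for the
#'   context algorithm and the ratios 1, 1.05, 1.1, 1.2, 1.5 for Learn-PSA.
#' @param maxDepth maximum context length.
#' @param tree optional pretrained \code{ContextTree}; when supplied,
#'   imputation uses it directly instead of selecting a model on the
#'   panel's observed subsequences.
#' @export
vlmcConfig <- function(algorithm = c("context", "learn_psa"),
                       thresholds = NULL, maxDepth = 6L, tree = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(thresholds))
    thresholds <- if (algorithm == "context")
      c(0.1, 0.05, 0.04, 0.03, 0.02, 0.01, 0.001)
    else c(1, 1.05, 1.1, 1.2, 1.5)
  if (algorithm == "context" && any(thresholds <= 0 | thresholds >= 1))
    stop("context-algorithm thresholds are chi-square quantiles in (0,1)")
  if (algorithm == "learn_psa" && any(thresholds < 1))
    stop("Learn-PSA ratio thresholds must be >= 1")
  list(algorithm = algorithm, thresholds = thresholds,
       maxDepth = as.integer(maxDepth), tree = tree)
}

#' Split a panel's sequences into observed subsequences
#'
#' Missing-data gaps divide each sequence into maximal observed runs; the
#' VLMC is fitted on the set of all such runs.
#'
#' @param panel a \linkS4class{SequencePanel}.
#' @return list of integer state-code vectors.
#' @export
observedSubsequences <- function(panel) {
  codes <- stateCodes(panel)
  lens <- effectiveLengths(panel)
  out <- list()
  for (i in seq_len(nrow(codes))) {
    x <- codes[i, seq_len(lens[i])]
    r <- rle(is.na(x))
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    for (k in which(!r$values)) out[[length(out) + 1L]] <- x[s[k]:e[k]]
  }
  out
}

#' Grow a context tree
#'
#' Tallies next-state counts for every context of length up to
#' \code{maxDepth} occurring in the subsequences. The root (empty context)
#' counts every position.
#'
#' @param subsequences list of integer code vectors (see
#'   \code{\link{observedSubsequences}}).
#' @param K alphabet size.
#' @param maxDepth maximum context length.
#' @return a \code{ContextTree}: list with \code{keys} (contexts as
#'   dot-joined codes, most recent first; "" = root), \code{counts}
#'   (nodes x K), \code{depth}, \code{parent} (index of the suffix node).
#' @export
growContextTree <- function(subsequences, K, maxDepth = 6L) {
  if (!any(vapply(subsequences, length, integer(1)) >= 2L))
    stop("need at least one observed subsequence of length >= 2")
  env <- new.env(parent = emptyenv())
  bump <- function(key, s) {
    cur <- env[[key]]
    if (is.null(cur)) cur <- integer(K)
    cur[s] <- cur[s] + 1L
    env[[key]] <- cur
  }
  for (x in subsequences) {
    L <- length(x)
    for (i in seq_len(L)) {
      s <- x[i]
      bump("r", s)  # "r" is the root (empty context) key
      d <- 1L
      while (d <= maxDepth && i - d >= 1L) {
        key <- paste(x[(i - 1L):(i - d)], collapse = ".")
        bump(key, s)
        d <- d + 1L
      }
    }
  }
  keys <- ls(env)
  keys <- c("r", setdiff(keys, "r"))
  depth <- ifelse(keys == "r", 0L,
                  lengths(strsplit(keys, ".", fixed = TRUE)))
  ord <- order(depth, keys)
  keys <- keys[ord]; depth <- depth[ord]
  counts <- do.call(rbind, lapply(keys, function(k) env[[k]]))
  parentKey <- vapply(keys, function(k) {
    if (k == "r") return(NA_character_)
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) return("r")
    paste(parts[-length(parts)], collapse = ".")
  }, character(1), USE.NAMES = FALSE)
  parent <- match(parentKey, keys)
  structure(list(keys = keys, counts = counts, depth = depth,
                 parent = parent, K = K, maxDepth = as.integer(maxDepth)),
            class = "ContextTree")
}

#' @export
print.ContextTree <- function(x, ...) {
  cat("ContextTree:", length(x$keys), "contexts, max depth",
      max(x$depth), "of", x$maxDepth, "\n")
  invisible(x)
}

# Internal: per-node deviance against the suffix (parent) distribution:
# 2 * sum_s n(s|c) log( P(s|c) / P(s|parent) ).
nodeDeviance <- function(tree) {
  P <- tree$counts / pmax(rowSums(tree$counts), 1L)
  dev <- numeric(length(tree$keys))
  for (i in seq_along(tree$keys)[-1L]) {
    p <- tree$parent[i]
    nz <- which(tree$counts[i, ] > 0L)
    dev[i] <- 2 * sum(tree$counts[i, nz] *
                        log(P[i, nz] / P[p, nz]))
  }
  dev
}

#' Prune a context tree with the context-algorithm deviance criterion
#'
#' Bottom-up: a node survives iff its deviance against its suffix exceeds
#' the chi-square quantile \code{qchisq(1 - q, K - 1)}, or one of its
#' descendants survives; otherwise it is merged into the suffix.
#'
#' @param tree a grown \code{ContextTree}.
#' @param q chi-square tail quantile in (0, 1).
#' @return the pruned tree.
#' @export
pruneContext <- function(tree, q) {
  thr <- stats::qchisq(1 - q, df = tree$K - 1L)
  dev <- nodeDeviance(tree)
  keepNodes(tree, dev > thr)
}

#' Prune a context tree with the Learn-PSA ratio criterion
#'
#' A node survives iff some next state with positive count has a conditional
#' probability ratio against the suffix of at least \code{r} (or at most
#' 1/r), subject to a minimum-count guard: contexts occurring fewer than
#' \code{minCount} times are pruned regardless. \code{r = 1} keeps every
#' observed context (with >= minCount occurrences).
#'
#' @param tree a grown \code{ContextTree}.
#' @param r ratio threshold >= 1.
#' @param minCount minimum context occurrences.
#' @return the pruned tree.
#' @export
prunePsa <- function(tree, r, minCount = 2L) {
  P <- tree$counts / pmax(rowSums(tree$counts), 1L)
  n <- length(tree$keys)
  sig <- logical(n)
  for (i in seq_len(n)[-1L]) {
    if (sum(tree$counts[i, ]) < minCount) next
    p <- tree$parent[i]
    nz <- which(tree$counts[i, ] > 0L)
    ratio <- P[i, nz] / pmax(P[p, nz], .Machine$double.xmin)
    sig[i] <- any(ratio >= r | ratio <= 1 / r)
  }
  keepNodes(tree, sig)
}

# Internal: close a significance mask upward (ancestors of kept nodes are
# kept; descendants of removed nodes disappear automatically) and subset.
keepNodes <- function(tree, significant) {
  n <- length(tree$keys)
  keep <- significant
  keep[1L] <- TRUE
  # propagate significance to ancestors, deepest first
  for (i in order(tree$depth, decreasing = TRUE)) {
    if (keep[i] && !is.na(tree$parent[i])) keep[tree$parent[i]] <- TRUE
  }
  idx <- which(keep)
  newParent <- match(tree$keys[tree$parent[idx]], tree$keys[idx])
  structure(list(keys = tree$keys[idx],
                 counts = tree$counts[idx, , drop = FALSE],
                 depth = tree$depth[idx], parent = newParent,
                 K = tree$K, maxDepth = tree$maxDepth),
            class = "ContextTree")
}

# Internal: index of the longest context in `tree` matching the history
# vector `h` (chronological order; most recent last).
matchContext <- function(tree, h) {
  best <- 1L
  if (!length(h)) return(best)
  key <- ""
  for (d in seq_len(min(length(h), tree$maxDepth))) {
    key <- if (d == 1L) as.character(h[length(h)])
      else paste(key, h[length(h) - d + 1L], sep = ".")
    i <- match(key, tree$keys)
    if (is.na(i)) break
    best <- i
  }
  best
}

#' Log-likelihood of subsequences under a context tree
#'
#' Each position is scored by the maximum-likelihood next-state distribution
#' of its longest matching context. Also returns the number of distinct
#' prediction contexts used, which is the complexity term of the AIC.
#'
#' @param tree a (pruned) \code{ContextTree}.
#' @param subsequences list of integer code vectors.
#' @return list with \code{logLik} and \code{nContexts}.
#' @export
treeLogLik <- function(tree, subsequences) {
  P <- tree$counts / pmax(rowSums(tree$counts), 1L)
  ll <- 0
  used <- logical(length(tree$keys))
  for (x in subsequences) {
    for (i in seq_along(x)) {
      j <- matchContext(tree, x[seq_len(i - 1L)])
      used[j] <- TRUE
      ll <- ll + log(P[j, x[i]])
    }
  }
  list(logLik = ll, nContexts = sum(used))
}

# Internal: number of terminal contexts of the completed partition. The
# pruned tree's prediction contexts form a complete prefix-free partition
# of the history space: every leaf is one cell, and an internal node with
# c kept children contributes K - c complement cells predicted with its
# own distribution. Each cell carries K - 1 free parameters.
partitionSize <- function(tree) {
  n <- length(tree$keys)
  nKids <- tabulate(tree$parent[!is.na(tree$parent)], nbins = n)
  sum(ifelse(nKids == 0L, 1L, tree$K - nKids))
}

#' Select a VLMC by AIC over candidate thresholds
#'
#' Fits and prunes the context tree at each candidate threshold and returns
#' the model minimising AIC = -2 logLik + 2 k (K - 1), where k is the
#' number of terminal contexts of the completed partition (leaves plus the
#' complement cells of partially split nodes); ties go to the smaller tree.
#'
#' @param subsequences list of integer code vectors.
#' @param K alphabet size.
#' @param config a \code{\link{vlmcConfig}}.
#' @return the selected pruned \code{ContextTree}, with attributes
#'   \code{threshold} and \code{aic}.
#' @export
selectVlmc <- function(subsequences, K, config = vlmcConfig()) {
  full <- growContextTree(subsequences, K, config$maxDepth)
  best <- NULL; bestAic <- Inf; bestSize <- Inf; bestThr <- NA_real_
  for (thr in config$thresholds) {
    pruned <- if (config$algorithm == "context") pruneContext(full, thr)
      else prunePsa(full, thr)
    sc <- treeLogLik(pruned, subsequences)
    aic <- -2 * sc$logLik + 2 * partitionSize(pruned) * (K - 1L)
    size <- length(pruned$keys)
    if (aic < bestAic - 1e-9 ||
        (abs(aic - bestAic) <= 1e-9 && size < bestSize)) {
      best <- pruned; bestAic <- aic; bestSize <- size; bestThr <- thr
    }
  }
  attr(best, "threshold") <- bestThr
  attr(best, "aic") <- bestAic
  best
}

#' Impute gaps with a variable-length Markov chain
#'
#' The VLMC is selected once on the observed subsequences; each imputation
#' then scans every sequence left to right, drawing each missing cell from
#' the tree's next-state distribution given the longest matching context of
#' the observed-plus-imputed prefix (with add-1/K smoothing). A gap's later
#' cells condition on its earlier imputed cells. The first cell of an
#' initial gap (no prefix) is drawn from the panel-wide state distribution.
#' Only past information is ever used.
#'
#' @param panel an incomplete \linkS4class{SequencePanel}.
#' @param config a \code{\link{vlmcConfig}}.
#' @param M number of imputations.
#' @param seed master seed.
#' @return a \linkS4class{MultipleImputation}; the selected tree is stored
#'   in the config.
#' @export
vlmcImpute <- function(panel, config = vlmcConfig(), M = 5L, seed = NULL) {
  stopifnot(M >= 1L)
  checkImputable(panel)
  K <- length(alphabet(panel))
  tree <- config$tree
  if (is.null(tree))
    tree <- selectVlmc(observedSubsequences(panel), K, config)
  # smoothed next-state probabilities per node
  Psm <- (tree$counts + 1 / K) / (rowSums(tree$counts) + 1)
  codes0 <- stateCodes(panel)
  marg <- tabulate(codes0[!is.na(codes0)], nbins = K)
  marg <- marg / sum(marg)
  lens <- effectiveLengths(panel)
  missMask <- missingMask(panel)
  panels <- vector("list", M)
  for (m in seq_len(M)) {
    sm <- if (is.null(seed)) NULL else deriveSeed(seed, 100L + m)
    codes <- withSeed(sm, {
      w <- codes0
      for (i in seq_len(nrow(w))) {
        for (t in which(missMask[i, seq_len(lens[i])])) {
          p <- if (t == 1L) marg
            else Psm[matchContext(tree, w[i, seq_len(t - 1L)]), ]
          w[i, t] <- sampleRows(matrix(p, 1L, K))
        }
      }
      w
    })
    panels[[m]] <- setCodes(panel, codes)
  }
  new("MultipleImputation", panels = panels, method = "vlmc",
      config = c(config, list(M = M, tree = tree)),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      fitLog = fitLogTable(log = NULL))
}
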