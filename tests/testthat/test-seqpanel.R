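# Core panel container, gap typology and descriptive statistics.

test_that("gap typology follows the six-pattern rules", {
  base <- rep(c("A", "B"), length.out = 15)

  s <- base; s[4:7] <- NA
  g <- classifyGaps(seqPanel(s, states = c("A", "B")), np = 2, nf = 2)
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 4L)
  expect_equal(g$end, 7L)
  expect_equal(g$type, "internal")

  expect_equal(nrow(classifyGaps(seqPanel(base), np = 2, nf = 2)), 0L)

  s <- base; s[1:3] <- NA
  expect_equal(classifyGaps(seqPanel(s), 2, 2)$type, "initial")

  s <- base; s[14:15] <- NA
  expect_equal(classifyGaps(seqPanel(s), 2, 2)$type, "terminal")

  s <- base; s[2] <- NA  # one observed cell before, plenty after
  g <- classifyGaps(seqPanel(s), 2, 2)
  expect_equal(g$type, "left_hand")
  expect_equal(g$n_before, 1L)

  s <- base; s[14] <- NA  # only one observed cell after the gap
  expect_equal(classifyGaps(seqPanel(s), 2, 2)$type, "right_hand")

  # two gaps separated by a single observed cell are deficient on the
  # inner sides
  s <- base; s[c(4, 5, 7, 8)] <- NA
  g <- classifyGaps(seqPanel(s), 2, 2)
  expect_equal(g$type, c("right_hand", "left_hand"))

  s <- base; s[c(2, 4, 6, 7)] <- NA
  g <- classifyGaps(seqPanel(s), 2, 2)
  expect_equal(g$type[2], "both_hand")
})

test_that("classifyGaps validates inputs and fully missing sequences", {
  p <- seqPanel(rep(c("A", "B"), 5))
  expect_error(classifyGaps(p, 0, 0))
  m <- rbind(c("A", "B", "A", "B"), c(NA, NA, NA, NA))
  pp <- new("SequencePanel", codes = matrix(match(m, c("A", "B")), 2, 4),
            states = c("A", "B"), ids = c("s1", "s2"),
            covariates = data.frame(matrix(nrow = 2, ncol = 0)),
            void = matrix(FALSE, 2, 4), missingToken = "")
  expect_error(classifyGaps(pp, 1, 1), "s2")
})

test_that("gaps partition the missing cells for random masks", {
  p0 <- markovPanel(20, 12, stayMatrix(3, 0.7), seed = 5)
  for (s in 1:5) {
    p <- punchRandom(p0, 0.3, seed = s)
    g <- classifyGaps(p, 2, 2)
    cells <- unlist(lapply(seq_len(nrow(g)), function(k)
      (g$seq[k] - 1) * 1000 + g$start[k]:g$end[k]))
    expect_false(any(duplicated(cells)))
    mm <- which(missingMask(p), arr.ind = TRUE)
    expect_setequal(cells, (mm[, 1] - 1) * 1000 + mm[, 2])
  }
})

test_that("transition rate matches direct enumeration", {
  expect_equal(transitionRate(seqPanel(rep("A", 6), states = c("A", "B"))), 0)
  expect_equal(transitionRate(seqPanel(rep(c("A", "B"), 5))), 1)
  expect_equal(transitionRate(seqPanel(c("A", "A", "B"))), 0.5)
  # missing cells drop their pairs
  expect_equal(transitionRate(seqPanel(c("A", NA, "B", "B"))), 0)
  expect_error(transitionRate(seqPanel(c("A", NA, NA, "B"))), "pair")
})

test_that("ANV spans its theoretical range", {
  expect_equal(anv(seqPanel(rep("A", 8), states = c("A", "B"))), 1)
  expect_equal(anv(seqPanel(rep(c("A", "B"), 5))), 5)  # L/2 with L = 10
  expect_equal(anv(seqPanel(c("A", "A", "B", "B", "A"))), 1.5)
  expect_error(anv(seqPanel(c("A", NA, "B"))), "complete")
  for (s in 1:5) {
    p <- markovPanel(30, 14, stayMatrix(3, 0.5), seed = s)
    a <- anv(p)
    expect_gte(a, 1)
    expect_lte(a, 14 / 2)
  }
})

test_that("panel statistics are row-permutation invariant", {
  p <- markovPanel(40, 10, stayMatrix(4, 0.6), seed = 9)
  q <- p[rev(seq_len(nSeq(p)))]
  expect_equal(transitionRate(p), transitionRate(q))
  expect_equal(anv(p), anv(q))
})

test_that("spell statistics distinguish absence from zero", {
  p <- seqPanel(c("A", "A", "B"), states = c("A", "B", "C"))
  expect_equal(as.numeric(spellStats(p, "A")), 2)
  expect_equal(as.numeric(spellStats(p, "B")), 1)
  absent <- spellStats(p, "C")
  expect_true(is.na(absent))
  expect_identical(attr(absent, "nSpells"), 0L)
  expect_error(spellStats(p, "Z"), "alphabet")
  expect_equal(as.numeric(spellStats(seqPanel(c("A", "B", "A", "B")), "A")),
               1)
})

test_that("wide CSV IO round-trips and rejects fully missing rows", {
  p <- punchRandom(markovPanel(15, 8, stayMatrix(3, 0.6), seed = 2), 0.2, 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSequencePanel(p, f)
  r <- readSequencePanel(f)
  expect_identical(stateLabels(r), stateLabels(p))
  expect_identical(missingMask(r), missingMask(p))
  # fully missing row rejected with its id
  lines <- readLines(f)
  lines[3] <- paste0("bad", paste(rep(",", 8), collapse = ""))
  writeLines(lines, f)
  expect_error(readSequencePanel(f), "bad")
})

test_that("long CSV converts to wide and padding stays structural", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,state", "u,1,A", "u,2,B", "v,1,B", "v,2,A"), f)
  p <- readSequencePanel(f, format = "long")
  expect_equal(stateLabels(p)[1, ], c("A", "B"))
  expect_equal(seqIDs(p), c("u", "v"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,t1,t2,t3,t4", "u,A,B,A,*", "v,B,,A,B"), f2)
  r <- readSequencePanel(f2)
  expect_equal(effectiveLengths(r), c(3L, 4L))
  expect_true(voidMask(r)[1, 4])
  expect_true(missingMask(r)[2, 2])
  # padding excluded: the v-row gap at t2 is internal; u has no gap
  expect_equal(classifyGaps(r, 1, 1)$seq, 2L)
  # round trip preserves the padding token
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeSequencePanel(r, f3)
  expect_identical(readLines(f3)[2], "u,A,B,A,*")
})

test_that("panel validity catches malformed objects", {
  expect_error(sequencePanel(matrix("A", 1, 1)), "2 time points")
  expect_error(sequencePanel(rbind(c("A", "B")), states = c("A", "B"),
                             missingToken = "A"), "missing token")
  p <- markovPanel(5, 6, stayMatrix(2, 0.5))
  expect_error(sequencePanel(matrix(c("A", "X"), 1, 2), states = "A"), "X")
})
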