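# MICT: displacement windows, staged gap filling, fallbacks, contracts.

test_that("the toy two-sequence panel yields the expected windows", {
  p <- mictExamplePanel()
  g <- classifyGaps(p, 2, 2)
  expect_equal(g[, c("start", "end")],
               data.frame(start = 4L, end = 7L))
  expect_equal(g$type, "internal")

  tw <- buildTrainingWindows(p, G = 4, np = 2, nf = 2)
  expect_equal(length(tw$y), 9L)
  s1 <- tw$seq == 1L
  expect_equal(sum(s1), 1L)       # sequence 1 provides one window
  expect_equal(tw$t[s1], 10L)     # target t = 10
  codes <- stateCodes(p)
  expect_equal(tw$X[s1, ], codes[1, c(8, 9, 14, 15)])  # predictors
  expect_equal(tw$y[s1], codes[1, 10])
  expect_equal(sum(tw$seq == 2L), 8L)  # fully observed row: t = 3..10
  expect_equal(sort(tw$t[tw$seq == 2L]), 3:10)
})

test_that("no window fits when the sequence is too short", {
  p <- markovPanel(5, 7, stayMatrix(2, 0.5), seed = 1)
  tw <- buildTrainingWindows(p, G = 4, np = 2, nf = 2)  # needs T >= 8
  expect_equal(length(tw$y), 0L)
})

test_that("imputation contracts: completeness, mask preservation, seeds", {
  p0 <- markovPanel(80, 12, stayMatrix(3, 0.7), seed = 4)
  p <- punchRandom(p0, 0.25, seed = 8)
  expect_error(mictImpute(p0, mictConfig(np = 1, nf = 1)), "nothing")
  mi <- mictImpute(p, mictConfig(np = 2, nf = 2), M = 3, seed = 42)
  expect_equal(length(mi), 3L)
  obs <- !is.na(stateCodes(p))
  for (m in 1:3) {
    cm <- stateCodes(mi[[m]])
    expect_false(anyNA(cm))
    expect_identical(cm[obs], stateCodes(p)[obs])
  }
  mi2 <- mictImpute(p, mictConfig(np = 2, nf = 2), M = 3, seed = 42)
  expect_identical(lapply(completedPanels(mi), stateCodes),
                   lapply(completedPanels(mi2), stateCodes))
  # different seeds give different imputations
  mi3 <- mictImpute(p, mictConfig(np = 2, nf = 2), M = 1, seed = 43)
  expect_false(identical(stateCodes(mi[[1]]), stateCodes(mi3[[1]])))
})

test_that("one model serves all gaps of the same remaining length", {
  # two internal gaps of lengths 4 and 2: after two reductions of the long
  # gap both remainders share a single length-2 model, so the internal
  # stage fits exactly max(G) = 4 models
  base <- rep(c("A", "B", "A", "A", "B"), 4)
  s1 <- base; s1[6:9] <- NA
  s2 <- base; s2[8:9] <- NA
  extra <- markovPanel(30, 20, stayMatrix(2, 0.6), seed = 3)
  p <- sequencePanel(rbind(rbind(s1, s2), stateLabels(extra)),
                     states = c("A", "B"))
  mi <- mictImpute(p, mictConfig(np = 2, nf = 2), M = 1, seed = 1)
  log <- fitLog(mi)
  internal <- log[log$stage == "internal", ]
  expect_equal(sort(internal$G, decreasing = TRUE), c(4, 3, 2, 1))
  # fit count equals the number of distinct (stage, G, window) combinations
  expect_false(any(duplicated(
    internal[, c("stage", "G", "np", "nf", "position")])))
})

test_that("deterministic periodic dynamics are recovered through a gap", {
  P <- cycleMatrix(3)
  p0 <- markovPanel(60, 12, P, seed = 6)
  p <- punch(p0, rows = 1:20, cols = rep(5:7, length.out = 20))
  cfg <- mictConfig(np = 1, nf = 1, lambda = 1e-4, argmax = TRUE)
  mi <- mictImpute(p, cfg, M = 1, seed = 2)
  expect_identical(stateCodes(mi[[1]]), stateCodes(p0))
})

test_that("initial gaps fill right-to-left and terminal gaps left-to-right", {
  # invertible cycle: each state determines both neighbours, so argmax
  # imputation must reproduce the truth exactly for edge gaps
  P <- cycleMatrix(4)
  p0 <- markovPanel(50, 10, P, seed = 7)
  p <- punch(p0, rows = rep(1:10, each = 2), cols = rep(c(1, 2), 10))
  p <- punch(p, rows = rep(11:20, each = 2), cols = rep(c(9, 10), 10))
  cfg <- mictConfig(np = 2, nf = 2, lambda = 1e-4, argmax = TRUE)
  mi <- mictImpute(p, cfg, M = 1, seed = 3)
  expect_identical(stateCodes(mi[[1]]), stateCodes(p0))
  log <- fitLog(mi)
  expect_true(any(log$stage == "initial"))
  expect_true(any(log$stage == "terminal"))
})

test_that("past-only presets still handle initial gaps via the future side", {
  p0 <- markovPanel(60, 10, stayMatrix(3, 0.7), seed = 9)
  p <- punch(p0, rows = 1:10, cols = rep(1, 10))
  mi <- mictImpute(p, mictConfig(preset = "P1"), M = 1, seed = 4)
  expect_false(anyNA(stateCodes(mi[[1]])))
  log <- fitLog(mi)
  init <- log[log$stage == "initial", ]
  expect_true(all(init$np == 0L) && all(init$nf >= 1L))
})

test_that("edge-constrained gaps use reduced windows", {
  base <- rep(c("A", "B", "B", "A"), 5)
  s1 <- base; s1[2:3] <- NA          # left-hand: one observed before
  s2 <- base; s2[17:18] <- NA        # right-hand: two observed after
  extra <- markovPanel(40, 20, stayMatrix(2, 0.6), seed = 2)
  p <- sequencePanel(rbind(rbind(s1, s2), stateLabels(extra)),
                     states = c("A", "B"))
  g <- classifyGaps(p, np = 2, nf = 3)
  expect_setequal(g$type[1:2], c("left_hand", "right_hand"))
  mi <- mictImpute(p, mictConfig(np = 2, nf = 3), M = 1, seed = 5)
  edge <- fitLog(mi)[fitLog(mi)$stage == "edge", ]
  expect_true(any(edge$np == 1L & edge$nf == 3L))  # left-hand reduced np
  expect_true(any(edge$np == 2L & edge$nf == 2L))  # right-hand reduced nf
  # a panel without edge gaps never enters the edge stage
  p2 <- punch(markovPanel(30, 12, stayMatrix(2, 0.6), seed = 3),
              rows = 1:5, cols = rep(6, 5))
  mi2 <- mictImpute(p2, mictConfig(np = 2, nf = 2), M = 1, seed = 6)
  expect_false(any(fitLog(mi2)$stage == "edge"))
})

test_that("sparse training engages the fallback ladder", {
  # tiny panel: length-3 gap windows cannot reach min_train_rows
  p0 <- markovPanel(6, 8, stayMatrix(2, 0.6), seed = 11)
  p <- punch(p0, rows = 1:2, cols = rep(4:6, each = 2))
  mi <- mictImpute(p, mictConfig(np = 2, nf = 2, minTrainRows = 10),
                   M = 1, seed = 7)
  expect_false(anyNA(stateCodes(mi[[1]])))
  expect_true(any(fitLog(mi)$fallback != "none"))
})

test_that("a stress panel amputed at the missingness cap completes", {
  p0 <- markovPanel(150, 16, stayMatrix(3, 0.75), seed = 13)
  cfg <- amputeConfig("mar", highRiskStates = "A", pStartHi = 0.5,
                      pStartLo = 0.4, pContinue = 0.9,
                      completeFraction = 0)
  ap <- amputeMAR(p0, cfg, seed = 14)
  expect_lte(max(rowMeans(missingMask(ap))), 0.75)
  mi <- mictImpute(ap, mictConfig(np = 2, nf = 2), M = 1, seed = 8)
  expect_false(anyNA(stateCodes(mi[[1]])))
})

test_that("imputed state frequencies track a stationary Markov panel", {
  P <- matrix(c(0.7, 0.2, 0.1,
                0.15, 0.7, 0.15,
                0.1, 0.2, 0.7), 3, 3, byrow = TRUE)
  p0 <- markovPanel(5000, 10, P, seed = 20, init = c(0.36, 0.4, 0.24))
  ap <- amputeMAR(p0, amputeConfig("mar", highRiskStates = "B",
                                   completeFraction = 0.4), seed = 21)
  mi <- mictImpute(ap, mictConfig(np = 1, nf = 1), M = 1, seed = 22)
  f0 <- tabulate(stateCodes(p0), 3) / length(stateCodes(p0))
  f1 <- tabulate(stateCodes(mi[[1]]), 3) / length(stateCodes(mi[[1]]))
  se <- sqrt(f0 * (1 - f0) / length(stateCodes(p0)))
  # imputed cross-sectional frequencies stay within a few binomial SEs of
  # the generator's marginal (cells are dependent, so allow extra slack)
  expect_true(all(abs(f1 - f0) < 6 * se + 0.005))
})
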