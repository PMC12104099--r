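# Missing-data generators: hazard recovery, structural rules, invariances.

test_that("zero hazards leave the panel untouched", {
  p <- markovPanel(100, 12, stayMatrix(3, 0.7), seed = 1)
  cfg <- amputeConfig("mar", highRiskStates = "A", pInitGap = 0,
                      pStartHi = 0, pStartLo = 0, pContinue = 0,
                      completeFraction = 0)
  expect_identical(stateCodes(amputeMAR(p, cfg, seed = 2)), stateCodes(p))
  cfgA <- amputeConfig("attrition", highRiskStates = "A", pAttrHi = 0,
                       pAttrLo = 0, completeFraction = 0)
  expect_identical(stateCodes(amputeAttrition(p, cfgA, seed = 3)),
                   stateCodes(p))
})

test_that("masks only remove information", {
  p <- markovPanel(200, 15, stayMatrix(4, 0.7), seed = 4)
  cfg <- amputeConfig("mar", highRiskStates = c("A", "B"))
  a <- amputeMAR(p, cfg, seed = 5)
  obs <- !is.na(stateCodes(a))
  expect_identical(stateCodes(a)[obs], stateCodes(p)[obs])
})

test_that("gap hazards are recovered empirically with redo disabled", {
  p <- markovPanel(6000, 20, stayMatrix(4, 0.8), seed = 6)
  cfg <- amputeConfig("mar", highRiskStates = "A", completeFraction = 0,
                      enforceRedo = FALSE)
  a <- amputeMAR(p, cfg, seed = 7)
  m <- is.na(stateCodes(a))
  truth <- stateCodes(p)
  # initial-gap rate
  p1 <- mean(m[, 1])
  expect_lt(abs(p1 - 0.06), 3 * sqrt(0.06 * 0.94 / nrow(m)))
  # start hazards conditional on the previous true state
  prevHi <- truth[, -20] == 1L
  atRisk <- !m[, -20]
  startHi <- m[, -1][atRisk & prevHi]
  startLo <- m[, -1][atRisk & !prevHi]
  expect_lt(abs(mean(startHi) - 0.20),
            3 * sqrt(0.2 * 0.8 / length(startHi)))
  expect_lt(abs(mean(startLo) - 0.03),
            3 * sqrt(0.03 * 0.97 / length(startLo)))
  # continuation
  cont <- m[, -1][m[, -20]]
  expect_lt(abs(mean(cont) - 0.66), 3 * sqrt(0.66 * 0.34 / length(cont)))
})

test_that("attrition is a monotone suffix with the stated trigger hazard", {
  p <- markovPanel(8000, 20, stayMatrix(4, 0.8), seed = 8)
  cfg <- amputeConfig("attrition", highRiskStates = "A",
                      completeFraction = 0, enforceRedo = FALSE)
  a <- amputeAttrition(p, cfg, seed = 9)
  m <- is.na(stateCodes(a))
  # monotone: once missing, always missing
  expect_true(all(m[, -1] >= m[, -20]))
  # nothing missing before the middle of the sequence (first trigger: 11)
  expect_true(all(!m[, 1:10]))
  truth <- stateCodes(p)
  eligible <- !m[, 10:19]          # not yet triggered entering t = 11..20
  prevHi <- truth[, 10:19] == 1L
  trig <- m[, 11:20]
  hHi <- mean(trig[eligible & prevHi])
  hLo <- mean(trig[eligible & !prevHi])
  expect_lt(abs(hHi - 0.10), 3 * sqrt(0.1 * 0.9 / sum(eligible & prevHi)))
  expect_lt(abs(hLo - 0.015),
            3 * sqrt(0.015 * 0.985 / sum(eligible & !prevHi)))
})

test_that("protection and the missingness cap hold for every mechanism", {
  p <- markovPanel(500, 16, stayMatrix(3, 0.6), seed = 10)
  for (mech in c("mar", "attrition")) {
    cfg <- amputeConfig(mech, highRiskStates = c("A", "B"), pStartHi = 0.5,
                        pContinue = 0.9, pAttrHi = 0.5)
    a <- ampute(p, cfg, seed = 11)
    mm <- missingMask(a)
    expect_gte(mean(rowSums(mm) == 0), 0.40)
    expect_lte(max(rowMeans(mm)), 0.75)
  }
})

test_that("the small-sample mechanism subsamples exactly smallN cases", {
  p <- markovPanel(900, 14, stayMatrix(3, 0.7), seed = 12)
  cfg <- amputeConfig("small_sample", highRiskStates = "A")
  a <- amputeSmallSample(p, cfg, seed = 13)
  expect_equal(nSeq(a), 200L)
  a2 <- amputeSmallSample(p, cfg, seed = 13)
  expect_identical(stateCodes(a), stateCodes(a2))
  expect_error(
    amputeSmallSample(markovPanel(50, 14, stayMatrix(3, 0.7), seed = 1),
                      cfg), "smallN")
  # smallN = n reduces to plain MAR on a row permutation
  cfgAll <- amputeConfig("small_sample", highRiskStates = "A",
                         smallN = 900L)
  expect_equal(nSeq(amputeSmallSample(p, cfgAll, seed = 14)), 900L)
})

test_that("the mask law ignores labels outside the high-risk set", {
  # swapping two low-risk states in the data leaves the mask unchanged
  # under the same seed
  p <- markovPanel(300, 12, stayMatrix(4, 0.7), seed = 15)
  cfg <- amputeConfig("mar", highRiskStates = "A")
  m1 <- missingMask(amputeMAR(p, cfg, seed = 16))
  codes <- stateCodes(p)
  swapped <- codes
  swapped[codes == 3L] <- 4L
  swapped[codes == 4L] <- 3L
  p2 <- seqgaps:::setCodes(p, swapped)
  m2 <- missingMask(amputeMAR(p2, cfg, seed = 16))
  expect_identical(m1, m2)
})

test_that("impossible redo configurations abort with a diagnostic", {
  p <- markovPanel(30, 12, stayMatrix(2, 0.5), seed = 17)
  cfg <- amputeConfig("mar", highRiskStates = c("A", "B"), pInitGap = 1,
                      pStartHi = 1, pStartLo = 1, pContinue = 1,
                      completeFraction = 0)
  expect_error(amputeMAR(p, cfg, seed = 18), "1000 attempts")
})

test_that("amputation requires complete panels and known states", {
  p <- punch(markovPanel(20, 10, stayMatrix(2, 0.5), seed = 19), 1, 5)
  cfg <- amputeConfig("mar", highRiskStates = "A")
  expect_error(amputeMAR(p, cfg, seed = 20), "complete")
  p2 <- markovPanel(20, 10, stayMatrix(2, 0.5), seed = 21)
  expect_error(amputeMAR(p2, amputeConfig("mar", highRiskStates = "Z"),
                         seed = 22), "Z")
})
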