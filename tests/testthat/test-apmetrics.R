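test_that("APD of an idealized square AP matches its plateau duration", {
  tr <- squareTrace(dur = 300)
  a90 <- apd(tr, 0.9)
  a50 <- apd(tr, 0.5)
  # the instantaneous-step idealization is only representable to one grid
  # interval (2 ms) on the recording grid
  expect_lt(abs(a90 - 300), 2 + 1e-9)
  expect_lt(abs(a50 - 300), 2 + 1e-9)
  expect_false(attr(a90, "did_not_repolarize"))
  expect_lte(as.numeric(a50), as.numeric(a90))
})

test_that("a trace that never repolarizes returns duration plus flag", {
  v <- c(-85, rep(30, 999))  # stuck depolarized
  a <- apd(v, 0.9)
  expect_equal(as.numeric(a), 999 * 2 - 2)  # duration from activation
  expect_true(attr(a, "did_not_repolarize"))
})

test_that("APD is invariant under uniform voltage offset", {
  ds <- makeSurrogateAps(2, surrogateAPParams(noise_sd = 0), seed = 1)
  v <- apTraces(ds)[1, ]
  expect_equal(as.numeric(apd(v, 0.9)), as.numeric(apd(v + 13.7, 0.9)))
  expect_equal(as.numeric(apd(v, 0.5)), as.numeric(apd(v + 13.7, 0.5)))
})

test_that("traces without an upstroke are rejected", {
  expect_error(apd(rep(-85, 1000), 0.9), "upstroke")
})

test_that("maximum repolarization slope separates monotone and EAD beats", {
  mono <- squareTrace(dur = 300)
  # smooth the plateau into a gentle decay so repolarization is monotone
  t <- (0:999) * 2
  mono <- -85 + (mono + 85) * exp(-pmax(t - 2, 0) / 400)
  expect_lt(maxRepolSlope(mono), 0)
  bumped <- withBump(mono, t0 = 200)
  expect_gt(maxRepolSlope(bumped), 0)
  expect_gt(maxRepolSlope(bumped), maxRepolSlope(mono))
})

test_that("EAD detection follows the slope threshold contract", {
  t <- (0:999) * 2
  mono <- -85 + (squareTrace(dur = 300) + 85) * exp(-pmax(t - 2, 0) / 400)
  expect_false(detectEad(mono))
  expect_true(detectEad(withBump(mono, t0 = 200)))
  # flat plateau: |dV/dt| below threshold everywhere after the peak
  flat <- c(-85, rep(30, 400), seq(30, -85, length.out = 599))
  expect_false(detectEad(flat))
})

test_that("beat selection maximizes repolarization slope with late ties", {
  t <- (0:999) * 2
  base <- -85 + (squareTrace(dur = 300) + 85) * exp(-pmax(t - 2, 0) / 400)
  b2 <- withBump(base, t0 = 200, height = 5)
  b3 <- withBump(base, t0 = 200, height = 2)
  series <- syntheticSeries(rbind(base, b2, b3))
  sel <- selectBeat(series, window = c(1, 3))
  expect_equal(sel@beat_index, 2L)            # argmax
  ties <- syntheticSeries(rbind(base, base, base))
  expect_equal(selectBeat(ties, window = c(1, 3))@beat_index, 3L)  # latest
  # the single EAD beat wins the window
  ead_series <- syntheticSeries(rbind(base, withBump(base, 200), base))
  expect_equal(selectBeat(ead_series, window = c(1, 3))@beat_index, 2L)
  expect_error(selectBeat(series, window = c(1, 10)), "exceeds")
})

test_that("biomarker summary is internally consistent", {
  ds <- makeSurrogateAps(2, surrogateAPParams(noise_sd = 0), seed = 3)
  bm <- apBiomarkers(apTraces(ds)[1, ])
  expect_lte(bm$apd50, bm$apd90)
  expect_lt(bm$resting_v, bm$peak_v)
  expect_false(bm$did_not_repolarize)
})
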