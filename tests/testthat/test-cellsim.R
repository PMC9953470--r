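steady <- steadyStateEndo()

test_that("neutral drug scales reproduce the drug-free model exactly", {
  cfg_free <- ordConfig()
  cfg_neutral <- ordConfig(drug_scales = setNames(rep(1, 7), tdpChannels()))
  d1 <- ordDerivatives(steady, cfg_free)
  d2 <- ordDerivatives(steady, cfg_neutral)
  expect_identical(d1$derivs, d2$derivs)
  s1 <- simulateDrug(steady, cfg_free, n_beats = 3)
  s2 <- simulateDrug(steady, cfg_neutral, n_beats = 3)
  expect_identical(s1@v, s2@v)
  expect_identical(s1@final_state, s2@final_state)
})

test_that("a fully blocked channel carries zero current", {
  cfg <- ordConfig(drug_scales = c(IKr = 0))
  mid <- steady; mid["v"] <- -20  # plateau-range potential
  d <- ordDerivatives(mid, cfg)
  expect_equal(unname(d$currents["IKr"]), 0)
  expect_true(abs(ordDerivatives(mid, ordConfig())$currents["IKr"]) > 0)
})

test_that("the converged drug-free state is a pacing fixed point", {
  d <- ordDerivatives(steady, ordConfig(), stim = 0)
  expect_lt(abs(d$derivs["v"]), 1e-2)       # diastolic dV/dt residual
  expect_true(all(abs(d$derivs) < 0.05))
})

test_that("the converged resting potential is physiological", {
  expect_gt(steady["v"], -90)
  expect_lt(steady["v"], -85)
})

test_that("steady-state pacing is deterministic and convergent", {
  st0 <- runToSteady(n_beats = 0)
  expect_identical(unname(st0[seq_along(st0)]), unname(ordInitialState()))
  a <- runToSteady(n_beats = 5)
  b <- runToSteady(n_beats = 5)
  expect_identical(unname(a[1:41]), unname(b[1:41]))
  long <- runToSteady(n_beats = 200)
  norms <- attr(long, "beat_norms")
  expect_lt(norms[200], norms[20])          # convergence monotonicity
})

test_that("paced beats carry 1000 samples and stay physical", {
  cfg <- ordConfig(drug_scales = c(IKr = 0.5))
  series <- simulateDrug(steady, cfg, n_beats = 5)
  expect_equal(ncol(series@v), 1000)
  expect_equal(nBeats(series), 5)
  st <- series@final_state
  gates <- st[setdiff(ordStateNames(),
                      c("v", "nai", "nass", "ki", "kss", "cai", "cass",
                        "cansr", "cajsr", "Jrelnp", "Jrelp", "CaMKt"))]
  expect_true(all(gates >= 0 & gates <= 1))
  conc <- st[c("nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr")]
  expect_true(all(conc > 0))
  expect_true(all(series@v >= -150 & series@v <= 80))
})

test_that("IKr block prolongs the action potential dose-dependently", {
  apd_at <- function(scale) {
    cfg <- ordConfig(drug_scales = c(IKr = scale))
    series <- simulateDrug(steady, cfg, n_beats = 10)
    as.numeric(apd(apTrace(series, 10), 0.9))
  }
  apds <- vapply(c(1, 0.75, 0.5), apd_at, numeric(1))
  expect_true(all(diff(apds) > 0))   # more block, longer APD
  expect_gt(apds[3] - apds[1], 10)   # a physiologically meaningful effect
})

test_that("per-sample drug scales follow the Hill pharmacology", {
  hp <- data.frame(channel = c("IKr", "ICaL"),
                   ic50 = c(2, Inf), hill = c(1.2, 1))
  sc <- drugScalesFromSamples(hp, cmax = 2, multiple = 1)
  expect_equal(unname(sc["IKr"]), 0.5)       # cmax at the IC50
  expect_equal(unname(sc["ICaL"]), 1)        # sentinel leaves channel free
  expect_equal(unname(sc["INa"]), 1)         # unmeasured channel untouched
  sc4 <- drugScalesFromSamples(hp, cmax = 2, multiple = 4)
  expect_true(all(sc4 <= sc))                # monotone in exposure
  none <- data.frame(channel = tdpChannels(), ic50 = Inf, hill = 1)
  expect_equal(unname(drugScalesFromSamples(none, 1, 2)), rep(1, 7))
})

test_that("numerical blowups are reported, not returned", {
  bad <- steady; bad["v"] <- NA_real_
  expect_error(ordDerivatives(bad, ordConfig()))
})
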