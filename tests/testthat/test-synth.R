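test_that("noiseless panels reproduce exact Hill values and round-trip fits", {
  sp <- syntheticDrugSpec("x", "high", list(IKr = c(ic50 = 2, hill = 1.4)),
                          cmax_uM = 1, noise_sd = 0)
  p <- makeDrugPanel(list(sp), seed = 1)
  m <- measurements(p)
  expect_equal(m$block, hillBlock(m$conc_uM, 2, 1.4))
  f <- fitHill(m$conc_uM, m$block)
  expect_equal(unname(f["ic50"]), 2, tolerance = 1e-6)
  expect_equal(unname(f["hill"]), 1.4, tolerance = 1e-6)
})

test_that("panel generation is a pure function of spec and seed", {
  p1 <- defaultPanel(seed = 6)
  p2 <- defaultPanel(seed = 6)
  p3 <- defaultPanel(seed = 7)
  expect_identical(measurements(p1), measurements(p2))
  expect_false(identical(measurements(p1), measurements(p3)))
})

test_that("the default panel encodes the designed risk mechanisms", {
  p <- defaultPanel(seed = 1)
  labs <- riskLabels(p)
  expect_equal(unname(table(labs)), rep(3L, 3), ignore_attr = TRUE)
  m <- measurements(p)
  for (d in drugNames(p)) {
    cm <- cmax(p, d)
    sub <- m[m$drug == d & m$channel == "IKr", ]
    f <- fitHill(sub$conc_uM, sub$block)
    if (labs[d] == "high") {
      # strong selective IKr block: below half conductance at 4x Cmax
      expect_lt(conductanceScale(4 * cm, f["ic50"], f["hill"]), 0.5)
    }
    if (labs[d] == "low") {
      # weak block everywhere: scales above 0.9 at therapeutic exposure
      for (ch in unique(m$channel[m$drug == d])) {
        subc <- m[m$drug == d & m$channel == ch, ]
        fc <- fitHill(subc$conc_uM, subc$block)
        expect_gt(conductanceScale(cm, fc["ic50"], fc["hill"]), 0.9)
      }
    }
  }
  f1 <- tempfile(); f2 <- tempfile()
  writePanelCsv(p, f1, f2)
  back <- readCipaCsv(f1, f2)
  expect_equal(measurements(back), measurements(p))
})

test_that("surrogate AP shapes realize their designed APD and EAD", {
  pars <- surrogateAPParams(noise_sd = 0,
                            ead_probability = c(high = 1, intermediate = 0,
                                                low = 0))
  ds <- makeSurrogateAps(6, pars, seed = 2)
  x <- apTraces(ds)
  y <- riskClass(ds)
  for (cls in tdpRiskLevels()) {
    want <- pars$baseline_apd + pars$apd_shift[[cls]]
    got <- vapply(which(y == cls),
                  function(i) as.numeric(apd(x[i, ], 0.9)), 1)
    expect_true(all(abs(got - want) <= 4))   # within two grid steps
  }
  eads <- vapply(seq_len(ncol(ds)), function(i) detectEad(x[i, ]),
                 logical(1))
  expect_true(all(eads[y == "high"]))
  expect_false(any(eads[y != "high"]))
  # class mean APD90 ordering follows the designed shifts
  mean_apd <- tapply(vapply(seq_len(ncol(ds)),
                            function(i) as.numeric(apd(x[i, ], 0.9)), 1),
                     y, mean)
  expect_true(mean_apd["high"] > mean_apd["intermediate"])
  expect_true(mean_apd["intermediate"] > mean_apd["low"])
})

test_that("surrogate generation is seed-deterministic", {
  a <- makeSurrogateAps(5, seed = 3)
  b <- makeSurrogateAps(5, seed = 3)
  c <- makeSurrogateAps(5, seed = 4)
  expect_identical(apTraces(a), apTraces(b))
  expect_false(identical(apTraces(a), apTraces(c)))
})
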