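test_that("Hill block has the midpoint, limit and sentinel behaviour", {
  for (h in c(0.5, 1, 2, 4.2)) {
    expect_equal(hillBlock(2.7, ic50 = 2.7, hill = h), 0.5)
    expect_equal(conductanceScale(2.7, ic50 = 2.7, hill = h), 0.5)
  }
  expect_equal(hillBlock(3, ic50 = 1, hill = 1), 0.75)
  expect_equal(conductanceScale(3, ic50 = 1, hill = 1), 0.25)
  expect_equal(hillBlock(1, ic50 = Inf, hill = 1), 0)
  expect_equal(conductanceScale(0, ic50 = 1, hill = 1), 1)
  expect_error(hillBlock(0, 1, 1), "positive")
  expect_error(hillBlock(-1, 1, 1), "positive")
  expect_error(conductanceScale(-1, 1, 1), "non-negative")
})

test_that("block and conductance scale are complementary and monotone", {
  d <- 10^seq(-3, 3, length.out = 41)
  for (h in c(0.7, 1, 2.3)) {
    b <- hillBlock(d, ic50 = 1.7, hill = h)
    expect_equal(b + conductanceScale(d, 1.7, h), rep(1, length(d)))
    expect_true(all(diff(b) > 0))          # strictly increasing in D
  }
  # increasing in h for D > IC50
  hs <- c(0.5, 1, 2, 4)
  above <- vapply(hs, function(h) hillBlock(5, 1, h), 1)
  expect_true(all(diff(above) > 0))
})

test_that("Hill fit recovers generating parameters on noiseless data", {
  d <- c(0.1, 1, 10, 100)
  f <- fitHill(d, hillBlock(d, ic50 = 1, hill = 1.2))
  expect_equal(unname(f["ic50"]), 1, tolerance = 1e-6)
  expect_equal(unname(f["hill"]), 1.2, tolerance = 1e-6)
  # invariance of the fit to the concentration scale
  f2 <- fitHill(d * 50, hillBlock(d * 50, ic50 = 50, hill = 0.8))
  expect_equal(unname(f2["ic50"]), 50, tolerance = 1e-4)
})

test_that("Hill fit handles degenerate inputs as specified", {
  expect_equal(unname(fitHill(c(1, 10), c(0, 0))["ic50"]), Inf)
  expect_error(fitHill(c(1, 1, 1), c(0.2, 0.3, 0.4)), "distinct")
  expect_error(fitHill(c(1, 10), c(0.5, 0.5)), "unidentifiable")
})

test_that("Hill fit is accurate under replicate noise", {
  d <- rep(c(1, 5, 25, 125), each = 6)
  blk <- withr::with_seed(42,
    pmin(pmax(hillBlock(d, 10, 2) + rnorm(length(d), 0, 0.01), 0), 1))
  f <- fitHill(d, blk)
  expect_lt(abs(log10(f["ic50"]) - 1), 0.1)
})

test_that("bootstrap returns exactly B samples and is seed-deterministic", {
  d <- rep(c(0.3, 1, 3, 10), each = 4)
  blk <- withr::with_seed(7,
    pmin(pmax(hillBlock(d, 2, 1.3) + rnorm(length(d), 0, 0.03), 0), 1))
  b1 <- bootstrapHill(d, blk, B = 60, seed = 11)
  b2 <- bootstrapHill(d, blk, B = 60, seed = 11)
  b3 <- bootstrapHill(d, blk, B = 60, seed = 12)
  expect_equal(nrow(b1), 60)
  expect_identical(b1, b2)
  expect_false(isTRUE(all.equal(b1$ic50, b3$ic50)))
  expect_true(all(b1$ic50 > 0) && all(b1$hill > 0))
})

test_that("bootstrap on noiseless replicates degenerates to the point fit", {
  d <- rep(c(0.1, 1, 10, 100), each = 3)
  blk <- hillBlock(d, 1, 1.2)
  b <- bootstrapHill(d, blk, B = 25, seed = 5)
  f <- fitHill(d, blk)
  expect_equal(b$ic50, rep(unname(f["ic50"]), 25), tolerance = 1e-8)
  expect_equal(b$hill, rep(unname(f["hill"]), 25), tolerance = 1e-8)
})

test_that("single-replicate designs fall back to a residual bootstrap", {
  d <- c(0.3, 1, 3, 10, 30)
  blk <- withr::with_seed(8,
    pmin(pmax(hillBlock(d, 2, 1) + rnorm(5, 0, 0.02), 0), 1))
  expect_warning(b <- bootstrapHill(d, blk, B = 30, seed = 2), "residual")
  expect_equal(nrow(b), 30)
})

test_that("bootstrap intervals cover the generating IC50", {
  # scaled-down coverage study: the returned set is already trimmed to the
  # central 95% band of the accepted fits, so its span is the bootstrap
  # confidence interval; it should cover the generating IC50 in >= 90% of
  # repetitions
  d <- rep(c(0.5, 2, 8, 32), each = 6)
  seeds <- seq_len(50)
  covered <- vapply(seeds, function(s) {
    blk <- withr::with_seed(1000 + s,
      pmin(pmax(hillBlock(d, 4, 1.5) + rnorm(length(d), 0, 0.03), 0), 1))
    b <- bootstrapHill(d, blk, B = 100, seed = s)
    r <- range(log10(b$ic50))
    r[1] <= log10(4) && log10(4) <= r[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("panel-level bootstrap covers every pair and encodes no-block", {
  panel <- defaultPanel(seed = 3)
  hs <- bootstrapPanel(panel, B = 10, seed = 4)
  s <- hillSamples(hs)
  expect_equal(nrow(s), 9 * 7 * 10)
  # channels never measured carry the no-block sentinel
  un <- s[s$drug == "high1" & s$channel == "INa", ]
  expect_true(all(is.infinite(un$ic50)))
  blocked <- s[s$drug == "high1" & s$channel == "IKr", ]
  expect_true(all(is.finite(blocked$ic50)))
})
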