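test_that("sensitivity and specificity follow their closed forms", {
  expect_equal(unname(sensSpec(tp = 7, fn = 3, tn = 8, fp = 2)),
               c(0.7, 0.8))
  expect_equal(unname(sensSpec(tp = 5, fn = 0, tn = 5, fp = 0)), c(1, 1))
  expect_equal(unname(sensSpec(tp = 0, fn = 5, tn = 0, fp = 5)), c(0, 0))
  expect_error(sensSpec(0, 0, 3, 1), "sensitivity undefined")
  expect_error(sensSpec(3, 1, 0, 0), "specificity undefined")
})

test_that("likelihood ratios are guarded against division by zero", {
  expect_equal(unname(likelihoodRatios(0.9, 0.8)), c(4.5, 0.125))
  expect_equal(unname(likelihoodRatios(0.773, 1.0, eps = 1e-4)),
               c(7730, 0.227))
  expect_equal(unname(likelihoodRatios(0.5, 0.5)), c(1, 1))
  expect_equal(unname(likelihoodRatios(0.6, 0, eps = 1e-4))[2], 4000)
})

test_that("LR+ exceeds one exactly when sensitivity beats 1 - specificity", {
  cases <- withr::with_seed(2, matrix(runif(200), ncol = 2))
  for (i in seq_len(nrow(cases))) {
    sens <- cases[i, 1]; spec <- cases[i, 2]
    lr <- likelihoodRatios(sens, spec)
    expect_equal(unname(lr["lr_plus"]) >= 1, sens >= 1 - spec)
  }
})

test_that("one-vs-rest AUC equals the pair-counting value", {
  # 1 concordant pair of 2 -> 0.5 (brute-force count)
  probs <- cbind(c(0.9, 0.8, 0.1), 0, 0)
  labels <- c("high", "intermediate", "high")
  expect_equal(unname(rocAucOvr(probs, labels)["high"]), 0.5)
  # perfectly separated and all-tied scores
  sep <- cbind(c(0.9, 0.8, 0.2, 0.1), 0, 0)
  lab <- c("high", "high", "intermediate", "low")
  expect_equal(unname(rocAucOvr(sep, lab)["high"]), 1)
  tied <- cbind(rep(0.5, 4), 0, 0)
  expect_equal(unname(rocAucOvr(tied, lab)["high"]), 0.5)
  expect_error(rocAucOvr(probs, rep("high", 3)), "single class")
})

test_that("the rank statistic equals the trapezoidal ROC area", {
  for (rep in 1:20) {
    n <- withr::with_seed(100 + rep, sample(10:200, 1))
    dat <- withr::with_seed(200 + rep, {
      list(scores = round(runif(n), 2),   # rounding forces ties
           pos = runif(n) < 0.4)
    })
    if (!any(dat$pos) || all(dat$pos)) next
    mw <- torsadeNet:::aucMW(dat$scores, dat$pos)
    trap <- trapezoidAuc(dat$scores, dat$pos)
    expect_equal(mw, trap, tolerance = 1e-12)
  }
})

test_that("an oracle model scores perfectly with degenerate intervals", {
  ds <- makeSurrogateAps(30, seed = 7)
  rep_ <- repeatedTest(oracleModel(ds), ds, n_repeats = 50, per_drug = 10,
                       seed = 3)
  m <- evalMetrics(rep_)
  for (mm in c("auc", "sensitivity", "specificity")) {
    sub <- m[m$metric == mm, ]
    expect_equal(sub$point, rep(1, 3))
    expect_equal(sub$ci_lo, sub$ci_hi)
  }
  expect_equal(unname(diag(confusionMatrix(rep_))), rep(1, 3))
})

test_that("an uninformative model brackets AUC 0.5", {
  ds <- makeSurrogateAps(40, seed = 8)
  rep_ <- repeatedTest(randomModel(ncol(ds)), ds, n_repeats = 200,
                       per_drug = 20, seed = 4)
  m <- evalMetrics(rep_)
  auc <- m[m$metric == "auc", ]
  expect_true(all(auc$ci_lo <= 0.5 & 0.5 <= auc$ci_hi))
})

test_that("repeated testing is seed-deterministic and guards pool sizes", {
  ds <- makeSurrogateAps(12, seed = 9)
  r1 <- repeatedTest(oracleModel(ds), ds, n_repeats = 20, per_drug = 5,
                     seed = 11)
  r2 <- repeatedTest(oracleModel(ds), ds, n_repeats = 20, per_drug = 5,
                     seed = 11)
  expect_identical(evalMetrics(r1), evalMetrics(r2))
  expect_error(repeatedTest(oracleModel(ds), ds, n_repeats = 2,
                            per_drug = 50, seed = 1), "surr_high")
})

test_that("more repeats stabilize the report's point estimates", {
  # the interval is a percentile summary of the per-repeat sampling
  # distribution (its width converges to that spread), while the point
  # estimate is a Monte-Carlo mean whose seed-to-seed variability shrinks
  # as repeats grow; assert the latter convergence property
  ds <- makeSurrogateAps(40, seed = 12)
  noisy <- local({
    oh <- oneHotRisk(ds)
    p <- withr::with_seed(13, oh + 2 * matrix(runif(length(oh)), nrow(oh)))
    p <- p / rowSums(p)
    function(x) p
  })
  point_sd <- function(nrep) {
    pts <- vapply(1:6, function(s) {
      m <- evalMetrics(repeatedTest(noisy, ds, n_repeats = nrep,
                                    per_drug = 15, seed = 100 + s))
      mean(m$point[m$metric == "auc"])
    }, numeric(1))
    sd(pts)
  }
  expect_lt(point_sd(400), point_sd(50))
})
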