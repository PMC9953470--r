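# Compact stand-in traces: dataset assembly is trace-length agnostic, so
# counting tests use short traces to stay light.
fakeTraces <- function(n_drugs, per_drug, len = 8, prefix = "d") {
  n <- n_drugs * per_drug
  meta <- data.frame(
    drug = rep(paste0(prefix, seq_len(n_drugs)), each = per_drug),
    hill_sample = rep(seq_len(per_drug %/% 4), times = n_drugs * 4)[1:n],
    cmax_multiple = rep(rep(1:4, each = per_drug / 4), times = n_drugs))
  list(x = matrix(seq_len(n * len) %% 97, n, len), meta = meta)
}

fakeLabels <- function(n_drugs, prefix = "d") {
  setNames(rep(tdpRiskLevels(), length.out = n_drugs),
           paste0(prefix, seq_len(n_drugs)))
}

test_that("assembly reproduces the protocol dataset sizes", {
  f <- fakeTraces(12, 2000)
  ds <- assembleAPDataset(f$x, f$meta, fakeLabels(12))
  expect_equal(ncol(ds), 24000)     # 12 training drugs x 2000 shapes
  f16 <- fakeTraces(16, 2000)
  ds16 <- assembleAPDataset(f16$x, f16$meta, fakeLabels(16))
  expect_equal(ncol(ds16), 32000)   # 16 test drugs x 2000 shapes
  sub <- assembleAPDataset(f$x, f$meta, fakeLabels(12),
                           subsample_per_drug = 500, seed = 1)
  expect_equal(ncol(sub), 6000)     # 500-per-drug subsample
})

test_that("per-drug pools carry all four Cmax multiples or fail loudly", {
  f <- fakeTraces(2, 80)
  drop <- !(f$meta$drug == "d2" & f$meta$cmax_multiple == 3)
  expect_error(
    assembleAPDataset(f$x[drop, ], f$meta[drop, ], fakeLabels(2)),
    "d2.*3")
  ds <- assembleAPDataset(f$x, f$meta, fakeLabels(2))
  expect_equal(ncol(ds), 160)
})

test_that("subsampling is deterministic by seed and sized exactly", {
  f <- fakeTraces(3, 40)
  a <- assembleAPDataset(f$x, f$meta, fakeLabels(3),
                         subsample_per_drug = 12, seed = 9)
  b <- assembleAPDataset(f$x, f$meta, fakeLabels(3),
                         subsample_per_drug = 12, seed = 9)
  c <- assembleAPDataset(f$x, f$meta, fakeLabels(3),
                         subsample_per_drug = 12, seed = 10)
  expect_identical(apTraces(a), apTraces(b))
  expect_false(identical(apTraces(a), apTraces(c)))
  expect_equal(unname(table(SummarizedExperiment::colData(a)$drug)),
               rep(12L, 3), ignore_attr = TRUE)
})

test_that("one-hot labels are exact and rows sum to one", {
  f <- fakeTraces(3, 8)
  ds <- assembleAPDataset(f$x, f$meta, fakeLabels(3))
  oh <- oneHotRisk(ds)
  expect_equal(rowSums(oh), rep(1, 24))
  expect_equal(colnames(oh), tdpRiskLevels())
  expect_equal(oh[cbind(1:24, as.integer(riskClass(ds)))], rep(1, 24))
})

test_that("stratified folds partition the samples evenly", {
  y <- factor(rep(tdpRiskLevels(), times = c(8000, 8000, 8000)),
              levels = tdpRiskLevels())
  fold <- makeFolds(y, k = 10, seed = 1)
  expect_equal(unname(table(fold)), rep(2400L, 10), ignore_attr = TRUE)
  # stratification: per-fold class counts within one of balance
  tab <- table(fold, y)
  expect_true(all(abs(tab - 800) <= 1))
  expect_identical(fold, makeFolds(y, k = 10, seed = 1))
  expect_false(identical(fold, makeFolds(y, k = 10, seed = 2)))
  # every sample in exactly one fold
  expect_true(all(fold %in% 1:10))
  expect_equal(length(fold), 24000)
})

test_that("fold construction balances uneven class sizes too", {
  y <- factor(rep(tdpRiskLevels(), times = c(23, 37, 11)),
              levels = tdpRiskLevels())
  fold <- makeFolds(y, k = 5, seed = 3)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  tab <- table(fold, y)
  for (cls in 1:3) expect_lte(max(tab[, cls]) - min(tab[, cls]), 1)
  expect_error(makeFolds(y[1:3], k = 5), "exceeds")
})
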