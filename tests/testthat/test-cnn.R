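test_that("valid-convolution output lengths follow the floor formula", {
  expect_equal(layerOutLen(1000, 32, 2), 485L)
  expect_equal(layerOutLen(10, 3, 1), 8L)
  for (L in c(5, 17, 100)) expect_equal(layerOutLen(L, 1, 1), as.integer(L))
  expect_error(layerOutLen(10, 11, 1), "exceeds")
})

test_that("the default architecture realizes both printed anchors", {
  a <- cnnArchitecture()
  expect_equal(a$chain, c(1000, 485, 482, 234, 114, 107))
  expect_equal(a$n_features, 214L)
  expect_equal(a$hidden, 5L)
  expect_equal(a$classes, 3L)
  expect_equal(a$dropout, 0.2)
})

test_that("architectures missing the anchors fail loudly with the chain", {
  err <- expect_error(cnnArchitecture(pool_strides = c(2, 2)), "chain")
  expect_match(conditionMessage(err), "214")
  expect_error(cnnArchitecture(conv_strides = c(3, 2, 1)), "485")
  # alternates are constructible when the anchors are waived
  alt <- cnnArchitecture(pool_strides = c(2, 2), expect_conv1 = NULL,
                         expect_features = NULL)
  expect_true(alt$n_features != 214L)
})

test_that("initialization is seeded and the forward pass is a softmax", {
  n1 <- initConvNet(seed = 4)
  n2 <- initConvNet(seed = 4)
  n3 <- initConvNet(seed = 5)
  expect_identical(n1@params, n2@params)
  expect_false(identical(n1@params, n3@params))
  x <- matrix(rnorm(4 * 1000), 4)
  p <- predictRisk(n1, x)
  expect_equal(rowSums(p[, 1:3]), rep(1, 4), tolerance = 1e-9)
  # zeroed final layer: exact uniform posterior
  n0 <- n1
  n0@params$W5[] <- 0; n0@params$b5[] <- 0
  p0 <- predictRisk(n0, x)
  expect_equal(unlist(p0[, 1:3]), rep(1 / 3, 12), ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences", {
  arch <- cnnArchitecture()
  params <- torsadeNet:::initParams(arch, seed = 2)
  x <- withr::with_seed(3, matrix(rnorm(4 * 1000, -40, 30), 4))
  y <- diag(3)[c(1, 2, 3, 1), ]
  fwd <- function(p) {
    .Call <- get(".cnn_batch_cpp", envir = asNamespace("torsadeNet"))
    .Call(x, y, p, arch, c(0, 0), c(1, 1), TRUE, numeric(0), TRUE)
  }
  res <- fwd(params)
  flat <- torsadeNet:::flattenParams(params)
  gflat <- torsadeNet:::flattenParams(res$grads)
  idx <- withr::with_seed(4, sample(length(flat), 40))
  h <- 1e-6
  for (i in idx) {
    up <- flat; up[i] <- up[i] + h
    dn <- flat; dn[i] <- dn[i] - h
    lu <- fwd(torsadeNet:::unflattenParams(up, params))$loss
    ld <- fwd(torsadeNet:::unflattenParams(dn, params))$loss
    num <- (lu - ld) / (2 * h)
    expect_equal(gflat[i], num, tolerance = 1e-4)
  }
})

test_that("the classifier overfits a separable surrogate set", {
  ds <- makeSurrogateAps(100, seed = 11)
  net <- trainConvNet(ds, epochs = 30, folds = 0, seed = 1)
  hist <- net@history
  expect_gte(hist$accuracy[nrow(hist)], 0.95)
  # descent sanity: first-epoch loss already beats the untrained loss
  expect_lt(hist$loss[1], log(3))
  expect_lt(hist$loss[nrow(hist)], hist$loss[1])
})

test_that("validation AUC on held-out surrogates is high for every class", {
  aucs <- sapply(1:3, function(s) {
    ds <- makeSurrogateAps(60, seed = 20 + s)
    fold <- makeFolds(ds, k = 4, seed = s)
    tr <- fold != 1
    x <- apTraces(ds)
    dtr <- ds[, tr]
    net <- trainConvNet(dtr, epochs = 20, folds = 0, seed = s)
    pr <- predictRisk(net, x[!tr, , drop = FALSE])
    rocAucOvr(as.matrix(pr[, 1:3]), riskClass(ds)[!tr])
  })
  expect_true(all(rowMeans(aucs) >= 0.9))
})

test_that("permuted labels yield chance-level validation accuracy", {
  ds <- makeSurrogateAps(60, seed = 31)
  cd <- SummarizedExperiment::colData(ds)
  cd$risk <- withr::with_seed(5, sample(cd$risk))
  SummarizedExperiment::colData(ds) <- cd
  fold <- makeFolds(ds, k = 3, seed = 2)
  tr <- fold != 1
  net <- trainConvNet(ds[, tr], epochs = 10, folds = 0, seed = 3)
  pr <- predictRisk(net, apTraces(ds)[!tr, , drop = FALSE])
  acc <- mean(as.character(pr$label) ==
                as.character(riskClass(ds)[!tr]))
  expect_gt(acc, 1 / 3 - 0.1)
  expect_lt(acc, 1 / 3 + 0.1)
})

test_that("inference is deterministic, batch-invariant and shape-strict", {
  net <- trainConvNet(makeSurrogateAps(20, seed = 41), epochs = 3,
                      folds = 0, seed = 2)
  x <- apTraces(makeSurrogateAps(5, seed = 42))
  p1 <- predictRisk(net, x)
  p2 <- predictRisk(net, x)
  expect_identical(p1, p2)
  singles <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    predictRisk(net, x[i, , drop = FALSE])[, 1:3]
  }))
  expect_equal(as.matrix(p1[, 1:3]), as.matrix(singles), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_error(predictRisk(net, x[, 1:999]), "999")
})

test_that("cross-validated training records per-fold histories", {
  ds <- makeSurrogateAps(24, seed = 51)
  net <- trainConvNet(ds, epochs = 2, folds = 3, seed = 1)
  expect_true(net@trained)
  h <- net@history
  expect_setequal(unique(h$fold), c(0, 1, 2, 3))
  expect_true(all(is.finite(h$val_loss[h$fold > 0])))
  expect_error(trainConvNet(ds[, riskClass(ds) == "high"],
                            epochs = 1, folds = 0), "single class")
})
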