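#' @include dataset.R
NULL

#' Output length of a valid (no-padding) convolution or pooling layer
#'
#' \code{floor((in_len - kernel) / stride) + 1}; e.g. a kernel of 32 moved
#' every two strides over a 1000-point trace yields 485 outputs.
#'
#' @param in_len input length.
#' @param kernel kernel (or pool) size; must not exceed \code{in_len}.
#' @param stride stride, >= 1.
#' @return Positive integer output length.
#' @export
#' @examples
#' layerOutLen(1000, 32, 2)  # 485
layerOutLen <- function(in_len, kernel, stride) {
  stopifnot(stride >= 1)
  if (kernel > in_len)
    stop("kernel size ", kernel, " exceeds input length ", in_len)
  as.integer(floor((in_len - kernel) / stride) + 1)
}

#' Architecture of the AP-shape risk classifier
#'
#' Three 1D convolutional layers with two filters each (kernels 32, 16, 8),
#' batch normalization after the first convolution, max pooling after the
#' first and second convolution groups, 20 percent dropout between the
#' second convolution and its pool, a five-node ReLU hidden layer and a
#' three-class softmax output. The default geometry is the unique chain
#' consistent with the two printed anchors of the design: a first-layer
#' output of 485 and 214 flattened features
#' (1000 -> 485 -> 482 -> 234 -> 114 -> 107, times two filters = 214).
#' Construction fails loudly, printing the per-layer chain, whenever the
#' chain misses the expected anchors.
#'
#' @param input_len trace length (1000 points at the 2 ms grid).
#' @param conv_kernels,conv_strides kernel sizes and strides of the three
#'   convolutions.
#' @param pool_sizes,pool_strides geometry of the two max-pooling layers.
#' @param hidden hidden-layer width.
#' @param classes number of output classes.
#' @param dropout dropout rate applied after the second convolution.
#' @param expect_conv1,expect_features expected first-convolution output
#'   length and flattened feature count; set to NULL to build an
#'   unconstrained variant.
#' @return A list describing the architecture, including the per-layer
#'   length \code{chain} and \code{n_features}.
#' @export
#' @examples
#' a <- cnnArchitecture()
#' a$chain       # 1000 485 482 234 114 107
#' a$n_features  # 214
cnnArchitecture <- function(input_len = 1000,
                            conv_kernels = c(32, 16, 8),
                            conv_strides = c(2, 2, 1),
                            pool_sizes = c(4, 8),
                            pool_strides = c(1, 2),
                            hidden = 5, classes = 3, dropout = 0.2,
                            expect_conv1 = 485, expect_features = 214) {
  L1 <- layerOutLen(input_len, conv_kernels[1], conv_strides[1])
  Q1 <- layerOutLen(L1, pool_sizes[1], pool_strides[1])
  L2 <- layerOutLen(Q1, conv_kernels[2], conv_strides[2])
  Q2 <- layerOutLen(L2, pool_sizes[2], pool_strides[2])
  L3 <- layerOutLen(Q2, conv_kernels[3], conv_strides[3])
  chain <- c(input_len, L1, Q1, L2, Q2, L3)
  n_features <- 2L * L3
  fail <- function(what, got, want) {
    stop("architecture ", what, " is ", got, ", expected ", want,
         "; layer length chain: ", paste(chain, collapse = " -> "),
         ", x2 filters = ", n_features, " features")
  }
  if (!is.null(expect_conv1) && L1 != expect_conv1)
    fail("conv1 output length", L1, expect_conv1)
  if (!is.null(expect_features) && n_features != expect_features)
    fail("flattened feature count", n_features, expect_features)
  list(input_len = as.integer(input_len),
       k1 = as.integer(conv_kernels[1]), s1 = as.integer(conv_strides[1]),
       p1 = as.integer(pool_sizes[1]), ps1 = as.integer(pool_strides[1]),
       k2 = as.integer(conv_kernels[2]), s2 = as.integer(conv_strides[2]),
       p2 = as.integer(pool_sizes[2]), ps2 = as.integer(pool_strides[2]),
       k3 = as.integer(conv_kernels[3]), s3 = as.integer(conv_strides[3]),
       hidden = as.integer(hidden), classes = as.integer(classes),
       dropout = dropout, chain = chain, n_features = n_features)
}

# He-uniform style seeded initialization of all weight arrays.
initParams <- function(arch, seed) {
  withLocalSeed(seed, {
    he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
    L3 <- arch$chain[6]
    list(
      W1 = matrix(he(arch$k1, 2 * arch$k1), 2, arch$k1),
      b1 = numeric(2),
      gamma = rep(1, 2), beta = numeric(2),
      W2 = he(2 * arch$k2, 2 * 2 * arch$k2),
      b2 = numeric(2),
      W3 = he(2 * arch$k3, 2 * 2 * arch$k3),
      b3 = numeric(2),
      W4 = matrix(he(arch$n_features, arch$hidden * arch$n_features),
                  arch$hidden, arch$n_features),
      b4 = numeric(arch$hidden),
      W5 = matrix(he(arch$hidden, arch$classes * arch$hidden),
                  arch$classes, arch$hidden),
      b5 = numeric(arch$classes))
  })
}

#' Initialize an untrained classifier
#'
#' @param arch architecture from [cnnArchitecture()].
#' @param seed integer seed for the weight initialization.
#' @return A \linkS4class{ConvNet}.
#' @export
initConvNet <- function(arch = cnnArchitecture(), seed = 1) {
  new("ConvNet", arch = arch, params = initParams(arch, seed),
      bn = list(mean = c(0, 0), var = c(1, 1)), trained = FALSE,
      history = data.frame(), seed = as.integer(seed))
}

flattenParams <- function(p) unlist(p, use.names = FALSE)

unflattenParams <- function(vec, template) {
  out <- template
  pos <- 1
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- vec[pos:(pos + n - 1)]
    if (is.matrix(template[[nm]]))
      v <- matrix(v, nrow(template[[nm]]), ncol(template[[nm]]))
    out[[nm]] <- v
    pos <- pos + n
  }
  out
}

# One training run over `idx` (Adam, fixed geometry); returns params, bn
# state and per-epoch history including metrics on `val_idx` when given.
trainOnce <- function(x, y, arch, params, epochs, lr, batch_size, seed,
                      val_x = NULL, val_y = NULL) {
  theta <- flattenParams(params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  bn_mean <- c(0, 0); bn_var <- c(1, 1); bn_momentum <- 0.1
  t_step <- 0
  n <- nrow(x)
  L2 <- arch$chain[4]
  hist <- vector("list", epochs)
  withLocalSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, n)]
        nb <- length(bi)
        mask <- if (arch$dropout > 0) {
          keep <- 1 - arch$dropout
          (stats::runif(nb * 2 * L2) < keep) / keep
        } else numeric(0)
        params <- unflattenParams(theta, params)
        res <- .cnn_batch_cpp(x[bi, , drop = FALSE],
                              y[bi, , drop = FALSE], params, arch,
                              bn_mean, bn_var, TRUE, mask, TRUE)
        g <- flattenParams(res$grads)
        t_step <- t_step + 1
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        mhat <- m / (1 - beta1^t_step)
        vhat <- v / (1 - beta2^t_step)
        theta <- theta - lr * mhat / (sqrt(vhat) + adam_eps)
        bn_mean <- (1 - bn_momentum) * bn_mean + bn_momentum * res$bn_mean
        bn_var <- (1 - bn_momentum) * bn_var + bn_momentum * res$bn_var
        ep_loss <- ep_loss + res$loss * nb
        pred <- max.col(res$probs, ties.method = "first")
        truth <- max.col(y[bi, , drop = FALSE], ties.method = "first")
        ep_correct <- ep_correct + sum(pred == truth)
      }
      row <- data.frame(epoch = ep, loss = ep_loss / n,
                        accuracy = ep_correct / n,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(val_x)) {
        params <- unflattenParams(theta, params)
        pv <- .cnn_batch_cpp(val_x, val_y, params, arch, bn_mean, bn_var,
                             FALSE, numeric(0), FALSE)
        predv <- max.col(pv$probs, ties.method = "first")
        truthv <- max.col(val_y, ties.method = "first")
        row$val_loss <- pv$loss
        row$val_accuracy <- mean(predv == truthv)
      }
      hist[[ep]] <- row
    }
  })
  list(params = unflattenParams(theta, params),
       bn = list(mean = bn_mean, var = bn_var),
       history = do.call(rbind, hist))
}

#' Train the risk classifier
#'
#' Trains with categorical cross-entropy and Adam (learning rate 0.01 in
#' the production protocol) for a fixed number of epochs. When
#' \code{folds > 1}, k-fold cross-validation is run first (stratified by
#' class), recording per-fold validation loss and accuracy per epoch, and
#' the final model is then retrained on all the data; \code{folds <= 1}
#' trains directly. Deterministic for a given seed.
#'
#' @param ds an \linkS4class{APDataset}.
#' @param epochs training epochs (production: 100).
#' @param lr Adam learning rate.
#' @param folds cross-validation folds (production: 10); <= 1 disables CV.
#' @param batch_size minibatch size.
#' @param seed integer seed (initialization, fold split, minibatch order,
#'   dropout).
#' @param arch architecture from [cnnArchitecture()].
#' @return A trained \linkS4class{ConvNet}; the \code{history} slot holds
#'   per-epoch rows with a \code{fold} column (\code{0} = final fit).
#' @export
trainConvNet <- function(ds, epochs = 100, lr = 0.01, folds = 10,
                         batch_size = 32, seed = 1,
                         arch = cnnArchitecture()) {
  x <- apTraces(ds)
  if (ncol(x) != arch$input_len)
    stop("traces have ", ncol(x), " points; the architecture expects ",
         arch$input_len)
  y <- oneHotRisk(ds)
  if (length(unique(max.col(y))) < 2)
    stop("training labels cover a single class")
  seeds <- deriveSeeds(seed, folds + 2)
  history <- list()
  params0 <- initParams(arch, seeds[1])
  if (folds > 1) {
    fold_id <- makeFolds(ds, k = folds, seed = seeds[2])
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      res <- trainOnce(x[tr, , drop = FALSE], y[tr, , drop = FALSE], arch,
                       params0, epochs, lr, batch_size, seeds[2 + f],
                       val_x = x[!tr, , drop = FALSE],
                       val_y = y[!tr, , drop = FALSE])
      history[[length(history) + 1]] <- cbind(fold = f, res$history)
    }
  }
  final <- trainOnce(x, y, arch, params0, epochs, lr, batch_size, seeds[2])
  history[[length(history) + 1]] <- cbind(fold = 0, final$history)
  new("ConvNet", arch = arch, params = final$params, bn = final$bn,
      trained = TRUE, history = do.call(rbind, history),
      seed = as.integer(seed))
}

#' Predict risk-class probabilities for AP shapes
#'
#' Inference is deterministic: dropout is disabled and batch normalization
#' uses the moving averages accumulated during training. Inputs of any
#' length other than the architecture's trace length are rejected, never
#' cropped.
#'
#' @param model a \linkS4class{ConvNet}.
#' @param traces numeric matrix [n x input_len] (or an
#'   \linkS4class{APDataset}).
#' @return data.frame with columns \code{p_high}, \code{p_intermediate},
#'   \code{p_low} (rows sum to 1) and \code{label} (argmax class).
#' @export
predictRisk <- function(model, traces) {
  if (is(traces, "APDataset")) traces <- apTraces(traces)
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  if (ncol(traces) != model@arch$input_len)
    stop("traces have ", ncol(traces), " points; the model expects ",
         model@arch$input_len)
  res <- .cnn_batch_cpp(traces, matrix(0, 0, 3), model@params, model@arch,
                        model@bn$mean, model@bn$var, FALSE, numeric(0),
                        FALSE)
  p <- res$probs
  colnames(p) <- tdpRiskLevels()
  data.frame(p_high = p[, 1], p_intermediate = p[, 2], p_low = p[, 3],
             label = factor(tdpRiskLevels()[max.col(p, ties.method = "first")],
                            levels = tdpRiskLevels()))
}

setMethod("show", "ConvNet", function(object) {
  a <- object@arch
  cat("ConvNet (1D):", paste(a$chain, collapse = " -> "), "x2 filters =",
      a$n_features, "features ->", a$hidden, "->", a$classes, "\n")
  cat("  ", if (object@trained) "trained" else "untrained",
      "(seed", object@seed, ")\n")
})
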