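# Shared fixtures and independent oracles for the suite.

# Toy measured panel: one drug, one channel, noiseless Hill values.
toyPanel <- function() {
  conc <- rep(c(0.1, 1, 10), each = 2)
  m <- data.frame(drug = "d1", channel = "IKr", conc_uM = conc,
                  block = hillBlock(conc, ic50 = 1, hill = 1))
  d <- data.frame(drug = "d1", cmax_uM = 1, risk = "high")
  DoseResponsePanel(m, d)
}

# Idealized square AP on the 2 ms grid: rest, instantaneous upstroke to
# +40 mV, constant plateau to `dur` ms, instantaneous return to rest.
squareTrace <- function(dur = 300, rest = -85, peak = 40, n = 1000, dt = 2) {
  t <- (seq_len(n) - 1) * dt
  v <- rep(rest, n)
  v[t >= dt & t <= dur] <- peak
  v
}

# Inserts a triangular depolarizing bump (peaking at `height` mV) of
# `width` ms starting at time t0; the rising flank spans several samples so
# dV/dt stays positive over consecutive points, as a real EAD upstroke does.
withBump <- function(v, t0, height = 10, width = 20, dt = 2) {
  i <- seq(t0 / dt + 1, (t0 + width) / dt)
  frac <- seq_along(i) / length(i)
  v[i] <- v[i] + height * (1 - abs(2 * frac - 1))
  v
}

# Wrap a matrix of beats into a BeatSeries (synthetic, for beat selection).
syntheticSeries <- function(vmat) {
  new("BeatSeries", v = vmat, final_state = ordInitialState(),
      beat_norms = numeric(nrow(vmat)), config = ordConfig())
}

# Independent AUC oracle: trapezoidal area under the empirical ROC curve.
trapezoidAuc <- function(scores, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(s) mean(scores[positive] >= s), 1), 1)
  fpr <- c(0, vapply(thr, function(s) mean(scores[!positive] >= s), 1), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Oracle model: emits probability 1 for the true class of dataset `ds`.
oracleModel <- function(ds) {
  onehot <- oneHotRisk(ds)
  function(x) onehot
}

# Fixed random-probability model (uninformative by construction).
randomModel <- function(n, seed = 99) {
  p <- withr::with_seed(seed, matrix(runif(n * 3), n, 3))
  p <- p / rowSums(p)
  function(x) p
}
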