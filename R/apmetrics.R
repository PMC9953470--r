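#' @include ord.R
NULL

traceVector <- function(trace) {
  if (is(trace, "APTrace")) list(v = trace@v, dt = trace@dt_ms)
  else list(v = as.numeric(trace), dt = 2)
}

# Activation time, peak, resting potential and the repolarization crossing
# at `level`; shared by the biomarker functions. Times are in ms with
# sample i at t = (i - 1) * dt. The activation time is taken at the end of
# the steepest upstroke interval (maximum forward-difference dV/dt); the
# resting potential is the first (pre-stimulus) sample; threshold crossings
# are linearly interpolated between the 2 ms samples.
traceGeometry <- function(v, dt, level) {
  n <- length(v)
  rest <- v[1]
  ipk <- which.max(v)
  peak <- v[ipk]
  if (peak - rest <= 30)
    stop("trace has no action-potential upstroke (peak - first sample <= 30 mV)")
  dvdt <- diff(v) / dt
  iup <- which.max(dvdt[seq_len(max(ipk - 1, 1))])
  t_act <- iup * dt                      # end of the steepest interval
  thr <- peak - level * (peak - rest)
  t_cross <- NA_real_
  flag <- FALSE
  for (j in seq(ipk, n - 1)) {
    if (v[j] > thr && v[j + 1] <= thr) {
      t_cross <- (j - 1) * dt + dt * (v[j] - thr) / (v[j] - v[j + 1])
      break
    }
  }
  if (is.na(t_cross)) {
    t_cross <- (n - 1) * dt
    flag <- TRUE
  }
  list(rest = rest, peak = peak, ipk = ipk, t_peak = (ipk - 1) * dt,
       t_act = t_act, t_cross = t_cross, did_not_repolarize = flag)
}

#' Action potential duration at a repolarization level
#'
#' APD at fractional repolarization \code{level} (0.9 for APD90, 0.5 for
#' APD50): time from the activation instant (maximum upstroke dV/dt) to the
#' first crossing of \eqn{V_{peak} - level \cdot (V_{peak} - V_{rest})}
#' after the peak, with linear interpolation between the 2 ms samples. If
#' the trace never repolarizes below the threshold (EAD / very long AP) the
#' trace duration is returned with attribute
#' \code{did_not_repolarize = TRUE}.
#'
#' @param trace an \linkS4class{APTrace} or a plain numeric trace on the
#'   2 ms grid.
#' @param level fraction of repolarization in (0, 1); default 0.9.
#' @return APD in ms, with logical attribute \code{did_not_repolarize}.
#' @export
#' @examples
#' tr <- c(-85, rep(40, 150), rep(-85, 849))  # idealized square AP
#' apd(tr, 0.9)
apd <- function(trace, level = 0.9) {
  stopifnot(level > 0, level < 1)
  tv <- traceVector(trace)
  g <- traceGeometry(tv$v, tv$dt, level)
  out <- g$t_cross - g$t_act
  attr(out, "did_not_repolarize") <- g$did_not_repolarize
  out
}

# Index range of the repolarization window: from 50 ms after the AP peak
# (skipping the phase-1 notch) to the APD90 crossing, or trace end when the
# beat does not repolarize.
repolWindow <- function(v, dt) {
  g <- traceGeometry(v, dt, 0.9)
  from <- g$ipk + ceiling(50 / dt)
  to <- min(floor(g$t_cross / dt) + 1, length(v) - 1)
  if (from > to) stop("empty repolarization window")
  c(from, to)
}

#' Maximum repolarization-phase slope
#'
#' Maximum finite-difference dV/dt over the repolarization window (from
#' 50 ms after the AP peak to the APD90 crossing or trace end). Negative
#' throughout for a monotone repolarization; positive values flag a
#' depolarizing deflection, the signature used to capture beats carrying
#' early afterdepolarizations.
#'
#' @inheritParams apd
#' @return Slope in mV/ms.
#' @export
maxRepolSlope <- function(trace) {
  tv <- traceVector(trace)
  w <- repolWindow(tv$v, tv$dt)
  dvdt <- (tv$v[(w[1] + 1):(w[2] + 1)] - tv$v[w[1]:w[2]]) / tv$dt
  max(dvdt)
}

#' Early-afterdepolarization detector
#'
#' Flags a beat as carrying an EAD when dV/dt exceeds \code{threshold} for
#' at least \code{min_consec} consecutive samples inside the repolarization
#' window. The defaults (+0.01 mV/ms over two consecutive 2 ms samples) are
#' robust to the coarse recording grid.
#'
#' @inheritParams apd
#' @param threshold dV/dt threshold, mV/ms.
#' @param min_consec minimum number of consecutive super-threshold samples.
#' @return Logical.
#' @export
detectEad <- function(trace, threshold = 0.01, min_consec = 2) {
  tv <- traceVector(trace)
  w <- repolWindow(tv$v, tv$dt)
  dvdt <- (tv$v[(w[1] + 1):(w[2] + 1)] - tv$v[w[1]:w[2]]) / tv$dt
  above <- dvdt > threshold
  r <- rle(above)
  any(r$values & r$lengths >= min_consec)
}

#' Select the classifier input beat from a paced run
#'
#' Within the late, quasi-stationary window of the run (the last 250
#' beats, 751-1000, of the production protocol) the beat with the maximal
#' repolarization-phase
#' slope is selected, so that a beat exhibiting an EAD is picked whenever
#' one occurs; ties are broken by the latest beat index.
#'
#' @param series a \linkS4class{BeatSeries}.
#' @param window inclusive beat-index range, default \code{c(751, 1000)}
#'   (the last 250 beats of a 1000-beat run).
#' @return An \linkS4class{APTrace}.
#' @export
selectBeat <- function(series, window = c(751, 1000)) {
  stopifnot(is(series, "BeatSeries"), length(window) == 2)
  if (window[2] > nBeats(series))
    stop("selection window [", window[1], ", ", window[2],
         "] exceeds the ", nBeats(series), " available beats")
  beats <- seq(window[1], window[2])
  slopes <- vapply(beats, function(b) maxRepolSlope(apTrace(series, b)),
                   numeric(1))
  best <- beats[max(which(slopes == max(slopes)))]
  apTrace(series, best)
}

#' AP biomarkers of one beat
#'
#' @inheritParams apd
#' @return One-row data.frame: apd50, apd90 (ms), peak_v, resting_v (mV),
#'   max_repol_slope (mV/ms), ead (logical), did_not_repolarize (logical).
#' @export
apBiomarkers <- function(trace) {
  tv <- traceVector(trace)
  a90 <- apd(trace, 0.9)
  a50 <- apd(trace, 0.5)
  g <- traceGeometry(tv$v, tv$dt, 0.9)
  data.frame(apd50 = as.numeric(a50), apd90 = as.numeric(a90),
             peak_v = g$peak, resting_v = g$rest,
             max_repol_slope = maxRepolSlope(trace),
             ead = detectEad(trace),
             did_not_repolarize = attr(a90, "did_not_repolarize"))
}
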