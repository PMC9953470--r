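#' @include io.R
NULL

#' State-variable names of the ventricular cell model
#'
#' Membrane potential, intracellular/subspace ion concentrations, SR calcium
#' stores, Hodgkin-Huxley and Markov-style gates, ryanodine-release fluxes
#' and trapped CaMKII, in the fixed order used by the integrator.
#'
#' @return Character vector of length 41.
#' @export
ordStateNames <- function() {
  c("v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
    "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
    "a", "iF", "iS", "ap", "iFp", "iSp",
    "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
    "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt")
}

#' Published initial conditions of the cell model
#'
#' The original model's resting initial state (endocardial), used as the
#' starting point of the drug-free steady-state pacing run.
#'
#' @return Named numeric state vector (length 41).
#' @export
ordInitialState <- function() {
  stats::setNames(
    c(-87, 7, 7, 145, 145, 1.0e-4, 1.0e-4, 1.2, 1.2,
      0, 1, 1, 1, 1, 1, 0, 1, 1,
      0, 1, 1, 0, 1, 1,
      0, 1, 1, 1, 1, 1, 0, 1, 1,
      0, 0, 0, 0, 1, 0, 0, 0),
    ordStateNames())
}

# Map channel -> conductance parameter acted on by drug block.
channelConductanceMap <- function() {
  c(INa = "GNa", INaL = "GNaL", ICaL = "PCa", IKr = "GKr",
    IKs = "GKs", IK1 = "GK1", Ito = "Gto")
}

#' Build a cell-model configuration
#'
#' Loads the versioned conductance set (baseline maximal conductances plus
#' the Dutta rescaling of IKr, IKs, IK1, ICaL, INaL) and combines it with
#' per-channel drug conductance scales and pacing settings. The defaults
#' encode the bradycardic assessment protocol: 2000 ms cycle length,
#' 0.1 ms integration step, 2 ms recording grid (1000 points per beat),
#' endocardial cell, -80 uA/uF stimulus for 0.5 ms at each cycle start.
#'
#' @param drug_scales named numeric over (a subset of) the seven channels,
#'   each in [0, 1]; missing channels default to 1 (unblocked).
#' @param cell_type "endo" (default), "epi" or "M".
#' @param cl_ms pacing cycle length, ms.
#' @param dt_ms integration step, ms.
#' @param record_dt_ms recording step, ms.
#' @param stim_amp,stim_dur stimulus amplitude (uA/uF) and duration (ms).
#' @param conductance_file YAML file with base conductances, Dutta scalers
#'   and a model version tag; defaults to the copy shipped with the package.
#' @return A \linkS4class{CellModelConfig}.
#' @export
#' @examples
#' cfg <- ordConfig(drug_scales = c(IKr = 0.5))
ordConfig <- function(drug_scales = NULL, cell_type = "endo",
                      cl_ms = 2000, dt_ms = 0.1, record_dt_ms = 2,
                      stim_amp = -80, stim_dur = 0.5,
                      conductance_file = NULL) {
  if (is.null(conductance_file))
    conductance_file <- system.file("extdata", "ord_dutta_conductances.yaml",
                                    package = "torsadeNet", mustWork = TRUE)
  cfgy <- yaml::read_yaml(conductance_file)
  base <- unlist(cfgy$base_conductances)
  dutta <- unlist(cfgy$dutta_scalers)
  scales <- stats::setNames(rep(1, 7), tdpChannels())
  if (!is.null(drug_scales)) {
    bad <- setdiff(names(drug_scales), tdpChannels())
    if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
    scales[names(drug_scales)] <- drug_scales
  }
  new("CellModelConfig", base_conductances = base, dutta_scalers = dutta,
      drug_scales = scales, cell_type = cell_type, stim_amp = stim_amp,
      stim_dur = stim_dur, cl_ms = cl_ms, dt_ms = dt_ms,
      record_dt_ms = record_dt_ms,
      model_version = as.character(cfgy$model_version))
}

# Effective conductances: base * Dutta scaler (drug scales handled in C++).
effectiveConductances <- function(config) {
  g <- config@base_conductances
  d <- config@dutta_scalers
  gmap <- channelConductanceMap()
  for (ch in names(d)) g[gmap[[ch]]] <- g[gmap[[ch]]] * d[[ch]]
  g
}

# Drug scales in the fixed order the C++ core expects.
scalesForCore <- function(config) {
  unname(config@drug_scales[c("INa", "INaL", "Ito", "ICaL",
                              "IKr", "IKs", "IK1")])
}

celltypeCode <- function(cell_type) {
  match(cell_type, c("endo", "epi", "M")) - 1L
}

#' Model right-hand side and ionic currents at a state
#'
#' Evaluates the time derivative of every state variable and the individual
#' ionic currents at one instant, with each drug-blocked channel current
#' scaled by its conductance scale factor. Useful for steady-state residual
#' checks and current decomposition.
#'
#' @param state named numeric state vector (see [ordStateNames()]).
#' @param config a \linkS4class{CellModelConfig}.
#' @param stim stimulus current at this instant, uA/uF (default 0).
#' @return List with \code{derivs} (named, per ms) and \code{currents}
#'   (named, uA/uF; SR fluxes in mM/ms).
#' @export
ordDerivatives <- function(state, config = ordConfig(), stim = 0) {
  stopifnot(length(state) == 41)
  res <- .ord_derivs_cpp(unname(state), effectiveConductances(config),
                         scalesForCore(config), celltypeCode(config@cell_type),
                         stim)
  if (any(!is.finite(res$derivs))) {
    bad <- ordStateNames()[which(!is.finite(res$derivs))]
    stop("non-finite derivative for state component(s): ",
         paste(bad, collapse = ", "))
  }
  names(res$derivs) <- ordStateNames()
  res
}

#' Pace the drug-free model to steady state
#'
#' Runs the unblocked model for \code{n_beats} paced cycles from the
#' published initial conditions (or a supplied state). The per-beat
#' state-change norms are attached as the \code{"beat_norms"} attribute so
#' that convergence can be inspected. The production protocol uses 10,000
#' drug-free pacings before any drug run.
#'
#' @param config a drug-free \linkS4class{CellModelConfig} (all drug scales
#'   must equal 1).
#' @param n_beats number of paced beats; 0 returns \code{state} unchanged.
#' @param state starting state (default: published initial conditions).
#' @return Named state vector at the end of pacing, with attribute
#'   \code{beat_norms}.
#' @export
runToSteady <- function(config = ordConfig(), n_beats = 10000,
                        state = ordInitialState()) {
  if (any(config@drug_scales != 1))
    stop("steady-state pacing must be drug-free (all drug scales 1)")
  if (n_beats == 0) {
    attr(state, "beat_norms") <- numeric(0)
    return(state)
  }
  res <- .ord_pace_cpp(unname(state), effectiveConductances(config),
                       scalesForCore(config),
                       celltypeCode(config@cell_type), as.integer(n_beats),
                       config@cl_ms, config@dt_ms, config@record_dt_ms,
                       config@stim_amp, config@stim_dur, FALSE)
  out <- stats::setNames(res$final_state, ordStateNames())
  attr(out, "beat_norms") <- res$beat_norms
  out
}

#' Converged drug-free endocardial steady state
#'
#' The state reached after 10,000 drug-free pacings at cycle length 2000 ms
#' (endocardial cell, default stimulus), shipped with the package as the
#' standard initial condition of every drug simulation. Regenerate with
#' \code{runToSteady(n_beats = 10000)} if the conductance set changes; the
#' stored file carries the model version tag and is checked against the
#' supplied configuration.
#'
#' @param config configuration whose model version must match the fixture.
#' @return Named state vector.
#' @export
steadyStateEndo <- function(config = ordConfig()) {
  path <- system.file("extdata", "ord_endo_steady_cl2000.txt",
                      package = "torsadeNet", mustWork = TRUE)
  lines <- readLines(path)
  ver <- sub("^# model_version: ", "",
             grep("^# model_version:", lines, value = TRUE))
  if (length(ver) && ver != config@model_version)
    warning("steady-state fixture was generated for model version ", ver,
            ", configuration has ", config@model_version)
  dat <- utils::read.table(textConnection(grep("^#", lines, value = TRUE,
                                               invert = TRUE)),
                           col.names = c("name", "value"))
  stats::setNames(dat$value, dat$name)[ordStateNames()]
}

#' Simulate a paced run under drug block
#'
#' Paces the model for \code{n_beats} cycles from \code{initial} (normally
#' the drug-free steady state) with the drug conductance scales in
#' \code{config}, recording the membrane potential of every beat on the
#' recording grid (samples at t = 0, 2, ..., 1998 ms within each cycle at
#' defaults, i.e. 1000 points per beat). The production protocol applies
#' 1000 beats at cycle length 2000 ms (bradycardia, 30 bpm).
#'
#' @param initial starting state vector.
#' @param config a \linkS4class{CellModelConfig} carrying the drug scales.
#' @param n_beats number of beats to simulate.
#' @return A \linkS4class{BeatSeries}.
#' @export
simulateDrug <- function(initial, config, n_beats = 1000) {
  stopifnot(length(initial) == 41)
  res <- .ord_pace_cpp(unname(initial), effectiveConductances(config),
                       scalesForCore(config),
                       celltypeCode(config@cell_type), as.integer(n_beats),
                       config@cl_ms, config@dt_ms, config@record_dt_ms,
                       config@stim_amp, config@stim_dur, TRUE)
  new("BeatSeries", v = res$v,
      final_state = stats::setNames(res$final_state, ordStateNames()),
      beat_norms = res$beat_norms, config = config)
}

#' Per-channel conductance scales for one Hill sample at a Cmax multiple
#'
#' Converts one bootstrap draw of Hill parameters into the seven-channel
#' scale map at \code{multiple} times the peak serum concentration; channels
#' without parameters (or with the IC50 = Inf sentinel) stay at 1.
#'
#' @param hill data.frame with columns \code{channel}, \code{ic50},
#'   \code{hill} (one row per available channel).
#' @param cmax peak serum concentration, micromolar.
#' @param multiple Cmax multiple (the assessment protocol uses 1-4).
#' @return Named numeric over the seven channels.
#' @export
drugScalesFromSamples <- function(hill, cmax, multiple) {
  stopifnot(multiple >= 1, cmax > 0)
  scales <- stats::setNames(rep(1, 7), tdpChannels())
  for (i in seq_len(nrow(hill))) {
    ch <- hill$channel[i]
    scales[ch] <- conductanceScale(multiple * cmax, hill$ic50[i],
                                   hill$hill[i])
  }
  scales
}

#' @rdname accessors
#' @export
setMethod("nBeats", "BeatSeries", function(object) nrow(object@v))

#' @rdname accessors
#' @export
setMethod("apTrace", "BeatSeries", function(object, beat) {
  stopifnot(beat >= 1, beat <= nrow(object@v))
  new("APTrace", v = object@v[beat, ],
      dt_ms = object@config@record_dt_ms, beat_index = as.integer(beat))
})

setMethod("show", "BeatSeries", function(object) {
  cat("BeatSeries:", nrow(object@v), "beats x", ncol(object@v),
      "samples (cycle length", object@config@cl_ms, "ms)\n")
  sc <- object@config@drug_scales
  blocked <- names(sc)[sc < 1]
  if (length(blocked))
    cat("  blocked channels:",
        paste(sprintf("%s=%.3f", blocked, sc[blocked]), collapse = ", "),
        "\n")
  else cat("  drug-free\n")
})

setMethod("show", "APTrace", function(object) {
  cat("APTrace: beat", object@beat_index, "-", length(object@v),
      "points at", object@dt_ms, "ms\n")
})
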