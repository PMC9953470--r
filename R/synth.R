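#' @include riskeval.R
NULL

#' Specification of one synthetic drug
#'
#' Describes the designed channel-block pharmacology of one synthetic drug:
#' the true (IC50, Hill) per affected channel, the replicate noise of the
#' emulated patch-clamp assay, the Cmax and the assay concentrations.
#'
#' @param drug drug identifier.
#' @param risk risk label ("high", "intermediate" or "low").
#' @param channel_profile named list: channel -> c(ic50 = , hill = ); only
#'   affected channels need appear.
#' @param cmax_uM peak serum concentration, micromolar.
#' @param concentrations assay concentrations; default four points
#'   log-spaced around Cmax (0.3x to 10x), matching the four-concentration
#'   design of the reference assay.
#' @param replicates replicates per concentration.
#' @param noise_sd Gaussian replicate noise on the block fraction.
#' @return A list of class "SyntheticDrugSpec".
#' @export
syntheticDrugSpec <- function(drug, risk, channel_profile, cmax_uM,
                              concentrations = cmax_uM * c(0.3, 1, 3, 10),
                              replicates = 6, noise_sd = 0.02) {
  stopifnot(risk %in% tdpRiskLevels(), cmax_uM > 0,
            all(concentrations > 0), noise_sd >= 0)
  structure(list(drug = drug, risk = risk,
                 channel_profile = channel_profile, cmax_uM = cmax_uM,
                 concentrations = concentrations, replicates = replicates,
                 noise_sd = noise_sd),
            class = "SyntheticDrugSpec")
}

#' Generate a synthetic dose-response panel
#'
#' Block replicates are drawn as the exact Hill value at each assay
#' concentration plus Gaussian noise, clamped to [0, 1]; deterministic for
#' a given seed. Channels absent from a drug's profile produce no
#' measurements (no measurable block).
#'
#' @param specs list of [syntheticDrugSpec()] objects.
#' @param seed integer seed.
#' @return A \linkS4class{DoseResponsePanel}.
#' @export
makeDrugPanel <- function(specs, seed = 1) {
  stopifnot(length(specs) > 0)
  withLocalSeed(seed, {
    rows <- list()
    for (sp in specs) {
      for (ch in names(sp$channel_profile)) {
        pars <- sp$channel_profile[[ch]]
        for (conc in sp$concentrations) {
          b <- hillBlock(conc, pars[["ic50"]], pars[["hill"]]) +
            stats::rnorm(sp$replicates, 0, sp$noise_sd)
          rows[[length(rows) + 1]] <- data.frame(
            drug = sp$drug, channel = ch, conc_uM = conc,
            block = pmin(pmax(b, 0), 1))
        }
      }
    }
    meas <- do.call(rbind, rows)
    drugs <- data.frame(
      drug = vapply(specs, `[[`, "", "drug"),
      cmax_uM = vapply(specs, `[[`, 1, "cmax_uM"),
      risk = vapply(specs, `[[`, "", "risk"))
    suppressWarnings(DoseResponsePanel(meas, drugs))
  })
}

#' The default nine-drug synthetic panel
#'
#' Three drugs per risk class with designed block mechanisms that follow
#' the pharmacology of torsadogenic risk: high-risk drugs block IKr
#' strongly at therapeutic exposure (IC50 at Cmax, so the conductance scale
#' falls below 0.5 across the 1-4x Cmax range); intermediate-risk drugs
#' block IKr moderately (IC50 near twice Cmax); low-risk drugs block every
#' channel only weakly (all IC50s at 15x Cmax or more, scales above 0.9 at
#' Cmax). The full pipeline separates these classes by construction.
#'
#' @param seed integer seed for the replicate noise.
#' @return A \linkS4class{DoseResponsePanel} of 9 drugs.
#' @export
defaultPanel <- function(seed = 1) {
  cmaxes <- c(0.5, 1, 2.5, 0.8, 1.6, 4, 0.6, 1.2, 3)
  specs <- list()
  for (i in 1:3) {
    cm <- cmaxes[i]
    specs[[length(specs) + 1]] <- syntheticDrugSpec(
      paste0("high", i), "high",
      list(IKr = c(ic50 = 1.0 * cm, hill = 0.9 + 0.1 * i)), cm)
  }
  for (i in 1:3) {
    cm <- cmaxes[3 + i]
    specs[[length(specs) + 1]] <- syntheticDrugSpec(
      paste0("inter", i), "intermediate",
      list(IKr = c(ic50 = 2.0 * cm, hill = 0.9 + 0.1 * i)), cm)
  }
  for (i in 1:3) {
    cm <- cmaxes[6 + i]
    specs[[length(specs) + 1]] <- syntheticDrugSpec(
      paste0("low", i), "low",
      list(IKr = c(ic50 = 15 * cm, hill = 1),
           ICaL = c(ic50 = 20 * cm, hill = 1)), cm)
  }
  makeDrugPanel(specs, seed = seed)
}

#' Parameters of the surrogate AP-shape generator
#'
#' @param baseline_apd baseline APD90, ms.
#' @param apd_shift named numeric per class, ms added to the baseline.
#' @param ead_probability named numeric per class, probability that a trace
#'   carries an EAD bump.
#' @param plateau_height plateau potential, mV.
#' @param noise_sd additive Gaussian noise, mV.
#' @return A list of class "SurrogateAPParams".
#' @export
surrogateAPParams <- function(baseline_apd = 280,
                              apd_shift = c(high = 120, intermediate = 60,
                                            low = 0),
                              ead_probability = c(high = 0.5,
                                                  intermediate = 0.1,
                                                  low = 0),
                              plateau_height = 18, noise_sd = 0.25) {
  stopifnot(all(ead_probability >= 0 & ead_probability <= 1))
  structure(list(baseline_apd = baseline_apd, apd_shift = apd_shift,
                 ead_probability = ead_probability,
                 plateau_height = plateau_height, noise_sd = noise_sd),
            class = "SurrogateAPParams")
}

# One parametric AP template on the 2 ms grid: resting potential, fast
# upstroke, transient spike decaying onto the plateau, and a sigmoidal
# repolarization whose center is placed analytically so that the measured
# APD90 equals `apd`; optional EAD bump mid-repolarization.
surrogateTrace <- function(apd, plateau, ead, noise_sd, n = 1000, dt = 2) {
  t <- (seq_len(n) - 1) * dt
  rest <- -85; peak <- 38; up_t <- 4; w <- 18
  ramp <- pmin(pmax(t / up_t, 0), 1)
  spike <- (peak - plateau) * exp(-pmax(t - up_t, 0) / 25)
  # APD90 threshold expressed as a fraction of the plateau amplitude fixes
  # the sigmoid center such that the 90% crossing lands at t_act + apd
  q <- 0.1 * (peak - rest) / (plateau - rest)
  center <- apd - w * log((1 - q) / q)
  repol <- 1 / (1 + exp((t - up_t - center) / w))
  v <- rest + ramp * (spike + (plateau - rest) * repol)
  if (ead) {
    t_ead <- up_t + 0.72 * apd
    v <- v + 12 * exp(-((t - t_ead) / 25)^2) * (t > up_t + 100)
  }
  v + stats::rnorm(n, 0, noise_sd)
}

#' Fast parametric surrogate AP shapes
#'
#' Generates class-labeled 1000-point AP shapes from a parametric template
#' (resting -85 mV, fast upstroke, plateau, sigmoidal repolarization with
#' class-dependent APD and an optional EAD bump) so that classifier and
#' evaluation code can be exercised without paying the cost of the ionic
#' model. Deterministic for a given seed.
#'
#' @param n_per_class traces per risk class.
#' @param params a [surrogateAPParams()] object.
#' @param seed integer seed.
#' @return An \linkS4class{APDataset}; surrogate "drugs" are named
#'   \code{surr_<class>}.
#' @export
makeSurrogateAps <- function(n_per_class, params = surrogateAPParams(),
                             seed = 1) {
  stopifnot(n_per_class >= 1)
  withLocalSeed(seed, {
    lev <- tdpRiskLevels()
    traces <- matrix(NA_real_, n_per_class * 3, 1000)
    meta <- data.frame(drug = character(n_per_class * 3),
                       hill_sample = integer(n_per_class * 3),
                       cmax_multiple = integer(n_per_class * 3))
    row <- 0
    for (cls in lev) {
      for (i in seq_len(n_per_class)) {
        row <- row + 1
        ead <- stats::runif(1) < params$ead_probability[[cls]]
        traces[row, ] <- surrogateTrace(
          params$baseline_apd + params$apd_shift[[cls]],
          params$plateau_height, ead, params$noise_sd)
        meta$drug[row] <- paste0("surr_", cls)
        meta$hill_sample[row] <- i
        meta$cmax_multiple[row] <- ((i - 1) %% 4) + 1
      }
    }
    labels <- stats::setNames(lev, paste0("surr_", lev))
    assembleAPDataset(traces, meta, labels)
  })
}
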