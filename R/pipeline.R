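#' @include synth.R
NULL

#' Run the full risk-assessment pipeline on a dose-response panel
#'
#' Drives every stage end to end: bootstrap Hill samples per drug-channel
#' pair, paced drug simulations at 1-4x Cmax from the drug-free steady
#' state, beat selection by maximal repolarization slope, dataset assembly,
#' classifier training and repeated resampled evaluation. The production
#' protocol corresponds to \code{B = 2000}, \code{n_hill = 2000},
#' \code{n_beats = 1000}, \code{window = c(751, 1000)},
#' \code{epochs = 100}, \code{folds = 10}, \code{n_repeats = 10000};
#' the defaults here are a reduced configuration sized for desk-scale runs
#' on the synthetic panel (drug effects on AP duration stabilize within a
#' few beats when starting from the drug-free steady state, and the
#' selection rule is window-size agnostic).
#'
#' @param panel a \linkS4class{DoseResponsePanel}.
#' @param B bootstrap samples per drug-channel pair.
#' @param n_hill Hill samples actually simulated per drug (first
#'   \code{n_hill} of the B samples).
#' @param multiples Cmax multiples to simulate.
#' @param n_beats paced beats per simulation.
#' @param window beat-selection window (inclusive range).
#' @param subsample_per_drug "all" or a per-drug subsample count.
#' @param epochs,folds,lr,batch_size training configuration.
#' @param n_repeats,per_drug evaluation configuration.
#' @param seed master seed for every stochastic stage.
#' @param initial starting state for the drug runs (default: the shipped
#'   drug-free steady state).
#' @param verbose print stage progress.
#' @return List with elements \code{hill} (\linkS4class{HillSamples}),
#'   \code{dataset} (\linkS4class{APDataset}), \code{model}
#'   (\linkS4class{ConvNet}) and \code{report}
#'   (\linkS4class{RiskEvalReport}).
#' @export
tdpPipeline <- function(panel, B = 50, n_hill = 12, multiples = 1:4,
                        n_beats = 20, window = c(16, 20),
                        subsample_per_drug = "all", epochs = 15, folds = 0,
                        lr = 0.01, batch_size = 32, n_repeats = 100,
                        per_drug = NULL, seed = 1, initial = NULL,
                        verbose = FALSE) {
  stopifnot(is(panel, "DoseResponsePanel"), n_hill <= B)
  seeds <- deriveSeeds(seed, 4)
  say <- function(...) if (verbose) message(...)
  say("bootstrapping Hill samples (B = ", B, ")")
  hill <- bootstrapPanel(panel, B = B, seed = seeds[1])
  hs <- hillSamples(hill)
  if (is.null(initial)) initial <- steadyStateEndo()
  drugs <- drugNames(panel)
  labels <- riskLabels(panel)
  n_per_drug <- n_hill * length(multiples)
  traces <- matrix(NA_real_, length(drugs) * n_per_drug, 1000)
  meta <- data.frame(drug = character(nrow(traces)),
                     hill_sample = integer(nrow(traces)),
                     cmax_multiple = integer(nrow(traces)))
  row <- 0
  for (d in drugs) {
    say("simulating ", d)
    cm <- cmax(panel, d)
    for (s in seq_len(n_hill)) {
      hp <- hs[hs$drug == d & hs$sample_index == s,
               c("channel", "ic50", "hill")]
      for (mult in multiples) {
        scales <- drugScalesFromSamples(hp, cm, mult)
        cfg <- ordConfig(drug_scales = scales)
        series <- simulateDrug(initial, cfg, n_beats = n_beats)
        tr <- selectBeat(series, window = window)
        row <- row + 1
        traces[row, ] <- tr@v
        meta$drug[row] <- d
        meta$hill_sample[row] <- s
        meta$cmax_multiple[row] <- mult
      }
    }
  }
  say("assembling dataset")
  ds <- assembleAPDataset(traces, meta, labels,
                          subsample_per_drug = subsample_per_drug,
                          seed = seeds[2])
  say("training classifier (", epochs, " epochs)")
  model <- trainConvNet(ds, epochs = epochs, lr = lr, folds = folds,
                        batch_size = batch_size, seed = seeds[3])
  if (is.null(per_drug))
    per_drug <- max(1, floor(min(table(
      SummarizedExperiment::colData(ds)$drug)) / 2))
  say("evaluating (", n_repeats, " repeats)")
  report <- repeatedTest(model, ds, n_repeats = n_repeats,
                         per_drug = per_drug, seed = seeds[4])
  list(hill = hill, dataset = ds, model = model, report = report)
}
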