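#' @include torsadeNet-package.R
NULL

#' DoseResponsePanel: measured ion-channel block for a drug panel
#'
#' Holds per-drug, per-channel fractional-block replicates across
#' concentrations together with drug metadata (peak serum concentration Cmax
#' and torsade-risk label). The panel is the raw input of the pipeline.
#'
#' @slot measurements data.frame with columns \code{drug}, \code{channel},
#'   \code{conc_uM} (positive, micromolar) and \code{block} (fraction in
#'   [0, 1]; one replicate per row).
#' @slot drugs data.frame with columns \code{drug}, \code{cmax_uM} (positive)
#'   and \code{risk} (one of \code{high}, \code{intermediate}, \code{low}).
#' @export
setClass("DoseResponsePanel",
  representation(measurements = "data.frame", drugs = "data.frame"))

setValidity("DoseResponsePanel", function(object) {
  m <- object@measurements
  d <- object@drugs
  msgs <- character()
  need_m <- c("drug", "channel", "conc_uM", "block")
  need_d <- c("drug", "cmax_uM", "risk")
  if (!all(need_m %in% names(m)))
    msgs <- c(msgs, paste("measurements must have columns",
                          paste(need_m, collapse = ", ")))
  if (!all(need_d %in% names(d)))
    msgs <- c(msgs, paste("drugs must have columns",
                          paste(need_d, collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (anyDuplicated(d$drug))
    msgs <- c(msgs, "duplicated drug ids in metadata")
  bad_ch <- setdiff(unique(m$channel), tdpChannels())
  if (length(bad_ch))
    msgs <- c(msgs, paste("unknown channel(s):", paste(bad_ch, collapse = ", ")))
  if (any(!is.finite(m$conc_uM)) || any(m$conc_uM <= 0))
    msgs <- c(msgs, "concentrations must be positive and finite")
  if (any(m$block < 0 | m$block > 1))
    msgs <- c(msgs, "block fractions must lie in [0, 1]")
  if (any(!is.finite(d$cmax_uM)) || any(d$cmax_uM <= 0))
    msgs <- c(msgs, "Cmax must be positive and finite")
  if (!all(d$risk %in% tdpRiskLevels()))
    msgs <- c(msgs, "risk labels must be high, intermediate or low")
  miss <- setdiff(unique(m$drug), d$drug)
  if (length(miss))
    msgs <- c(msgs, paste("measured drug(s) without metadata:",
                          paste(miss, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' HillSamples: bootstrap samples of Hill-curve parameters
#'
#' Tabular container of bootstrap replicates of (IC50, Hill coefficient)
#' per drug-channel pair, quantifying experimental uncertainty of the
#' dose-response assay. An infinite IC50 is the "no measurable block"
#' sentinel.
#'
#' @slot samples data.frame with columns \code{drug}, \code{channel},
#'   \code{sample_index}, \code{ic50} (micromolar, may be \code{Inf}) and
#'   \code{hill} (positive).
#' @slot B integer, number of samples per drug-channel pair.
#' @slot seed integer master seed used to generate the samples.
#' @export
setClass("HillSamples",
  representation(samples = "data.frame", B = "integer", seed = "integer"))

setValidity("HillSamples", function(object) {
  s <- object@samples
  msgs <- character()
  need <- c("drug", "channel", "sample_index", "ic50", "hill")
  if (!all(need %in% names(s)))
    return(paste("samples must have columns", paste(need, collapse = ", ")))
  if (any(s$ic50 <= 0, na.rm = TRUE)) msgs <- c(msgs, "ic50 must be positive")
  if (any(!is.finite(s$hill) | s$hill <= 0))
    msgs <- c(msgs, "hill must be positive and finite")
  cnt <- table(paste(s$drug, s$channel))
  if (length(cnt) && any(cnt != object@B))
    msgs <- c(msgs, "every drug-channel pair must carry exactly B samples")
  if (length(msgs)) msgs else TRUE
})

#' CellModelConfig: paced myocyte simulation configuration
#'
#' Configuration of one paced O'Hara-Rudy simulation: baseline maximal
#' conductances, the Dutta rescaling of the five repolarization-critical
#' currents, per-channel drug conductance scales, cell type, stimulus and
#' timing grids.
#'
#' @slot base_conductances named numeric, baseline maximal conductances /
#'   permeabilities (mS/uF and model-native permeability units).
#' @slot dutta_scalers named numeric over IKr, IKs, IK1, ICaL, INaL.
#' @slot drug_scales named numeric over the seven channels, each in [0, 1];
#'   1 means drug-free.
#' @slot cell_type "endo", "epi" or "M".
#' @slot stim_amp stimulus amplitude, uA/uF (negative = depolarizing).
#' @slot stim_dur stimulus duration, ms.
#' @slot cl_ms pacing cycle length, ms.
#' @slot dt_ms integration step, ms.
#' @slot record_dt_ms membrane-potential recording step, ms.
#' @slot model_version version tag of the conductance set.
#' @export
setClass("CellModelConfig",
  representation(base_conductances = "numeric", dutta_scalers = "numeric",
                 drug_scales = "numeric", cell_type = "character",
                 stim_amp = "numeric", stim_dur = "numeric",
                 cl_ms = "numeric", dt_ms = "numeric",
                 record_dt_ms = "numeric", model_version = "character"))

setValidity("CellModelConfig", function(object) {
  msgs <- character()
  if (!object@cell_type %in% c("endo", "epi", "M"))
    msgs <- c(msgs, "cell_type must be endo, epi or M")
  sc <- object@drug_scales
  if (!all(tdpChannels() %in% names(sc)))
    msgs <- c(msgs, "drug_scales must be named over all seven channels")
  if (any(sc < 0 | sc > 1))
    msgs <- c(msgs, "drug_scales must lie in [0, 1]")
  r1 <- object@record_dt_ms / object@dt_ms
  r2 <- object@cl_ms / object@record_dt_ms
  if (abs(r1 - round(r1)) > 1e-9)
    msgs <- c(msgs, "dt_ms must divide record_dt_ms")
  if (abs(r2 - round(r2)) > 1e-9)
    msgs <- c(msgs, "record_dt_ms must divide cl_ms")
  if (length(msgs)) msgs else TRUE
})

#' APTrace: one beat's membrane-potential trace
#'
#' @slot v numeric membrane potential, mV, sampled on the recording grid
#'   (1000 points for the default 2000 ms cycle at 2 ms).
#' @slot dt_ms sampling interval, ms.
#' @slot beat_index index of the beat within its paced run.
#' @export
setClass("APTrace",
  representation(v = "numeric", dt_ms = "numeric", beat_index = "integer"))

setValidity("APTrace", function(object) {
  if (any(!is.finite(object@v))) "trace contains non-finite values" else TRUE
})

#' BeatSeries: a paced run of consecutive beats
#'
#' @slot v matrix, one row per beat, one column per recorded sample.
#' @slot final_state named numeric, full model state at the end of the run.
#' @slot beat_norms numeric, Euclidean norm of the full-state change over
#'   each beat (a convergence diagnostic).
#' @slot config the \linkS4class{CellModelConfig} used.
#' @export
setClass("BeatSeries",
  representation(v = "matrix", final_state = "numeric",
                 beat_norms = "numeric", config = "CellModelConfig"))

setValidity("BeatSeries", function(object) {
  cfg <- object@config
  want <- cfg@cl_ms / cfg@record_dt_ms
  if (ncol(object@v) != want)
    sprintf("each beat must carry %d samples (cl_ms / record_dt_ms)", want)
  else TRUE
})

#' APDataset: labeled AP shapes for classifier training and testing
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"ap"} holds
#' membrane-potential traces (rows = time points on the 2 ms grid, columns =
#' samples) and whose \code{colData} carries per-sample metadata:
#' \code{drug}, \code{risk} (factor over high/intermediate/low),
#' \code{hill_sample} and \code{cmax_multiple}.
#' @export
setClass("APDataset", contains = "SummarizedExperiment")

setValidity("APDataset", function(object) {
  msgs <- character()
  if (!"ap" %in% SummarizedExperiment::assayNames(object))
    return("assay 'ap' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("drug", "risk", "hill_sample", "cmax_multiple")
  if (!all(need %in% names(cd)))
    msgs <- c(msgs, paste("colData must have columns",
                          paste(need, collapse = ", ")))
  else if (!all(as.character(cd$risk) %in% tdpRiskLevels()))
    msgs <- c(msgs, "risk labels must be high, intermediate or low")
  if (length(msgs)) msgs else TRUE
})

#' ConvNet: the 1D convolutional risk classifier
#'
#' @slot arch list describing the layer chain (kernel sizes, strides, pool
#'   geometry, hidden width, classes) plus the derived per-layer lengths.
#' @slot params list of weight arrays.
#' @slot bn list with batch-normalization moving averages
#'   (\code{mean}, \code{var}) used at inference time.
#' @slot trained logical.
#' @slot history data.frame of per-epoch training (and, when cross-validated,
#'   per-fold validation) loss and accuracy.
#' @slot seed integer seed used for initialization and minibatch order.
#' @export
setClass("ConvNet",
  representation(arch = "list", params = "list", bn = "list",
                 trained = "logical", history = "data.frame", seed = "integer"))

#' RiskEvalReport: repeated-testing evaluation summary
#'
#' @slot metrics data.frame with columns \code{class}, \code{metric},
#'   \code{point}, \code{ci_lo}, \code{ci_hi}; metrics are auc, sensitivity,
#'   specificity, lr_plus and lr_minus per risk class, point = mean over
#'   repeats, CI = central 95 percent percentile interval.
#' @slot confusion 3x3 row-normalized confusion matrix averaged over repeats
#'   (rows = truth, columns = prediction).
#' @slot n_repeats integer number of resampled test sets.
#' @slot per_drug integer samples drawn per drug per repeat.
#' @slot seed integer.
#' @export
setClass("RiskEvalReport",
  representation(metrics = "data.frame", confusion = "matrix",
                 n_repeats = "integer", per_drug = "integer", seed = "integer"))

setValidity("RiskEvalReport", function(object) {
  msgs <- character()
  rs <- rowSums(object@confusion)
  if (any(abs(rs - 1) > 1e-9))
    msgs <- c(msgs, "confusion matrix rows must sum to 1")
  m <- object@metrics
  if (any(m$point < m$ci_lo - 1e-12 | m$point > m$ci_hi + 1e-12))
    msgs <- c(msgs, "point estimates must lie within their intervals")
  a <- m[m$metric == "auc", ]
  if (any(a$point < 0 | a$point > 1))
    msgs <- c(msgs, "AUC must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
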