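#' @include apmetrics.R
NULL

#' Assemble a labeled AP-shape dataset
#'
#' Collects selected AP traces into an \linkS4class{APDataset}
#' (a \linkS4class{SummarizedExperiment}: traces as the \code{"ap"} assay,
#' per-sample metadata as \code{colData}). Every drug must contribute traces
#' from all four Cmax multiples of the assessment protocol; with 2000 Hill
#' samples per drug this yields 8000 shapes per drug before subsampling,
#' 24,000 rows for the 12-drug training panel and 32,000 for the 16-drug
#' test panel. Traces are deliberately not normalized: the raw
#' membrane-potential morphology is the classifier input.
#'
#' @param traces numeric matrix, one row per AP shape (1000 points at the
#'   default grid).
#' @param meta data.frame aligned with \code{traces}: columns \code{drug},
#'   \code{hill_sample}, \code{cmax_multiple}.
#' @param risk_labels named character/factor mapping each drug to its risk
#'   class.
#' @param subsample_per_drug "all" (default) or a count of shapes drawn
#'   without replacement per drug (the production subsample uses 500 of the
#'   8000 per drug).
#' @param seed integer seed for the subsampling draw.
#' @return An \linkS4class{APDataset}.
#' @export
assembleAPDataset <- function(traces, meta, risk_labels,
                              subsample_per_drug = "all", seed = 1) {
  stopifnot(nrow(traces) == nrow(meta))
  drugs <- unique(meta$drug)
  miss <- setdiff(drugs, names(risk_labels))
  if (length(miss))
    stop("no risk label for drug(s): ", paste(miss, collapse = ", "))
  mults <- sort(unique(meta$cmax_multiple))
  for (d in drugs) {
    have <- unique(meta$cmax_multiple[meta$drug == d])
    lack <- setdiff(mults, have)
    if (length(lack))
      stop("drug ", d, " is missing Cmax multiple(s) ",
           paste(lack, collapse = ", "))
  }
  keep <- seq_len(nrow(meta))
  if (!identical(subsample_per_drug, "all")) {
    n_sub <- as.integer(subsample_per_drug)
    keep <- withLocalSeed(seed, {
      unlist(lapply(drugs, function(d) {
        i <- which(meta$drug == d)
        if (length(i) < n_sub)
          stop("drug ", d, " has only ", length(i),
               " shapes, cannot subsample ", n_sub)
        sort(i[sample.int(length(i), n_sub)])
      }), use.names = FALSE)
    })
  }
  x <- traces[keep, , drop = FALSE]
  md <- meta[keep, , drop = FALSE]
  cd <- S4Vectors::DataFrame(
    drug = md$drug,
    risk = factor(as.character(risk_labels[md$drug]),
                  levels = tdpRiskLevels()),
    hill_sample = md$hill_sample,
    cmax_multiple = md$cmax_multiple)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ap = t(x)), colData = cd)
  new("APDataset", se)
}

#' @rdname accessors
#' @export
setMethod("apTraces", "APDataset", function(object) {
  t(SummarizedExperiment::assay(object, "ap"))
})

#' @rdname accessors
#' @export
setMethod("riskClass", "APDataset", function(object) {
  SummarizedExperiment::colData(object)$risk
})

#' One-hot encoding of the risk labels
#'
#' @param ds an \linkS4class{APDataset}.
#' @return Matrix [n x 3] over (high, intermediate, low); rows sum to 1.
#' @export
oneHotRisk <- function(ds) {
  y <- riskClass(ds)
  m <- matrix(0, length(y), 3, dimnames = list(NULL, tdpRiskLevels()))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' Stratified cross-validation folds
#'
#' Partitions the samples into k folds sized within one of each other and
#' stratified by risk class (per-fold class counts within one of the
#' balanced allocation), deterministically for a given seed.
#'
#' @param ds an \linkS4class{APDataset} (or a factor of labels).
#' @param k number of folds (10 in the production protocol).
#' @param seed integer seed.
#' @return Integer vector of fold assignments (1..k) per sample.
#' @export
makeFolds <- function(ds, k = 10, seed = 1) {
  y <- if (is(ds, "APDataset")) riskClass(ds) else as.factor(ds)
  n <- length(y)
  if (k > n) stop("k = ", k, " exceeds the ", n, " available samples")
  fold <- integer(n)
  withLocalSeed(seed, {
    counts <- integer(k)
    for (cls in levels(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        f <- which.min(counts)   # least-filled fold, ties to lowest index
        fold[i] <- f
        counts[f] <- counts[f] + 1L
      }
    }
  })
  fold
}

setMethod("show", "APDataset", function(object) {
  cat("APDataset:", ncol(object), "AP shapes x", nrow(object),
      "time points\n")
  tab <- table(riskClass(object))
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  drugs:", length(unique(SummarizedExperiment::colData(object)$drug)),
      "\n")
})
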