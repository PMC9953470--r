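#' @include AllGenerics.R
NULL

#' Construct a dose-response panel
#'
#' Builds a validated \linkS4class{DoseResponsePanel} from a measurement
#' table and a drug metadata table. Block fractions slightly outside [0, 1]
#' (as raw patch-clamp replicates can be) are clamped with a warning.
#'
#' @param measurements data.frame with columns \code{drug}, \code{channel},
#'   \code{conc_uM}, \code{block} (fractions; one replicate per row).
#' @param drugs data.frame with columns \code{drug}, \code{cmax_uM},
#'   \code{risk}.
#' @return A \linkS4class{DoseResponsePanel}.
#' @export
#' @examples
#' m <- data.frame(drug = "d1", channel = "IKr",
#'                 conc_uM = c(0.1, 1, 10), block = c(0.1, 0.5, 0.9))
#' d <- data.frame(drug = "d1", cmax_uM = 1, risk = "high")
#' DoseResponsePanel(m, d)
DoseResponsePanel <- function(measurements, drugs) {
  measurements <- as.data.frame(measurements)
  drugs <- as.data.frame(drugs)
  out_of_range <- measurements$block < 0 | measurements$block > 1
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " block fraction(s) outside [0, 1] clamped to the unit interval")
    measurements$block <- pmin(pmax(measurements$block, 0), 1)
  }
  drugs$risk <- as.character(drugs$risk)
  new("DoseResponsePanel", measurements = measurements, drugs = drugs)
}

#' @rdname DoseResponsePanel-class
#' @export
setMethod("measurements", "DoseResponsePanel", function(object) {
  object@measurements
})

#' @rdname DoseResponsePanel-class
#' @export
setMethod("drugInfo", "DoseResponsePanel", function(object) object@drugs)

#' @rdname DoseResponsePanel-class
#' @export
setMethod("drugNames", "DoseResponsePanel", function(object) {
  object@drugs$drug
})

#' Peak serum concentration of one drug
#'
#' @param panel a \linkS4class{DoseResponsePanel}.
#' @param drug drug identifier.
#' @return Cmax in micromolar.
#' @export
cmax <- function(panel, drug) {
  i <- match(drug, panel@drugs$drug)
  if (is.na(i)) stop("unknown drug: ", drug)
  panel@drugs$cmax_uM[i]
}

#' Risk labels of a panel, named by drug
#'
#' @param panel a \linkS4class{DoseResponsePanel}.
#' @return Named factor with levels high, intermediate, low.
#' @export
riskLabels <- function(panel) {
  stats::setNames(factor(panel@drugs$risk, levels = tdpRiskLevels()),
                  panel@drugs$drug)
}

setMethod("show", "DoseResponsePanel", function(object) {
  cat("DoseResponsePanel with", nrow(object@drugs), "drugs,",
      nrow(object@measurements), "measurements\n")
  tab <- table(factor(object@drugs$risk, levels = tdpRiskLevels()))
  cat("  risk classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat("  channels:",
      paste(sort(unique(object@measurements$channel)), collapse = ", "), "\n")
})

setMethod("show", "HillSamples", function(object) {
  pairs <- unique(object@samples[, c("drug", "channel")])
  cat("HillSamples:", object@B, "bootstrap samples x", nrow(pairs),
      "drug-channel pairs (seed", object@seed, ")\n")
})

#' @rdname accessors
#' @export
setMethod("hillSamples", "HillSamples", function(object) object@samples)
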