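#' @include hill.R
NULL

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a dose-response panel from CSV files
#'
#' Reads a measurement table in the public CiPA repository dialect (columns
#' \code{drug}, \code{channel}, \code{conc_uM}, \code{block}; replicates as
#' repeated rows) plus a drug metadata table (\code{drug}, \code{cmax_uM},
#' \code{risk}). Block columns on the percent scale are auto-detected (any
#' value > 1.5) and rescaled to fractions with a message.
#'
#' @param path path to the measurement CSV.
#' @param meta_path path to the drug metadata CSV.
#' @return A \linkS4class{DoseResponsePanel}.
#' @export
readCipaCsv <- function(path, meta_path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "channel", "conc_uM", "block")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("measurement file is missing column(s): ",
         paste(miss, collapse = ", "))
  bad_ch <- which(!m$channel %in% tdpChannels())
  if (length(bad_ch))
    stop("unknown channel '", m$channel[bad_ch[1]], "' at row ", bad_ch[1])
  conc <- suppressWarnings(as.numeric(m$conc_uM))
  if (anyNA(conc))
    stop("non-numeric concentration at row ", which(is.na(conc))[1])
  m$conc_uM <- conc
  m$block <- suppressWarnings(as.numeric(m$block))
  if (anyNA(m$block))
    stop("non-numeric block value at row ", which(is.na(m$block))[1])
  if (any(m$block > 1.5)) {
    message("block column appears to be on the percent scale; ",
            "rescaling to fractions (value / 100)")
    m$block <- m$block / 100
  }
  d <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  needd <- c("drug", "cmax_uM", "risk")
  missd <- setdiff(needd, names(d))
  if (length(missd))
    stop("metadata file is missing column(s): ", paste(missd, collapse = ", "))
  no_meta <- setdiff(unique(m$drug), d$drug)
  if (length(no_meta))
    stop("no Cmax / risk metadata for drug(s): ",
         paste(no_meta, collapse = ", "))
  DoseResponsePanel(m, d)
}

#' Write a dose-response panel to CSV files
#'
#' Numeric columns are written with full double precision so that
#' \code{readCipaCsv(writePanelCsv(...))} is an exact round trip on
#' canonical (fraction-scale) panels.
#'
#' @param panel a \linkS4class{DoseResponsePanel}.
#' @param path measurement CSV destination.
#' @param meta_path drug metadata CSV destination.
#' @return Invisibly, the panel.
#' @export
writePanelCsv <- function(panel, path, meta_path) {
  m <- measurements(panel)
  m$conc_uM <- fmt_num(m$conc_uM)
  m$block <- fmt_num(m$block)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  d <- drugInfo(panel)
  d$cmax_uM <- fmt_num(d$cmax_uM)
  utils::write.csv(d, meta_path, row.names = FALSE, quote = FALSE)
  invisible(panel)
}

#' Write / read bootstrap Hill samples as CSV
#'
#' The tabular container has columns drug, channel, sample_index, ic50,
#' hill; an infinite ic50 (no-block sentinel) is stored as the string "Inf".
#'
#' @param x a \linkS4class{HillSamples} object.
#' @param path CSV destination / source.
#' @return \code{writeHillSamples}: invisibly \code{x};
#'   \code{readHillSamples}: a \linkS4class{HillSamples}.
#' @export
writeHillSamples <- function(x, path) {
  s <- hillSamples(x)
  s$ic50 <- fmt_num(s$ic50)
  s$hill <- fmt_num(s$hill)
  md <- data.frame(drug = "#meta", channel = "", sample_index = x@B,
                   ic50 = "", hill = fmt_num(as.numeric(x@seed)))
  utils::write.csv(rbind(s, md), path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' @rdname writeHillSamples
#' @export
readHillSamples <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- s[s$drug == "#meta", ]
  s <- s[s$drug != "#meta", ]
  s$ic50 <- as.numeric(s$ic50)
  s$hill <- as.numeric(s$hill)
  s$sample_index <- as.integer(s$sample_index)
  B <- if (nrow(meta)) as.integer(meta$sample_index[1]) else
    max(s$sample_index)
  seed <- if (nrow(meta)) as.integer(as.numeric(meta$hill[1])) else NA_integer_
  new("HillSamples", samples = s, B = B, seed = seed)
}

#' Save / load an AP-shape dataset
#'
#' Serializes an \linkS4class{APDataset} (traces plus metadata in one file)
#' with a bit-exact round trip of the trace matrix.
#'
#' @param ds an \linkS4class{APDataset}.
#' @param path file destination / source.
#' @return \code{writeAPDataset}: invisibly \code{ds};
#'   \code{readAPDataset}: an \linkS4class{APDataset}.
#' @export
writeAPDataset <- function(ds, path) {
  saveRDS(ds, path)
  invisible(ds)
}

#' @rdname writeAPDataset
#' @export
readAPDataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(is(ds, "APDataset"))
  validObject(ds)
  ds
}
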