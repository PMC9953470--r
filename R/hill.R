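#' @include panel-methods.R
NULL

#' Fractional channel block at a drug concentration (Hill equation)
#'
#' The blocked fraction of a channel at free drug concentration \eqn{D} is
#' \deqn{b(D) = \frac{1}{1 + (IC_{50}/D)^h}}
#' so that \eqn{b = 0.5} exactly at \eqn{D = IC_{50}}, \eqn{b \to 0} as
#' \eqn{D \to 0} and \eqn{b \to 1} at saturating concentration. An infinite
#' IC50 is the no-measurable-block sentinel and yields 0.
#'
#' @param conc drug concentration, micromolar; must be positive.
#' @param ic50 half-maximal inhibitory concentration, micromolar
#'   (may be \code{Inf}).
#' @param hill Hill coefficient, positive.
#' @return Block fraction(s) in [0, 1]; vectorized over \code{conc}.
#' @seealso [conductanceScale()] for the conductance multiplier
#'   \eqn{1 - b(D)} applied in the cell model.
#' @export
#' @examples
#' hillBlock(1, ic50 = 1, hill = 1.5)   # 0.5 at the midpoint
#' hillBlock(3, ic50 = 1, hill = 1)     # 0.75
hillBlock <- function(conc, ic50, hill) {
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentration must be positive and finite")
  if (any(ic50 <= 0)) stop("ic50 must be positive (Inf = no block)")
  if (any(!is.finite(hill)) || any(hill <= 0)) stop("hill must be positive")
  1 / (1 + (ic50 / conc)^hill)
}

#' Conductance scale factor under drug block
#'
#' The unblocked fraction \eqn{1 - b(D)} multiplying the channel's maximal
#' conductance in the cell model; 1 at zero concentration (drug-free), 0.5
#' at the IC50, and monotonically non-increasing in concentration.
#'
#' @inheritParams hillBlock
#' @param conc drug concentration, micromolar; zero means drug-free.
#' @return Scale factor(s) in [0, 1].
#' @export
#' @examples
#' conductanceScale(0, 1, 1)    # 1: drug-free
#' conductanceScale(3, 1, 1)    # 0.25
conductanceScale <- function(conc, ic50, hill) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentration must be non-negative and finite")
  out <- numeric(length(conc))
  zero <- conc == 0
  out[zero] <- 1
  if (any(!zero)) out[!zero] <- 1 - hillBlock(conc[!zero], ic50, hill)
  out
}

#' Least-squares Hill-curve fit for one drug-channel pair
#'
#' Fits (IC50, Hill coefficient) to measured block fractions by minimizing
#' the sum of squared residuals. The optimization runs over
#' (log10 IC50, h) with h constrained to (0, 10], from three starting
#' points to avoid local minima; ties are broken by lower residual, then
#' lower h. If every replicate shows zero block the no-block sentinel
#' (IC50 = Inf) is returned rather than an error.
#'
#' @param conc concentrations, micromolar (>= 2 distinct values).
#' @param block measured block fractions in [0, 1], one replicate per entry.
#' @return Named numeric \code{c(ic50 = , hill = )}.
#' @export
#' @examples
#' d <- c(0.1, 1, 10, 100)
#' fitHill(d, hillBlock(d, ic50 = 1, hill = 1.2))
fitHill <- function(conc, block) {
  if (length(conc) != length(block))
    stop("conc and block must have equal length")
  if (length(unique(conc)) < 2)
    stop("at least 2 distinct concentrations are required")
  if (all(block == 0)) return(c(ic50 = Inf, hill = 1))
  if (length(unique(block)) == 1)
    stop("all block fractions are equal; the Hill curve is unidentifiable")
  sse <- function(par) {
    pred <- 1 / (1 + (10^par[1] / conc)^par[2])
    sum((pred - block)^2)
  }
  med <- stats::median(log10(conc))
  starts <- list(c(med, 1), c(med - 1.5, 0.7), c(med + 1.5, 2.5))
  fits <- lapply(starts, function(s) {
    stats::optim(s, sse, method = "L-BFGS-B",
                 lower = c(-12, 1e-3), upper = c(12, 10),
                 control = list(factr = 1e4))
  })
  vals <- vapply(fits, function(f) f$value, numeric(1))
  hills <- vapply(fits, function(f) f$par[2], numeric(1))
  best <- order(vals, hills)[1]
  par <- fits[[best]]$par
  c(ic50 = 10^par[1], hill = par[2])
}

# Resample replicates with replacement within each concentration group.
resampleWithinConc <- function(conc, block) {
  idx <- unlist(lapply(split(seq_along(conc), conc), function(i) {
    i[sample.int(length(i), length(i), replace = TRUE)]
  }), use.names = FALSE)
  list(conc = conc[idx], block = block[idx])
}

#' Bootstrap Hill-parameter samples for one drug-channel pair
#'
#' Quantifies experimental uncertainty by nonparametric bootstrap:
#' replicates are resampled with replacement within each concentration and
#' refitted until B fits are accepted; fits whose log10(IC50) falls outside
#' the central 95 percent interval of the accepted set are then discarded
#' and replaced by redrawing (with replacement) from the retained fits, so
#' the returned set has exactly B samples concentrated within the 95 percent
#' confidence band. With fewer than 2 replicates at every concentration a
#' residual (parametric) bootstrap around the point fit is used instead,
#' with a warning.
#'
#' @inheritParams fitHill
#' @param B number of bootstrap samples (2000 reproduces the production
#'   protocol of 2000 Hill curves per drug).
#' @param seed integer seed; the procedure is deterministic given it.
#' @return data.frame with columns \code{sample_index}, \code{ic50},
#'   \code{hill}.
#' @export
bootstrapHill <- function(conc, block, B = 2000, seed = 1) {
  point <- fitHill(conc, block)
  if (!is.finite(point["ic50"])) {
    return(data.frame(sample_index = seq_len(B),
                      ic50 = rep(Inf, B), hill = rep(1, B)))
  }
  n_rep <- table(conc)
  residual_mode <- all(n_rep < 2)
  if (residual_mode)
    warning("fewer than 2 replicates at every concentration; ",
            "falling back to a residual bootstrap")
  fitted_vals <- hillBlock(conc, point["ic50"], point["hill"])
  resid <- block - fitted_vals
  withLocalSeed(seed, {
    fits <- matrix(NA_real_, nrow = 0, ncol = 2)
    tries <- 0
    while (nrow(fits) < B && tries < 20 * B + 100) {
      tries <- tries + 1
      dat <- if (residual_mode) {
        bb <- fitted_vals + resid[sample.int(length(resid), length(resid),
                                             replace = TRUE)]
        list(conc = conc, block = pmin(pmax(bb, 0), 1))
      } else {
        resampleWithinConc(conc, block)
      }
      f <- tryCatch(fitHill(dat$conc, dat$block), error = function(e) NULL)
      if (!is.null(f)) fits <- rbind(fits, unname(f))
    }
    if (nrow(fits) < B)
      stop("bootstrap failed to accumulate ", B, " accepted fits")
    l10 <- log10(fits[, 1])
    qs <- stats::quantile(l10, c(0.025, 0.975), names = FALSE, type = 7)
    keep <- is.finite(l10) & l10 >= qs[1] & l10 <= qs[2]
    if (!any(keep)) keep <- rep(TRUE, nrow(fits))
    kept <- fits[keep, , drop = FALSE]
    need <- B - nrow(kept)
    if (need > 0) {
      extra <- kept[sample.int(nrow(kept), need, replace = TRUE), ,
                    drop = FALSE]
      kept <- rbind(kept, extra)
    }
    data.frame(sample_index = seq_len(B), ic50 = kept[, 1], hill = kept[, 2])
  })
}

#' Bootstrap Hill samples for every drug-channel pair of a panel
#'
#' Runs [bootstrapHill()] on each measured drug-channel pair; pairs with no
#' measurements (no measurable block in the assay) receive the IC50 = Inf
#' sentinel for all B samples.
#'
#' @param panel a \linkS4class{DoseResponsePanel}.
#' @param B bootstrap samples per pair (default 2000, the production count;
#'   28 drugs x 2000 gives the full 56,000-sample campaign).
#' @param seed master seed; per-pair sub-seeds are derived from it.
#' @param channels channels to cover (defaults to all seven).
#' @return A \linkS4class{HillSamples} object.
#' @export
bootstrapPanel <- function(panel, B = 2000, seed = 1,
                           channels = tdpChannels()) {
  stopifnot(is(panel, "DoseResponsePanel"))
  m <- measurements(panel)
  drugs <- drugNames(panel)
  grid <- expand.grid(drug = drugs, channel = channels,
                      stringsAsFactors = FALSE)
  seeds <- deriveSeeds(seed, nrow(grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- m[m$drug == grid$drug[i] & m$channel == grid$channel[i], ]
    s <- if (nrow(sub) == 0) {
      data.frame(sample_index = seq_len(B), ic50 = rep(Inf, B),
                 hill = rep(1, B))
    } else {
      bootstrapHill(sub$conc_uM, sub$block, B = B, seed = seeds[i])
    }
    cbind(drug = grid$drug[i], channel = grid$channel[i], s)
  })
  new("HillSamples", samples = do.call(rbind, res), B = as.integer(B),
      seed = as.integer(seed))
}
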