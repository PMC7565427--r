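# Three-parameter Hill (sigmoid) dose-response model and the
# dose-range-normalized AUC used as the regression target.

.sigmoid <- function(eInf, log10EC50, hill, log10Dose) {
  eInf + (1 - eInf) / (1 + 10 ^ (hill * (log10Dose - log10EC50)))
}

#' Evaluate a fitted Hill curve
#'
#' Growth(dose) = eInf + (1 - eInf) / (1 + 10^(hill * (log10(dose) -
#' log10EC50))), clipped to [0, 1]. The upper asymptote is fixed at 1, the
#' growth of the untreated control.
#'
#' @param fit a \linkS4class{SigmoidFit}
#' @param dose positive dose (molar), vectorized
#' @return growth fraction(s) in [0, 1]
#' @export
sigmoidCurve <- function(fit, dose) {
  stopifnot(is(fit, "SigmoidFit"))
  if (any(dose <= 0)) stop("dose must be positive")
  g <- .sigmoid(fit@eInf, fit@log10EC50, fit@hill, log10(dose))
  pmin(1, pmax(0, g))
}

# bounded parameter box used by the multi-start fit
.fitLower <- c(eInf = -0.5, log10EC50 = -12, hill = 0.05)
.fitUpper <- c(eInf = 1.1, log10EC50 = -2, hill = 10)

#' Fit the three-parameter Hill model to a growth curve
#'
#' Bounded least squares on (eInf, log10EC50, hill), minimizing the squared
#' residuals of the relative growth values by Levenberg-Marquardt, with a
#' deterministic 3 x 3 x 3 multi-start over the parameter box (eInf in
#' [-0.5, 1.1], log10EC50 in [-12, -2], hill in [0.05, 10]); the start
#' reaching the smallest residual sum of squares wins, ties going to the
#' earlier start. If optimization fails from every start, a flat curve at
#' the mean growth (clipped to [0, 1], hill at its lower bound) is returned
#' with a warning.
#'
#' @param doses positive molar concentrations (>= 3)
#' @param growths relative tumor cell growth values, 1 = untreated control
#' @return a \linkS4class{SigmoidFit}
#' @export
fitSigmoid <- function(doses, growths) {
  if (length(doses) != length(growths)) stop("doses and growths must align")
  if (length(doses) < 3L) stop("need >= 3 dose points for 3 parameters")
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (!all(is.finite(doses)) || !all(is.finite(growths)))
    stop("doses and growths must be finite")
  ld <- log10(doses)
  residFun <- function(par) growths - .sigmoid(par[1L], par[2L], par[3L], ld)
  grid <- function(lo, hi) lo + (hi - lo) * c(0.25, 0.5, 0.75)
  starts <- expand.grid(eInf = grid(.fitLower[1L], .fitUpper[1L]),
                        log10EC50 = grid(.fitLower[2L], .fitUpper[2L]),
                        hill = grid(.fitLower[3L], .fitUpper[3L]))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(as.numeric(starts[i, ]), .fitLower, .fitUpper,
                         residFun,
                         control = minpack.lm::nls.lm.control(maxiter = 200L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) {
    warning("sigmoid fit failed from every start; returning flat fit")
    eInf <- min(1, max(0, mean(growths)))
    return(new("SigmoidFit", eInf = eInf, log10EC50 = mean(ld),
               hill = .fitLower[["hill"]],
               rss = sum((growths - eInf)^2), converged = FALSE))
  }
  new("SigmoidFit", eInf = best$par[1L], log10EC50 = best$par[2L],
      hill = best$par[3L], rss = best$deviance, converged = TRUE)
}

#' Dose-range-normalized area under the dose-response curve
#'
#' Integrates the fitted curve (clipped to [0, 1]) over log10-dose on the
#' assay range, by default [1e-10 M, 1e-4 M], and normalizes by the range so
#' the result lies in [0, 1]: 0 means complete response, 1 means no response.
#' Trapezoidal integration on a fixed uniform 1001-point log10-dose grid
#' keeps the value deterministic and converged for realistic hill slopes.
#'
#' @param fit a \linkS4class{SigmoidFit}
#' @param log10DoseLo,log10DoseHi integration range in log10 molar
#' @param nGrid grid points for the trapezoidal rule
#' @return normalized AUC in [0, 1]
#' @export
normalizedAUC <- function(fit, log10DoseLo = -10, log10DoseHi = -4,
                          nGrid = 1001L) {
  stopifnot(is(fit, "SigmoidFit"))
  if (log10DoseLo >= log10DoseHi) stop("need log10DoseLo < log10DoseHi")
  x <- seq(log10DoseLo, log10DoseHi, length.out = nGrid)
  y <- pmin(1, pmax(0, .sigmoid(fit@eInf, fit@log10EC50, fit@hill, x)))
  # trapezoid on a uniform grid, divided by the range = mean with half weights
  auc <- (sum(y) - (y[1L] + y[nGrid]) / 2) / (nGrid - 1L)
  min(1, max(0, auc))
}

#' Turn a raw dose/growth screen into a normalized-AUC response table
#'
#' Fits the Hill model per (sample, drug) experiment and computes the
#' normalized AUC for each; experiments with fewer than 3 dose points are an
#' error.
#'
#' @param raw data.frame with columns \code{sample}, \code{drug},
#'   \code{dose_M}, \code{growth}
#' @param log10DoseLo,log10DoseHi AUC integration range in log10 molar
#' @return a \linkS4class{ResponseTable}
#' @export
aucFromRawScreen <- function(raw, log10DoseLo = -10, log10DoseHi = -4) {
  need <- c("sample", "drug", "dose_M", "growth")
  if (!all(need %in% names(raw)))
    stop("raw screen needs columns sample, drug, dose_M, growth")
  key <- interaction(raw$sample, raw$drug, drop = TRUE, lex.order = TRUE)
  pieces <- split(raw, key)
  rec <- do.call(rbind, lapply(pieces, function(p) {
    fit <- fitSigmoid(p$dose_M, p$growth)
    data.frame(sample = p$sample[1L], drug = p$drug[1L],
               auc = normalizedAUC(fit, log10DoseLo, log10DoseHi),
               stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  ResponseTable(rec)
}

#' Simulate noisy growth measurements from Hill parameters
#'
#' Convenience wrapper emitting dose/growth points from given curve
#' parameters, mainly for exercising \code{\link{fitSigmoid}} and
#' \code{\link{aucFromRawScreen}}; no attempt is made at assay realism.
#'
#' @param eInf,log10EC50,hill curve parameters
#' @param doses molar doses (default 8 log-spaced points over 1e-10..1e-4)
#' @param noiseSd Gaussian noise added to the growth values
#' @return data.frame with columns dose_M, growth
#' @export
simulateGrowthCurve <- function(eInf, log10EC50, hill,
                                doses = 10 ^ seq(-10, -4, length.out = 8L),
                                noiseSd = 0) {
  g <- .sigmoid(eInf, log10EC50, hill, log10(doses))
  if (noiseSd > 0) g <- g + stats::rnorm(length(g), 0, noiseSd)
  data.frame(dose_M = doses, growth = g)
}
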