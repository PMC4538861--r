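# Hill-function input and dose-response readout fitting ------------------

#' Hill activation of the receptor kinase by EGF
#'
#' Phenomenological coupling between extracellular EGF and the fraction
#' of fully activated EGFR kinase used by the MPM and MPM-B:
#' a(x) = x^n / (J^n + x^n).
#'
#' @param egf EGF dose(s), ng/ml, >= 0.
#' @param hill_n Hill exponent (> 0).
#' @param hill_j half-activation dose (ng/ml, > 0).
#' @return activation fraction in [0, 1], same length as \code{egf}.
#' @export
hill_activation <- function(egf, hill_n, hill_j) {
  if (any(egf < 0)) stop("EGF dose must be >= 0")
  if (hill_n <= 0 || hill_j <= 0) stop("hill_n and hill_j must be > 0")
  xn <- (egf / hill_j)^hill_n
  ifelse(egf == 0, 0, xn / (1 + xn))
}

#' Construct a dose-response object
#'
#' @param egf dose grid (ng/ml), strictly increasing.
#' @param readout readout values (absolute scale).
#' @param kind one of "pY", "Ub", "cbl_bound".
#' @param normalization how \code{readout_normalized} was obtained.
#' @return data.frame of class \code{dose_response} with columns
#'   \code{egf_ng_per_ml}, \code{readout}, \code{readout_normalized}.
#' @export
dose_response <- function(egf, readout, kind = c("pY", "Ub", "cbl_bound"),
                          normalization = "own_max") {
  kind <- match.arg(kind)
  stopifnot(length(egf) == length(readout), !is.unsorted(egf, strictly = TRUE))
  mx <- max(readout)
  norm <- if (mx > 0) readout / mx else readout * 0
  out <- data.frame(egf_ng_per_ml = egf, readout = readout,
                    readout_normalized = norm)
  attr(out, "kind") <- kind
  attr(out, "normalization") <- normalization
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Fit a Hill function to a dose-response curve
#'
#' Least-squares fit of plateau * x^n / (x_half^n + x^n), the form used
#' to quantify the steepness of phosphorylation (n_H ~ 1) and
#' ubiquitination (n_H ~ 3) curves.
#'
#' @param curve a [dose_response()] object, or a data.frame with columns
#'   \code{egf_ng_per_ml} and either \code{readout_normalized} or
#'   \code{readout}.
#' @param use_normalized fit the normalized readout (default) or the
#'   absolute one.
#' @return object of class \code{hill_fit}: list with \code{n_h},
#'   \code{x_half}, \code{plateau}, \code{rss}, \code{ok}.  On
#'   degenerate input \code{ok} is FALSE and the estimates are NA
#'   (fit-failure flag, not silent garbage).
#' @export
fit_hill <- function(curve, use_normalized = TRUE) {
  x <- curve$egf_ng_per_ml
  y <- if (use_normalized && !is.null(curve$readout_normalized)) {
    curve$readout_normalized
  } else {
    curve$readout
  }
  keep <- x > 0
  x <- x[keep]; y <- y[keep]
  fail <- function(reason) {
    structure(list(n_h = NA_real_, x_half = NA_real_, plateau = NA_real_,
                   rss = NA_real_, ok = FALSE, reason = reason),
              class = "hill_fit")
  }
  if (length(x) < 4L || max(y) <= 0 || stats::sd(y) == 0) {
    return(fail("degenerate curve"))
  }
  # starting values: plateau from the top of the curve, x_half from the
  # half-crossing, n from the log-log slope around the midpoint
  p0 <- max(y)
  xh0 <- tryCatch(.interp_crossing(x, y / p0, 0.5), error = function(e) NA)
  if (!is.finite(xh0)) xh0 <- exp(mean(log(range(x))))
  mid <- y > 0.2 * p0 & y < 0.8 * p0
  n0 <- if (sum(mid) >= 2L) {
    z <- stats::coef(stats::lm(log(y[mid] / (p0 * 1.05 - y[mid])) ~ log(x[mid])))[2L]
    max(min(unname(z), 8), 0.3)
  } else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ plateau * x^n / (xh^n + x^n),
      start = list(plateau = p0, n = n0, xh = xh0),
      lower = c(plateau = 1e-12, n = 0.05, xh = min(x) / 100),
      upper = c(plateau = 100 * p0, n = 50, xh = max(x) * 100),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  structure(list(n_h = unname(cf["n"]), x_half = unname(cf["xh"]),
                 plateau = unname(cf["plateau"]),
                 rss = sum(stats::resid(fit)^2), ok = TRUE, reason = NULL),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$ok) {
    cat("<hill_fit> failed:", x$reason, "\n")
  } else {
    cat(sprintf("<hill_fit> n_H = %.4g, x_half = %.4g ng/ml, plateau = %.4g (rss %.3g)\n",
                x$n_h, x$x_half, x$plateau, x$rss))
  }
  invisible(x)
}

# log-linear interpolation of the dose at which a normalized, monotone
# curve crosses `level`
.interp_crossing <- function(x, ynorm, level) {
  above <- which(ynorm >= level)
  if (!length(above)) stop("curve never reaches the requested level")
  i <- above[1L]
  if (i == 1L) return(x[1L])
  lx1 <- log10(x[i - 1L]); lx2 <- log10(x[i])
  y1 <- ynorm[i - 1L]; y2 <- ynorm[i]
  10^(lx1 + (level - y1) * (lx2 - lx1) / (y2 - y1))
}

#' Ubiquitination threshold of a dose-response curve
#'
#' x_T is the half-maximal EGF concentration of the curve normalized to
#' its own maximum, obtained by log-linear interpolation between the
#' bracketing grid points.
#'
#' @param curve a [dose_response()] object (or compatible data.frame).
#' @return the threshold dose (ng/ml); \code{NA} with attribute
#'   \code{reason} when the curve never reaches half-maximum
#'   (undefined-threshold flag).
#' @export
threshold_xt <- function(curve) {
  x <- curve$egf_ng_per_ml
  y <- curve$readout_normalized
  if (is.null(y)) {
    y <- curve$readout / max(curve$readout)
  }
  if (max(y) <= 0) {
    return(structure(NA_real_, reason = "flat curve"))
  }
  y <- y / max(y)
  keep <- x > 0
  tryCatch(.interp_crossing(x[keep], y[keep], 0.5),
           error = function(e) structure(NA_real_, reason = conditionMessage(e)))
}
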