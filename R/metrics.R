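# Sensitivity analyses on dose-response metrics --------------------------
#
# Two perturbation schemes are used on the models: a 1% local scheme for
# curve-shape metrics (n_H, pY_0.5, x_T) and a 10-fold scheme for the
# ubiquitination threshold, which flags parameters able to displace the
# threshold by more than the parameter change itself.

#' Local (1%) sensitivity coefficient
#'
#' sigma = |relative change of the metric| / |relative change of the
#' parameter|, by central difference at +/- \code{rel_step}.
#'
#' @param metric_fn function(params) -> scalar metric (n_H, pY_0.5 or
#'   x_T); \code{params} is a named list or vector.
#' @param params baseline parameter set.
#' @param param name of the parameter to perturb.
#' @param rel_step relative step (default 0.01).
#' @return list with \code{sigma}, the perturbed metric values and a
#'   \code{defined} flag (FALSE when the metric is undefined at a
#'   perturbed point).
#' @export
sensitivity_local <- function(metric_fn, params, param, rel_step = 0.01) {
  m0 <- metric_fn(params)
  pu <- .set_param(params, param, .get_param(params, param) * (1 + rel_step))
  pd <- .set_param(params, param, .get_param(params, param) * (1 - rel_step))
  mu <- metric_fn(pu)
  md <- metric_fn(pd)
  if (!is.finite(m0) || !is.finite(mu) || !is.finite(md) || m0 == 0) {
    return(list(sigma = NA_real_, metric = m0, up = mu, down = md,
                defined = FALSE))
  }
  sigma <- abs((mu - md) / m0) / (2 * rel_step)
  list(sigma = sigma, metric = m0, up = mu, down = md, defined = TRUE)
}

#' Large-perturbation (10-fold) sensitivity for the threshold
#'
#' Each parameter is multiplied and divided by one order of magnitude;
#' the reported coefficient is the larger of
#' |log10(x_T(perturbed) / x_T(baseline))| per decade of parameter
#' change.  Values above 1 mean the threshold moves more than the
#' parameter did; parameters at or above 0.1 are worth reporting.
#'
#' @param metric_fn function(params) -> x_T (ng/ml).
#' @param params baseline parameters.
#' @param param parameter name.
#' @param fold perturbation factor (default 10).
#' @param grid_limits dose-grid limits used as boundary values when the
#'   threshold is undefined after a perturbation (saturated response).
#' @return list with \code{s_large}, \code{direction} ("up"/"down"),
#'   per-direction values, and \code{saturated} flag.
#' @export
sensitivity_large <- function(metric_fn, params, param, fold = 10,
                              grid_limits = c(0.01, 100)) {
  m0 <- metric_fn(params)
  if (!is.finite(m0)) stop("baseline threshold is undefined")
  eval_dir <- function(f) {
    p <- .set_param(params, param, .get_param(params, param) * f)
    m <- metric_fn(p)
    sat <- !is.finite(m)
    if (sat) {
      # response pushed off the scanned dose grid; record the boundary
      m <- if (f > 1) grid_limits[2L] else grid_limits[1L]
    }
    list(m = m, sat = sat)
  }
  up <- eval_dir(fold)
  dn <- eval_dir(1 / fold)
  s_up <- abs(log10(up$m / m0)) / log10(fold)
  s_dn <- abs(log10(dn$m / m0)) / log10(fold)
  dir <- if (s_up >= s_dn) "up" else "down"
  list(s_large = max(s_up, s_dn), direction = dir,
       baseline = m0, up = up$m, down = dn$m,
       s_up = s_up, s_down = s_dn,
       saturated = up$sat || dn$sat)
}

#' Threshold-sensitivity screen over a parameter set
#'
#' @param metric_fn function(params) -> x_T.
#' @param params baseline parameters.
#' @param param_names parameters to screen (default: all numeric scalar
#'   entries of \code{params}).
#' @param cutoff reporting cutoff on S (default 0.1).
#' @inheritParams sensitivity_large
#' @return data.frame with one row per parameter: \code{parameter},
#'   \code{s_large}, \code{direction}, \code{saturated},
#'   \code{reported} (S >= cutoff).
#' @export
sensitivity_screen <- function(metric_fn, params, param_names = NULL,
                               cutoff = 0.1, fold = 10,
                               grid_limits = c(0.01, 100)) {
  if (is.null(param_names)) {
    param_names <- names(params)[vapply(params, function(p)
      is.numeric(p) && length(p) == 1L && p > 0, logical(1))]
  }
  rows <- lapply(param_names, function(nm) {
    s <- sensitivity_large(metric_fn, params, nm, fold = fold,
                           grid_limits = grid_limits)
    data.frame(parameter = nm, s_large = s$s_large, direction = s$direction,
               saturated = s$saturated, reported = s$s_large >= cutoff)
  })
  out <- do.call(rbind, rows)
  out[order(-out$s_large), , drop = FALSE]
}

.get_param <- function(params, name) {
  v <- params[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  v
}

.set_param <- function(params, name, value) {
  params[[name]] <- value
  params
}
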