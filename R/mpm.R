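# Multisite Phosphorylation Model (MPM) ----------------------------------
#
# Nine (or fewer) identical tyrosines on each receptor are
# phosphorylated independently in the free-enzyme regime.  Receptors
# with the same number of phosphoryl groups are lumped, giving a linear
# birth-death chain R_0 <-> R_1 <-> ... <-> R_n with rates
#   phi_alpha(+) = (n - alpha) * a(EGF) * k_KIN
#   phi_alpha(-) = alpha * k_PTP,
# where a(EGF) is the phenomenological Hill activation.  Because sites
# are independent, the solution is Binomial(n, p(t)) with p obeying a
# scalar ODE; the package integrates the chain and tests check it
# against that closed form.

#' MPM parameter set
#'
#' @param n_sites number of phosphorylatable tyrosines (9 for WT, 3 for
#'   the 3Y+ add-back, 1 for Y1045+).
#' @param k_kin per-site phosphorylation rate constant at full kinase
#'   activation (min^-1).
#' @param k_ptp per-site dephosphorylation rate constant (min^-1);
#'   phosphatases are active from the earliest phase of stimulation.
#' @param hill_n,hill_j Hill exponent and half-activation dose (ng/ml)
#'   of the EGF -> kinase-activation function.
#' @param r_total receptors per cell.
#' @param t_end readout time after EGF addition (min); phosphorylation
#'   and ubiquitination are scored at 2 min, while both still happen
#'   predominantly at the plasma membrane.
#' @return list of class \code{mpm_params}.
#' @export
mpm_params <- function(n_sites = 9L, k_kin = 6, k_ptp = 3,
                       hill_n = 1, hill_j = 6,
                       r_total = 3e5, t_end = 2) {
  stopifnot(n_sites >= 1, k_kin >= 0, k_ptp >= 0,
            hill_n > 0, hill_j > 0, r_total > 0, t_end > 0)
  structure(list(n_sites = as.integer(n_sites), k_kin = k_kin,
                 k_ptp = k_ptp, hill_n = hill_n, hill_j = hill_j,
                 r_total = r_total, t_end = t_end),
            class = c("mpm_params", "list"))
}

# chain network R_0 ... R_n for a given activation level
.mpm_network <- function(params, activation) {
  n <- params$n_sites
  sp <- paste0("R", 0:n)
  x0 <- stats::setNames(c(params$r_total, rep(0, n)), sp)
  reactions <- list()
  rates <- numeric(0)
  for (a in 0:(n - 1)) {
    up <- paste0("kup", a)
    rates[up] <- (n - a) * activation * params$k_kin
    reactions[[length(reactions) + 1L]] <-
      list(rate = up, reactants = sp[a + 1L], products = sp[a + 2L])
  }
  for (a in 1:n) {
    dn <- paste0("kdn", a)
    rates[dn] <- a * params$k_ptp
    reactions[[length(reactions) + 1L]] <-
      list(rate = dn, reactants = sp[a + 1L], products = sp[a])
  }
  mk_network(sp, x0, reactions, rates,
             conservation = list(receptor = stats::setNames(rep(1, n + 1L), sp)))
}

#' Simulate the MPM phosphorylation chain
#'
#' Starts from the EGF-free steady state (every receptor fully
#' dephosphorylated) and integrates the lumped chain to \code{t_end}.
#'
#' @param params an [mpm_params()] object.
#' @param egf EGF dose (ng/ml).
#' @param t_end readout time (min); defaults to \code{params$t_end}.
#' @param rtol,atol solver tolerances.
#' @return list of class \code{phospho_chain}: \code{R} (abundances of
#'   R_0..R_n), \code{t}, \code{egf}, \code{params}.
#' @export
simulate_mpm <- function(params, egf, t_end = params$t_end,
                         rtol = 1e-10, atol = 1e-8) {
  stopifnot(inherits(params, "mpm_params"), egf >= 0)
  a <- hill_activation(egf, params$hill_n, params$hill_j)
  net <- .mpm_network(params, a)
  traj <- simulate_network(net, times = c(0, t_end), rtol = rtol, atol = atol)
  check_conservation(net, traj, rel_tol = 1e-8)
  R <- traj[nrow(traj), -1L]
  structure(list(R = R, t = t_end, egf = egf, params = params),
            class = "phospho_chain")
}

#' Total receptor phosphorylation of a chain state
#'
#' Sum over alpha of alpha * R_alpha: phosphoryl groups per cell.  For
#' identical rates this scales exactly with the number of sites, which
#' is why total pY of the 9-site receptor is three times that of the
#' 3-site add-back at every dose.
#'
#' @param state a \code{phospho_chain} from [simulate_mpm()].
#' @return total phosphotyrosine per cell.
#' @export
total_phosphorylation <- function(state) {
  stopifnot(inherits(state, "phospho_chain"))
  R <- state$R
  if (any(R < -1e-6 * sum(abs(R)))) stop("invalid chain state")
  sum(seq_along(R[-1L]) * R[-1L])
}

#' MPM dose-response curve of total phosphorylation
#'
#' @param params an [mpm_params()] object.
#' @param egf_grid dose grid (ng/ml), strictly increasing.
#' @param t_end readout time (min).
#' @return a [dose_response()] of kind "pY".
#' @export
mpm_dose_response <- function(params, egf_grid = default_dose_grid(),
                              t_end = params$t_end) {
  py <- vapply(egf_grid, function(d)
    total_phosphorylation(simulate_mpm(params, d, t_end)), numeric(1))
  dose_response(egf_grid, py, kind = "pY")
}

#' Default log-spaced EGF dose grid
#'
#' @param from,to dose limits (ng/ml).
#' @param n number of points.
#' @export
default_dose_grid <- function(from = 0.01, to = 100, n = 8L) {
  10^seq(log10(from), log10(to), length.out = n)
}
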