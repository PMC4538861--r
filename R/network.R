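# Generic mass-action reaction networks ----------------------------------
#
# All three EGFR models (MPM chain, MPM-B binding layer, EAM activation
# layer) compile down to the same representation: a species list plus
# elementary reactions with at most two reactants and two products, each
# carrying a named rate constant.  Keeping this layer generic gives one
# ODE right-hand side, one conservation checker and one SBML serializer
# for every model.

#' Build a mass-action reaction network
#'
#' @param species character vector of species names (unique).
#' @param x0 named numeric vector of initial abundances (molecules per
#'   cell); names must match \code{species}.
#' @param reactions list of reactions, each a list with elements
#'   \code{rate} (name of a rate constant in \code{rates}),
#'   \code{reactants} (character, length 0--2) and \code{products}
#'   (character, length 0--2).  A species appearing on both sides acts
#'   as a catalyst (net stoichiometry zero) but still enters the
#'   propensity.
#' @param rates named numeric vector of rate constants.  First-order
#'   constants are in min^-1, second-order constants in
#'   cell molecule^-1 min^-1.
#' @param conservation optional named list of named weight vectors; for
#'   each entry, sum(weights * x) is expected to be constant in time
#'   (checked by [check_conservation()]).
#'
#' @return an object of class \code{reaction_network}.
#' @export
mk_network <- function(species, x0, reactions, rates, conservation = NULL) {
  stopifnot(is.character(species), !anyDuplicated(species))
  if (!all(names(x0) %in% species) || length(x0) != length(species)) {
    stop("x0 must be a named vector covering every species")
  }
  x0 <- x0[species]
  nr <- length(reactions)
  i1 <- integer(nr)
  i2 <- integer(nr)
  rate_name <- character(nr)
  S <- matrix(0, nrow = length(species), ncol = nr,
              dimnames = list(species, NULL))
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    re <- rx$reactants
    pr <- rx$products
    if (length(re) > 2L || length(pr) > 2L) {
      stop("at most two reactants and two products are supported")
    }
    idx <- match(re, species)
    if (anyNA(idx)) stop("unknown reactant in reaction ", j)
    pidx <- match(pr, species)
    if (anyNA(pidx)) stop("unknown product in reaction ", j)
    i1[j] <- if (length(idx) >= 1L) idx[1L] else 0L
    i2[j] <- if (length(idx) == 2L) idx[2L] else 0L
    for (i in idx)  S[i, j] <- S[i, j] - 1
    for (i in pidx) S[i, j] <- S[i, j] + 1
    if (is.null(rx$rate)) stop("reaction ", j, " has no rate")
    rate_name[j] <- rx$rate
  }
  if (!all(rate_name %in% names(rates))) {
    stop("rate constants missing for: ",
         paste(setdiff(rate_name, names(rates)), collapse = ", "))
  }
  if (any(rates < 0)) stop("rate constants must be >= 0")
  structure(list(
    species = species, x0 = x0, reactions = reactions,
    rates = rates, rate_name = rate_name,
    i1 = i1, i2 = i2, S = S, conservation = conservation
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions, ",
      length(x$rates), " rate constants\n", sep = "")
  invisible(x)
}

# Resolved rate vector (one value per reaction), with optional overrides.
reaction_rate_vector <- function(net, params = NULL) {
  rates <- net$rates
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(rates))
    if (length(unknown)) {
      stop("unknown rate constant(s): ", paste(unknown, collapse = ", "))
    }
    rates[names(params)] <- params
  }
  unname(rates[net$rate_name])
}

#' Integrate a reaction network
#'
#' Deterministic mass-action kinetics integrated with a stiff solver.
#' The binding layer mixes fast enforced-proximity closures with slow
#' activation kinetics, so the default is lsoda with tight tolerances.
#'
#' @param net a [mk_network()] object.
#' @param times numeric vector of output times (min); must start at 0.
#' @param params optional named numeric overriding rate constants.
#' @param x0 optional initial state (defaults to the network's).
#' @param rtol,atol solver tolerances.
#' @param method deSolve integrator name.
#' @param rate_fn optional function(t, x, k) -> k, applied to the
#'   per-reaction rate vector at every evaluation (used for the
#'   non-mass-action phosphorylation rule variants of the EAM).
#' @return matrix with a \code{time} column and one column per species.
#' @export
simulate_network <- function(net, times, params = NULL, x0 = NULL,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda",
                             rate_fn = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (is.null(x0)) x0 <- net$x0
  x0 <- x0[net$species]
  k <- reaction_rate_vector(net, params)
  i1 <- net$i1
  i2 <- net$i2
  S <- net$S
  rhs <- if (is.null(rate_fn)) {
    function(t, x, p) {
      xx <- c(1, x)
      v <- k * xx[i1 + 1L] * xx[i2 + 1L]
      list(S %*% v)
    }
  } else {
    function(t, x, p) {
      xx <- c(1, x)
      kk <- rate_fn(t, x, k)
      v <- kk * xx[i1 + 1L] * xx[i2 + 1L]
      list(S %*% v)
    }
  }
  out <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0) {
    stop("integration failed (istate = ", attr(out, "istate")[1L], ")")
  }
  scale <- max(abs(x0), 1)
  if (min(out[, -1L]) < -1e-6 * scale) {
    stop("integration produced negative abundances beyond tolerance")
  }
  colnames(out)[1L] <- "time"
  class(out) <- "matrix"
  out
}

# Right-hand-side residual at a state (used to verify pre-equilibrated
# initial conditions really are fixed points).
network_residual <- function(net, x, params = NULL) {
  k <- reaction_rate_vector(net, params)
  xx <- c(1, x[net$species])
  v <- k * xx[net$i1 + 1L] * xx[net$i2 + 1L]
  drop(net$S %*% v)
}

#' Check conserved totals along a trajectory
#'
#' @param net network with a \code{conservation} list.
#' @param traj trajectory matrix from [simulate_network()].
#' @param rel_tol maximum allowed relative drift.
#' @return invisibly TRUE; errors if any conserved total drifts.
#' @export
check_conservation <- function(net, traj, rel_tol = 1e-6) {
  if (is.null(net$conservation)) return(invisible(TRUE))
  for (nm in names(net$conservation)) {
    w <- net$conservation[[nm]]
    tot <- as.vector(traj[, names(w), drop = FALSE] %*% w)
    ref <- tot[1L]
    if (ref > 0 && max(abs(tot - ref)) > rel_tol * ref) {
      stop("conserved total '", nm, "' drifts by ",
           signif(max(abs(tot - ref)) / ref, 3), " (relative)")
    }
  }
  invisible(TRUE)
}
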