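# Early Activation Model (EAM) -------------------------------------------
#
# Replaces the phenomenological Hill input of the MPM/MPM-B with the
# molecular steps of receptor activation: conformational opening and
# closing of the ectodomain (only the extended form dimerizes), EGF
# binding (which stabilizes the extended form), and reversible
# dimerization.  Dimers are not tracked as explicit pair species;
# receptors are followed as individual moieties whose pairing partner
# is drawn from the current dimer pool (mean-field mixing).  A tyrosine
# is phosphorylated only on a moiety whose dimer partner is EGF-bound,
# so the effective per-site kinase rate is k_KIN times the fraction of
# moieties with an EGF-loaded partner, which in moiety coordinates is
# exactly DL / R_T.
#
# Activation-layer species (moieties):
#   Mc, McL : closed monomer, without / with EGF
#   Me, MeL : extended monomer
#   D,  DL  : dimer member
# The C-terminal tail (three tyrosines plus the Cbl/Grb2 binding layer)
# reuses the MPM-B state space, with phosphorylation catalysed by DL.

#' EAM parameter set
#'
#' Thermodynamic consistency of the ligand x conformation cycle is
#' built in through the stabilization factor \code{omega}: EGF
#' dissociates omega-fold slower from the extended form, and
#' EGF-bound receptors close omega-fold slower.
#'
#' @param k_open,k_close conformational rates (min^-1) of the
#'   ligand-free receptor; the basal equilibrium strongly favours the
#'   closed form.
#' @param k_egf_on EGF association rate (per ng/ml per min).
#' @param k_egf_off EGF dissociation rate from the closed form (min^-1).
#' @param omega fold-stabilization of the extended form by EGF (>= 1).
#' @param k_dim_on dimerization rate (cell molecule^-1 min^-1);
#'   dimerization is proportional to the product of all dimerizing
#'   species.
#' @param k_dim_off dimer dissociation rate (min^-1); dimers are
#'   short-lived, continuously formed and disrupted.
#' @param k_kin,k_ptp per-site phosphorylation (at full partner
#'   loading) and dephosphorylation rates (min^-1).
#' @param kb45,ku45,kb68,ku68,kbcg,kucg,floc Cbl/Grb2 binding layer,
#'   as in [mpmb_params()].
#' @param r_total,cbl_total,grb2_total molecule counts per cell.
#' @param k_ub ubiquitination proportionality constant.
#' @param t_end readout time (min).
#' @param phospho_rule "partner_bound" (a moiety is a kinase substrate
#'   only when its partner carries EGF) or "either_bound" (any dimer
#'   with at least one EGF-loaded member phosphorylates both tails).
#' @return list of class \code{eam_params}.
#' @export
eam_params <- function(k_open = 1, k_close = 20,
                       k_egf_on = 3.04, k_egf_off = 6, omega = 1.16,
                       k_dim_on = 1.29e-4, k_dim_off = 10,
                       k_kin = 8.03, k_ptp = 0.639,
                       kb45 = 1.16e-4, ku45 = 42.3,
                       kb68 = 2.01e-5, ku68 = 6.54,
                       kbcg = 4.40e-7, kucg = 4.62,
                       floc = 2.54e9,
                       r_total = 3e5, cbl_total = 5000, grb2_total = 1e6,
                       k_ub = 1, t_end = 2,
                       phospho_rule = c("partner_bound", "either_bound")) {
  phospho_rule <- match.arg(phospho_rule)
  p <- list(k_open = k_open, k_close = k_close,
            k_egf_on = k_egf_on, k_egf_off = k_egf_off, omega = omega,
            k_dim_on = k_dim_on, k_dim_off = k_dim_off,
            k_kin = k_kin, k_ptp = k_ptp,
            kb45 = kb45, ku45 = ku45, kb68 = kb68, ku68 = ku68,
            kbcg = kbcg, kucg = kucg, floc = floc,
            r_total = r_total, cbl_total = cbl_total,
            grb2_total = grb2_total, k_ub = k_ub, t_end = t_end,
            phospho_rule = phospho_rule)
  num <- unlist(p[setdiff(names(p), "phospho_rule")])
  stopifnot(all(num >= 0), omega >= 1, floc >= 1, r_total > 0)
  structure(p, class = c("eam_params", "list"))
}

#' Check thermodynamic closure of the ligand x conformation cycle
#'
#' For explicitly supplied cycle rates, the product of equilibrium
#' constants around closed/extended x free/EGF-bound must be one.
#'
#' @param k_open,k_close,k_on_closed,k_off_closed,k_on_ext,k_off_ext,
#'   k_open_l,k_close_l the eight cycle rates.
#' @param tol relative tolerance.
#' @return invisibly TRUE; errors naming the violated closure.
#' @export
check_cycle_closure <- function(k_open, k_close, k_on_closed, k_off_closed,
                                k_on_ext, k_off_ext, k_open_l, k_close_l,
                                tol = 1e-8) {
  lhs <- (k_open / k_close) * (k_on_ext / k_off_ext)
  rhs <- (k_on_closed / k_off_closed) * (k_open_l / k_close_l)
  if (abs(lhs - rhs) > tol * max(lhs, rhs)) {
    stop("ligand/conformation cycle violates detailed balance: ",
         "(k_open/k_close)*(kon_e/koff_e) = ", signif(lhs, 6),
         " but (kon_c/koff_c)*(k_open_L/k_close_L) = ", signif(rhs, 6))
  }
  invisible(TRUE)
}

.eam_act_species <- c("Mc", "McL", "Me", "MeL", "D", "DL")

.eam_rate_values <- function(params, egf) {
  kegf <- params$k_egf_on * egf
  koff_e <- params$k_egf_off / params$omega
  kclose_l <- params$k_close / params$omega
  c(kopen = params$k_open, kclose = params$k_close,
    kopen_l = params$k_open, kclose_l = kclose_l,
    kegf = kegf, koff_c = params$k_egf_off, koff_e = koff_e,
    kdim = params$k_dim_on, kdim2 = 2 * params$k_dim_on,
    kdimoff = params$k_dim_off,
    # tail: phosphorylation is catalysed by DL at k_kin / R_T per site
    akin = params$k_kin / params$r_total,
    kptp = params$k_ptp,
    kb45 = params$kb45, ku45 = params$ku45,
    kb68 = params$kb68, ku68 = params$ku68,
    kbcg = params$kbcg, kucg = params$kucg,
    kb45s = params$floc * params$kb45,
    kb68s = params$floc * params$kb68,
    kbcgs = params$floc * params$kbcg)
}

.eam_act_reactions <- function() {
  list(
    list(rate = "kopen",   reactants = "Mc",  products = "Me"),
    list(rate = "kclose",  reactants = "Me",  products = "Mc"),
    list(rate = "kopen_l", reactants = "McL", products = "MeL"),
    list(rate = "kclose_l", reactants = "MeL", products = "McL"),
    list(rate = "kegf",    reactants = "Mc",  products = "McL"),
    list(rate = "koff_c",  reactants = "McL", products = "Mc"),
    list(rate = "kegf",    reactants = "Me",  products = "MeL"),
    list(rate = "koff_e",  reactants = "MeL", products = "Me"),
    list(rate = "kegf",    reactants = "D",   products = "DL"),
    list(rate = "koff_e",  reactants = "DL",  products = "D"),
    list(rate = "kdim",    reactants = c("Me", "Me"),   products = c("D", "D")),
    list(rate = "kdim2",   reactants = c("Me", "MeL"),  products = c("D", "DL")),
    list(rate = "kdim",    reactants = c("MeL", "MeL"), products = c("DL", "DL")),
    list(rate = "kdimoff", reactants = "D",   products = "Me"),
    list(rate = "kdimoff", reactants = "DL",  products = "MeL"))
}

# EGF-free steady state of the activation layer (closed form): extended
# monomers e satisfy (1 + k_close/k_open) e + (2 k_dim_on/k_dim_off) e^2
# = R_T; no ligand, so DL = 0 and the tail is unphosphorylated.
.eam_x0 <- function(params, species) {
  x0 <- stats::setNames(numeric(length(species)), species)
  B <- 1 + params$k_close / params$k_open
  A <- if (params$k_dim_off > 0) 2 * params$k_dim_on / params$k_dim_off else 0
  e <- if (A > 0) {
    (-B + sqrt(B^2 + 4 * A * params$r_total)) / (2 * A)
  } else params$r_total / B
  x0["Me"] <- e
  x0["Mc"] <- e * params$k_close / params$k_open
  x0["D"] <- params$r_total - x0["Me"] - x0["Mc"]
  tail_x0 <- .mpmb_x0(params, setdiff(species, .eam_act_species))
  x0[names(tail_x0)] <- tail_x0
  x0
}

#' Assemble the EAM reaction network
#'
#' @param params an [eam_params()] object.
#' @param mutant tail configuration (default "3yplus"; normalized WT
#'   curves coincide with the 3Y+ add-back, so the tail keeps only the
#'   three adaptor-competent tyrosines).
#' @param egf EGF dose used to set ligand-binding rates.
#' @return a \code{reaction_network}; simulate with [simulate_eam()].
#' @export
build_eam <- function(params, mutant = "3yplus", egf = 0) {
  stopifnot(inherits(params, "eam_params"))
  check_cycle_closure(params$k_open, params$k_close,
                      params$k_egf_on, params$k_egf_off,
                      params$k_egf_on, params$k_egf_off / params$omega,
                      params$k_open, params$k_close / params$omega)
  tail_species <- enumerate_species(mutant)
  species <- c(.eam_act_species, tail_species)
  sites <- .mutant_sites(mutant)
  tail_rx <- .mpmb_reactions(tail_species, sites)
  # phosphorylation becomes second order, catalysed by EGF-loaded dimer
  # members (DL); everything else in the tail is unchanged
  tail_rx <- lapply(tail_rx, function(r) {
    if (r$rate == "akin") {
      r$reactants <- c(r$reactants, "DL")
      r$products <- c(r$products, "DL")
    }
    r
  })
  info <- .mpmb_species_info(tail_species)
  net <- mk_network(
    species, .eam_x0(params, species),
    c(.eam_act_reactions(), tail_rx),
    .eam_rate_values(params, egf),
    conservation = list(
      moiety = stats::setNames(rep(1, 6L), .eam_act_species),
      receptor = stats::setNames(rep(1, sum(info$is_receptor)),
                                 tail_species[info$is_receptor]),
      cbl = stats::setNames(info$n_cbl[info$n_cbl > 0],
                            tail_species[info$n_cbl > 0]),
      grb2 = stats::setNames(info$n_grb2[info$n_grb2 > 0],
                             tail_species[info$n_grb2 > 0])))
  attr(net, "species_info") <- info
  attr(net, "mutant") <- mutant
  net
}

# rate modifier implementing the "either_bound" kinase-competence
# variant: substrates are all dimer members belonging to a dimer with
# at least one EGF-loaded moiety, estimated mean-field from (D, DL)
.eam_rate_fn <- function(net, params) {
  if (params$phospho_rule == "partner_bound") return(NULL)
  akin_idx <- which(net$rate_name == "akin")
  iD <- match("D", net$species)
  iDL <- match("DL", net$species)
  function(t, x, k) {
    dtot <- x[iD] + x[iDL]
    if (dtot > 0 && x[iDL] > 0) {
      competent <- dtot * (1 - (x[iD] / dtot)^2)
      # reactions carry x[DL] as the catalyst; rescale to `competent`
      k[akin_idx] <- k[akin_idx] * competent / x[iDL]
    }
    k
  }
}

#' Simulate the EAM from the EGF-free steady state
#'
#' @param params an [eam_params()].
#' @param egf dose (ng/ml).
#' @param mutant tail configuration.
#' @param t_end readout time (min).
#' @param net optional prebuilt network from [build_eam()].
#' @param rtol,atol solver tolerances.
#' @return list of class \code{eam_state}: species vector \code{x},
#'   tail \code{info}, \code{activation} (fraction of moieties with an
#'   EGF-loaded partner), plus metadata.  Compatible with
#'   [ubiquitination()] and [bound_cbl_breakdown()] readouts through
#'   the shared \code{mpmb_state} contract.
#' @export
simulate_eam <- function(params, egf, mutant = "3yplus",
                         t_end = params$t_end, net = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "eam_params"), egf >= 0)
  if (is.null(net)) net <- build_eam(params, mutant)
  traj <- simulate_network(net, times = c(0, t_end),
                           params = .eam_rate_values(params, egf),
                           x0 = .eam_x0(params, net$species),
                           rtol = rtol, atol = atol,
                           rate_fn = .eam_rate_fn(net, params))
  check_conservation(net, traj, rel_tol = 1e-6)
  x <- traj[nrow(traj), -1L]
  structure(list(x = x[!names(x) %in% .eam_act_species],
                 moieties = x[.eam_act_species],
                 activation = unname(x["DL"] / params$r_total),
                 info = attr(net, "species_info"),
                 params = params, egf = egf, t = t_end,
                 mutant = attr(net, "mutant")),
            class = c("eam_state", "mpmb_state"))
}

#' EAM dose-response curve
#'
#' @inheritParams mpmb_dose_response
#' @param params an [eam_params()].
#' @export
eam_dose_response <- function(params, egf_grid = default_dose_grid(),
                              mutant = "3yplus",
                              readout = c("Ub", "pY", "cbl_bound"),
                              t_end = params$t_end, net = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  readout <- match.arg(readout)
  if (is.null(net)) net <- build_eam(params, mutant)
  vals <- vapply(egf_grid, function(d) {
    st <- simulate_eam(params, d, t_end = t_end, net = net,
                       rtol = rtol, atol = atol)
    switch(readout,
           Ub = ubiquitination(st),
           pY = mpmb_total_py(st),
           cbl_bound = sum(bound_cbl_breakdown(st)))
  }, numeric(1))
  dose_response(egf_grid, vals,
                kind = if (readout == "pY") "pY" else if (readout == "Ub")
                  "Ub" else "cbl_bound")
}

#' Per-receptor phosphorylation and ubiquitination surfaces
#'
#' Scans EGF dose against receptor surface density and reports pY/R_T
#' and Ub/R_T, normalized to their maxima at the highest dose of the
#' grid (the presentation used for receptor-titration experiments).
#'
#' @param params an [eam_params()] (its \code{r_total} is replaced by
#'   each grid value).
#' @param egf_grid EGF doses (ng/ml).
#' @param rt_grid receptor numbers per cell.
#' @param cbl_factor fold change applied to \code{cbl_total} (for Cbl
#'   rescue scenarios).
#' @return data.frame with columns \code{egf_ng_per_ml}, \code{r_total},
#'   \code{py_per_r}, \code{ub_per_r}, \code{py_per_r_norm},
#'   \code{ub_per_r_norm}.
#' @export
dose_receptor_surface <- function(params, egf_grid = c(1, 10, 100),
                                  rt_grid = 10^seq(4, 7, length.out = 10L),
                                  cbl_factor = 1) {
  stopifnot(all(egf_grid > 0), all(rt_grid > 0))
  rows <- list()
  for (rt in rt_grid) {
    p <- params
    p$r_total <- rt
    p$cbl_total <- params$cbl_total * cbl_factor
    net <- build_eam(p)
    for (d in egf_grid) {
      st <- simulate_eam(p, d, net = net)
      rows[[length(rows) + 1L]] <- data.frame(
        egf_ng_per_ml = d, r_total = rt,
        py_per_r = mpmb_total_py(st) / rt,
        ub_per_r = ubiquitination(st) / rt)
    }
  }
  out <- do.call(rbind, rows)
  top <- out$egf_ng_per_ml == max(egf_grid)
  out$py_per_r_norm <- out$py_per_r / max(out$py_per_r[top])
  out$ub_per_r_norm <- out$ub_per_r / max(out$ub_per_r[top])
  out
}

#' Named EAM scenario overlays
#'
#' Documented parameter overlays for the experimental settings explored
#' with the model: HeLa baseline, incomplete EGFR knockdown (4.2-fold
#' receptor loss), the three NIH 3T3 EGFR clones, 100-fold Cbl
#' overexpression, and the kinase-activated, Cbl-binding-impaired
#' L834R receptor (5-fold k_KIN, 10-fold lower kb45).
#'
#' @param name scenario name.
#' @return list with \code{multiply} (named factors) and \code{set}
#'   (named absolute values); apply with [apply_scenario()].
#' @export
eam_scenario <- function(name = c("hela_default", "egfr_kd", "nih_phy",
                                  "nih_mov", "nih_hov", "cbl_oe_x100",
                                  "l834r")) {
  name <- match.arg(name)
  ov <- switch(name,
    hela_default = list(multiply = list(), set = list()),
    egfr_kd = list(multiply = list(r_total = 1 / 4.2), set = list()),
    nih_phy = list(multiply = list(), set = list(r_total = 7e4)),
    nih_mov = list(multiply = list(), set = list(r_total = 2e5)),
    nih_hov = list(multiply = list(), set = list(r_total = 6e5)),
    cbl_oe_x100 = list(multiply = list(cbl_total = 100), set = list()),
    l834r = list(multiply = list(k_kin = 5, kb45 = 0.1), set = list()))
  ov$name <- name
  ov
}

#' Apply a scenario overlay to a parameter set
#'
#' @param params [eam_params()] or [mpmb_params()].
#' @param overlay from [eam_scenario()].
#' @export
apply_scenario <- function(params, overlay) {
  for (nm in names(overlay$multiply)) {
    params[[nm]] <- params[[nm]] * overlay$multiply[[nm]]
  }
  for (nm in names(overlay$set)) params[[nm]] <- overlay$set[[nm]]
  params
}

#' Ubiquitination threshold of the EAM
#'
#' Convenience metric runner used by the sensitivity screens.
#'
#' @param params an [eam_params()].
#' @param egf_grid dose grid for the threshold.
#' @export
eam_threshold <- function(params, egf_grid = default_dose_grid(n = 10L)) {
  as.numeric(threshold_xt(eam_dose_response(params, egf_grid, readout = "Ub")))
}
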