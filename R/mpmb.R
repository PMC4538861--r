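# MPM-B: the MPM plus cooperative Cbl/Grb2 binding -----------------------
#
# The three ubiquitination-relevant tyrosines are resolved explicitly:
# Y1045 docks Cbl directly, Y1068 and Y1086 dock Grb2, and Cbl and Grb2
# also bind each other in solution.  Once one arm of a Cbl:Grb2 pair is
# receptor-bound, the remaining ring-closing step becomes a fast
# first-order reaction whose rate is the solution rate scaled by the
# enforced-proximity factor fLOC (an effective local concentration in
# molecules per cell).  Ubiquitination is proportional to the number of
# receptors carrying at least one Cbl.
#
# Occupied phosphotyrosines are protected from phosphatases (bound
# SH2/TKB modules shield the site); only bare pY is dephosphorylated.
#
# Per-site codes:
#   Y1045:      Y | P | PC  (pY.Cbl) | PCG (pY.Cbl.Grb2, Grb2 dangling)
#   Y1068/86:   Y | P | PG  (pY.Grb2) | PGC (pY.Grb2.Cbl, Cbl dangling)
# plus a bridge flag (n | b68 | b86) marking that the Cbl at 1045 and
# the Grb2 at 1068 (or 1086) belong to one doubly-bound complex.

.S45 <- c("Y", "P", "PC", "PCG")
.S68 <- c("Y", "P", "PG", "PGC")

.mpmb_mutants <- function() c("3yplus", "wt", "y1045plus", "y106886plus")

.mutant_sites <- function(mutant) {
  switch(mutant,
    "3yplus" = , "wt" = c(s45 = TRUE, s68 = TRUE, s86 = TRUE),
    "y1045plus" = c(s45 = TRUE, s68 = FALSE, s86 = FALSE),
    "y106886plus" = c(s45 = FALSE, s68 = TRUE, s86 = TRUE),
    stop("unknown mutant: ", mutant,
         " (valid: ", paste(.mpmb_mutants(), collapse = ", "), ")"))
}

.rname <- function(s45, s68, s86, br) paste("R", s45, s68, s86, br, sep = ".")

#' MPM-B parameter set
#'
#' Molecule counts default to the HeLa measurements (3e5 surface EGFR,
#' 1e6 Grb2, 5e3 binding-competent Cbl); binding rates default to the
#' values obtained by fitting the bundled synthetic dose-response
#' defaults (see the methods vignette).
#'
#' @param k_kin,k_ptp,hill_n,hill_j per-site phosphorylation /
#'   dephosphorylation rates (min^-1) and Hill input parameters, as in
#'   [mpm_params()].
#' @param kb45,ku45 Cbl <-> pY1045 on (cell molecule^-1 min^-1) and off
#'   (min^-1) rates.
#' @param kb68,ku68 Grb2 <-> pY1068/pY1086 on/off rates.
#' @param kbcg,kucg Cbl <-> Grb2 on/off rates (solution and dangling
#'   arms).
#' @param floc enforced-proximity factor (>= 1, molecules per cell):
#'   ring-closure rates are kb45* = floc*kb45, kb68* = floc*kb68,
#'   kbcg* = floc*kbcg.  floc = 1 gives the noncooperative variant.
#' @param cbl_total EGFR-binding-competent Cbl per cell.
#' @param grb2_total Grb2 per cell.
#' @param r_total receptors per cell.
#' @param k_ub proportionality constant mapping Cbl-bound receptors to
#'   the ubiquitination signal.
#' @param t_end readout time (min).
#' @return list of class \code{mpmb_params}.
#' @export
mpmb_params <- function(k_kin = 0.267, k_ptp = 0.639, hill_n = 1,
                        hill_j = 2.77,
                        kb45 = 1.16e-4, ku45 = 42.3,
                        kb68 = 2.01e-5, ku68 = 6.54,
                        kbcg = 4.40e-7, kucg = 4.62,
                        floc = 2.54e9,
                        cbl_total = 5000, grb2_total = 1e6, r_total = 3e5,
                        k_ub = 1, t_end = 2) {
  p <- list(k_kin = k_kin, k_ptp = k_ptp, hill_n = hill_n, hill_j = hill_j,
            kb45 = kb45, ku45 = ku45, kb68 = kb68, ku68 = ku68,
            kbcg = kbcg, kucg = kucg, floc = floc,
            cbl_total = cbl_total, grb2_total = grb2_total,
            r_total = r_total, k_ub = k_ub, t_end = t_end)
  rates <- unlist(p[c("k_kin", "k_ptp", "kb45", "ku45", "kb68", "ku68",
                      "kbcg", "kucg")])
  stopifnot(all(rates >= 0), floc >= 1, cbl_total >= 0, grb2_total >= 0,
            r_total > 0, hill_n > 0, hill_j > 0, k_ub >= 0, t_end > 0)
  structure(p, class = c("mpmb_params", "list"))
}

#' Enumerate the MPM-B species list for a mutant
#'
#' Complete, duplicate-free state space: the product of per-site states
#' restricted to the mutant's phosphorylatable sites, bridged states
#' only where both participating sites are occupied, plus the three
#' cytosolic species.
#'
#' @param mutant one of "3yplus", "wt" (modelled as 3Y+), "y1045plus",
#'   "y106886plus".
#' @return character vector of species names.
#' @export
enumerate_species <- function(mutant = "3yplus") {
  sites <- .mutant_sites(mutant)
  s45 <- if (sites[["s45"]]) .S45 else "Y"
  s68 <- if (sites[["s68"]]) .S68 else "Y"
  s86 <- if (sites[["s86"]]) .S68 else "Y"
  g <- expand.grid(s45 = s45, s68 = s68, s86 = s86, br = c("n", "b68", "b86"),
                   stringsAsFactors = FALSE)
  ok <- (g$br == "n") |
    (g$br == "b68" & g$s45 == "PC" & g$s68 == "PG") |
    (g$br == "b86" & g$s45 == "PC" & g$s86 == "PG")
  g <- g[ok, , drop = FALSE]
  c(.rname(g$s45, g$s68, g$s86, g$br), "Cbl", "Grb2", "CblGrb2")
}

# species annotation: molecule counts and readout flags
.mpmb_species_info <- function(species) {
  is_rec <- startsWith(species, "R.")
  parts <- strsplit(species, ".", fixed = TRUE)
  n_cbl <- n_grb2 <- n_py <- integer(length(species))
  bridged <- logical(length(species))
  for (i in seq_along(species)) {
    if (is_rec[i]) {
      p <- parts[[i]]
      s45 <- p[2L]; s68 <- p[3L]; s86 <- p[4L]; br <- p[5L]
      n_cbl[i] <- (s45 %in% c("PC", "PCG")) + (s68 == "PGC") + (s86 == "PGC")
      n_grb2[i] <- (s45 == "PCG") + (s68 %in% c("PG", "PGC")) +
        (s86 %in% c("PG", "PGC"))
      n_py[i] <- (s45 != "Y") + (s68 != "Y") + (s86 != "Y")
      bridged[i] <- br != "n"
    } else {
      n_cbl[i] <- as.integer(species[i] %in% c("Cbl", "CblGrb2"))
      n_grb2[i] <- as.integer(species[i] %in% c("Grb2", "CblGrb2"))
    }
  }
  data.frame(name = species, is_receptor = is_rec, n_cbl = n_cbl,
             n_grb2 = n_grb2, n_py = n_py, bridged = bridged,
             has_cbl = is_rec & n_cbl > 0, stringsAsFactors = FALSE)
}

# reaction list for one receptor configuration; grb2 sites handled
# symmetrically through `gsite` = "68" or "86"
.mpmb_reactions <- function(species, sites) {
  rec <- species[startsWith(species, "R.")]
  states <- do.call(rbind, strsplit(sub("^R\\.", "", rec), ".", fixed = TRUE))
  colnames(states) <- c("s45", "s68", "s86", "br")
  rx <- list()
  add <- function(rate, reactants, products) {
    rx[[length(rx) + 1L]] <<- list(rate = rate, reactants = reactants,
                                   products = products)
  }
  nm <- function(st) .rname(st[["s45"]], st[["s68"]], st[["s86"]], st[["br"]])
  gcols <- c("68" = "s68", "86" = "s86")
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    self <- nm(st)
    br <- st[["br"]]
    # --- site Y1045
    s45 <- st[["s45"]]
    if (s45 == "Y" && sites[["s45"]]) {
      add("akin", self, nm(replace(st, "s45", "P")))
    } else if (s45 == "P") {
      add("kptp", self, nm(replace(st, "s45", "Y")))
      add("kb45", c(self, "Cbl"), nm(replace(st, "s45", "PC")))
      add("kb45", c(self, "CblGrb2"), nm(replace(st, "s45", "PCG")))
    } else if (s45 == "PC" && br == "n") {
      add("ku45", self, c(nm(replace(st, "s45", "P")), "Cbl"))
      add("kbcg", c(self, "Grb2"), nm(replace(st, "s45", "PCG")))
    } else if (s45 == "PCG") {
      add("ku45", self, c(nm(replace(st, "s45", "P")), "CblGrb2"))
      add("kucg", self, c(nm(replace(st, "s45", "PC")), "Grb2"))
    }
    # --- Grb2 sites (Y1068, Y1086)
    for (g in c("68", "86")) {
      col <- gcols[[g]]
      sg <- st[[col]]
      in_bridge <- br == paste0("b", g)
      if (sg == "Y" && sites[[col]]) {
        add("akin", self, nm(replace(st, col, "P")))
      } else if (sg == "P") {
        add("kptp", self, nm(replace(st, col, "Y")))
        add("kb68", c(self, "Grb2"), nm(replace(st, col, "PG")))
        add("kb68", c(self, "CblGrb2"), nm(replace(st, col, "PGC")))
      } else if (sg == "PG" && !in_bridge) {
        add("ku68", self, c(nm(replace(st, col, "P")), "Grb2"))
        add("kbcg", c(self, "Cbl"), nm(replace(st, col, "PGC")))
      } else if (sg == "PGC") {
        add("ku68", self, c(nm(replace(st, col, "P")), "CblGrb2"))
        add("kucg", self, c(nm(replace(st, col, "PG")), "Cbl"))
      }
      # --- ring closures into a bridge (first-order, fLOC-enhanced)
      if (br == "n") {
        bst <- replace(replace(replace(st, "s45", "PC"), col, "PG"),
                       "br", paste0("b", g))
        if (s45 == "PCG" && sg == "P")  add("kb68s", self, nm(bst))
        if (s45 == "P"   && sg == "PGC") add("kb45s", self, nm(bst))
        if (s45 == "PC"  && sg == "PG")  add("kbcgs", self, nm(bst))
      }
      # --- bridge opening (one bond at a time)
      if (in_bridge) {
        op <- replace(st, "br", "n")
        add("ku68", self, nm(replace(replace(op, "s45", "PCG"), col, "P")))
        add("ku45", self, nm(replace(replace(op, "s45", "P"), col, "PGC")))
        add("kucg", self, nm(op))
      }
    }
  }
  # cytosolic Cbl:Grb2 pre-complex
  add("kbcg", c("Cbl", "Grb2"), "CblGrb2")
  add("kucg", "CblGrb2", c("Cbl", "Grb2"))
  rx
}

# bridged states generate their own dephosphorylation reactions above;
# the per-site blocks skip them via the `in_bridge` / br == "n" guards.

.mpmb_rate_values <- function(params, egf) {
  a <- hill_activation(egf, params$hill_n, params$hill_j)
  c(akin = a * params$k_kin, kptp = params$k_ptp,
    kb45 = params$kb45, ku45 = params$ku45,
    kb68 = params$kb68, ku68 = params$ku68,
    kbcg = params$kbcg, kucg = params$kucg,
    kb45s = params$floc * params$kb45,
    kb68s = params$floc * params$kb68,
    kbcgs = params$floc * params$kbcg)
}

# EGF-free steady state: unphosphorylated receptors plus the closed-form
# solution Cbl:Grb2 equilibrium
.mpmb_x0 <- function(params, species) {
  x0 <- stats::setNames(numeric(length(species)), species)
  x0[.rname("Y", "Y", "Y", "n")] <- params$r_total
  ct <- params$cbl_total; gt <- params$grb2_total
  if (params$kbcg > 0 && ct > 0 && gt > 0) {
    a <- params$kbcg
    b <- params$kbcg * (ct + gt) + params$kucg
    cc <- params$kbcg * ct * gt
    cg <- (b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  } else cg <- 0
  x0["CblGrb2"] <- cg
  x0["Cbl"] <- ct - cg
  x0["Grb2"] <- gt - cg
  x0
}

#' Assemble the MPM-B reaction network
#'
#' @param params an [mpmb_params()] object.
#' @param mutant receptor configuration (see [enumerate_species()]).
#' @param egf EGF dose used to set the kinase activation rate; can be
#'   overridden per simulation.
#' @return a \code{reaction_network}.
#' @export
build_mpmb <- function(params, mutant = "3yplus", egf = 0) {
  species <- enumerate_species(mutant)
  info <- .mpmb_species_info(species)
  net <- mk_network(
    species, .mpmb_x0(params, species),
    .mpmb_reactions(species, .mutant_sites(mutant)),
    .mpmb_rate_values(params, egf),
    conservation = list(
      receptor = stats::setNames(rep(1, sum(info$is_receptor)),
                                 species[info$is_receptor]),
      cbl = stats::setNames(info$n_cbl[info$n_cbl > 0],
                            species[info$n_cbl > 0]),
      grb2 = stats::setNames(info$n_grb2[info$n_grb2 > 0],
                             species[info$n_grb2 > 0])))
  attr(net, "species_info") <- info
  attr(net, "mutant") <- mutant
  net
}

#' Simulate MPM-B from the EGF-free steady state
#'
#' All species start at their steady state without EGF (no
#' phosphotyrosines, Cbl:Grb2 at its solution equilibrium); EGF is
#' added at time zero and the state is read at \code{t_end}.
#'
#' @param params an [mpmb_params()] object.
#' @param egf dose (ng/ml).
#' @param mutant receptor configuration.
#' @param t_end readout time (min).
#' @param net optional prebuilt network from [build_mpmb()] (reused
#'   across doses or fit iterations for speed).
#' @param rtol,atol solver tolerances.
#' @return list of class \code{mpmb_state}: \code{x} (named species
#'   abundances), \code{info}, \code{params}, \code{egf}, \code{t}.
#' @export
simulate_mpmb <- function(params, egf, mutant = "3yplus",
                          t_end = params$t_end, net = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "mpmb_params"), egf >= 0)
  if (is.null(net)) net <- build_mpmb(params, mutant)
  traj <- simulate_network(net, times = c(0, t_end),
                           params = .mpmb_rate_values(params, egf),
                           x0 = .mpmb_x0(params, net$species),
                           rtol = rtol, atol = atol)
  check_conservation(net, traj, rel_tol = 1e-6)
  structure(list(x = traj[nrow(traj), -1L],
                 info = attr(net, "species_info"),
                 params = params, egf = egf, t = t_end,
                 mutant = attr(net, "mutant")),
            class = "mpmb_state")
}

#' Ubiquitination signal of an MPM-B state
#'
#' Ub = k_ub times the number of receptors carrying at least one Cbl.
#' Receptors with two independently bound Cbl molecules count once:
#' ubiquitination is a per-receptor property.
#'
#' @param state an \code{mpmb_state}.
#' @param k_ub proportionality constant (defaults to the state's).
#' @export
ubiquitination <- function(state, k_ub = state$params$k_ub) {
  stopifnot(inherits(state, "mpmb_state"))
  k_ub * sum(state$x[state$info$has_cbl])
}

#' Singly versus doubly bound Cbl:EGFR complexes
#'
#' Partitions Cbl-carrying receptors by the bridge flag: doubly bound
#' complexes hold the receptor through pY1045 and, via Grb2, through
#' pY1068/86 simultaneously.
#'
#' @param state an \code{mpmb_state}.
#' @return named numeric: \code{singly_bound}, \code{doubly_bound}.
#' @export
bound_cbl_breakdown <- function(state) {
  stopifnot(inherits(state, "mpmb_state"))
  info <- state$info
  c(singly_bound = sum(state$x[info$has_cbl & !info$bridged]),
    doubly_bound = sum(state$x[info$has_cbl & info$bridged]))
}

#' Total phosphotyrosine of an MPM-B state
#'
#' @param state an \code{mpmb_state}.
#' @export
mpmb_total_py <- function(state) {
  stopifnot(inherits(state, "mpmb_state"))
  sum(state$x * state$info$n_py)
}

#' MPM-B dose-response curve
#'
#' @param params an [mpmb_params()].
#' @param egf_grid dose grid (ng/ml).
#' @param mutant receptor configuration.
#' @param readout "Ub", "pY" or "cbl_bound".
#' @param t_end readout time (min).
#' @param net optional prebuilt network.
#' @param rtol,atol solver tolerances.
#' @return a [dose_response()].
#' @export
mpmb_dose_response <- function(params, egf_grid = default_dose_grid(),
                               mutant = "3yplus",
                               readout = c("Ub", "pY", "cbl_bound"),
                               t_end = params$t_end, net = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  readout <- match.arg(readout)
  if (is.null(net)) net <- build_mpmb(params, mutant)
  vals <- vapply(egf_grid, function(d) {
    st <- simulate_mpmb(params, d, t_end = t_end, net = net,
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

#' Cbl modulation scenario (overexpression / dominant-negative)
#'
#' Overexpression and Cbl-70Z expression are modelled as a fold change
#' of the binding-competent Cbl pool.  Absolute ubiquitination scales
#' with Cbl availability while the normalized threshold stays put, as
#' long as basal Cbl remains limiting.
#'
#' @param params baseline [mpmb_params()].
#' @param factor fold change of \code{cbl_total} (> 0); 2 for
#'   overexpression, 0.5 for 70Z downregulation.
#' @param egf_grid dose grid.
#' @param mutant receptor configuration.
#' @return list with \code{absolute} and \code{normalized}
#'   [dose_response()]s, the scenario \code{x_t} and the baseline
#'   \code{x_t_baseline}.
#' @export
cbl_modulation_scenario <- function(params, factor,
                                    egf_grid = default_dose_grid(n = 12L),
                                    mutant = "3yplus") {
  stopifnot(factor > 0)
  base <- mpmb_dose_response(params, egf_grid, mutant, "Ub")
  mod_params <- params
  mod_params$cbl_total <- params$cbl_total * factor
  mod <- mpmb_dose_response(mod_params, egf_grid, mutant, "Ub")
  normalized <- dose_response(egf_grid, mod$readout, kind = "Ub")
  list(absolute = mod, normalized = normalized,
       x_t = threshold_xt(normalized), x_t_baseline = threshold_xt(base))
}

#' Scan basal Cbl for threshold invariance under modulation
#'
#' For each basal level of binding-competent Cbl, compares the
#' normalized threshold at 1x and \code{factor}x Cbl and reports the
#' largest basal level at which the threshold is unchanged
#' (|delta log10 x_T| < \code{tol}).
#'
#' @param params [mpmb_params()] (its \code{cbl_total} is replaced by
#'   each scanned level).
#' @param basal_grid basal Cbl levels to scan (molecules per cell).
#' @param factor modulation fold (default 2).
#' @param tol invariance tolerance on log10 x_T (default 0.05).
#' @param egf_grid dose grid used for each threshold.
#' @return list with \code{scan} (data.frame basal, x_t, x_t_mod,
#'   delta_log10) and \code{ceiling} (largest invariant basal level).
#' @export
cbl_ceiling_scan <- function(params,
                             basal_grid = 10^seq(log10(500), 5, length.out = 12L),
                             factor = 2, tol = 0.05,
                             egf_grid = default_dose_grid(n = 12L)) {
  rows <- lapply(basal_grid, function(b) {
    p1 <- params; p1$cbl_total <- b
    p2 <- params; p2$cbl_total <- b * factor
    x1 <- threshold_xt(mpmb_dose_response(p1, egf_grid, readout = "Ub"))
    x2 <- threshold_xt(mpmb_dose_response(p2, egf_grid, readout = "Ub"))
    data.frame(basal = b, x_t = as.numeric(x1), x_t_mod = as.numeric(x2),
               delta_log10 = abs(log10(x2 / x1)))
  })
  scan <- do.call(rbind, rows)
  ok <- scan$delta_log10 < tol & is.finite(scan$delta_log10)
  # the invariant region is contiguous from below: at very large basal
  # pools both curves become site-limited and the shift shrinks again,
  # so the ceiling is the last level before the first violation
  first_bad <- which(!ok)[1L]
  ceiling <- if (is.na(first_bad)) {
    max(scan$basal)
  } else if (first_bad == 1L) {
    NA_real_
  } else {
    scan$basal[first_bad - 1L]
  }
  list(scan = scan, ceiling = ceiling, factor = factor, tol = tol)
}
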