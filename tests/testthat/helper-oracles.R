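# Independent oracles used across the suite.  These deliberately avoid
# the package's reaction-network machinery: closed forms, brute-force
# enumeration, the chemical master equation, and explicit-dimer ODE
# systems written out by hand.

# closed-form per-site phosphorylation probability for the lumped chain:
# dp/dt = kappa (1 - p) - k_ptp p, p(0) = 0
oracle_p_site <- function(t, kappa, k_ptp) {
  tot <- kappa + k_ptp
  if (tot == 0) return(0)
  kappa / tot * (1 - exp(-tot * t))
}

# brute-force MPM-B species enumeration over the raw per-site product,
# filtering invalid bridge combinations
oracle_enumerate <- function(mutant) {
  s45_all <- c("Y", "P", "PC", "PCG")
  s68_all <- c("Y", "P", "PG", "PGC")
  allow <- switch(mutant,
    "3yplus" = , "wt" = list(s45_all, s68_all, s68_all),
    y1045plus = list(s45_all, "Y", "Y"),
    y106886plus = list("Y", s68_all, s68_all))
  out <- character(0)
  for (s45 in allow[[1]]) for (s68 in allow[[2]]) for (s86 in allow[[3]]) {
    for (br in c("n", "b68", "b86")) {
      ok <- switch(br,
        n = TRUE,
        b68 = s45 == "PC" && s68 == "PG",
        b86 = s45 == "PC" && s86 == "PG")
      if (ok) out <- c(out, paste("R", s45, s68, s86, br, sep = "."))
    }
  }
  c(out, "Cbl", "Grb2", "CblGrb2")
}

# exact first moment of the Michaelis-Menten scheme by integrating the
# chemical master equation (state = (#complex, #product); kinase count
# follows by conservation)
oracle_mm_cme_mean <- function(scheme, times) {
  nk <- scheme$n_kinase
  ns <- scheme$n_sites
  states <- expand.grid(C = 0:min(nk, ns), P = 0:ns)
  states <- states[states$C + states$P <= ns, ]
  ns_states <- nrow(states)
  idx <- function(C, P) which(states$C == C & states$P == P)
  Q <- matrix(0, ns_states, ns_states)
  for (i in seq_len(ns_states)) {
    C <- states$C[i]; P <- states$P[i]
    S <- ns - C - P; K <- nk - C
    a1 <- scheme$k_on * K * S
    a2 <- scheme$k_off * C
    a3 <- scheme$k_cat * C
    if (a1 > 0 && C + 1 <= min(nk, ns)) {
      j <- idx(C + 1, P); Q[j, i] <- Q[j, i] + a1; Q[i, i] <- Q[i, i] - a1
    }
    if (a2 > 0) {
      j <- idx(C - 1, P); Q[j, i] <- Q[j, i] + a2; Q[i, i] <- Q[i, i] - a2
    }
    if (a3 > 0) {
      j <- idx(C - 1, P + 1); Q[j, i] <- Q[j, i] + a3; Q[i, i] <- Q[i, i] - a3
    }
  }
  p0 <- numeric(ns_states)
  p0[idx(0, 0)] <- 1
  sol <- deSolve::ode(p0, times, function(t, y, parms) list(Q %*% y),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  as.vector(sol[, -1] %*% states$P)
}

# explicit-dimer reference for the EAM activation layer: monomers plus
# pair species Pff / Pfb / Pbb (dimers with 0, 1, 2 EGF-loaded members)
oracle_eam_activation <- function(params, egf, times) {
  kegf <- params$k_egf_on * egf
  koff_c <- params$k_egf_off
  koff_e <- params$k_egf_off / params$omega
  kcl_l <- params$k_close / params$omega
  kd <- params$k_dim_on
  rhs <- function(t, y, parms) {
    with(as.list(y), {
      M <- Me + MeL
      dMc  <- -params$k_open * Mc + params$k_close * Me - kegf * Mc +
        koff_c * McL
      dMcL <- -params$k_open * McL + kcl_l * MeL + kegf * Mc - koff_c * McL
      dMe  <- params$k_open * Mc - params$k_close * Me - kegf * Me +
        koff_e * MeL - 2 * kd * Me * M + params$k_dim_off * (2 * Pff + Pfb)
      dMeL <- params$k_open * McL - kcl_l * MeL + kegf * Me - koff_e * MeL -
        2 * kd * MeL * M + params$k_dim_off * (Pfb + 2 * Pbb)
      dPff <- kd * Me^2 - params$k_dim_off * Pff - 2 * kegf * Pff +
        koff_e * Pfb
      dPfb <- 2 * kd * Me * MeL - params$k_dim_off * Pfb + 2 * kegf * Pff -
        koff_e * Pfb - kegf * Pfb + 2 * koff_e * Pbb
      dPbb <- kd * MeL^2 - params$k_dim_off * Pbb + kegf * Pfb -
        2 * koff_e * Pbb
      list(c(dMc, dMcL, dMe, dMeL, dPff, dPfb, dPbb))
    })
  }
  B <- 1 + params$k_close / params$k_open
  A <- 2 * params$k_dim_on / params$k_dim_off
  e <- (-B + sqrt(B^2 + 4 * A * params$r_total)) / (2 * A)
  y0 <- c(Mc = e * params$k_close / params$k_open, McL = 0, Me = e,
          MeL = 0, Pff = (params$r_total - e * B) / 2, Pfb = 0, Pbb = 0)
  sol <- deSolve::ode(y0, times, rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  data.frame(time = sol[, "time"],
             D = 2 * sol[, "Pff"] + sol[, "Pfb"],
             DL = sol[, "Pfb"] + 2 * sol[, "Pbb"],
             Mc = sol[, "Mc"], McL = sol[, "McL"],
             Me = sol[, "Me"], MeL = sol[, "MeL"])
}

# hand-written site-resolved ODEs for the Y1045+ MPM-B network (seven
# species), used as the independent dual-solver check; integrated with
# radau rather than lsoda
oracle_y1045_trajectory <- function(params, egf, times) {
  a <- ubithresh::hill_activation(egf, params$hill_n, params$hill_j)
  akin <- a * params$k_kin
  kptp <- params$k_ptp
  # bound pY1045 is protected from dephosphorylation; only bare pY
  # (state RP) returns to RY
  rhs <- function(t, y, parms) {
    with(as.list(y), {
      dRY <- -akin * RY + kptp * RP
      dRP <- akin * RY - kptp * RP - params$kb45 * RP * (Cbl + CG) +
        params$ku45 * (RPC + RPCG)
      dRPC <- params$kb45 * RP * Cbl - params$ku45 * RPC -
        params$kbcg * RPC * Grb2 + params$kucg * RPCG
      dRPCG <- params$kb45 * RP * CG + params$kbcg * RPC * Grb2 -
        (params$ku45 + params$kucg) * RPCG
      dCbl <- -params$kb45 * RP * Cbl + params$ku45 * RPC -
        params$kbcg * Cbl * Grb2 + params$kucg * CG
      dGrb2 <- -params$kbcg * RPC * Grb2 + params$kucg * RPCG -
        params$kbcg * Cbl * Grb2 + params$kucg * CG
      dCG <- params$kbcg * Cbl * Grb2 - params$kucg * CG -
        params$kb45 * RP * CG + params$ku45 * RPCG
      list(c(dRY, dRP, dRPC, dRPCG, dCbl, dGrb2, dCG))
    })
  }
  ct <- params$cbl_total; gt <- params$grb2_total
  aa <- params$kbcg
  bb <- params$kbcg * (ct + gt) + params$kucg
  cc <- params$kbcg * ct * gt
  cg0 <- if (aa > 0) (bb - sqrt(bb^2 - 4 * aa * cc)) / (2 * aa) else 0
  y0 <- c(RY = params$r_total, RP = 0, RPC = 0, RPCG = 0,
          Cbl = ct - cg0, Grb2 = gt - cg0, CG = cg0)
  deSolve::ode(y0, times, rhs, parms = NULL, method = "radau",
               rtol = 1e-10, atol = 1e-10)
}

# weighted least-squares Hill fit by dense grid search (oracle for the
# Levenberg-Marquardt route)
oracle_hill_gridsearch <- function(x, y) {
  best <- NULL
  for (n in seq(0.2, 6, by = 0.02)) {
    for (lxh in seq(log10(min(x)), log10(max(x)), length.out = 160)) {
      xh <- 10^lxh
      m <- x^n / (xh^n + x^n)
      plateau <- sum(m * y) / sum(m * m)
      rss <- sum((plateau * m - y)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(n_h = n, x_half = xh, plateau = plateau, rss = rss)
      }
    }
  }
  best
}
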