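# a small, fast parameter set used for the structural checks; the
# shipped defaults are exercised by the acceptance suite
fast_mpmb <- function(...) {
  args <- utils::modifyList(
    list(k_kin = 2, k_ptp = 0.5, hill_n = 1, hill_j = 5,
         kb45 = 3e-5, ku45 = 30, kb68 = 3e-6, ku68 = 2,
         kbcg = 5e-6, kucg = 2, floc = 1e8,
         cbl_total = 5000, grb2_total = 1e6, r_total = 3e5),
    list(...))
  do.call(mpmb_params, args)
}

test_that("species enumeration matches the brute-force oracle", {
  for (m in c("3yplus", "wt", "y1045plus", "y106886plus")) {
    got <- enumerate_species(m)
    expect_setequal(got, oracle_enumerate(m))
    expect_false(anyDuplicated(got) > 0)
  }
  # single-site mutant: only the four Y1045 states plus cytosol
  expect_length(enumerate_species("y1045plus"), 7L)
  # no Cbl-at-1045 state reachable for the Grb2-only mutant
  expect_false(any(grepl("R\\.(PC|PCG)", enumerate_species("y106886plus"))))
  expect_error(enumerate_species("nonsense"), "unknown mutant")
})

test_that("without EGF nothing binds the receptor and Cbl:Grb2 sits at
           its solution equilibrium", {
  p <- fast_mpmb()
  st <- simulate_mpmb(p, egf = 0)
  expect_equal(unname(st$x["R.Y.Y.Y.n"]), p$r_total, tolerance = 1e-9)
  expect_equal(ubiquitination(st), 0, tolerance = 1e-6)
  cg <- st$x["CblGrb2"]
  expect_equal(unname(p$kbcg * st$x["Cbl"] * st$x["Grb2"] / cg), p$kucg,
               tolerance = 1e-6)
})

test_that("no ligase, no ubiquitination at any dose", {
  p <- fast_mpmb(cbl_total = 0)
  for (egf in c(1, 100)) {
    expect_equal(ubiquitination(simulate_mpmb(p, egf)), 0, tolerance = 1e-9)
  }
})

test_that("receptor, Cbl and Grb2 totals are conserved along the
           trajectory", {
  p <- fast_mpmb()
  net <- build_mpmb(p, "3yplus")
  traj <- simulate_network(net, times = seq(0, 2, by = 0.25),
                           params = ubithresh:::.mpmb_rate_values(p, 30))
  expect_true(check_conservation(net, traj, rel_tol = 1e-6))
})

test_that("the Y1045+ network matches an independently hand-written
           stiff-solver implementation", {
  p <- fast_mpmb()
  times <- seq(0, 2, by = 0.5)
  ref <- oracle_y1045_trajectory(p, egf = 20, times = times)
  net <- build_mpmb(p, "y1045plus")
  got <- simulate_network(net, times,
                          params = ubithresh:::.mpmb_rate_values(p, 20),
                          x0 = ubithresh:::.mpmb_x0(p, net$species),
                          rtol = 1e-10, atol = 1e-10)
  map <- c(RY = "R.Y.Y.Y.n", RP = "R.P.Y.Y.n", RPC = "R.PC.Y.Y.n",
           RPCG = "R.PCG.Y.Y.n", Cbl = "Cbl", Grb2 = "Grb2",
           CG = "CblGrb2")
  for (nm in names(map)) {
    expect_lt(max(abs(got[, map[[nm]]] - ref[, nm])) / p$r_total, 1e-8)
  }
})

test_that("ubiquitination is k_ub times the Cbl-carrying receptors,
           counted per receptor", {
  p <- fast_mpmb()
  st <- simulate_mpmb(p, 30)
  # species-tagging oracle: sum abundances of receptor species whose
  # name carries a Cbl in any position, once per receptor
  nm <- names(st$x)
  has_cbl <- grepl("^R\\.(PC|PCG)\\.", nm) |
    (startsWith(nm, "R.") & grepl("\\.PGC", nm))
  expect_equal(ubiquitination(st), sum(st$x[has_cbl]), tolerance = 1e-12)
  expect_equal(ubiquitination(st, k_ub = 2), 2 * ubiquitination(st),
               tolerance = 1e-12)
  bd <- bound_cbl_breakdown(st)
  expect_equal(unname(sum(bd)), sum(st$x[has_cbl]), tolerance = 1e-12)
})

test_that("doubling k_ub rescales the curve without moving its shape", {
  p <- fast_mpmb()
  net <- build_mpmb(p, "3yplus")
  grid <- default_dose_grid(n = 5)
  d1 <- mpmb_dose_response(p, grid, net = net)
  p2 <- p; p2$k_ub <- 2 * p$k_ub
  d2 <- mpmb_dose_response(p2, grid, net = net)
  expect_equal(d2$readout, 2 * d1$readout, tolerance = 1e-10)
  expect_equal(d2$readout_normalized, d1$readout_normalized,
               tolerance = 1e-10)
})

test_that("the Y1045+ mutant can never be doubly bound", {
  p <- fast_mpmb()
  st <- simulate_mpmb(p, 100, mutant = "y1045plus")
  expect_equal(unname(bound_cbl_breakdown(st)["doubly_bound"]), 0)
})

test_that("thermodynamic cycle is consistent between assembly orders", {
  p <- fast_mpmb()
  # bind Cbl then Grb2 arm closure versus bind Grb2 then Cbl arm
  # closure: equilibrium-constant products around the ring must match
  k1 <- (p$kb45 / p$ku45) * (p$kbcg / p$kucg) * (p$floc * p$kb68 / p$ku68)
  k2 <- (p$kb68 / p$ku68) * (p$kbcg / p$kucg) * (p$floc * p$kb45 / p$ku45)
  expect_equal(k1, k2, tolerance = 1e-12)
  # and the relaxed network with no phosphatase/kinase flux reaches an
  # equilibrium whose bridge occupancies are path-independent: detailed
  # balance holds on the closure reactions
  q <- fast_mpmb(k_kin = 0)
  q$k_ptp <- 0
  net <- build_mpmb(q, "3yplus")
  x0 <- ubithresh:::.mpmb_x0(q, net$species)
  # start from phosphorylated receptors so binding states are reachable
  x0["R.Y.Y.Y.n"] <- 0
  x0["R.P.P.P.n"] <- q$r_total
  traj <- simulate_network(net, c(0, 2000),
                           params = ubithresh:::.mpmb_rate_values(q, 0),
                           x0 = x0, rtol = 1e-10, atol = 1e-10)
  xeq <- traj[nrow(traj), -1]
  # flux balance on one closure: kbcgs * [PC,PG] = kucg * [bridge]
  lhs <- q$floc * q$kbcg * xeq[["R.PC.PG.P.n"]]
  rhs <- q$kucg * xeq[["R.PC.PG.P.b68"]]
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("Cbl modulation rescales ubiquitination but leaves the
           normalized threshold in place at the measured basal level", {
  p <- fast_mpmb()
  base <- cbl_modulation_scenario(p, 1, egf_grid = default_dose_grid(n = 8))
  expect_equal(base$x_t, base$x_t_baseline, tolerance = 1e-9)
  up <- cbl_modulation_scenario(p, 2, egf_grid = default_dose_grid(n = 8))
  dn <- cbl_modulation_scenario(p, 0.5, egf_grid = default_dose_grid(n = 8))
  expect_gt(max(up$absolute$readout), max(base$absolute$readout))
  expect_lt(max(dn$absolute$readout), max(base$absolute$readout))
  expect_lt(abs(log10(up$x_t / up$x_t_baseline)), 0.05)
  expect_lt(abs(log10(dn$x_t / dn$x_t_baseline)), 0.05)
})

test_that("ubiquitination dose-response is monotone on the grid", {
  p <- fast_mpmb()
  dr <- mpmb_dose_response(p, default_dose_grid(n = 8))
  expect_true(all(diff(dr$readout) >= -1e-8 * max(dr$readout)))
})
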