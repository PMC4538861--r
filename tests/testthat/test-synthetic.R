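test_that("zero noise reproduces the generating truth exactly", {
  cfg <- generator_config(cv = 0, replicates = 2, seed = 5)
  ds <- generate_dose_response(cfg)
  tr <- attr(ds, "truth")$ub_3yplus
  d <- ds[ds$condition == "ub_3yplus" & ds$replicate == 1, ]
  mu <- tr$plateau * d$egf_ng_per_ml^tr$n_h /
    (tr$x_half^tr$n_h + d$egf_ng_per_ml^tr$n_h)
  expect_equal(d$value, mu, tolerance = 1e-12)
  expect_equal(d$value_normalized, mu / max(mu), tolerance = 1e-12)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- generate_dose_response(generator_config(seed = 42))
  b <- generate_dose_response(generator_config(seed = 42))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_dose_response(generator_config(seed = 43))
  expect_false(identical(a$value, c$value))
})

test_that("replicate means converge to the truth (law of large numbers)", {
  cfg <- generator_config(cv = 0.1, replicates = 3000, seed = 9,
                          truths = default_truths()["ub_3yplus"])
  ds <- generate_dose_response(cfg)
  tr <- default_truths()$ub_3yplus
  mu <- tr$plateau * cfg$doses^tr$n_h / (tr$x_half^tr$n_h + cfg$doses^tr$n_h)
  m <- tapply(ds$value, ds$egf_ng_per_ml, mean)[as.character(cfg$doses)]
  se <- tapply(ds$value, ds$egf_ng_per_ml, sd)[as.character(cfg$doses)] /
    sqrt(cfg$replicates)
  expect_true(all(abs(m - mu) < 3 * pmax(se, 1e-12)))
})

test_that("Hill fits of the noise-free defaults recover the published
           steepness contrast", {
  ds <- generate_dose_response(generator_config(cv = 0, replicates = 1))
  f_ub <- fit_hill(dataset_curve(ds, "ub_3yplus"))
  f_py <- fit_hill(dataset_curve(ds, "py_3yplus"))
  expect_equal(f_ub$n_h, 3, tolerance = 1e-4)
  expect_equal(f_py$n_h, 1, tolerance = 1e-4)
})

test_that("cell profiles carry the measured molecule counts", {
  h <- cell_profile("hela")
  expect_equal(h$egfr, 3e5)
  expect_equal(h$grb2, 1e6)
  expect_equal(h$cbl_total, 1.5e5)
  expect_equal(h$cbl_available, 5e3)
  expect_equal(cell_profile("nih_phy")$egfr, 7e4)
  expect_equal(cell_profile("nih_mov")$egfr, 2e5)
  expect_equal(cell_profile("nih_hov")$egfr, 6e5)
  expect_equal(cell_profile("hela_egfr_kd")$egfr / h$egfr, 1 / 4.2)
  expect_error(cell_profile("hek293"))
})

test_that("mutant configurations list the phosphorylatable and
           adaptor-competent sites", {
  expect_equal(mutant_config("wt")$n_sites, 9L)
  expect_equal(mutant_config("3yplus")$n_sites, 3L)
  expect_length(mutant_config("y1045plus")$grb2_sites, 0L)
  expect_false(mutant_config("y106886plus")$cbl_site)
  expect_error(mutant_config("5yplus"))
})

test_that("apply_profile transfers counts into a parameter set", {
  p <- apply_profile(mpmb_params(), "nih_hov")
  expect_equal(p$r_total, 6e5)
  expect_equal(p$cbl_total, 5e3)
  expect_equal(p$grb2_total, 1e6)
})
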