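# synthetic quadratic test model: curve = plateau * x^n / (xh^n + x^n),
# free parameters recovered from self-generated data
.toy_problem <- function(truth = c(n = 2, xh = 3), noise = 0, seed = 1,
                         free = c("n", "xh"), weight = 1) {
  x <- 10^seq(-1.5, 1.5, length.out = 9)
  mu <- x^truth["n"] / (truth["xh"]^truth["n"] + x^truth["n"])
  set.seed(seed + 1000)
  y <- mu * if (noise > 0) rlnorm(length(mu), -noise^2 / 2, noise) else 1
  predict_fn <- function(fr) {
    p <- c(truth)
    p[names(fr)] <- fr
    list(curve = x^p["n"] / (p["xh"]^p["n"] + x^p["n"]))
  }
  fit_problem(predict_fn,
              targets = list(curve = list(y = y, weight = weight,
                                          group = "g1")),
              lower = setNames(truth[free] / 30, free),
              upper = setNames(truth[free] * 30, free),
              start = setNames(truth[free] * c(2.5, 0.4)[seq_along(free)],
                               free),
              seed = seed)
}

test_that("annealing plus simplex recovers parameters from noise-free
           self-generated data", {
  pr <- .toy_problem()
  fit <- fit_parameters(pr, sa_control = list(n_temps = 10, n_per_temp = 30))
  expect_lt(max(abs(fit$par - c(n = 2, xh = 3)) / c(2, 3)), 0.05)
  expect_lt(fit$objective, 1e-8)
})

test_that("initializing at the truth yields a near-zero objective and no
           movement away from it", {
  pr <- .toy_problem()
  pr$start <- c(n = 2, xh = 3)
  fit <- fit_parameters(pr, sa_control = list(n_temps = 4, n_per_temp = 10))
  expect_lt(fit$objective, 1e-10)
  expect_lt(fit$start_objective, 1e-20)
})

test_that("the incumbent objective is monotone along the trace and the
           simplex stage never ends above its start", {
  pr <- .toy_problem(noise = 0.1)
  fit <- fit_parameters(pr, sa_control = list(n_temps = 8, n_per_temp = 25))
  inc <- fit$trace$incumbent
  expect_true(all(diff(inc) <= 1e-12))
  sa_best <- min(fit$trace$incumbent[fit$trace$stage == "sa"])
  expect_lte(fit$objective, sa_best + 1e-12)
})

test_that("identical seed and problem give identical results", {
  f1 <- fit_parameters(.toy_problem(noise = 0.1, seed = 7),
                       sa_control = list(n_temps = 5, n_per_temp = 20))
  f2 <- fit_parameters(.toy_problem(noise = 0.1, seed = 7),
                       sa_control = list(n_temps = 5, n_per_temp = 20))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
})

test_that("a parameter with no effect on the objective is flagged
           non-identifiable", {
  x <- 10^seq(-1, 1, length.out = 6)
  y <- x / (1 + x)
  # normalized data cannot constrain a pure output scale
  predict_fn <- function(fr) list(curve = y)
  pr <- fit_problem(predict_fn,
                    targets = list(curve = list(y = y, weight = 1,
                                                group = "g")),
                    lower = c(k_ub = 0.01), upper = c(k_ub = 100),
                    seed = 2)
  fit <- fit_parameters(pr, sa_control = list(n_temps = 4, n_per_temp = 15))
  expect_true(fit$non_identifiable)
})

test_that("optimized maxima equal the closed-form weighted ratio and the
           joint numerical optimum", {
  x <- seq(1, 8)
  m <- x / (3 + x)
  targets <- list(a = list(y = 2 * m, weight = 1, group = "g"),
                  b = list(y = 2 * m + 0.01, weight = 2, group = "g"))
  s <- optimized_maxima(list(a = m, b = m), targets)
  expect_equal(unname(s["g"]),
               (sum(m * 2 * m) + 2 * sum(m * (2 * m + 0.01))) /
                 (3 * sum(m * m)), tolerance = 1e-12)
  # conditional closed form agrees with a 1-d numerical minimization
  num <- optimize(function(sc)
    sum((sc * m - 2 * m)^2) + 2 * sum((sc * m - 2 * m - 0.01)^2),
    c(0, 10), tol = 1e-10)$minimum
  expect_equal(unname(s["g"]), num, tolerance = 1e-6)
  # identical curves give scale 1; doubled data give scale 2
  expect_equal(unname(optimized_maxima(list(a = m),
    list(a = list(y = m, weight = 1, group = "g")))["g"]), 1)
  expect_equal(unname(optimized_maxima(list(a = m),
    list(a = list(y = 2 * m, weight = 1, group = "g")))["g"]), 2)
  # an identically zero model curve has no defined scale
  expect_warning(
    s0 <- optimized_maxima(list(a = rep(0, 8)),
      list(a = list(y = m, weight = 1, group = "g"))),
    "undefined")
  expect_true(is.na(s0["g"]))
})
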