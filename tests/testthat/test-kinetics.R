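test_that("residence_time is the exact half-life transform", {
  expect_identical(residence_time(log(2)), 1)
  expect_equal(residence_time(log(2) / 53), 53, tolerance = 1e-12)
  set.seed(14)
  kd <- 10^runif(1000, -3, 1)
  expect_equal(residence_time(kd) * kd, rep(log(2), 1000), tolerance = 1e-12)
  expect_error(residence_time(0), "positive")
})

test_that("the occupancy ratio converges to the concentration ratio", {
  # competitive equilibrium holds for any (k_a, k_d)
  curve <- study_curve()
  for (pars in list(c(0.001, 0.05), c(0.01, log(2) / 10), c(0.2, 1))) {
    r <- simulate_occupancy(kinetic_model(pars[1], pars[2]), curve,
                            c(0, 100, 500, 3000))
    expect_equal(r[4], 2.23, tolerance = 1e-3)
  }
})

test_that("fast exchange tracks the induction curve", {
  # quasi-equilibrium lag bound: rel. deviation ~ (d log rho/dt) / lambda,
  # which at t_half = 0.01 min is ~1.1% at t = 5 and < 1% from t = 10 on
  curve <- study_curve()
  tt <- c(0, seq(5, 70, by = 5))
  r <- simulate_occupancy(kinetic_model(0.01, log(2) / 0.01), curve, tt)
  rho <- eval_induction(curve, tt)
  dev <- abs(r / rho - 1)
  expect_true(all(dev[tt >= 5] < 0.015))
  expect_true(all(dev[tt >= 10] < 0.01))
})

test_that("the closed form equals the ODE under step induction", {
  tt <- default_time_grid()
  for (ka in c(0.001, 0.01, 0.1)) {
    for (kd in c(0.01, 0.07, 0.5)) {
      for (rho0 in c(0.5, 2, 2.23)) {
        step <- local({r <- rho0; function(t) rep(r, length(t))})
        num <- simulate_occupancy(kinetic_model(ka, kd), step, tt)
        ana <- ideal_induction_solution(kinetic_model(ka, kd), step, tt)
        expect_lt(max(abs(num - ana)), 1e-6)
      }
    }
  }
})

test_that("the ideal solution satisfies its limits", {
  m <- kinetic_model(0.01, 0.1)
  step2 <- function(t) rep(2, length(t))
  expect_identical(ideal_induction_solution(m, step2, 0), 0)
  expect_equal(ideal_induction_solution(m, step2, 1e5), 2, tolerance = 1e-8)
})

test_that("fit_ideal is self-consistent on ideal-generated data", {
  curve <- study_curve()
  tt <- default_time_grid()
  for (kd in c(0.03, 0.1, 0.4)) {
    y <- ideal_induction_solution(kinetic_model(0.01, kd), curve, tt)
    fit <- fit_ideal(list(times = tt, values = y), curve)
    expect_equal(fit$k_d_ideal, kd, tolerance = 1e-4)
    expect_true(fit$converged)
  }
})

test_that("fit_ideal is insensitive to the nuisance association rate", {
  # low-occupancy regime: k_a (1 + rho_inf) << k_d
  curve <- study_curve()
  tt <- default_time_grid()
  y <- simulate_occupancy(kinetic_model(5e-4, log(2) / 10), curve, tt)
  s <- list(times = tt, values = y)
  k1 <- fit_ideal(s, curve, k_a = 5e-4)$k_d_ideal
  k2 <- fit_ideal(s, curve, k_a = 1e-3)$k_d_ideal
  expect_lt(abs(k2 / k1 - 1), 0.02)
})

test_that("the ideal fit of exact-ODE data is biased toward longer residence", {
  # the step-induction solution responds faster than the gradually driven
  # system, so matching the delayed data forces k_d down (t_half up); the
  # lookup table removes exactly this bias
  curve <- study_curve()
  tt <- default_time_grid()
  kd <- log(2) / 10
  y <- simulate_occupancy(kinetic_model(0.01, kd), curve, tt)
  kd_ideal <- fit_ideal(list(times = tt, values = y), curve)$k_d_ideal
  expect_lt(kd_ideal, kd)
  tab <- cached_bias_table()
  expect_equal(correct_bias(kd_ideal, tab), kd, tolerance = 0.02)
})

test_that("the bias table is monotone and near-identity on ideal data", {
  tab <- cached_bias_table()
  expect_true(all(diff(tab$k_d_true) > 0))
  expect_true(all(diff(tab$k_d_ideal) > 0))

  # fitting the ideal solution to ideal-generated data maps onto the
  # diagonal, so the lookup built that way would be the identity
  curve <- study_curve()
  tt <- default_time_grid()
  for (kd in log(2) / c(2, 10, 60)) {
    y <- ideal_induction_solution(kinetic_model(0.01, kd), curve, tt)
    expect_equal(fit_ideal(list(times = tt, values = y), curve)$k_d_ideal,
                 kd, tolerance = 1e-5)
  }
})

test_that("off-grid bias correction round-trips within 2%", {
  tab <- cached_bias_table()
  curve <- study_curve()
  tt <- default_time_grid()
  set.seed(6)
  for (th in exp(runif(20, log(1), log(100)))) {
    kd <- log(2) / th
    y <- simulate_occupancy(kinetic_model(0.01, kd), curve, tt)
    ki <- fit_ideal(list(times = tt, values = y), curve)$k_d_ideal
    expect_equal(correct_bias(ki, tab), kd, tolerance = 0.02)
  }
})

test_that("correct_bias handles identity tables, exact hits and range limits", {
  ident <- data.frame(k_d_true = 10^seq(-3, 0, length.out = 30))
  ident$k_d_ideal <- ident$k_d_true
  class(ident) <- c("bias_table", "data.frame")
  expect_equal(correct_bias(0.05, ident), 0.05, tolerance = 1e-10)

  tab <- cached_bias_table()
  i <- 17
  expect_equal(correct_bias(tab$k_d_ideal[i], tab), tab$k_d_true[i],
               tolerance = 1e-10)
  expect_error(correct_bias(max(tab$k_d_ideal) * 3, tab), "2x")
  expect_warning(correct_bias(max(tab$k_d_ideal) * 1.5, tab), "clamped")
})

test_that("Newton refinement converges immediately from the truth", {
  curve <- study_curve()
  s <- noiseless_series(10)
  res <- newton_refine(s, curve, k_d_start = log(2) / 10)
  expect_true(res$converged)
  expect_lte(res$n_iter, 2)
  expect_equal(res$t_half, 10, tolerance = 1e-4)
})

test_that("the three-stage estimator recovers the resolution extremes", {
  tab <- cached_bias_table()
  curve <- study_curve()
  for (th in c(1.3, 53)) {
    res <- fit_residence_time(noiseless_series(th), curve, bias_table = tab)
    expect_equal(res$t_half, th, tolerance = 0.05)
    expect_identical(res$method_trace[1:3], c("ideal", "lookup", "newton"))
    expect_equal(res$t_half * res$k_d, log(2), tolerance = 1e-12)
  }
})

test_that("noisy loci are recovered with bounded median error", {
  tab <- cached_bias_table()
  curve <- study_curve()
  tt <- default_time_grid()
  mu <- noiseless_series(10)$values
  set.seed(11)
  err <- replicate(30, {
    y <- mu * 2^rnorm(length(mu), 0, 0.1)
    res <- fit_residence_time(list(times = tt, values = y), curve,
                              bias_table = tab)
    abs(res$t_half - 10) / 10
  })
  expect_lte(median(err), 0.10)
})

test_that("the ratio curve is insensitive to k_a in the dilute regime", {
  # two decades of k_a with k_a (1 + rho_inf) <= k_d / 10 throughout
  curve <- study_curve()
  tt <- c(0, seq(5, 70, by = 5))
  base <- simulate_occupancy(kinetic_model(2e-5, log(2) / 10), curve, tt)
  hi <- simulate_occupancy(kinetic_model(2e-3, log(2) / 10), curve, tt)
  expect_lt(max(abs(hi - base)), 0.02)
})

test_that("response curves shift right as residence time grows", {
  curve <- study_curve()
  tt <- seq(0, 200, by = 2)
  tt[1] <- 0
  cross <- vapply(c(1, 5, 10, 30, 70), function(th) {
    r <- simulate_occupancy(kinetic_model(0.01, log(2) / th), curve, tt)
    tt[which(r >= max(r) / 2)[1]]
  }, numeric(1))
  expect_true(all(diff(cross) > 0))
})

test_that("profile rescaling recovers k_d, B and alpha from unscaled data", {
  curve <- study_curve()
  tt <- default_time_grid()
  for (th in c(2.5, 11.3, 53)) {
    kd <- log(2) / th
    r <- simulate_occupancy(kinetic_model(0.01, kd), curve, tt)
    vals <- 1.07 * (0.12 + r / 2.2)  # arbitrary normalisation factor
    res <- profile_rescale_fit(list(times = tt, values = vals), curve,
                               center = kd * 3)
    expect_equal(res$t_half, th, tolerance = 1e-3)
    expect_equal(res$B, 1.07 * 0.12, tolerance = 1e-4)
    expect_equal(res$alpha, 2.2 / 1.07, tolerance = 1e-3)
  }
})

test_that("bias tables survive a TSV round trip", {
  tab <- cached_bias_table()
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_bias_table(tab, path)
  rd <- read_bias_table(path)
  expect_equal(rd$k_d_true, tab$k_d_true, tolerance = 1e-12)
  expect_equal(rd$k_d_ideal, tab$k_d_ideal, tolerance = 1e-12)
})
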