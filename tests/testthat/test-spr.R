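test_that("the default single-cycle schedule encodes the 2-fold series", {
  sch <- sck_schedule()
  inj <- sch$conc[sch$conc > 0]
  expect_equal(inj, c(31.25, 62.5, 125, 250, 500) * 1e-9)
  expect_true(all(sch$t_end - sch$t_start == 120))  # all 120 s phases
  expect_equal(attr(sch, "t_end"), 1200)
  expect_error(sck_schedule(concentrations = c(-1e-9)), ">= 0")
})

test_that("zero analyte and zero initial response give a flat zero trace", {
  sch <- sck_schedule(concentrations = c(0, 0))
  p <- kinetic_params(1e5, 1e-3, 100, R0 = 0)
  sg <- simulate_sck(sch, p)
  expect_true(all(sg$response == 0))
})

test_that("a long injection approaches the Langmuir equilibrium", {
  p <- kinetic_params(1e5, 1e-3, 100)
  C <- 1e-7
  sch <- as_sck_schedule(data.frame(t_start = 0, t_end = 5e4, conc = C))
  r_end <- sck_response(5e4, p, sch)
  expect_equal(r_end, p$ka * C * p$Rmax / (p$ka * C + p$kd), tolerance = 1e-9)
})

test_that("the closed form matches numerical ODE integration to < 1e-6 RU", {
  p <- kinetic_params(2e5, 5e-3, 80)
  sch <- sck_schedule()
  # integrate each constant-concentration phase numerically, chaining
  # the final response into the next phase
  ode_times <- numeric(0); ode_vals <- numeric(0); y0 <- 0
  for (ph in seq_len(nrow(sch))) {
    tt <- seq(sch$t_start[ph], sch$t_end[ph], by = 1)
    C <- sch$conc[ph]
    sol <- deSolve::ode(y = c(R = unname(y0)), times = tt,
                        func = function(t, y, parms)
                          list(p$ka * C * (p$Rmax - y[1]) - p$kd * y[1]),
                        parms = NULL, rtol = 1e-12, atol = 1e-12)
    y0 <- sol[nrow(sol), 2]
    keep <- if (ph == nrow(sch)) seq_len(nrow(sol)) else seq_len(nrow(sol) - 1)
    ode_times <- c(ode_times, sol[keep, "time"])
    ode_vals <- c(ode_vals, sol[keep, 2])
  }
  closed <- sck_response(ode_times, p, sch)
  expect_lt(max(abs(closed - ode_vals)), 1e-6)
})

test_that("the response is continuous across phase boundaries and bounded", {
  p <- kinetic_params(3e5, 2e-3, 120, R0 = 10)
  sch <- sck_schedule()
  eps <- 1e-9
  for (tb in sch$t_start[-1]) {
    expect_lt(abs(sck_response(tb, p, sch) - sck_response(tb - eps, p, sch)),
              1e-6)
  }
  r <- sck_response(seq(0, 1200, by = 0.5), p, sch)
  expect_true(all(r >= -1e-9 & r <= p$Rmax + 1e-9))
})

test_that("noise is reproducible from the seed", {
  sch <- sck_schedule()
  p <- kinetic_params(1e5, 2e-3, 100)
  s1 <- simulate_sck(sch, p, noise_sd = 2, seed = 7)
  s2 <- simulate_sck(sch, p, noise_sd = 2, seed = 7)
  s3 <- simulate_sck(sch, p, noise_sd = 2, seed = 8)
  expect_identical(s1$response, s2$response)
  expect_false(identical(s1$response, s3$response))
  expect_error(simulate_sck(sch, p, noise_sd = -1), ">= 0")
})

test_that("a noiseless trace returns the generating parameters", {
  sch <- sck_schedule()
  p <- kinetic_params(1e5, 2e-3, 100)
  fit <- fit_sck(simulate_sck(sch, p))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$ka - p$ka) / p$ka, 1e-4)
  expect_lt(abs(fit$params$kd - p$kd) / p$kd, 1e-4)
  expect_lt(abs(fit$params$Rmax - p$Rmax) / p$Rmax, 1e-4)
  expect_lt(fit$rss, 1e-8)
})

test_that("non-identifiable designs are refused", {
  one <- as_sck_schedule(data.frame(t_start = 0, t_end = 120, conc = 1e-7))
  p <- kinetic_params(1e5, 2e-3, 100)
  sg <- simulate_sck(one, p)
  expect_error(fit_sck(sg), "two distinct")
  flat <- simulate_sck(sck_schedule(), kinetic_params(1e5, 2e-3, 1e-9))
  flat$response <- rep(0, length(flat$response))
  expect_error(fit_sck(flat), "flat|identifiable")
})

test_that("K_D is exactly kd/ka and invariant to Rmax rescaling", {
  expect_equal(kd_of(kinetic_params(1e5, 2e-3, 100)), 2e-8)
  expect_equal(kd_of(kinetic_params(0.5, 0.5, 10)), 1)
  # equilibrium response identifies KD regardless of surface capacity
  sch <- sck_schedule()
  p1 <- kinetic_params(1e5, 2e-3, 50)
  p2 <- kinetic_params(1e5, 2e-3, 500)
  f1 <- fit_sck(simulate_sck(sch, p1))
  f2 <- fit_sck(simulate_sck(sch, p2))
  expect_equal(kd_of(f1$params), kd_of(f2$params), tolerance = 1e-3)
  # and the asymptote of a long injection is consistent with KD
  C <- 1e-7
  long <- as_sck_schedule(data.frame(t_start = 0, t_end = 1e5, conc = C))
  req <- sck_response(1e5, p1, long)
  expect_equal(req, p1$Rmax * C / (C + kd_of(p1)), tolerance = 1e-6)
})

test_that("the packaged affinity table carries sources and known entries", {
  kd <- load_kd_fixtures()
  expect_true(all(c("label", "kd_molar", "source") %in% names(kd)))
  expect_equal(kd$kd_molar[kd$label == "B*44:05 wt"], 2.0e-8)
  expect_equal(kd$kd_molar[kd$label == "quadruple mutant"], 7.0e-9)
  expect_true(all(nzchar(kd$source)))
  expect_equal(sum(kd$label == "no such entry"), 0)
})
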