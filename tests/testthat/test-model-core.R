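test_that("radiation damage combines self-damage, cross-fire and blood terms", {
  p <- basic_params()
  # empty state: no nuclides anywhere
  expect_equal(radiation_damage(state_at(p, N = 0, fFN = 0), p), 0)
  # pure self-damage at full occupancy: alpha*lambda*gamma/nu
  p1 <- basic_params(k_s = 1)
  expect_equal(radiation_damage(state_at(p1, fAN = 1), p1),
               500 * 0.07 * 2.1 / 0.015)  # 4900 per day
  # cross-fire with equal occupancy on viable and damaged cells equals
  # self-damage at that occupancy, for any N, D > 0
  p0 <- basic_params(k_s = 0)
  s <- state_at(p0, N = 2, D = 1, fAN = 0.4, uAD = 0.4 * 1)
  expect_equal(radiation_damage(s, p0),
               radiation_damage(state_at(p1, fAN = 0.4), p1))
  # unanchored-nuclide term
  pf <- basic_params(k_s = 0)
  s <- state_at(pf, N = 1, fFN = 1, a = 2, p = 1)
  expect_equal(radiation_damage(s, pf), pf$alpha * pf$k_f * 0.07 * 3)
  expect_error(radiation_damage(state_at(p, a = -1), p), "non-negative")
})

test_that("vector field matches direct substitution into the model equations", {
  p <- basic_params()
  # drug-free growth: only proliferation terms are active
  d <- trt_derivatives(state_at(p), p)
  expect_equal(d[["N"]], 0.34 * 3)
  expect_equal(d[["born"]], 0.34 * 3)
  expect_equal(sum(abs(d[setdiff(names(d), c("N", "born"))])), 0)
  # plasma decay of active antibody: -lambda - kon*gamma/V*N - kappa_c
  d <- trt_derivatives(state_at(p, a = 1), p)
  expect_equal(d[["a"]], -(0.07 + 11.15 * 2.1 * 3 + 0.1))  # -70.415
  # active-fraction decay: -(lambda + rho)*fAN
  d <- trt_derivatives(state_at(p, fAN = 0.5), p)
  expect_equal(d[["fAN"]], -(0.07 + 0.34) * 0.5)  # -0.205
  expect_error(trt_derivatives(state_at(p, a = NaN), p), "non-finite")
})

test_that("compiled dynamics agree with the plain-R vector field", {
  p <- basic_params()
  y0 <- apply_injection(trt_initial_state(p), 0.003, eta = 5, V = p$V)
  times <- seq(0, 2, by = 0.05)
  ref <- deSolve::lsoda(y0, times,
                        function(t, y, parms)
                          list(trt_derivatives(setNames(pmax(y, 0),
                                                        names(y0)), p)),
                        parms = NULL, rtol = 1e-10, atol = 1e-14)
  sim <- simulate_trt(p, trt_schedule(0, 0.003, eta = 5), horizon = 2,
                      points_per_day = 20, rtol = 1e-10, atol = 1e-14)
  tr <- sim$trajectory
  for (nm in c("a", "b", "N", "D", "f_AN")) {
    refcol <- c(a = "a", b = "b", N = "N", D = "D", f_AN = "fAN")[[nm]]
    expect_equal(tr[[nm]], unname(ref[, refcol]), tolerance = 1e-6,
                 label = nm)
  }
})

test_that("injections are instantaneous concentration jumps", {
  p <- basic_params()
  s <- trt_initial_state(p)
  expect_equal(apply_injection(s, 0, 1780, 1), s)
  s2 <- apply_injection(s, 0.03, eta = 0, V = 1)
  expect_equal(s2[["a"]], 0.03)
  expect_equal(s2[["b"]], 0)
  s3 <- apply_injection(s, 0.001, eta = 1780, V = 1)
  expect_equal(s3[["a"]], 0.001)
  expect_equal(s3[["b"]], 1.78)
  expect_equal(s3[setdiff(names(s3), c("a", "b"))],
               s[setdiff(names(s), c("a", "b"))])
  expect_error(apply_injection(s, -1, 0, 1), "non-negative")
  # in a simulation, the first trajectory row carries the t = 0 jump
  sim <- simulate_trt(p, trt_schedule(0, 0.002, eta = 3), horizon = 1)
  expect_equal(sim$trajectory$a[1], 0.002)
  expect_equal(sim$trajectory$b[1], 0.006)
  # a mid-course injection raises a across the injection time
  sim2 <- simulate_trt(p, trt_schedule(c(0, 0.5), c(0.001, 0.002), eta = 0),
                       horizon = 1, points_per_day = 2000)
  tr <- sim2$trajectory
  i <- max(which(tr$time <= 0.5))
  expect_gt(tr$a[i + 1], tr$a[i] + 0.0015)
  expect_error(trt_schedule(c(1, 1), c(0, 0)), "strictly increasing")
  expect_error(simulate_trt(p, trt_schedule(5, 0.001), horizon = 4),
               "horizon")
})

test_that("drug-free dynamics reduce to exponential growth up to lethal burden", {
  p <- basic_params()
  sim <- simulate_trt(p, horizon = 10)
  expect_equal(tail(sim$trajectory$N, 1), 3 * exp(0.34 * 10),
               tolerance = 1e-3)
  expect_true(all(diff(sim$trajectory$N) > 0))
  # death when N + D reaches C_d: ln(1e4/3)/0.34 days
  sim <- simulate_trt(p, horizon = 40, stop_at_endpoints = "death")
  expect_equal(sim$death_time, log(1e4 / 3) / 0.34, tolerance = 1e-4)
  expect_equal(sim$survival_time, sim$death_time)
})

test_that("undecayed nuclides are conserved when clearance is switched off", {
  p <- basic_params(kappa_c = 1e-12, kappa_p = 1e-12)
  A <- 3e-3
  sim <- simulate_trt(p, trt_schedule(0, A, eta = 0), horizon = 30,
                      rtol = 1e-10, atol = 1e-14)
  tr <- sim$trajectory
  total <- (tr$a + tr$p) * p$V +
    p$gamma * (tr$f_AN * tr$N + tr$f_AD * tr$D)
  drift <- total * exp(p$lambda_decay * tr$time) / A - 1
  # relative drift below 1e-6/day over 30 days
  expect_lt(max(abs(drift)), 30 * 1e-6)
})

test_that("receptor occupancy decays at the published rates after binding", {
  p <- basic_params()
  sim <- simulate_trt(p, trt_schedule(0, 5e-3, eta = 0), horizon = 60,
                      points_per_day = 20)
  tr <- sim$trajectory
  # viable cells: decay plus dilution over newborn cells, -(lambda+rho)
  m <- tr$time > 5 & tr$time < 20
  slope_AN <- coef(lm(log(f_AN) ~ time, tr[m, ]))[[2]]
  expect_equal(slope_AN, -(p$lambda_decay + p$rho), tolerance = 0.01)
  # damaged cells after the damage-transfer phase: pure decay, -lambda
  m <- tr$time > 20 & tr$time < 50
  slope_AD <- coef(lm(log(f_AD) ~ time, tr[m, ]))[[2]]
  expect_equal(slope_AD, -p$lambda_decay, tolerance = 0.01)
})

test_that("plasma drug decays near-exponentially at rate lambda+kappa_c+kon*gamma*N0/V during binding", {
  p <- basic_params()
  sim <- simulate_trt(p, trt_schedule(0, 1e-3, eta = 0), horizon = 0.1,
                      points_per_day = 2000)
  tr <- sim$trajectory
  m <- tr$time > 0.002 & tr$time < 0.03
  k_obs <- -coef(lm(log(a) ~ time, tr[m, ]))[[2]]
  k_expected <- p$lambda_decay + p$kappa_c + p$k_on * p$gamma * p$N0 / p$V
  expect_equal(k_obs, k_expected, tolerance = 0.01)
})

test_that("fractions stay within [0,1] and cumulative tallies never decrease", {
  p_base <- basic_params()
  set.seed(42)
  for (rep in 1:6) {
    k <- sample(1:3, 1)
    times <- sort(runif(k, 0, 20))
    times[1] <- 0
    amounts <- 10^runif(k, -4, -1.3)
    eta <- sample(c(0, 10, 1780), 1)
    p <- basic_params(k_s = runif(1))
    sim <- simulate_trt(p, trt_schedule(times, amounts, eta = eta),
                        horizon = 40, points_per_day = 10)
    tr <- sim$trajectory
    tol <- 1e-6
    expect_true(all(tr$f_FN + tr$f_AN <= 1 + tol))
    expect_true(all(tr$f_FD + tr$f_AD <= 1 + tol))
    expect_true(all(tr[c("f_FN", "f_AN", "f_FD", "f_AD")] >= -tol))
    for (nm in c("cum_blood_decays", "cum_viable_decays",
                 "cum_damaged_decays", "cum_cells_born"))
      expect_true(all(diff(tr[[nm]]) >= -1e-12), label = nm)
    expect_lte(sim$N_min, min(tr$N) + 1e-12)
  }
})
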