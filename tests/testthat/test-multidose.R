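test_that("ks groups partition [0,1] and subset populations correctly", {
  g <- ks_groups()
  expect_equal(g$lo[1], 0)
  expect_equal(g$hi[3], 1)
  expect_equal(g$lo[-1], g$hi[-3])
  pop <- sample_population(100, seed = 2)
  ns <- vapply(g$label, function(lb)
    length(trtsim:::pop_subset_ks(pop, lb)$mice), numeric(1))
  expect_equal(sum(ns), 100)
})

test_that("idealized saturation dynamics give a constant kill rate independent of ks", {
  p <- basic_params()
  idl <- idealized_saturation_dynamics(p, horizon = 30)
  # at full saturation with impurity, active occupancy 1/(eta+1) and
  # kill rate alpha*lambda*gamma/(nu*(eta+1)) for any ks
  expect_equal(idl$kill_rate, 500 * 0.07 * 2.1 / (0.015 * 1781),
               tolerance = 1e-9)
  expect_equal(idl$kill_rate,
               idealized_saturation_dynamics(basic_params(k_s = 1),
                                             horizon = 30)$kill_rate)
  expect_true(idl$curable)
  # viable cells follow the closed-form exponential
  tr <- idl$trajectory
  expect_equal(tr$N, p$N0 * exp((p$rho - idl$kill_rate) * tr$time),
               tolerance = 1e-9)
  # occupancy that cannot outpace proliferation: regrowth
  weak <- idealized_saturation_dynamics(p, occupancy = 1e-5, horizon = 30)
  expect_false(weak$curable)
  expect_gt(tail(weak$trajectory$N, 1), p$N0)
  # zero dosing (occupancy -> 0) reduces to pure exponential growth:
  # kill rate vanishes linearly with occupancy
  tiny <- idealized_saturation_dynamics(p, occupancy = 1e-12, horizon = 5)
  expect_equal(tail(tiny$trajectory$N, 1), p$N0 * exp(p$rho * 5),
               tolerance = 1e-6)
  expect_warning(idealized_saturation_dynamics(p, occupancy = 0.5),
                 "not sustainable")
})

test_that("discretizing a dosing profile conserves total injected activity", {
  p <- basic_params()
  idl <- idealized_saturation_dynamics(p, horizon = 40)
  total <- with(idl$trajectory,
                sum(diff(time) * (head(dose_rate_active, -1) +
                                    tail(dose_rate_active, -1)) / 2))
  for (K in c(1, 4, 8)) {
    sch <- discretize_schedule(idl$trajectory, K = K, t_end = 40)
    expect_equal(length(sch$times), K)
    expect_equal(sum(sch$amounts), total, tolerance = 1e-6)
  }
  # uniform profile with equal intervals: equal boluses
  schu <- discretize_schedule(function(t) 0.25, K = 5, t_end = 10)
  expect_equal(schu$amounts, rep(0.5, 5), tolerance = 1e-9)
  # K -> 2K leaves the cumulative injected activity unchanged
  s1 <- discretize_schedule(function(t) exp(-0.1 * t), K = 3, t_end = 30)
  s2 <- discretize_schedule(function(t) exp(-0.1 * t), K = 6, t_end = 30)
  expect_equal(sum(s1$amounts), sum(s2$amounts), tolerance = 1e-9)
})

test_that("family schedules respect per-dose and cumulative safety caps", {
  p <- basic_params()
  fam <- schedule_family(c1 = 1.5, c0 = 3, c2 = 0.5, tau = 7, K = 8)
  cap6 <- max_safe_dose(6.3, p)$pmol
  sch <- schedule_from_family(fam, capacity = 6.3, eta = 1780, params = p)
  expect_true(all(sch$amounts <= cap6 + 1e-12))
  expect_lte(sum(sch$amounts), cap6 + 1e-9)
  expect_equal(sch$amounts[1], (1.5 * 6.3 + 3) / 1781, tolerance = 1e-9)
  # follow-ups are the stated fraction of the first dose
  if (length(sch$amounts) > 1)
    expect_equal(sch$amounts[2], 0.5 * sch$amounts[1], tolerance = 1e-9)
  # huge capacity: first dose capped at the safe limit
  schb <- schedule_from_family(fam, capacity = 1e4, eta = 1780, params = p)
  expect_equal(schb$amounts[1],
               max_safe_dose(1e4, p)$pmol, tolerance = 1e-9)
})

test_that("single-bolus damage rate from anchored nuclides never decays slower than exp(-lambda t)", {
  for (ks in c(0, 0.3, 1)) {
    p <- basic_params(k_s = ks)
    sim <- simulate_trt(p, trt_schedule(0, 4e-3, eta = 0), horizon = 50,
                        points_per_day = 10)
    tr <- sim$trajectory
    M <- tr$N + tr$D
    anchored <- p$alpha * p$lambda_decay * p$gamma *
      (ks * tr$f_AN / p$nu +
         (1 - ks) * ifelse(M > 1e-30,
                           (tr$f_AN * tr$N + tr$f_AD * tr$D) / (p$nu * M),
                           0))
    # after binding completes (t > 1 d), compare against pure decay
    idx <- which(tr$time >= 1)
    rate0 <- anchored[idx[1]]
    bound <- rate0 * exp(-p$lambda_decay * (tr$time[idx] - tr$time[idx[1]]))
    expect_true(all(anchored[idx] <= bound * 1.02),
                label = sprintf("ks=%g", ks))
  }
})

test_that("schedule optimization explores the grid and returns the best family", {
  grid <- list(c1 = 1.5, c2 = 0.25, tau = c(7, 14), K = c(1, 3))
  train <- sample_population(40, seed = 31)
  opt <- optimize_universal_schedule(train, "intermediate", grid = grid)
  expect_s3_class(opt$family, "trt_schedule_family")
  # the reported survival is the maximum over the candidate table
  expect_equal(opt$survival, max(opt$results$survival))
  # evaluating the winning family on the same group reproduces it
  ev <- evaluate_schedule(train, opt$family, group = "intermediate")
  expect_equal(final_survival(ev), opt$survival, tolerance = 1e-9)
})
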