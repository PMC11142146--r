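#' Stratification of the self-damage weight
#'
#' Partition of the admissible range of `k_s` into low, intermediate
#' and high self-damage groups used for multi-dose schedule
#' optimization. The boundaries are configurable; the defaults split
#' \[0, 1\] at 0.2 and 0.6.
#'
#' @param boundaries Two increasing interior cut points in (0, 1).
#' @return data.frame with columns `label`, `lo`, `hi`; intervals are
#'   `[lo, hi)` except the last, which is closed.
#' @export
ks_groups <- function(boundaries = c(0.2, 0.6)) {
  stopifnot(length(boundaries) == 2, boundaries[1] < boundaries[2],
            boundaries[1] > 0, boundaries[2] < 1)
  data.frame(label = c("low", "intermediate", "high"),
             lo = c(0, boundaries),
             hi = c(boundaries, 1),
             stringsAsFactors = FALSE)
}

# Mice of a population whose k_s lies in a named group.
pop_subset_ks <- function(pop, group, groups = ks_groups()) {
  g <- groups[groups$label == group, ]
  if (nrow(g) != 1) stop("unknown k_s group: ", group)
  ks <- vapply(pop$mice, `[[`, numeric(1), "k_s")
  keep <- if (group == "high") ks >= g$lo & ks <= g$hi else
    ks >= g$lo & ks < g$hi
  if (!any(keep)) stop("no mice in k_s group '", group, "'")
  structure(list(mice = pop$mice[keep],
                 table = pop$table[keep, , drop = FALSE],
                 seed = pop$seed, ranges = pop$ranges),
            class = "trt_population")
}

#' Idealized receptor-saturation dynamics
#'
#' Auxiliary reduced model in which injected antibodies bind
#' instantaneously and keep total receptor occupancy constant, so the
#' active occupancy equals `occupancy` on viable and damaged cells
#' alike. The radiation damage rate from anchored nuclides is then the
#' constant `RD = alpha*lambda*gamma*occupancy/nu` regardless of
#' `k_s`, and the cell dynamics have the closed form
#' `N(t) = N0*exp((rho - RD)t)`. The maximal sustainable active
#' occupancy under impurity `eta` is `1/(eta+1)`, giving the long-term
#' curability condition `alpha*lambda*gamma/(nu*(eta+1)) > rho`
#' (necessary, not sufficient). The function also reports the
#' continuous antibody dosing rate required to maintain the occupancy
#' against decay and receptor production by proliferating cells; this
#' profile is the starting point for discrete multi-dose schedules via
#' [discretize_schedule()].
#'
#' @param params A [trt_parameters()] record.
#' @param occupancy Constant active receptor occupancy in (0, 1\];
#'   default `1/(eta+1)`, the maximum under impurity.
#' @param horizon Horizon, days.
#' @param dt Output step, days.
#' @param eta Impurity coefficient; defaults to `params$eta`.
#' @return List with `trajectory` (data.frame `time, N, D,
#'   dose_rate_active, dose_rate_antibodies` in pmol/day),
#'   `kill_rate` (the constant anchored-decay damage rate) and
#'   `curable` (`kill_rate > rho` at the default occupancy).
#' @export
idealized_saturation_dynamics <- function(params, occupancy = NULL,
                                          horizon = 60, dt = 0.1,
                                          eta = params$eta) {
  if (is.null(occupancy)) occupancy <- 1 / (eta + 1)
  if (occupancy <= 0 || occupancy > 1)
    stop("occupancy must lie in (0, 1]")
  if (occupancy > 1 / (eta + 1) + 1e-12)
    warning("occupancy above 1/(eta+1) is not sustainable at this impurity")
  lam <- params$lambda_decay
  RD <- params$alpha * lam * params$gamma * occupancy / params$nu
  g <- params$rho - RD
  t <- seq(0, horizon, by = dt)
  N <- params$N0 * exp(g * t)
  om <- params$omega
  # D' = RD*N - omega*D, D(0) = 0
  D <- if (abs(g + om) > 1e-12)
    RD * params$N0 * (exp(g * t) - exp(-om * t)) / (g + om)
  else RD * params$N0 * t * exp(-om * t)
  # active nuclides needed to replace decays and occupy newborn receptors
  rate_active <- params$gamma * occupancy * (lam * (N + D) + params$rho * N)
  data_out <- data.frame(time = t, N = N, D = D,
                         dose_rate_active = rate_active,
                         dose_rate_antibodies = (eta + 1) * rate_active)
  list(trajectory = data_out, kill_rate = RD, curable = RD > params$rho,
       occupancy = occupancy)
}

#' Discretize a continuous dosing profile into boluses
#'
#' Converts a continuous dosing-rate profile (pmol of active
#' radioconjugates per day) into a bolus schedule: each bolus carries
#' the profile's integral over its interval, so the cumulative
#' injected activity is conserved.
#'
#' @param profile Function of time returning the dosing rate, or a
#'   data.frame with columns `time` and `dose_rate_active` (linearly
#'   interpolated), e.g. the trajectory of
#'   [idealized_saturation_dynamics()].
#' @param K Number of boluses.
#' @param t_end End of the dosing period, days.
#' @param times Optional explicit bolus times (length `K`, starting at
#'   the start of the profile); by default boluses are equally spaced
#'   on `[0, t_end)`.
#' @param eta Impurity coefficient recorded on the schedule.
#' @return A [trt_schedule()] with `K` boluses.
#' @export
discretize_schedule <- function(profile, K, t_end, times = NULL,
                                eta = NULL) {
  stopifnot(K >= 1, t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = K + 1)[1:K]
  if (any(diff(times) <= 0)) stop("bolus times must be increasing")
  edges <- c(times, t_end)
  if (is.data.frame(profile)) {
    # piecewise-linear profile: trapezoid rule on the union of the
    # tabulated grid and the bolus edges is exact
    tt <- sort(unique(c(profile$time, edges)))
    tt <- tt[tt >= edges[1] & tt <= t_end]
    rr <- approx(profile$time, profile$dose_rate_active, xout = tt,
                 rule = 2)$y
    cum <- c(0, cumsum(diff(tt) * (head(rr, -1) + tail(rr, -1)) / 2))
    cum_at <- approxfun(tt, cum)
    amounts <- diff(vapply(edges, cum_at, numeric(1)))
  } else {
    amounts <- vapply(seq_len(K), function(i) {
      stats::integrate(function(s) vapply(s, profile, numeric(1)),
                       edges[i], edges[i + 1],
                       rel.tol = 1e-9, subdivisions = 1000L)$value
    }, numeric(1))
  }
  trt_schedule(times, amounts, eta = eta)
}

#' Universal multi-dose schedule family
#'
#' A parametric family of bolus schedules tailored to a mouse's cancer
#' binding capacity `gamma*N0`: the first injection carries
#' `c1*capacity + c0` pmol of antibodies (active dose divided by
#' `eta + 1`), aiming at receptor saturation; `K - 1` follow-up doses,
#' each a fraction `c2` of the first, are given every `tau` days and
#' redistribute activity towards still-viable cells that keep
#' producing receptors.
#'
#' @param c1 Slope of the first-dose antibody amount in capacity
#'   (dimensionless).
#' @param c0 Intercept, pmol of antibodies (compensates for slow
#'   binding at small capacity).
#' @param c2 Follow-up dose as a fraction of the first dose.
#' @param tau Inter-dose interval, days.
#' @param K Total number of doses (>= 1).
#' @return An object of class `trt_schedule_family`.
#' @export
schedule_family <- function(c1 = 1.5, c0 = 3, c2 = 0.2, tau = 7, K = 4) {
  stopifnot(K >= 1, tau > 0, c1 >= 0, c0 >= 0, c2 >= 0)
  structure(list(c1 = c1, c0 = c0, c2 = c2, tau = tau, K = as.integer(K)),
            class = "trt_schedule_family")
}

#' @export
print.trt_schedule_family <- function(x, ...) {
  cat(sprintf(
    "Schedule family: first dose (%.2f*capacity + %.2f) pmol antibodies,\n",
    x$c1, x$c0))
  cat(sprintf("  %d dose(s); follow-ups %.0f%% of first, every %g days\n",
              x$K, 100 * x$c2, x$tau))
  invisible(x)
}

#' Instantiate a schedule family for one mouse
#'
#' Builds the bolus schedule of a [schedule_family()] for a mouse with
#' a given binding capacity. Each bolus is capped at the worst-case
#' [max_safe_dose()] for that capacity, and trailing doses are dropped
#' once the cumulative injected activity reaches the same safety cap
#' (the cap is expressed in total activity, so the whole schedule obeys
#' the worst-case blood-decay budget).
#'
#' @param family A [schedule_family()].
#' @param capacity Cancer binding capacity `gamma*N0`, pmol.
#' @param eta Impurity coefficient.
#' @param params A [trt_parameters()] record.
#' @param ranges Sweep ranges for the safety cap.
#' @return A [trt_schedule()].
#' @export
schedule_from_family <- function(family, capacity, eta = params$eta,
                                 params, ranges = trt_parameter_ranges()) {
  stopifnot(inherits(family, "trt_schedule_family"))
  cap <- max_safe_dose(capacity, params, ranges, eta = eta)$pmol
  A1 <- min((family$c1 * capacity + family$c0) / (eta + 1), cap)
  amounts <- c(A1, rep(family$c2 * A1, family$K - 1))
  amounts <- pmin(amounts, cap)
  keep <- cumsum(amounts) <= cap + 1e-15
  keep[1] <- TRUE
  amounts <- amounts[keep]
  times <- family$tau * (seq_along(amounts) - 1)
  trt_schedule(times, amounts, eta = eta)
}

#' Optimize a universal schedule family on a training population
#'
#' Grid search over the family parameters (`c1`, `c2`, `tau`, `K`)
#' maximizing survival at the horizon on the mice of one `k_s` group
#' of the training population, with every candidate schedule obeying
#' the capacity-dependent safety caps of [schedule_from_family()].
#' The single-dose families (`K = 1`) are part of the search space, so
#' the optimized family can never do worse on the training set than
#' the best capacity-tailored single dose in the grid.
#'
#' @param train_pop A [sample_population()] object.
#' @param group `k_s` group label: "low", "intermediate" or "high".
#' @param grid Named list of candidate values for `c1`, `c2`, `tau`,
#'   `K` (`c0` is held at its default).
#' @param groups Group boundaries from [ks_groups()].
#' @param horizon Horizon, days.
#' @param ... Passed to [run_trial()].
#' @return List with the best `family`, its training `survival`, the
#'   full `results` table, and the `group`.
#' @export
optimize_universal_schedule <- function(train_pop, group,
                                        grid = list(c1 = c(1, 1.5),
                                                    c2 = c(0.1, 0.25, 0.5),
                                                    tau = c(5, 10, 20),
                                                    K = c(1, 3, 6)),
                                        groups = ks_groups(),
                                        horizon = 365, ...) {
  sub <- pop_subset_ks(train_pop, group, groups)
  cand <- expand.grid(c1 = grid$c1, c2 = grid$c2, tau = grid$tau,
                      K = grid$K)
  # K = 1 families are insensitive to c2 and tau: deduplicate
  cand$c2[cand$K == 1] <- grid$c2[1]
  cand$tau[cand$K == 1] <- grid$tau[1]
  cand <- unique(cand)
  surv <- vapply(seq_len(nrow(cand)), function(i) {
    fam <- schedule_family(c1 = cand$c1[i], c2 = cand$c2[i],
                           tau = cand$tau[i], K = cand$K[i])
    tr <- run_trial(sub, strategy_schedule(fam), horizon = horizon, ...)
    tr$curves$surviving[nrow(tr$curves)]
  }, numeric(1))
  best <- which.max(surv)
  list(family = schedule_family(c1 = cand$c1[best], c2 = cand$c2[best],
                                tau = cand$tau[best], K = cand$K[best]),
       survival = surv[best],
       results = cbind(cand, survival = surv),
       group = group)
}

#' Evaluate a schedule family on a test population
#'
#' Runs an in-silico trial applying a previously optimized universal
#' schedule family, with per-mouse doses computed from each mouse's
#' binding capacity.
#'
#' @param test_pop A [sample_population()] object.
#' @param family A [schedule_family()].
#' @param group Optional `k_s` group label to restrict the test
#'   population.
#' @param groups Group boundaries from [ks_groups()].
#' @param horizon Horizon, days.
#' @param ... Passed to [run_trial()].
#' @return A `trt_trial` object.
#' @export
evaluate_schedule <- function(test_pop, family, group = NULL,
                              groups = ks_groups(), horizon = 365, ...) {
  pop <- if (is.null(group)) test_pop else
    pop_subset_ks(test_pop, group, groups)
  run_trial(pop, strategy_schedule(family), horizon = horizon, ...)
}
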