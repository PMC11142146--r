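#' Compose a virtual population from explicit parameter records
#'
#' Builds a `trt_population` from a list of [trt_parameters()], e.g.
#' worst-case mice for bounding analyses. [sample_population()] is the
#' random counterpart.
#'
#' @param mice List of [trt_parameters()] records.
#' @param seed Optional seed to record (for provenance only).
#' @return An object of class `trt_population`.
#' @export
trt_population <- function(mice, seed = NA) {
  stopifnot(length(mice) >= 1,
            all(vapply(mice, inherits, logical(1), "trt_parameters")))
  tab <- cbind(id = seq_along(mice),
               as.data.frame(do.call(rbind, lapply(mice, unlist))))
  structure(list(mice = mice, table = tab, seed = seed, ranges = NULL),
            class = "trt_population")
}

#' Sample a virtual-mouse population
#'
#' Draws `n` parameter records independently from the physiologic
#' sweep ranges. Parameters spanning orders of magnitude are sampled
#' log-uniformly; the self-damage weight `k_s` uniformly on \[0, 1\];
#' `lambda_decay`, `k_on`, `nu` and `eta` stay at their values in
#' `base`. Sampling is reproducible from `seed` and leaves the
#' caller's random-number stream untouched.
#'
#' @param n Population size.
#' @param ranges Sweep ranges as from [trt_parameter_ranges()].
#' @param seed Integer seed.
#' @param base A [trt_parameters()] record supplying the fixed
#'   parameters.
#' @return An object of class `trt_population`: list with `mice` (list
#'   of `trt_parameters`), `table` (data.frame of sampled values),
#'   `seed` and `ranges`.
#' @examples
#' pop <- sample_population(10, seed = 1)
#' range(pop$table$alpha)
#' @export
sample_population <- function(n, ranges = trt_parameter_ranges(), seed,
                              base = trt_parameters()) {
  stopifnot(n >= 1)
  if (any(ranges$min > ranges$max) ||
      any(ranges$distribution == "loguniform" & ranges$min <= 0))
    stop("invalid sampling range")
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)
  draws <- lapply(seq_len(nrow(ranges)), function(i) {
    lo <- ranges$min[i]; hi <- ranges$max[i]
    if (ranges$distribution[i] == "loguniform")
      exp(runif(n, log(lo), log(hi)))
    else runif(n, lo, hi)
  })
  tab <- as.data.frame(setNames(draws, ranges$parameter))
  mice <- lapply(seq_len(n), function(j) {
    p <- unclass(base)
    for (nm in ranges$parameter) p[[nm]] <- tab[[nm]][j]
    validate_trt_parameters(p)
  })
  tab <- cbind(id = seq_len(n), tab)
  structure(list(mice = mice, table = tab, seed = seed, ranges = ranges),
            class = "trt_population")
}

#' @export
print.trt_population <- function(x, ...) {
  cat(sprintf("Virtual population: %d mice (seed %s)\n",
              length(x$mice), format(x$seed)))
  print(summary(x$table[-1]))
  invisible(x)
}

#' Dosing strategies for in-silico trials
#'
#' Constructors for the dosing strategies accepted by [run_trial()]:
#' a one-size-fits-all fixed dose, the capacity-personalized rule of
#' [personalized_dose()], per-mouse numerical optimization assuming
#' full parameter knowledge ([optimize_single_dose_per_mouse()]), and
#' a multi-dose schedule family with doses tailored to each mouse's
#' binding capacity ([schedule_from_family()]).
#'
#' @param dose_pmol Fixed active dose, pmol.
#' @param family A [schedule_family()].
#' @param ... Passed through to the per-mouse optimizer.
#' @return A classed strategy object.
#' @name trial_strategies
NULL

#' @rdname trial_strategies
#' @export
strategy_fixed <- function(dose_pmol) {
  structure(list(dose_pmol = dose_pmol),
            class = c("trt_strategy_fixed", "trt_strategy"))
}

#' @rdname trial_strategies
#' @export
strategy_personalized <- function() {
  structure(list(), class = c("trt_strategy_personalized", "trt_strategy"))
}

#' @rdname trial_strategies
#' @export
strategy_optimized <- function(...) {
  structure(list(args = list(...)),
            class = c("trt_strategy_optimized", "trt_strategy"))
}

#' @rdname trial_strategies
#' @export
strategy_schedule <- function(family) {
  stopifnot(inherits(family, "trt_schedule_family"))
  structure(list(family = family),
            class = c("trt_strategy_schedule", "trt_strategy"))
}

# Schedule assigned by a strategy to one mouse.
mouse_schedule <- function(strategy, mouse, horizon) {
  if (inherits(strategy, "trt_strategy_fixed")) {
    trt_schedule(0, strategy$dose_pmol)
  } else if (inherits(strategy, "trt_strategy_personalized")) {
    cap <- mouse$gamma * mouse$N0
    trt_schedule(0, personalized_dose(cap, eta = mouse$eta, mouse)$pmol)
  } else if (inherits(strategy, "trt_strategy_optimized")) {
    opt <- do.call(optimize_single_dose_per_mouse,
                   c(list(mouse, horizon = horizon), strategy$args))
    trt_schedule(0, opt$dose_pmol)
  } else if (inherits(strategy, "trt_strategy_schedule")) {
    schedule_from_family(strategy$family, mouse$gamma * mouse$N0,
                         eta = mouse$eta, params = mouse)
  } else stop("unknown dosing strategy")
}

#' Run an in-silico trial
#'
#' Simulates every mouse of a virtual population under a dosing
#' strategy. A mouse dies when its cancer burden `N + D` reaches the
#' lethal count `C_d` or when its cumulative blood decays reach
#' `A_bl_cr`, whichever comes first (both located by the solver's root
#' finder); mice alive at the horizon are censored. A mouse whose
#' viable-cell count fell below the extinction threshold `N_cur`
#' before any lethal event is cured and censored alive: regrowth of
#' the continuous model from below a hundredth of a cell is an
#' artifact, not a relapse.
#'
#' @param pop A [sample_population()] object.
#' @param strategy A strategy from [trial_strategies].
#' @param horizon Trial horizon, days.
#' @param points_per_day Trajectory grid density (endpoints are found
#'   by root detection and do not depend on it).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `trt_trial`: `mice` data.frame (id,
#'   dose, survival_time, cause in cancer/toxicity/censored, cured,
#'   blood_decays), `curves` data.frame (day, surviving,
#'   toxicity_cum), and the strategy.
#' @export
run_trial <- function(pop, strategy, horizon = 365, points_per_day = 4,
                      rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(pop, "trt_population"),
            inherits(strategy, "trt_strategy"))
  rows <- lapply(seq_along(pop$mice), function(j) {
    mouse <- pop$mice[[j]]
    sched <- mouse_schedule(strategy, mouse, horizon)
    sim <- simulate_trt(mouse, sched, horizon = horizon,
                        points_per_day = points_per_day,
                        stop_at_endpoints = TRUE, rtol = rtol, atol = atol)
    cause <- trial_cause(sim)
    total <- sum(sched$amounts)
    data.frame(id = j, dose = total,
               n_doses = length(sched$amounts),
               survival_time = if (cause == "censored") horizon
                               else sim$survival_time,
               cause = cause, cured = sim$cured,
               blood_decays = max(sim$trajectory$cum_blood_decays),
               viable_fraction = if (total > 0)
                 max(sim$trajectory$cum_viable_decays) / total
               else NA_real_)
  })
  mice <- do.call(rbind, rows)
  days <- 0:horizon
  dead <- mice$cause != "censored"
  surviving <- vapply(days, function(d)
    mean(!(dead & mice$survival_time <= d)), numeric(1))
  toxicity_cum <- vapply(days, function(d)
    mean(mice$cause == "toxicity" & mice$survival_time <= d), numeric(1))
  structure(list(mice = mice,
                 curves = data.frame(day = days, surviving = surviving,
                                     toxicity_cum = toxicity_cum),
                 strategy = strategy, horizon = horizon),
            class = "trt_trial")
}

# Endpoint classification. Toxicity kills whenever lethal blood decays
# accumulate before a cancer death. A mouse whose viable-cell minimum
# fell below the extinction threshold N_cur is cured: the continuous
# model would eventually regrow the cancer from a fraction of a cell,
# and a lethal-burden crossing driven by that unphysical tail is
# censoring, not death.
trial_cause <- function(sim) {
  d <- sim$death_time; x <- sim$toxicity_time
  if (!is.na(x) && (is.na(d) || x <= d)) return("toxicity")
  if (sim$cured) return("censored")
  if (!is.na(d)) return("cancer")
  "censored"
}

#' @export
print.trt_trial <- function(x, ...) {
  n <- nrow(x$mice)
  cat(sprintf("In-silico trial: %d mice, horizon %g days\n", n, x$horizon))
  cat(sprintf("  survival at horizon: %.1f%%; causes: cancer %d, toxicity %d, censored %d\n",
              100 * x$curves$surviving[nrow(x$curves)],
              sum(x$mice$cause == "cancer"),
              sum(x$mice$cause == "toxicity"),
              sum(x$mice$cause == "censored")))
  cat(sprintf("  cured: %d (%.1f%%)\n", sum(x$mice$cured),
              100 * mean(x$mice$cured)))
  invisible(x)
}

# TRUE when dose A kills the mouse through blood-decay toxicity
# (before any cancer death) within the horizon.
toxic_death <- function(mouse, A, horizon, points_per_day = 2,
                        rtol = 1e-8, atol = 1e-12) {
  sim <- simulate_trt(mouse, trt_schedule(0, A), horizon = horizon,
                      points_per_day = points_per_day,
                      stop_at_endpoints = TRUE, rtol = rtol, atol = atol)
  trial_cause(sim) == "toxicity"
}

#' Maximum tolerated one-size-fits-all dose
#'
#' Bisects for the largest uniform single dose that causes no
#' toxicity-related deaths in any mouse of the population within the
#' horizon. Mice are screened in order of increasing binding capacity
#' (the most toxicity-vulnerable first) so that failing dose levels
#' are rejected early.
#'
#' @param pop A [sample_population()] object.
#' @param bracket_nCi Initial dose bracket in nCi.
#' @param tol_nCi Bisection resolution, nCi.
#' @param horizon Horizon, days.
#' @return List with `pmol`, `nCi` and the number of bisection
#'   iterations.
#' @export
find_max_tolerated_dose <- function(pop, bracket_nCi = c(300, 2000),
                                    tol_nCi = 0.5, horizon = 365) {
  stopifnot(length(pop$mice) >= 1)
  lam <- pop$mice[[1]]$lambda_decay
  ord <- order(vapply(pop$mice, function(m) m$gamma * m$N0, numeric(1)))
  any_toxic <- function(A) {
    for (j in ord) if (toxic_death(pop$mice[[j]], A, horizon)) return(TRUE)
    FALSE
  }
  lo <- pmol_from_activity_nCi(bracket_nCi[1], lam)
  hi <- pmol_from_activity_nCi(bracket_nCi[2], lam)
  while (any_toxic(lo)) lo <- lo / 2
  while (!any_toxic(hi)) {
    lo <- hi
    hi <- hi * 2
    if (activity_nCi_from_pmol(hi, lam) > 1e6)
      stop("no toxic dose found below 1e6 nCi; bracket invalid")
  }
  tol <- pmol_from_activity_nCi(tol_nCi, lam)
  iter <- 0
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (any_toxic(mid)) hi <- mid else lo <- mid
    iter <- iter + 1
  }
  list(pmol = lo, nCi = activity_nCi_from_pmol(lo, lam), iterations = iter)
}

#' Optimal single dose for one fully-characterized mouse
#'
#' Personalized numerical optimization assuming precise knowledge of
#' all model parameters: cure feasibility is probed on a dose grid
#' spanning the mouse's individual toxicity limit (near the limit a
#' curative dose can still lose the race against blood-decay
#' accumulation, so the whole interval is scanned); if any safe dose
#' cures, the smallest curing dose is returned (bisection on the cure
#' boundary), otherwise the dose maximizing survival time over the
#' safe interval (coarse grid followed by golden-section refinement).
#'
#' @param mouse A [trt_parameters()] record.
#' @param horizon Horizon, days.
#' @param tol Relative dose tolerance.
#' @param grid_n Size of the coarse survival grid for incurable mice.
#' @return List with `dose_pmol`, `cured`, `survival_time`,
#'   `toxicity_limit` (pmol).
#' @export
optimize_single_dose_per_mouse <- function(mouse, horizon = 365,
                                           tol = 1e-3, grid_n = 12) {
  # individual toxicity limit: largest dose with no toxicity death
  lo <- 1e-3; hi <- 0.05
  while (toxic_death(mouse, lo, horizon)) lo <- lo / 4
  while (!toxic_death(mouse, hi, horizon)) {
    lo <- hi; hi <- hi * 2
    if (hi > 1e3) break
  }
  while ((hi - lo) / hi > tol) {
    mid <- 0.5 * (lo + hi)
    if (toxic_death(mouse, mid, horizon)) hi <- mid else lo <- mid
  }
  tox_limit <- lo

  sim_at <- function(A) {
    simulate_trt(mouse, trt_schedule(0, A), horizon = horizon,
                 points_per_day = 4, stop_at_endpoints = TRUE)
  }
  # scan the safe interval: near the toxicity limit a curative dose
  # can still lose the race against blood-decay accumulation, so cure
  # feasibility is probed on a dose grid, not just at the limit
  A_hi <- 0.999 * tox_limit
  grid <- seq(0, A_hi, length.out = grid_n)
  sims <- lapply(grid, sim_at)
  cured <- vapply(sims, function(s)
    s$cured && trial_cause(s) == "censored", logical(1))
  if (any(cured)) {
    # smallest curing dose: bisect between the largest non-curing dose
    # below the first cured grid point and that point
    i <- which(cured)[1]
    lo <- if (i > 1) grid[i - 1] else 0
    hi <- grid[i]
    while (hi - lo > max(tol * hi, 1e-9)) {
      mid <- 0.5 * (lo + hi)
      s <- sim_at(mid)
      if (s$cured && trial_cause(s) == "censored") hi <- mid else lo <- mid
    }
    return(list(dose_pmol = hi, cured = TRUE,
                survival_time = horizon, toxicity_limit = tox_limit))
  }
  surv_at <- function(A) sim_at(A)$survival_time
  sv <- vapply(sims, `[[`, numeric(1), "survival_time")
  b <- which.max(sv)
  lo_g <- grid[max(1, b - 1)]; hi_g <- grid[min(grid_n, b + 1)]
  op <- optimize(surv_at, c(lo_g, hi_g), maximum = TRUE,
                 tol = max(tol * A_hi, 1e-6))
  if (op$objective >= sv[b]) {
    best <- op$maximum; best_s <- op$objective
  } else {
    best <- grid[b]; best_s <- sv[b]
  }
  list(dose_pmol = best, cured = FALSE, survival_time = best_s,
       toxicity_limit = tox_limit)
}
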