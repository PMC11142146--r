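.state_names <- c("a", "b", "p", "N", "D", "fFN", "fAN", "uFD", "uAD",
                  "Abl", "cumV", "cumD", "born")

#' Initial model state
#'
#' All receptors free, no antibodies in plasma, `N0` viable cells.
#'
#' @param params A [trt_parameters()] record.
#' @return Named numeric vector of the 13 integrated state components
#'   (damaged-cell receptor pools are carried as the absolute amounts
#'   `uFD = D*fFD`, `uAD = D*fAD`).
#' @export
trt_initial_state <- function(params) {
  y <- setNames(numeric(13), .state_names)
  y["N"] <- params$N0
  y["fFN"] <- 1
  y
}

#' Radiation damage rate
#'
#' The per-day damage rate of viable cancer cells from three radiation
#' sources: decays on a cell's own receptors (self-damage, weight
#' `k_s`), decays on the receptors of neighboring viable and damaged
#' cells (cross-fire, weight `1 - k_s`), and decays of unanchored
#' nuclides in plasma (weight `k_f`):
#'
#' `RD = alpha * ( k_s * lambda*gamma*fAN/nu
#'   + (1-k_s) * lambda*gamma*(fAN*N + fAD*D)/(nu*(N+D))
#'   + k_f * lambda*(a + p) )`
#'
#' The cross-fire term is defined as 0 when `N + D = 0`.
#'
#' @param state Named state vector as in [trt_initial_state()].
#' @param params A [trt_parameters()] record.
#' @return Damage rate, 1/day.
#' @export
radiation_damage <- function(state, params) {
  s <- as.list(state)
  if (any(unlist(s[c("a", "p", "N", "D", "fAN", "uAD")]) < 0))
    stop("state components entering the damage rate must be non-negative")
  with(c(s, params), {
    M <- N + D
    cross <- if (M > 1e-30)
      lambda_decay * gamma * (fAN * N + uAD) / (nu * M) else 0
    alpha * (k_s * lambda_decay * gamma * fAN / nu + (1 - k_s) * cross +
               k_f * lambda_decay * (a + p))
  })
}

#' Model vector field (reference implementation)
#'
#' Time derivative of the model state between injections. This is a
#' plain-R transcription of the compiled derivatives used by
#' [simulate_trt()]; it exists for inspection and for testing the
#' compiled code against an independent implementation.
#'
#' @param state Named state vector as in [trt_initial_state()].
#' @param params A [trt_parameters()] record.
#' @return Named vector of derivatives, per day.
#' @export
trt_derivatives <- function(state, params) {
  if (any(!is.finite(state))) stop("non-finite state component")
  s <- as.list(state)
  RD <- radiation_damage(state, params)
  d <- with(c(s, params), {
    bfree <- fFN * N + uFD
    c(a = -lambda_decay * a - k_on * a * gamma / V * bfree - kappa_c * a,
      b = lambda_decay * a - k_on * b * gamma / V * bfree - kappa_c * b,
      p = omega * gamma * uAD / V - lambda_decay * p - kappa_p * p,
      N = rho * N - RD * N,
      D = RD * N - omega * D,
      fFN = (1 - fFN) * rho - k_on * (a + b) * fFN,
      fAN = k_on * a * fFN - (lambda_decay + rho) * fAN,
      uFD = RD * N * fFN - (k_on * (a + b) + omega) * uFD,
      uAD = RD * N * fAN + k_on * a * uFD - (lambda_decay + omega) * uAD,
      Abl = lambda_decay * (a + p) * V,
      cumV = lambda_decay * gamma * fAN * N,
      cumD = lambda_decay * gamma * uAD,
      born = rho * N)
  })
  d
}

# Integrate one injection-free interval with the compiled model,
# stopping at whichever terminal roots (lethal burden, lethal blood
# decays) are enabled.
integrate_segment <- function(y, times, params, rtol, atol,
                              death_root, toxicity_root) {
  args <- list(y = y, times = times, func = "trt_derivs",
               parms = c_parms(params, death_root, toxicity_root),
               dllname = "trtsim", initfunc = "trt_initmod",
               rtol = rtol, atol = atol, maxsteps = 50000)
  if (death_root || toxicity_root) {
    args$rootfunc <- "trt_root"
    args$nroot <- 2L
    out <- do.call(deSolve::lsodar, args)
  } else {
    out <- do.call(deSolve::lsoda, args)
  }
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("solver failure on interval [%g, %g]",
                 times[1], times[length(times)]))
  out
}

#' Simulate treatment
#'
#' Integrates the model over `[0, horizon]` days under a bolus dose
#' schedule. Integration proceeds piecewise between injection times;
#' each injection is applied as an instantaneous jump of the plasma
#' antibody concentrations, never as a delta function inside the
#' vector field. The adaptive, stiffness-switching lsoda solver
#' resolves both the fast binding phase (rates of order 70/day) and
#' the slow decay phase.
#'
#' @param params A [trt_parameters()] record.
#' @param schedule A [trt_schedule()]. The schedule's `eta` (if set)
#'   overrides `params$eta`.
#' @param horizon Simulation horizon, days (must exceed the last
#'   injection time).
#' @param points_per_day Density of the output grid used for
#'   trajectory reporting and minimum detection.
#' @param stop_at_endpoints Which endpoint crossings terminate the
#'   integration (located exactly by the solver's root finder):
#'   `"death"` (default) stops when the cancer burden `N + D` reaches
#'   the lethal count `C_d` — past that point the host is dead and the
#'   unbounded regrowth of the model has no meaning; `TRUE` or
#'   `"both"` additionally stops at the lethal blood-decay amount
#'   `A_bl_cr` (used in trials, where toxicity kills); `"toxicity"`
#'   stops only there; `FALSE` or `"none"` integrates the full horizon
#'   regardless (crossings are then located on the output grid), which
#'   is appropriate when tracking cumulative blood decays of a
#'   curative-but-toxic dose.
#' @param rtol,atol Solver relative and absolute tolerances.
#'
#' @return An object of class `trt_sim` with elements
#' \describe{
#'   \item{trajectory}{data.frame `time, a, b, p, N, D, f_FN, f_AN,
#'     f_FD, f_AD, cum_blood_decays, cum_viable_decays,
#'     cum_damaged_decays, cum_cells_born`. Damaged-cell fractions are
#'     recovered from the integrated absolute receptor amounts where
#'     `D > 1e-12`; while no damaged cells exist they are reported at
#'     their initial values `f_FD = 1`, `f_AD = 0`.}
#'   \item{N_min, t_N_min}{global minimum of viable cells over the
#'     horizon (spline-refined between grid points) and its time.}
#'   \item{cured}{`TRUE` when `N_min < N_cur`.}
#'   \item{death_time}{first time `N + D` crosses `C_d`, or `NA`.}
#'   \item{toxicity_time}{first time cumulative blood decays cross
#'     `A_bl_cr`, or `NA`.}
#'   \item{survival_time}{`min(death_time, toxicity_time, horizon)`.}
#' }
#' @examples
#' p <- trt_parameters()
#' sim <- simulate_trt(p, trt_schedule(0, 0.004, eta = 0), horizon = 60)
#' sim$N_min
#' @export
simulate_trt <- function(params, schedule = trt_schedule(numeric(0),
                                                         numeric(0)),
                         horizon = 365, points_per_day = 20,
                         stop_at_endpoints = "death",
                         rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "trt_parameters"),
            inherits(schedule, "trt_schedule"))
  mode <- if (isTRUE(stop_at_endpoints)) "both"
          else if (isFALSE(stop_at_endpoints)) "none"
          else match.arg(stop_at_endpoints,
                         c("death", "both", "none", "toxicity"))
  death_root <- mode %in% c("death", "both")
  toxicity_root <- mode %in% c("toxicity", "both")
  eta <- if (!is.null(schedule$eta)) schedule$eta else params$eta
  inj_t <- schedule$times
  inj_A <- schedule$amounts
  if (length(inj_t) > 0 && horizon <= inj_t[length(inj_t)])
    stop("horizon must exceed the last injection time")

  grid <- seq(0, horizon, by = 1 / points_per_day)
  if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
  # segment boundaries: 0, injection times (>0), horizon
  bounds <- sort(unique(c(0, inj_t[inj_t > 0], horizon)))

  y <- trt_initial_state(params)
  rows <- NULL
  stopped <- FALSE
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    i <- match(t0, inj_t)
    if (!is.na(i)) y <- apply_injection(y, inj_A[i], eta, params$V)
    seg_times <- unique(c(t0, grid[grid > t0 & grid < t1], t1))
    out <- integrate_segment(y, seg_times, params, rtol, atol,
                             death_root, toxicity_root)
    # drop the segment's first row except for the very first segment
    rows <- rbind(rows, out[if (k == 1) TRUE else -1, , drop = FALSE])
    y <- setNames(out[nrow(out), -1], .state_names)
    if ((death_root || toxicity_root) &&
        out[nrow(out), "time"] < t1 - 1e-9) { # root hit inside segment
      stopped <- TRUE
      break
    }
  }
  # injection at t = 0 of the final state is impossible; injection at
  # horizon is rejected above.
  traj <- as.data.frame(rows)
  names(traj) <- c("time", .state_names)
  finalize_trt_sim(traj, params, schedule, eta, horizon, stopped)
}

# Assemble the trt_sim object: recover damaged-cell fractions, refine
# the viable-cell minimum, locate endpoint crossings.
finalize_trt_sim <- function(traj, params, schedule, eta, horizon,
                             stopped) {
  has_D <- traj$D > 1e-12
  f_FD <- ifelse(has_D, traj$uFD / traj$D, 1)
  f_AD <- ifelse(has_D, traj$uAD / traj$D, 0)

  # global minimum of N, refined with a spline in log N around the
  # grid minimum (N stays positive up to solver tolerance; clamp at
  # the absolute tolerance floor for the log)
  Npos <- pmax(traj$N, 1e-300)
  i_min <- which.min(Npos)
  N_min <- Npos[i_min]; t_N_min <- traj$time[i_min]
  if (i_min > 1 && i_min < nrow(traj)) {
    idx <- max(1, i_min - 5):min(nrow(traj), i_min + 5)
    sf <- splinefun(traj$time[idx], log(Npos[idx]))
    op <- optimize(sf, range(traj$time[idx]))
    if (op$objective < log(N_min)) {
      N_min <- exp(op$objective); t_N_min <- op$minimum
    }
  }

  death_time <- crossing_time(traj$time, traj$N + traj$D, params$C_d)
  toxicity_time <- crossing_time(traj$time, traj$Abl, params$A_bl_cr)
  survival_time <- min(death_time, toxicity_time, horizon, na.rm = TRUE)

  out <- data.frame(
    time = traj$time, a = traj$a, b = traj$b, p = traj$p,
    N = traj$N, D = traj$D, f_FN = traj$fFN, f_AN = traj$fAN,
    f_FD = f_FD, f_AD = f_AD,
    cum_blood_decays = traj$Abl, cum_viable_decays = traj$cumV,
    cum_damaged_decays = traj$cumD, cum_cells_born = traj$born)

  structure(list(trajectory = out, N_min = N_min, t_N_min = t_N_min,
                 cured = N_min < params$N_cur,
                 death_time = death_time, toxicity_time = toxicity_time,
                 survival_time = survival_time, horizon = horizon,
                 stopped_at_endpoint = stopped,
                 params = params, schedule = schedule, eta = eta),
            class = "trt_sim")
}

# First upward crossing of a threshold, linearly interpolated on the
# output grid; NA if never crossed.
crossing_time <- function(time, value, threshold) {
  above <- value >= threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(time[1])
  t0 <- time[i - 1]; t1 <- time[i]
  v0 <- value[i - 1]; v1 <- value[i]
  if (v1 == v0) return(t1)
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' @export
print.trt_sim <- function(x, ...) {
  cat(sprintf("TRT simulation: %d injection(s), horizon %g days\n",
              length(x$schedule$times), x$horizon))
  cat(sprintf("  N_min = %.4g (1e7 cells) at t = %.2f d; cured: %s\n",
              x$N_min, x$t_N_min, x$cured))
  cat(sprintf("  death_time = %s, toxicity_time = %s, survival = %.1f d\n",
              format(x$death_time), format(x$toxicity_time),
              x$survival_time))
  cat(sprintf("  cumulative blood decays = %.4g pmol\n",
              max(x$trajectory$cum_blood_decays)))
  invisible(x)
}
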