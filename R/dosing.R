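#' Minimal single curative dose
#'
#' Finds the smallest single bolus of active radioconjugates for which
#' the minimal number of viable cells over the horizon falls to the
#' cure threshold `N_cur`, by bisection on the monotone-decreasing
#' `N_min(A)`. The bracket is expanded geometrically until it straddles
#' the cure threshold; if no dose within `bracket_limit` cures (as
#' happens with `k_f = 0` once injected antibodies exceed the total
#' receptor amount), the search reports non-convergence with
#' `A_cur = Inf` instead of silently accepting a bound.
#'
#' @param params A [trt_parameters()] record.
#' @param eta Impurity coefficient for the injected preparation;
#'   defaults to `params$eta`.
#' @param injection_time Time of the bolus, days.
#' @param horizon Horizon over which cure is assessed, days.
#' @param bracket Initial dose bracket, pmol.
#' @param tol Relative dose tolerance of the bisection.
#' @param bracket_limit Largest dose considered before declaring the
#'   case incurable, pmol.
#' @param points_per_day Output-grid density passed to
#'   [simulate_trt()].
#'
#' @return An object of class `trt_curative_dose`: list with `A_cur`
#'   (pmol), `A_cur_nCi`, `per_cell` (radioconjugate molecules per
#'   initial cell), `N_min` at `A_cur`, `converged`, `bracket` used,
#'   and the final simulation `sim`.
#' @examples
#' \donttest{
#' p <- trt_parameters(k_s = 0)
#' cd <- find_minimal_curative_dose(p, eta = 0)
#' cd$per_cell  # about 76 radioconjugates per cell
#' }
#' @export
find_minimal_curative_dose <- function(params, eta = params$eta,
                                       injection_time = 0, horizon = 365,
                                       bracket = c(1e-5, 1), tol = 1e-4,
                                       bracket_limit = 1e4,
                                       points_per_day = 10) {
  nmin_at <- function(A) {
    simulate_trt(params, trt_schedule(injection_time, A, eta = eta),
                 horizon = horizon, points_per_day = points_per_day)$N_min
  }
  lo <- bracket[1]; hi <- bracket[2]
  # expand upward until cure
  while (nmin_at(hi) >= params$N_cur) {
    hi <- hi * 4
    if (hi > bracket_limit) {
      return(structure(list(A_cur = Inf, A_cur_nCi = Inf, per_cell = Inf,
                            N_min = NA_real_, converged = FALSE,
                            bracket = c(lo, hi), sim = NULL,
                            message = "no dose within bracket_limit cures"),
                       class = "trt_curative_dose"))
    }
  }
  # contract downward until the lower end does not cure
  while (nmin_at(lo) < params$N_cur) {
    hi <- lo
    lo <- lo / 4
    if (lo < 1e-12) break
  }
  while ((hi - lo) / hi > tol) {
    mid <- 0.5 * (lo + hi)
    if (nmin_at(mid) < params$N_cur) hi <- mid else lo <- mid
  }
  A_cur <- 0.5 * (lo + hi)
  sim <- simulate_trt(params,
                      trt_schedule(injection_time, A_cur, eta = eta),
                      horizon = horizon, points_per_day = points_per_day)
  structure(list(A_cur = A_cur,
                 A_cur_nCi = activity_nCi_from_pmol(A_cur,
                                                    params$lambda_decay),
                 per_cell = radioconjugates_per_cell(A_cur,
                                                     params$N0 * 1e7),
                 N_min = sim$N_min, converged = TRUE,
                 bracket = c(lo, hi), sim = sim, message = "converged"),
            class = "trt_curative_dose")
}

#' @export
print.trt_curative_dose <- function(x, ...) {
  if (!x$converged) {
    cat("Minimal curative dose search did not converge:", x$message, "\n")
  } else {
    cat(sprintf("Minimal single curative dose: %.4g pmol (%.1f nCi)\n",
                x$A_cur, x$A_cur_nCi))
    cat(sprintf("  %.1f radioconjugates per initial cell; N_min = %.3g\n",
                x$per_cell, x$N_min))
  }
  invisible(x)
}

#' Sweep of the minimal curative dose over drug impurity
#'
#' For each impurity coefficient in `eta_grid`, finds the minimal
#' single curative dose and reports it together with the cumulative
#' blood decays and the fraction of injected activity spent on viable
#' cells at that dose. Reproduces the impurity phenomenology: the
#' curative dose is nearly flat while injected antibodies are few
#' relative to the receptor pool; as antibodies approach receptor
#' saturation the self-damage-dominated cases dip while the cross-fire
#' case rises sharply; with `k_f = 0` cure becomes impossible past
#' saturation (reported as `Inf`), while with `k_f > 0` the curative
#' dose tends to a finite but highly toxic limit.
#'
#' @param params A [trt_parameters()] record.
#' @param eta_grid Impurity coefficients to sweep.
#' @param ... Passed to [find_minimal_curative_dose()].
#' @return data.frame with columns `eta`, `A_cur_pmol`, `A_cur_nCi`,
#'   `per_cell`, `blood_decays_pmol`, `blood_decay_factor` (ratio to
#'   the lethal amount `A_bl_cr`), `viable_fraction` (share of
#'   injected nuclides decaying on viable-cell receptors), and
#'   `converged`.
#' @export
impurity_sweep <- function(params, eta_grid, ...) {
  rows <- lapply(eta_grid, function(eta) {
    cd <- find_minimal_curative_dose(params, eta = eta, ...)
    if (!cd$converged) {
      data.frame(eta = eta, A_cur_pmol = Inf, A_cur_nCi = Inf,
                 per_cell = Inf, blood_decays_pmol = NA_real_,
                 blood_decay_factor = NA_real_,
                 viable_fraction = NA_real_, converged = FALSE)
    } else {
      tr <- cd$sim$trajectory
      abl <- max(tr$cum_blood_decays)
      data.frame(eta = eta, A_cur_pmol = cd$A_cur,
                 A_cur_nCi = cd$A_cur_nCi, per_cell = cd$per_cell,
                 blood_decays_pmol = abl,
                 blood_decay_factor = abl / params$A_bl_cr,
                 viable_fraction = max(tr$cum_viable_decays) / cd$A_cur,
                 converged = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Estimate cancer binding capacity from a diagnostic PK curve
#'
#' After a small diagnostic injection that occupies a negligible
#' fraction of receptors, the plasma radioconjugate concentration
#' decays approximately single-exponentially with rate
#' `k_obs = lambda + kappa_c + k_on*gamma*N0/V` during the binding
#' phase. Ordinary least squares on the log-concentration recovers
#' `k_obs`, from which the binding capacity is
#' `gamma*N0 = (k_obs - lambda - kappa_c) * V / k_on`, floored at 0.
#'
#' @param pk A data.frame with columns `time` (days) and
#'   `concentration` (nM), e.g. from [generate_pk_fixture()].
#' @param k_on Binding rate, 1/(nM day).
#' @param V Volume of distribution, ml.
#' @param lambda_decay Nuclide decay rate, 1/day.
#' @param kappa_c Intact-antibody clearance rate, 1/day.
#' @return Estimated capacity `gamma*N0` in pmol, with the fitted decay
#'   rate attached as attribute `k_obs`.
#' @export
estimate_binding_capacity <- function(pk, k_on, V, lambda_decay,
                                      kappa_c) {
  if (nrow(pk) < 3)
    stop("need at least 3 observations within the binding phase")
  if (any(pk$concentration <= 0))
    stop("concentrations must be positive")
  fit <- lm(log(concentration) ~ time, data = pk)
  k_obs <- -coef(fit)[["time"]]
  cap <- (k_obs - lambda_decay - kappa_c) * V / k_on
  if (cap < 0) {
    warning("fitted decay rate below lambda + kappa_c; capacity floored at 0")
    cap <- 0
  }
  structure(cap, k_obs = k_obs)
}

#' Capacity-based personalized single dose
#'
#' The personalized dosing rule keyed to a single measurable quantity,
#' the cancer binding capacity `gamma*N0`: inject the amount of
#' antibodies `1.5*gamma*N0 + 3` pmol (the additive 3 pmol compensates
#' for slow drug binding when few specific receptors are present),
#' i.e. an active dose of `(1.5*gamma*N0 + 3)/(eta + 1)` pmol, capped
#' by the worst-case [max_safe_dose()] for that capacity.
#'
#' @param capacity Cancer binding capacity `gamma*N0`, pmol.
#' @param eta Impurity coefficient; defaults to `params$eta`.
#' @param params A [trt_parameters()] record.
#' @param ranges Sweep ranges for the safety cap.
#' @return List with `pmol`, `nCi`, logical `capped`, and the safety
#'   cap `safe_pmol`.
#' @export
personalized_dose <- function(capacity, eta = params$eta, params,
                              ranges = trt_parameter_ranges()) {
  if (capacity < 0) stop("capacity must be non-negative")
  rule <- (1.5 * capacity + 3) / (eta + 1)
  cap <- max_safe_dose(capacity, params, ranges, eta = eta)$pmol
  A <- min(rule, cap)
  list(pmol = A, nCi = activity_nCi_from_pmol(A, params$lambda_decay),
       capped = rule > cap, safe_pmol = cap)
}
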