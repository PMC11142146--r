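#' Closed-form minimal surviving fraction, self-damage-only setting
#'
#' Analytic estimate of the minimal surviving fraction `Nm/N0` reached
#' under a single pure bolus of `A` pmol when all radiation damage is
#' self-damage (`k_s = 1`). With `x = alpha*A/(nu*N0)` (the deposited
#' energy per unit cancer mass, in units of the radiosensitivity) and
#' `r = rho/lambda` (proliferation per nuclide lifetime),
#'
#' `Nm/N0 = (x/r)^(r/(1+r)) * exp((r - x)/(1+r))`
#'
#' The self-damage setting needs higher doses than cross-fire because
#' the anchored-nuclide density on viable cells falls as
#' `exp(-(lambda+rho)t)`: decay is compounded by dilution of the
#' conjugates over newborn cells. As `rho -> 0` (or immediate decay)
#' the estimate tends to the classical instantaneous-irradiation
#' survival `exp(-alpha*A/(nu*N0))`.
#'
#' Valid when the injected antibodies bind quickly and nearly
#' completely, i.e. `(eta+1)*A` well below the binding capacity
#' `gamma*N0` and binding fast relative to decay.
#'
#' @param A Injected active radioconjugate amount, pmol.
#' @param params A [trt_parameters()] record.
#' @return Estimated minimal surviving fraction in (0, 1]. Evaluated in
#'   log space; returns 1 when the dose cannot outpace proliferation
#'   (`x <= r`) or when `A = 0`.
#' @export
surviving_fraction_selfdamage <- function(A, params) {
  sf_closed_form(A, params, selfdamage = TRUE)
}

#' Closed-form minimal surviving fraction, cross-fire-only setting
#'
#' Analytic estimate of the minimal surviving fraction under a single
#' pure bolus when all damage is cross-fire (`k_s = 0`):
#'
#' `Nm/N0 = (x/r)^r * exp(2*r - x)`
#'
#' with `x = alpha*A/(nu*N0)` and `r = rho/lambda`. Cross-fire
#' irradiation decays only with nuclide decay (`exp(-lambda*t)`), the
#' slowest possible decline of the damage rate, so this setting needs
#' the lowest curative doses.
#'
#' @inheritParams surviving_fraction_selfdamage
#' @return Estimated minimal surviving fraction in (0, 1].
#' @export
surviving_fraction_crossfire <- function(A, params) {
  sf_closed_form(A, params, selfdamage = FALSE)
}

sf_closed_form <- function(A, params, selfdamage) {
  if (any(A < 0)) stop("dose must be non-negative")
  x <- params$alpha * A / (params$nu * params$N0)
  r <- params$rho / params$lambda_decay
  log_sf <- ifelse(x <= r, 0,
                   if (selfdamage) {
                     (r * log(x / r) + r - x) / (1 + r)
                   } else {
                     r * log(x / r) + 2 * r - x
                   })
  exp(pmin(log_sf, 0))
}

#' Decomposition of decays in blood at curative single doses
#'
#' Estimates which fraction of the injected activity is spent as toxic
#' decays of plasma-resident nuclides, split into the intact
#' radioconjugates that decay before binding or clearance,
#'
#' `lambda / (lambda + kappa_c + k_on*gamma*N0/V)`
#'
#' and the radioconjugate fragments released from dead cancer cells,
#'
#' `omega*lambda / ((lambda + omega) * (lambda + kappa_p))`
#'
#' (a nuclide anchored to a cell decays before release with probability
#' `lambda/(lambda+omega)` and a released fragment decays in plasma
#' before clearance with probability `lambda/(lambda+kappa_p)`). At the
#' basic parameters about 97% of decays in blood are due to fragments.
#'
#' @param params A [trt_parameters()] record.
#' @return List with `intact`, `fragment`, `total` (their sum, the
#'   estimated ratio of blood decays to injected activity) and
#'   `fragment_share` of the total.
#' @export
blood_decay_fraction <- function(params) {
  intact <- with(params, lambda_decay /
                   (lambda_decay + kappa_c + k_on * gamma * N0 / V))
  fragment <- with(params, omega * lambda_decay /
                     ((lambda_decay + omega) * (lambda_decay + kappa_p)))
  list(intact = intact, fragment = fragment, total = intact + fragment,
       fragment_share = fragment / (intact + fragment))
}

#' Upper bound on the fraction of activity spent on viable cells
#'
#' In a curative single-dose setting the fraction of injected activity
#' whose decays occur on viable-cell receptors cannot exceed
#' `1 / log(N0/N_cur)`, which is below 5% whenever the initial
#' population exceeds 1e7 cells (with the 0.01-cell cure threshold).
#'
#' @param N0 Initial viable-cell count.
#' @param N_cur Cure threshold, in the same units as `N0`.
#' @return The bound, dimensionless.
#' @export
viable_fraction_bound <- function(N0, N_cur) {
  if (any(N0 <= N_cur) || any(N_cur <= 0))
    stop("need N0 > N_cur > 0")
  1 / log(N0 / N_cur)
}

#' Maximal safe single dose for a given cancer binding capacity
#'
#' Largest injected activity guaranteed not to push cumulative blood
#' decays past the lethal amount `A_bl_cr` for any parameter set within
#' the physiologic sweep ranges. Injected antibodies split between a
#' bound part (limited by the binding capacity shared with co-injected
#' inert antibodies) and an unbound surplus. Worst cases are evaluated
#' at range corners, where each branch is monotone: intact-antibody
#' decays at minimal `kappa_c` (and maximal `V`), fragment decays at
#' maximal `omega` and minimal `kappa_p`.
#'
#' In the limits this reproduces the two capacity-independent bounds:
#' about 362 nCi at zero capacity (all decays from intact antibodies in
#' plasma) and about 1763 nCi as capacity grows large (all decays from
#' released fragments).
#'
#' @param binding_capacity Cancer binding capacity `gamma*N0`, pmol.
#' @param params A [trt_parameters()] record (supplies `lambda_decay`,
#'   `k_on`, `eta`, `A_bl_cr`).
#' @param ranges Sweep ranges as from [trt_parameter_ranges()].
#' @param eta Impurity coefficient; defaults to `params$eta`.
#' @return List with the dose as `pmol` and `nCi`, and the worst-case
#'   blood-decay fraction `fraction` at that dose.
#' @export
max_safe_dose <- function(binding_capacity, params,
                          ranges = trt_parameter_ranges(),
                          eta = params$eta) {
  if (binding_capacity < 0) stop("binding capacity must be non-negative")
  lam <- params$lambda_decay
  rng <- function(nm) {
    i <- match(nm, ranges$parameter)
    if (is.na(i)) stop("range for '", nm, "' missing")
    c(ranges$min[i], ranges$max[i])
  }
  kc_min <- rng("kappa_c")[1]
  om_max <- rng("omega")[2]
  kp_min <- rng("kappa_p")[1]
  V_max <- rng("V")[2]

  frag <- om_max * lam / ((lam + om_max) * (lam + kp_min))
  # worst-case blood-decay fraction of a dose A (pmol of nuclides)
  worst_fraction <- function(A) {
    if (A <= 0) return(lam / (lam + kc_min))
    # share of injected antibodies that can bind given the capacity
    q <- min(1, binding_capacity / ((eta + 1) * A))
    bind_rate <- params$k_on * binding_capacity / V_max
    intact <- lam / (lam + kc_min + bind_rate)
    anchored <- bind_rate / (lam + kc_min + bind_rate)
    q * (intact + anchored * frag) + (1 - q) * lam / (lam + kc_min)
  }
  target <- function(A) A * worst_fraction(A) - params$A_bl_cr
  hi <- params$A_bl_cr / frag # capacity -> infinity limit, upper bound
  A <- if (target(hi) <= 0) hi else
    uniroot(target, c(params$A_bl_cr, hi), tol = 1e-12)$root
  list(pmol = A, nCi = activity_nCi_from_pmol(A, lam),
       fraction = worst_fraction(A))
}

#' Long-term curability condition under saturated dosing
#'
#' With cancer receptors kept saturated by antibodies of which a
#' fraction `1/(eta+1)` is active, the maximal achievable damage rate
#' from anchored nuclides is `alpha*lambda*gamma/(nu*(eta+1))`. A
#' necessary (not sufficient) condition for driving viable cells down
#' in the long term is that this rate exceeds the proliferation rate
#' `rho`.
#'
#' @param params A [trt_parameters()] record.
#' @param eta Impurity coefficient; defaults to `params$eta`.
#' @return List with `max_damage_rate` (1/day), `rho`, the logical
#'   `curable`, and the `margin` (ratio of the two rates).
#' @export
curability_condition <- function(params, eta = params$eta) {
  rate <- params$alpha * params$lambda_decay * params$gamma /
    (params$nu * (eta + 1))
  list(max_damage_rate = rate, rho = params$rho,
       curable = rate > params$rho, margin = rate / params$rho)
}
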