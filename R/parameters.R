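#' Model parameters for targeted radionuclide therapy simulation
#'
#' Constructs a validated parameter record. Defaults are the basic
#' values of the published parameter table for treatment of a
#' disseminated multiple myeloma mouse model by an
#' actinium-225-labeled anti-CD38 antibody.
#'
#' Units: time in days, volumes in ml, amounts of antibodies and
#' receptors in pmol, concentrations in nM (pmol/ml), cell counts in
#' units of 1e7 cells. With these normalizations every default below
#' can be used verbatim.
#'
#' @param lambda_decay Radionuclide decay rate, 1/day (225Ac half-life
#'   about 9.9 days).
#' @param k_on Antibody-receptor binding rate, 1/(nM day).
#' @param kappa_c Intact-antibody clearance rate, 1/day.
#' @param kappa_p Antibody-fragment clearance rate, 1/day.
#' @param gamma Amount of receptors on 1e7 cancer cells, pmol.
#' @param V Volume of drug distribution, ml.
#' @param nu Volume of a lesion containing 1e7 cancer cells, ml.
#' @param k_s Relative significance of self-damage, in \[0, 1\]. 0 means
#'   all damage of a cell comes from decays on neighboring cells
#'   (cross-fire), 1 means all damage comes from decays on its own
#'   receptors.
#' @param rho Viable-cell proliferation rate, 1/day.
#' @param omega Damaged-cell death rate, 1/day.
#' @param alpha Cancer-cell radiosensitivity: damage rate per unit
#'   concentration of anchored-nuclide decays.
#' @param k_f Significance of unanchored-nuclide decays for cancer
#'   damage, dimensionless.
#' @param eta Coefficient of drug impurity: inert antibodies injected
#'   per active radioconjugate.
#' @param N0 Initial number of viable cancer cells, units of 1e7 cells.
#' @param N_cur Cure threshold, units of 1e7 cells (default 1e-9, i.e.
#'   0.01 cell).
#' @param C_d Lethal cancer burden, units of 1e7 cells (default 1e4,
#'   i.e. 1e11 cells).
#' @param A_bl_cr Lethal cumulative amount of decays in blood, pmol
#'   (default 0.0175 pmol, equivalent to about 230 nCi of 225Ac).
#'
#' @return An object of class `trt_parameters` (a named list).
#' @examples
#' p <- trt_parameters()
#' p_selfdamage <- trt_parameters(k_s = 1)
#' @export
trt_parameters <- function(lambda_decay = 0.07,
                           k_on = 11.15,
                           kappa_c = 0.1,
                           kappa_p = 1,
                           gamma = 2.1,
                           V = 1,
                           nu = 0.015,
                           k_s = 0.3,
                           rho = 0.34,
                           omega = 0.05,
                           alpha = 500,
                           k_f = 0.05,
                           eta = 1780,
                           N0 = 3,
                           N_cur = 1e-9,
                           C_d = 1e4,
                           A_bl_cr = 0.0175) {
  p <- list(lambda_decay = lambda_decay, k_on = k_on, kappa_c = kappa_c,
            kappa_p = kappa_p, gamma = gamma, V = V, nu = nu, k_s = k_s,
            rho = rho, omega = omega, alpha = alpha, k_f = k_f, eta = eta,
            N0 = N0, N_cur = N_cur, C_d = C_d, A_bl_cr = A_bl_cr)
  validate_trt_parameters(p)
}

#' Validate a parameter record
#'
#' Checks positivity and range invariants of a parameter list and
#' returns it classed as `trt_parameters`.
#'
#' @param p Named list with the fields of [trt_parameters()].
#' @return The validated `trt_parameters` object.
#' @export
validate_trt_parameters <- function(p) {
  required <- c("lambda_decay", "k_on", "kappa_c", "kappa_p", "gamma", "V",
                "nu", "k_s", "rho", "omega", "alpha", "k_f", "eta", "N0",
                "N_cur", "C_d", "A_bl_cr")
  missing <- setdiff(required, names(p))
  if (length(missing) > 0)
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(p), required)
  if (length(extra) > 0)
    stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  for (nm in required) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  strictly_pos <- c("lambda_decay", "k_on", "kappa_c", "kappa_p", "gamma",
                    "V", "nu", "rho", "omega", "alpha", "N0", "N_cur",
                    "C_d", "A_bl_cr")
  for (nm in strictly_pos)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  for (nm in c("k_s", "k_f", "eta"))
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative")
  if (p$k_s > 1) stop("k_s must lie in [0, 1]")
  if (!(p$N_cur < p$N0 && p$N0 < p$C_d))
    stop("parameters must satisfy N_cur < N0 < C_d")
  structure(p[required], class = "trt_parameters")
}

#' Physiologic sweep ranges of the model parameters
#'
#' Returns the ranges over which the varied parameters are swept when
#' generating virtual-mouse populations, together with the sampling
#' distribution used by [sample_population()]. Rates, amounts and cell
#' counts span orders of magnitude and are sampled log-uniformly; the
#' self-damage weight `k_s` is bounded in \[0, 1\] and is sampled
#' uniformly. `lambda_decay`, `k_on`, `nu` and `eta` are held fixed.
#'
#' @return A data.frame with columns `parameter`, `min`, `max`,
#'   `distribution`.
#' @export
trt_parameter_ranges <- function() {
  data.frame(
    parameter = c("kappa_c", "kappa_p", "gamma", "V", "rho", "omega",
                  "alpha", "k_f", "N0", "k_s"),
    min = c(0.04, 0.4, 0.13, 0.75, 0.15, 0.005, 50, 0.01, 1, 0),
    max = c(0.28, 4, 10, 1.5, 0.7, 0.5, 5000, 0.25, 10, 1),
    distribution = c(rep("loguniform", 9), "uniform"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.trt_parameters <- function(x, ...) {
  cat("Targeted radionuclide therapy model parameters\n")
  cat(sprintf("  nuclide:   lambda_decay = %g /day\n", x$lambda_decay))
  cat(sprintf("  binding:   k_on = %g /(nM day), gamma = %g pmol/1e7 cells\n",
              x$k_on, x$gamma))
  cat(sprintf("  clearance: kappa_c = %g, kappa_p = %g /day\n",
              x$kappa_c, x$kappa_p))
  cat(sprintf("  geometry:  V = %g ml, nu = %g ml/1e7 cells\n", x$V, x$nu))
  cat(sprintf("  cancer:    N0 = %g (1e7 cells), rho = %g, omega = %g /day\n",
              x$N0, x$rho, x$omega))
  cat(sprintf("  damage:    alpha = %g, k_s = %g, k_f = %g\n",
              x$alpha, x$k_s, x$k_f))
  cat(sprintf("  dosing:    eta = %g inert antibodies per radioconjugate\n",
              x$eta))
  cat(sprintf("  endpoints: N_cur = %g, C_d = %g (1e7 cells), A_bl_cr = %g pmol\n",
              x$N_cur, x$C_d, x$A_bl_cr))
  invisible(x)
}

# Parameter vector in the order expected by the compiled derivatives;
# the last two entries switch the terminal root functions on or off.
c_parms <- function(p, death_root = 1, toxicity_root = 0) {
  c(p$lambda_decay, p$k_on, p$kappa_c, p$kappa_p, p$gamma, p$V, p$nu,
    p$k_s, p$rho, p$omega, p$alpha, p$k_f, p$C_d, p$A_bl_cr,
    death_root, toxicity_root)
}
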