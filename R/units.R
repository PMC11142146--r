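#' Convert an amount of radionuclide to instantaneous activity
#'
#' An amount of `n` pmol of a nuclide with decay rate `lambda_decay`
#' (per day) has instantaneous activity
#' `n * 6.022e11 * lambda_decay / 86400` decays per second (Bq), which
#' is converted to nanocurie at 37 Bq/nCi. With the default 225Ac decay
#' rate, 0.0175 pmol corresponds to about 230 nCi.
#'
#' @param n_pmol Amount of nuclide, pmol. Must be non-negative.
#' @param lambda_decay Decay rate, 1/day.
#' @return Activity in nCi.
#' @seealso [pmol_from_activity_nCi()] for the inverse.
#' @examples
#' activity_nCi_from_pmol(0.0175) # ~230 nCi
#' @export
activity_nCi_from_pmol <- function(n_pmol, lambda_decay = 0.07) {
  if (any(n_pmol < 0)) stop("amount must be non-negative")
  n_pmol * .AVOGADRO_PMOL * (lambda_decay / .SECONDS_PER_DAY) / .BQ_PER_NCI
}

#' Convert instantaneous activity to an amount of radionuclide
#'
#' Inverse of [activity_nCi_from_pmol()].
#'
#' @param nCi Activity in nanocurie.
#' @param lambda_decay Decay rate, 1/day.
#' @return Amount in pmol.
#' @export
pmol_from_activity_nCi <- function(nCi, lambda_decay = 0.07) {
  if (any(nCi < 0)) stop("activity must be non-negative")
  nCi * .BQ_PER_NCI / (.AVOGADRO_PMOL * lambda_decay / .SECONDS_PER_DAY)
}

#' Impurity coefficient implied by a labeling ratio
#'
#' The labeling (specific) activity of a radioconjugate preparation,
#' in kBq of nuclide per microgram of antibody, determines how many
#' antibodies carry no nuclide per labeled one. Per microgram there are
#' `1e-6 / M` mol of antibody and the labeled amount follows from the
#' activity via the decay rate; the impurity coefficient eta is the
#' ratio of unlabeled to labeled antibodies.
#'
#' @param ratio_kBq_per_ug Labeling ratio, kBq per microgram.
#' @param antibody_molar_mass Antibody molar mass, g/mol. The default
#'   148000 (148 kDa) is a typical IgG1 mass.
#' @param lambda_decay Nuclide decay rate, 1/day.
#' @return eta, inert antibodies per active radioconjugate
#'   (dimensionless). A labeling ratio of 1.85 kBq/ug gives eta of
#'   about 1780 at the defaults.
#' @examples
#' eta_from_labeling_ratio(1.85)
#' @export
eta_from_labeling_ratio <- function(ratio_kBq_per_ug,
                                    antibody_molar_mass = 148000,
                                    lambda_decay = 0.07) {
  if (any(ratio_kBq_per_ug <= 0)) stop("labeling ratio must be positive")
  antibodies_pmol <- 1e-6 / antibody_molar_mass * 1e12   # pmol per ug
  lambda_s <- lambda_decay / .SECONDS_PER_DAY
  nuclides_pmol <- ratio_kBq_per_ug * 1000 / lambda_s / .AVOGADRO_PMOL
  if (any(nuclides_pmol > antibodies_pmol))
    stop("labeling ratio implies more nuclides than antibodies")
  (antibodies_pmol - nuclides_pmol) / nuclides_pmol
}

#' Receptors per cell implied by the receptor density parameter
#'
#' @param gamma Amount of receptors on 1e7 cancer cells, pmol.
#' @return Average number of receptor molecules per cell. The default
#'   receptor density gamma = 2.1 pmol per 1e7 cells corresponds to
#'   about 126,000 CD38 receptors per MM.1S cell.
#' @examples
#' receptors_per_cell(2.1)
#' @export
receptors_per_cell <- function(gamma) {
  if (any(gamma < 0)) stop("gamma must be non-negative")
  gamma * .AVOGADRO_PMOL / 1e7
}

#' Radioconjugate molecules per initial cancer cell
#'
#' Converts an injected amount of radioconjugates into the number of
#' molecules initially available per cancer cell.
#'
#' @param A_pmol Injected amount of active radioconjugates, pmol.
#' @param N0_cells Initial number of cancer cells (absolute count, not
#'   units of 1e7).
#' @return Molecules per cell.
#' @export
radioconjugates_per_cell <- function(A_pmol, N0_cells) {
  if (any(N0_cells <= 0)) stop("N0_cells must be positive")
  A_pmol * .AVOGADRO_PMOL / N0_cells
}
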