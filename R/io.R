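#' Load model parameters from a file
#'
#' Reads a flat key-value parameter file (JSON, or YAML when the
#' 'yaml' package is available) with keys named exactly as the fields
#' of [trt_parameters()]. Keys not present fall back to the packaged
#' defaults; unknown keys are rejected. The packaged file
#' `system.file("extdata", "parameters_basic.json", package = "trtsim")`
#' reproduces the basic published parameter set.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated [trt_parameters()] record.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML parameter files requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(vals)) vals <- list()
  vals <- vals[!vapply(vals, is.null, logical(1))]
  # keys starting with "_" are metadata (units, comments), not parameters
  if (length(vals) > 0) vals <- vals[!startsWith(names(vals), "_")]
  defaults <- unclass(trt_parameters())
  extra <- setdiff(names(vals), names(defaults))
  if (length(extra) > 0)
    stop("unknown parameter key(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  validate_trt_parameters(modifyList(defaults, vals))
}

#' Write simulation or trial outputs to a directory
#'
#' Writes the trajectory (for a `trt_sim`) or the per-mouse outcomes
#' and survival curves (for a `trt_trial`) as CSV, plus a JSON run
#' manifest recording parameters, schedule, seed, solver tolerances
#' and package version, sufficient to re-run the computation.
#'
#' @param result A `trt_sim` or `trt_trial` object.
#' @param outdir Output directory (created if needed).
#' @param seed Optional seed to record in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, outdir, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  manifest <- list(package = "trtsim",
                   version = as.character(packageVersion("trtsim")),
                   seed = seed)
  if (inherits(result, "trt_sim")) {
    f <- file.path(outdir, "trajectory.csv")
    write.csv(result$trajectory, f, row.names = FALSE)
    paths <- c(paths, f)
    f <- file.path(outdir, "outcome.csv")
    write.csv(data.frame(N_min = result$N_min, t_N_min = result$t_N_min,
                         cured = result$cured,
                         death_time = result$death_time,
                         toxicity_time = result$toxicity_time,
                         survival_time = result$survival_time),
              f, row.names = FALSE)
    paths <- c(paths, f)
    manifest$parameters <- unclass(result$params)
    manifest$schedule <- list(times = result$schedule$times,
                              amounts = result$schedule$amounts,
                              eta = result$eta)
    manifest$horizon <- result$horizon
  } else if (inherits(result, "trt_trial")) {
    f <- file.path(outdir, "mice.csv")
    write.csv(result$mice, f, row.names = FALSE)
    paths <- c(paths, f)
    f <- file.path(outdir, "survival_curves.csv")
    write.csv(result$curves, f, row.names = FALSE)
    paths <- c(paths, f)
    manifest$strategy <- class(result$strategy)[1]
    manifest$horizon <- result$horizon
  } else stop("unsupported result type")
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, mf))
}

#' Generate a synthetic diagnostic pharmacokinetic curve
#'
#' Simulates the plasma concentration of a small diagnostic
#' radioconjugate dose during the binding phase and applies
#' multiplicative log-normal measurement noise. The diagnostic dose
#' must occupy a negligible fraction of receptors for the
#' single-exponential capacity estimate of
#' [estimate_binding_capacity()] to apply; a warning is issued when
#' the injected antibodies exceed 1% of the binding capacity.
#'
#' @param params A [trt_parameters()] record (its `gamma*N0` is the
#'   true capacity, recorded as attribute `true_capacity`).
#' @param diagnostic_dose Injected diagnostic amount, pmol.
#' @param times Sampling times, days. The default confines sampling to
#'   the first hour after injection: the binding-phase decay rate is of
#'   order 70/day, so the curve is well resolved there, while the
#'   receptor pool grown by proliferating cells is still within a
#'   fraction of a percent of its value at injection, keeping the
#'   single-exponential capacity estimate essentially unbiased.
#' @param noise_sd Standard deviation of the log-normal multiplicative
#'   noise (0.05 is 5% noise).
#' @param seed Optional seed for the noise (the caller's random stream
#'   is restored afterwards).
#' @param eta Impurity of the diagnostic preparation (default 0,
#'   pure tracer).
#' @return data.frame of class `trt_pk` with columns `time`,
#'   `concentration` (nM), and attributes `true_capacity` and
#'   `noise_sd`.
#' @export
generate_pk_fixture <- function(params, diagnostic_dose = 0.01,
                                times = seq(0.005, 0.045,
                                            length.out = 8),
                                noise_sd = 0, seed = NULL, eta = 0) {
  capacity <- params$gamma * params$N0
  if ((eta + 1) * diagnostic_dose > 0.01 * capacity)
    warning("diagnostic dose occupies more than 1% of receptors; ",
            "the negligible-occupancy assumption is strained")
  sim <- simulate_trt(params, trt_schedule(0, diagnostic_dose, eta = eta),
                      horizon = max(times) * 1.2, points_per_day = 2000)
  conc <- approx(sim$trajectory$time, sim$trajectory$a, xout = times)$y
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", globalenv())) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, globalenv()))
      }
      set.seed(seed)
    }
    conc <- conc * rlnorm(length(conc), 0, noise_sd)
  }
  structure(data.frame(time = times, concentration = conc),
            class = c("trt_pk", "data.frame"),
            true_capacity = capacity, noise_sd = noise_sd)
}
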