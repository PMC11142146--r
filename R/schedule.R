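#' Bolus dose schedule
#'
#' An ordered list of bolus injections of radioconjugates. Each
#' injection of `A` pmol of active radioconjugates instantaneously
#' raises the active-antibody plasma concentration by `A/V` and the
#' inert-antibody concentration by `eta*A/V`.
#'
#' @param times Injection times, days (strictly increasing).
#' @param amounts Active radioconjugate amounts, pmol (non-negative,
#'   same length as `times`).
#' @param eta Optional impurity coefficient overriding the parameter
#'   record's `eta` for this schedule.
#' @return An object of class `trt_schedule`.
#' @examples
#' trt_schedule(0, 0.005)                 # one pure bolus at t = 0
#' trt_schedule(c(0, 7, 14), c(4e-3, 1e-3, 1e-3), eta = 1780)
#' @export
trt_schedule <- function(times = 0, amounts = 0, eta = NULL) {
  if (length(times) != length(amounts))
    stop("times and amounts must have the same length")
  if (length(times) > 0) {
    if (any(!is.finite(times)) || any(!is.finite(amounts)))
      stop("times and amounts must be finite")
    if (is.unsorted(times, strictly = TRUE))
      stop("injection times must be strictly increasing")
    if (any(amounts < 0)) stop("injected amounts must be non-negative")
  }
  if (!is.null(eta) && (length(eta) != 1 || eta < 0))
    stop("eta must be a single non-negative number")
  structure(list(times = as.numeric(times), amounts = as.numeric(amounts),
                 eta = eta),
            class = "trt_schedule")
}

#' @export
print.trt_schedule <- function(x, ...) {
  cat(sprintf("Dose schedule: %d injection(s)%s\n", length(x$times),
              if (is.null(x$eta)) "" else sprintf(", eta = %g", x$eta)))
  if (length(x$times) > 0)
    print(data.frame(t_days = x$times, A_pmol = x$amounts))
  invisible(x)
}

#' Apply a bolus injection to a model state
#'
#' @param state Named numeric state vector (components `a`, `b`, ...,
#'   as in the trajectory of [simulate_trt()]).
#' @param amount_pmol Active radioconjugate amount, pmol.
#' @param eta Impurity coefficient (inert antibodies per
#'   radioconjugate).
#' @param V Volume of distribution, ml.
#' @return The state with `a` increased by `amount/V` and `b` by
#'   `eta*amount/V`; all other components unchanged.
#' @export
apply_injection <- function(state, amount_pmol, eta, V) {
  if (amount_pmol < 0) stop("injected amount must be non-negative")
  state["a"] <- state["a"] + amount_pmol / V
  state["b"] <- state["b"] + eta * amount_pmol / V
  state
}
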