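#' Single-step model parameters
#'
#' Parameters of the single-step SHS model: exponential growth at rate `mu`
#' and a division hazard \eqn{k s^\alpha}. `alpha = 1` is the adder,
#' `alpha = 0` the size-independent (non-homeostatic) hazard, and large
#' `alpha` approaches sizer control with threshold \eqn{k^{1/\alpha}}.
#'
#' @param mu Fractional growth rate (1/time), > 0.
#' @param k Division-rate constant (size^(-alpha)/time), > 0.
#' @param alpha Hazard exponent, dimensionless, >= 0.
#' @return Object of class `"single_step_params"`.
#' @export
single_step_params <- function(mu = 1, k = 1, alpha = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu), mu > 0,
            is.numeric(k), length(k) == 1L, is.finite(k), k > 0,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            alpha >= 0)
  structure(list(mu = mu, k = k, alpha = alpha),
            class = "single_step_params")
}

#' Multi-step (staged cell cycle) model parameters
#'
#' Parameters of the M-stage model: the cell cycle is a progression through
#' stages 1..M, each stage-i transition firing with a size-proportional
#' hazard \eqn{k_i s}; reaching stage M, the cell divides at hazard
#' \eqn{k_M s}. `M = 1` recovers the single-step adder. The equal-rate case
#' \eqn{k_i = kM} makes the added size Erlang with mean \eqn{\mu/k} and
#' noise \eqn{CV^2_\Delta = 1/M}.
#'
#' @param mu Fractional growth rate (1/time), > 0.
#' @param rates Vector of per-stage rate constants \eqn{k_1 \ldots k_M}
#'   (1/(size time)), all > 0; its length defines the stage count M.
#' @return Object of class `"multi_step_params"` with elements `mu`,
#'   `rates`, `M`.
#' @export
multi_step_params <- function(mu, rates) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu), mu > 0,
            is.numeric(rates), length(rates) >= 1L, all(is.finite(rates)),
            all(rates > 0))
  structure(list(mu = mu, rates = as.numeric(rates), M = length(rates)),
            class = "multi_step_params")
}

#' Equal-rate multi-step parameters
#'
#' Convenience constructor for the equal-rate staged model with
#' \eqn{k_i = kM} for all stages, which keeps the mean added size per cycle
#' at \eqn{\mu/k} for every M.
#'
#' @inheritParams multi_step_params
#' @param k Overall rate constant; each stage rate is `k * M`.
#' @param M Number of stages, >= 1.
#' @return Object of class `"multi_step_params"`.
#' @export
equal_rate_params <- function(mu, k, M) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0,
            length(M) == 1L, M >= 1, M == round(M))
  multi_step_params(mu, rep(k * M, M))
}

#' @export
print.single_step_params <- function(x, ...) {
  cat(sprintf("Single-step SHS: mu = %g, hazard k*s^alpha with k = %g, alpha = %g\n",
              x$mu, x$k, x$alpha))
  invisible(x)
}

#' @export
print.multi_step_params <- function(x, ...) {
  cat(sprintf("Multi-step SHS: mu = %g, M = %d stages, rates k_i*s with k_i =\n",
              x$mu, x$M))
  print(x$rates)
  invisible(x)
}

#' Steady-state moment summary
#'
#' Container for steady-state cell-size moments. `cv2` is derived from the
#' first two uncentered moments; `exact` records whether every value is a
#' closed-form exact result (`TRUE`) or came from the derivative-matching
#' closure (`FALSE`).
#'
#' @param mean_size Steady-state mean size \eqn{\bar{\langle s\rangle}}.
#' @param second_moment Steady-state \eqn{\bar{\langle s^2\rangle}}.
#' @param skewness Optional standardized skewness.
#' @param moments Optional named vector of uncentered moments
#'   \eqn{\bar{\langle s^p\rangle}}, p = 1, 2, ...
#' @param exact Logical; `FALSE` iff any value is closure-approximate.
#' @return Object of class `"moment_summary"`.
#' @export
moment_summary <- function(mean_size, second_moment, skewness = NULL,
                           moments = NULL, exact = TRUE) {
  stopifnot(mean_size > 0, second_moment >= mean_size^2)
  out <- list(mean_size = mean_size,
              second_moment = second_moment,
              cv2 = second_moment / mean_size^2 - 1,
              skewness = skewness,
              moments = moments,
              exact = exact)
  class(out) <- "moment_summary"
  out
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("Steady-state size moments (%s)\n",
              if (x$exact) "exact" else "closure approximation"))
  cat(sprintf("  mean       : %.6g\n", x$mean_size))
  cat(sprintf("  <s^2>      : %.6g\n", x$second_moment))
  cat(sprintf("  CV^2       : %.6g\n", x$cv2))
  if (!is.null(x$skewness))
    cat(sprintf("  skewness   : %.6g\n", x$skewness))
  if (!is.null(x$moments))
    cat("  moments    :", paste(format(x$moments, digits = 6),
                                collapse = " "), "\n")
  invisible(x)
}
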