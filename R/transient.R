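#' Balanced division rate for the size-independent hazard
#'
#' With a size-independent division hazard (\eqn{\alpha = 0}, constant rate
#' k), the ensemble mean obeys
#' \eqn{d\langle s\rangle/dt = (\mu - k(1-\langle\beta\rangle))
#' \langle s\rangle}; a bounded non-zero mean therefore requires the rate
#' to exactly balance growth, \eqn{k = \mu/(1-\langle\beta\rangle)}.
#'
#' @param mu Growth rate, > 0.
#' @param law A [partition_law()].
#' @return The balanced rate constant k.
#' @export
alpha0_balanced_rate <- function(mu, law) {
  stopifnot(mu > 0, inherits(law, "partition_law"))
  mu / (1 - law$mean_beta)
}

#' Growth exponent of the second moment at the balanced rate
#'
#' Even at the balanced rate the second moment of size grows exponentially:
#' \deqn{\frac{d\langle s^2\rangle}{dt} = \mu \langle s^2\rangle\,
#'   \frac{(1-\langle\beta\rangle)^2 + \mathrm{Var}(\beta)}
#'        {1-\langle\beta\rangle} > 0,}
#' so \eqn{\langle s^2\rangle(t) = \langle s^2\rangle(0)\,e^{rt}} with the
#' returned rate \eqn{r}, strictly positive for every valid partition law.
#' The variance of cell size thus diverges: size-independent division
#' timing cannot provide homeostasis, and active size sensing is necessary.
#'
#' @inheritParams alpha0_balanced_rate
#' @return The exponential growth rate of \eqn{\langle s^2\rangle}.
#' @export
alpha0_second_moment_exponent <- function(mu, law) {
  stopifnot(mu > 0, inherits(law, "partition_law"))
  mb <- law$mean_beta
  var_b <- law$cv2_beta * mb^2
  mu * ((1 - mb)^2 + var_b) / (1 - mb)
}

#' Analytic transient moments for the size-independent hazard
#'
#' The \eqn{\alpha = 0} moment system closes at every order, so the first
#' two ensemble moments have the exact exponential solutions
#' \deqn{\langle s\rangle(t) = s_0\,e^{(\mu - k(1-\langle\beta\rangle))t},
#'  \qquad
#'  \langle s^2\rangle(t) = s_0^2\,e^{(2\mu - k(1-\langle\beta^2\rangle))t}.}
#' At the balanced rate of [alpha0_balanced_rate()] the mean is flat while
#' the second moment grows at [alpha0_second_moment_exponent()].
#'
#' @inheritParams alpha0_balanced_rate
#' @param k Division rate constant (use [alpha0_balanced_rate()] for the
#'   flat-mean case).
#' @param s0 Initial size (all lineages start at `s0`).
#' @param times Numeric vector of times at which to evaluate.
#' @return Data frame with columns `time`, `mean`, `second_moment`.
#' @export
alpha0_moments <- function(mu, k, law, s0 = 1, times) {
  stopifnot(mu > 0, k > 0, s0 > 0, inherits(law, "partition_law"),
            is.numeric(times), all(times >= 0))
  mb <- law$mean_beta
  b2 <- mb^2 * (1 + law$cv2_beta)
  data.frame(time = times,
             mean = s0 * exp((mu - k * (1 - mb)) * times),
             second_moment = s0^2 * exp((2 * mu - k * (1 - b2)) * times))
}
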