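#' Partition-fraction law of cell division
#'
#' Construct the law of the partition fraction \eqn{\beta \in (0,1)}, the
#' fraction of the mother's size inherited by the tracked daughter at
#' division. Noisy partitioning is modelled by a beta distribution with mean
#' `mean_beta` and squared coefficient of variation `cv2_beta`; perfect
#' (deterministic) partitioning is the point mass obtained at
#' `cv2_beta = 0`.
#'
#' The beta shape parameters are recovered from the (mean, noise) pair as
#' \deqn{a = z, \quad b = z\,(1/\langle\beta\rangle - 1), \quad
#'   z = \frac{1 - \langle\beta\rangle (1 + CV^2_\beta)}{CV^2_\beta},}
#' so that \eqn{a/(a+b) = \langle\beta\rangle} and the implied variance is
#' \eqn{CV^2_\beta \langle\beta\rangle^2}. A beta variable with mean
#' \eqn{\langle\beta\rangle} can carry at most
#' \eqn{CV^2_\beta < (1-\langle\beta\rangle)/\langle\beta\rangle}; pairs at
#' or beyond that bound are rejected.
#'
#' @param mean_beta Mean partition fraction \eqn{\langle\beta\rangle},
#'   strictly inside (0, 1). A symmetric split with the daughter chosen at
#'   random has `mean_beta = 0.5` (the default).
#' @param cv2_beta Squared coefficient of variation \eqn{CV^2_\beta \ge 0}
#'   of the partition fraction. `0` gives the deterministic point mass.
#' @return An object of class `"partition_law"`: a list with elements
#'   `mean_beta`, `cv2_beta`, `degenerate`, and (unless degenerate) the beta
#'   shapes `shape_a`, `shape_b`.
#' @examples
#' partition_law(0.5, 0.1)   # Beta(4.5, 4.5)
#' partition_law(0.5, 0)     # deterministic halving
#' @export
partition_law <- function(mean_beta = 0.5, cv2_beta = 0) {
  if (!is.numeric(mean_beta) || length(mean_beta) != 1L ||
      !is.finite(mean_beta) || mean_beta <= 0 || mean_beta >= 1)
    stop("`mean_beta` must be a single number strictly inside (0, 1), got ",
         format(mean_beta), call. = FALSE)
  if (!is.numeric(cv2_beta) || length(cv2_beta) != 1L ||
      !is.finite(cv2_beta) || cv2_beta < 0)
    stop("`cv2_beta` must be a single finite number >= 0, got ",
         format(cv2_beta), call. = FALSE)
  bound <- (1 - mean_beta) / mean_beta
  if (cv2_beta >= bound)
    stop("infeasible partition law: cv2_beta = ", format(cv2_beta),
         " must lie below the beta-distribution support bound ",
         "(1 - mean_beta)/mean_beta = ", format(bound),
         " for mean_beta = ", format(mean_beta), call. = FALSE)

  law <- list(mean_beta = mean_beta, cv2_beta = cv2_beta,
              degenerate = cv2_beta == 0)
  if (!law$degenerate) {
    z <- (1 - mean_beta * (1 + cv2_beta)) / cv2_beta
    law$shape_a <- z
    law$shape_b <- z * (1 / mean_beta - 1)
    # internal consistency: shapes must reproduce the requested moments
    ab <- law$shape_a + law$shape_b
    v <- law$shape_a * law$shape_b / (ab^2 * (ab + 1))
    stopifnot(abs(v / (cv2_beta * mean_beta^2) - 1) < 1e-10)
  }
  class(law) <- "partition_law"
  law
}

#' @export
print.partition_law <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Partition law: point mass at beta = %g\n", x$mean_beta))
  } else {
    cat(sprintf(
      "Partition law: Beta(%.6g, %.6g)  <beta> = %g, CV2_beta = %g\n",
      x$shape_a, x$shape_b, x$mean_beta, x$cv2_beta))
  }
  invisible(x)
}

#' Exact expectation of the log partition fraction
#'
#' Computes \eqn{\langle \log\beta \rangle} exactly: for the beta case,
#' \eqn{\psi(a) - \psi(a + b)} with \eqn{\psi} the digamma function; for the
#' degenerate case, \eqn{\log\langle\beta\rangle}. This quantity drives all
#' steady-state size moments and is always strictly negative.
#'
#' @param law A [partition_law()].
#' @return The expectation of \eqn{\log\beta} (a negative scalar).
#' @seealso [mean_log_beta_approx()] for the small-noise closed form.
#' @export
mean_log_beta <- function(law) {
  stopifnot(inherits(law, "partition_law"))
  if (law$degenerate) return(log(law$mean_beta))
  digamma(law$shape_a) - digamma(law$shape_a + law$shape_b)
}

#' Small-noise approximation to the expected log partition fraction
#'
#' Closed-form expansion of \eqn{\langle \log\beta \rangle} valid for small
#' partitioning noise \eqn{CV^2_\beta \ll 1}:
#' \deqn{\langle\log\beta\rangle \approx \log\langle\beta\rangle -
#'   \frac{(1-\langle\beta\rangle)\,CV^2_\beta}
#'        {2\,(1-\langle\beta\rangle-\langle\beta\rangle CV^2_\beta)}.}
#' A warning is emitted when `cv2_beta > 0.2`, where the expansion degrades.
#'
#' @inheritParams mean_log_beta
#' @return Approximate expectation of \eqn{\log\beta}.
#' @export
mean_log_beta_approx <- function(law) {
  stopifnot(inherits(law, "partition_law"))
  if (law$cv2_beta > 0.2)
    warning("small-noise approximation requested at cv2_beta = ",
            format(law$cv2_beta), " > 0.2; accuracy degrades", call. = FALSE)
  mb <- law$mean_beta
  denom <- 1 - mb - mb * law$cv2_beta
  if (denom <= 0)
    stop("small-noise expansion undefined: 1 - <beta> - <beta>*cv2_beta = ",
         format(denom), " <= 0", call. = FALSE)
  log(mb) - (1 - mb) * law$cv2_beta / (2 * denom)
}

#' Power moments of the partition fraction
#'
#' Exact \eqn{\langle \beta^p \rangle} for any real order `p > 0`, computed
#' via log-gamma differences,
#' \eqn{\Gamma(a+p)\Gamma(a+b) / (\Gamma(a)\Gamma(a+b+p))}, so that
#' non-integer orders (needed for power-law hazard exponents) retain full
#' precision. Degenerate laws return \eqn{\langle\beta\rangle^p}.
#'
#' @inheritParams mean_log_beta
#' @param p Moment order(s), real and strictly positive; vectorized.
#' @return \eqn{\langle\beta^p\rangle}, in (0, 1).
#' @export
beta_power_moment <- function(law, p) {
  stopifnot(inherits(law, "partition_law"), is.numeric(p), all(p > 0))
  if (law$degenerate) return(law$mean_beta^p)
  a <- law$shape_a
  ab <- a + law$shape_b
  exp(lgamma(a + p) + lgamma(ab) - lgamma(a) - lgamma(ab + p))
}

#' Draw partition fractions
#'
#' Samples `n` independent partition fractions from the law. Degenerate laws
#' return `n` copies of the mean. If `seed` is given the R random number
#' generator is seeded first, making the draw reproducible.
#'
#' @inheritParams mean_log_beta
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` with values in (0, 1).
#' @export
sample_beta <- function(law, n, seed = NULL) {
  stopifnot(inherits(law, "partition_law"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (law$degenerate) return(rep(law$mean_beta, n))
  rbeta(n, law$shape_a, law$shape_b)
}
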