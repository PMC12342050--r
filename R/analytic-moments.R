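#' @keywords internal
#' @noRd
.skewness_from_moments <- function(m1, m2, m3) {
  v <- m2 - m1^2
  (m3 - 3 * m1 * m2 + 2 * m1^3) / v^1.5
}

#' Exact steady-state moments of the single-step adder
#'
#' Closed-form steady-state size moments when the division hazard is
#' proportional to size (\eqn{\alpha = 1}), the adder regime. The mean is
#' \deqn{\bar{\langle s\rangle} = -\frac{\mu}{k\,\langle\log\beta\rangle},}
#' higher uncentered moments follow the exact recursion
#' \deqn{\bar{\langle s^{p+1}\rangle} =
#'   \frac{p\,\mu\,\bar{\langle s^p\rangle}}{k\,(1-\langle\beta^p\rangle)},}
#' and the noise
#' \deqn{CV^2_s = -1 + \frac{\langle\log\beta\rangle}{\langle\beta\rangle-1}}
#' is independent of both \eqn{\mu} and \eqn{k}. For deterministic halving
#' (\eqn{\beta = 1/2}) this gives \eqn{CV^2_s = \log 4 - 1 \approx 0.39}.
#'
#' @param params A [single_step_params()] with `alpha = 1`.
#' @param law A [partition_law()].
#' @param max_order Highest uncentered moment order to compute (>= 2).
#' @return A [moment_summary()] with `exact = TRUE`; skewness is filled in
#'   when `max_order >= 3`.
#' @examples
#' adder_moments(single_step_params(1, 1, 1), partition_law(0.5, 0))
#' @export
adder_moments <- function(params, law, max_order = 3) {
  stopifnot(inherits(params, "single_step_params"),
            inherits(law, "partition_law"),
            max_order >= 2, max_order == round(max_order))
  if (params$alpha != 1)
    stop("adder_moments() requires alpha = 1; use powerlaw_closure() or ",
         "powerlaw_exact_rational() for other exponents", call. = FALSE)
  mu <- params$mu; k <- params$k
  Lb <- mean_log_beta(law)
  m <- numeric(max_order)
  m[1] <- -mu / (k * Lb)
  for (p in seq_len(max_order - 1))
    m[p + 1] <- p * mu * m[p] / (k * (1 - beta_power_moment(law, p)))
  names(m) <- paste0("m", seq_len(max_order))
  moment_summary(
    mean_size = m[[1]], second_moment = m[[2]],
    skewness = if (max_order >= 3) .skewness_from_moments(m[[1]], m[[2]], m[[3]]),
    moments = m, exact = TRUE)
}

#' @keywords internal
#' @noRd
.adder_moment_closed <- function(params, law, order) {
  # closed product form for <s^(p+1)>: -(mu/k)^(p+1) p! /
  #   (<log beta> * prod_{i=1..p} (1 - <beta^i>))
  p <- order - 1
  Lb <- mean_log_beta(law)
  if (p == 0) return(-params$mu / (params$k * Lb))
  -(params$mu / params$k)^(p + 1) * factorial(p) /
    (Lb * prod(1 - beta_power_moment(law, seq_len(p))))
}

#' Small-noise approximation of adder size noise
#'
#' For a symmetric split (\eqn{\langle\beta\rangle = 1/2}) and small
#' partitioning noise, the adder size noise expands as
#' \deqn{CV^2_s \approx \log 4 - 1 +
#'   \frac{CV^2_\beta}{1 - CV^2_\beta},}
#' a monotonically increasing function of \eqn{CV^2_\beta} with unit slope
#' at zero. The exact digamma expression (via [adder_moments()]) should be
#' preferred outside the small-noise regime.
#'
#' @param law A [partition_law()] with `mean_beta = 0.5`, or a plain numeric
#'   \eqn{CV^2_\beta}.
#' @return Approximate \eqn{CV^2_s}.
#' @export
adder_cv2_approx <- function(law) {
  if (inherits(law, "partition_law")) {
    if (law$mean_beta != 0.5)
      stop("adder_cv2_approx() assumes a symmetric split (mean_beta = 0.5)",
           call. = FALSE)
    x <- law$cv2_beta
  } else {
    stopifnot(is.numeric(law))
    x <- law
  }
  if (any(x >= 1))
    stop("approximation undefined at cv2_beta >= 1", call. = FALSE)
  log(4) - 1 + x / (1 - x)
}

#' Exact steady-state skewness of adder cell size
#'
#' Standardized third central moment of the stationary size distribution,
#' computed from the exact first three uncentered moments. It is invariant
#' under rescaling of \eqn{(\mu, k)} and stays close to 1.68 for
#' \eqn{0 \le CV^2_\beta < 0.1} with a symmetric split.
#'
#' @param law A [partition_law()].
#' @return Skewness \eqn{\gamma_s} (dimensionless).
#' @export
adder_skewness <- function(law) {
  adder_moments(single_step_params(1, 1, 1), law, max_order = 3)$skewness
}

#' Noise in newborn cell size
#'
#' Squared coefficient of variation of size at birth,
#' \deqn{CV^2_{s_b} = \frac{4 CV^2_\beta +
#'   CV^2_\Delta (1 + CV^2_\beta)}{3 - CV^2_\beta},}
#' where \eqn{CV^2_\Delta} is the noise of the added size per cycle: 1 for
#' the single-step adder (exponential added size), `1/M` for the equal-rate
#' M-stage model (Erlang added size). With perfect partitioning and
#' `cv2_added = 1` this is the newborn noise floor 1/3.
#'
#' @param law A [partition_law()] or a plain numeric \eqn{CV^2_\beta}.
#' @param cv2_added Noise of the added size \eqn{CV^2_\Delta} (default 1).
#' @return \eqn{CV^2_{s_b}}.
#' @export
newborn_cv2 <- function(law, cv2_added = 1) {
  x <- if (inherits(law, "partition_law")) law$cv2_beta else law
  stopifnot(is.numeric(x), is.numeric(cv2_added), all(cv2_added >= 0))
  if (any(x >= 3))
    stop("newborn noise formula undefined at cv2_beta >= 3", call. = FALSE)
  (4 * x + cv2_added * (1 + x)) / (3 - x)
}

#' Exact moments of the transformed size y = s^alpha
#'
#' For a general power-law hazard \eqn{k s^\alpha}, the variable
#' \eqn{y = s^\alpha} itself follows an adder-type SHS: it grows at rate
#' \eqn{\alpha\mu}, divides at hazard \eqn{k y}, and resets by the factor
#' \eqn{\beta^\alpha}. Its steady-state moments are therefore exact, with
#' \eqn{\bar{\langle y\rangle} = -\mu/(k\langle\log\beta\rangle)}
#' independent of \eqn{\alpha}, and
#' \deqn{\bar{\langle y^{p+1}\rangle} = \frac{p\,\alpha\mu\,
#'   \bar{\langle y^p\rangle}}{k\,(1 - \langle\beta^{\alpha p}\rangle)}.}
#'
#' @param params A [single_step_params()] with `alpha > 0`.
#' @param law A [partition_law()].
#' @param max_order Highest moment order of y to compute (>= 2).
#' @return A [moment_summary()] for \eqn{y = s^\alpha} (`exact = TRUE`).
#' @export
powerlaw_y_moments <- function(params, law, max_order = 3) {
  stopifnot(inherits(params, "single_step_params"),
            inherits(law, "partition_law"),
            params$alpha > 0,
            max_order >= 2, max_order == round(max_order))
  mu <- params$mu; k <- params$k; a <- params$alpha
  Lb <- mean_log_beta(law)
  m <- numeric(max_order)
  m[1] <- -mu / (k * Lb)
  for (p in seq_len(max_order - 1))
    m[p + 1] <- p * a * mu * m[p] / (k * (1 - beta_power_moment(law, a * p)))
  names(m) <- paste0("m", seq_len(max_order))
  moment_summary(
    mean_size = m[[1]], second_moment = m[[2]],
    skewness = if (max_order >= 3) .skewness_from_moments(m[[1]], m[[2]], m[[3]]),
    moments = m, exact = TRUE)
}

#' Exact size moments for rational sub-linear exponents alpha = 1/q
#'
#' When \eqn{\alpha = 1/q} for a positive integer q, size moments are exact:
#' \eqn{s = y^q} for \eqn{y = s^\alpha}, so
#' \eqn{\bar{\langle s\rangle} = \bar{\langle y^q\rangle}} and
#' \eqn{\bar{\langle s^2\rangle} = \bar{\langle y^{2q}\rangle}}, both
#' available from the exact y-moment recursion.
#'
#' @param params A [single_step_params()] whose `alpha` equals `1/q` for a
#'   positive integer q (to within 1e-9); other exponents are refused with a
#'   pointer to [powerlaw_closure()].
#' @param law A [partition_law()].
#' @return A [moment_summary()] with `exact = TRUE`.
#' @export
powerlaw_exact_rational <- function(params, law) {
  stopifnot(inherits(params, "single_step_params"), params$alpha > 0)
  q <- 1 / params$alpha
  if (abs(q - round(q)) > 1e-9)
    stop("alpha = ", format(params$alpha), " is not of the form 1/q for ",
         "integer q; use powerlaw_closure() for alpha >= 1 or ",
         "powerlaw_y_moments() for transformed moments", call. = FALSE)
  q <- as.integer(round(q))
  ym <- powerlaw_y_moments(params, law, max_order = 2L * q)$moments
  moment_summary(mean_size = ym[[q]], second_moment = ym[[2L * q]],
                 exact = TRUE)
}

#' Derivative-matching closure for power-law hazards (alpha >= 1)
#'
#' For sizer-like hazards (\eqn{\alpha > 1}) the size-moment system does not
#' close; the derivative-matching scheme approximates
#' \eqn{\bar{\langle s^\alpha\rangle}} and
#' \eqn{\bar{\langle s^{\alpha+1}\rangle}} by lognormal-consistent products
#' of the first two moments, yielding
#' \deqn{CV^2_s \approx -1 + \left(
#'   \frac{\langle\log\beta\rangle}{\langle\beta\rangle-1}
#'   \right)^{1/\alpha}, \qquad
#'   \bar{\langle s\rangle} \approx \left(\frac{\mu}{k}\right)^{1/\alpha}
#'   \left(\frac{\langle\beta\rangle-1}{\langle\log\beta\rangle}
#'   \right)^{\frac{1+\alpha}{2\alpha}}
#'   \frac{1}{(1-\langle\beta\rangle)^{1/\alpha}}.}
#' At \eqn{\alpha = 1} the closure coincides with the exact adder result;
#' for \eqn{\alpha > 1} it tends to underestimate the simulated noise. The
#' noise is strictly decreasing in \eqn{\alpha}.
#'
#' @param params A [single_step_params()] with `alpha >= 1`.
#' @param law A [partition_law()].
#' @return A [moment_summary()]; `exact` is `TRUE` only at `alpha = 1`.
#' @export
powerlaw_closure <- function(params, law) {
  stopifnot(inherits(params, "single_step_params"),
            inherits(law, "partition_law"))
  if (params$alpha < 1)
    stop("the derivative-matching closure applies for alpha >= 1; ",
         "use powerlaw_exact_rational() for alpha = 1/q", call. = FALSE)
  mu <- params$mu; k <- params$k; a <- params$alpha
  mb <- law$mean_beta
  Lb <- mean_log_beta(law)
  R <- Lb / (mb - 1)                 # > 1 for every valid law
  cv2 <- -1 + R^(1 / a)
  mean_s <- (mu / k)^(1 / a) * ((mb - 1) / Lb)^((1 + a) / (2 * a)) *
    (1 / (1 - mb))^(1 / a)
  moment_summary(mean_size = mean_s,
                 second_moment = (1 + cv2) * mean_s^2,
                 exact = a == 1)
}

#' Exact steady-state moments of the multi-step model
#'
#' Steady-state mean and second moment of size for the M-stage cell cycle
#' with arbitrary per-stage rates \eqn{k_i}. The mean is
#' \deqn{\bar{\langle s\rangle} = -\frac{\mu}{\langle\log\beta\rangle}
#'   \sum_{i=1}^{M} \frac{1}{k_i},}
#' and the second moment is assembled from the per-stage quantities
#' \eqn{\bar{\langle g_i s^2\rangle}} via the exact iterative scheme
#' \deqn{\bar{\langle g_1 s^2\rangle} =
#'     -\frac{(\mu/k_1)^2}{\langle\log\beta\rangle}
#'     + \frac{k_M}{k_1}\langle\beta\rangle \bar{\langle g_M s^2\rangle},
#'   \qquad
#'   \bar{\langle g_{i+1} s^2\rangle} =
#'     -\frac{(\mu/k_{i+1})^2}{\langle\log\beta\rangle}
#'     + \frac{k_i}{k_{i+1}} \bar{\langle g_i s^2\rangle},}
#' where \eqn{g_i} indicates occupancy of stage i and
#' \eqn{\bar{\langle g_M s^2\rangle} = \mu\bar{\langle s\rangle}/
#' (k_M(1-\langle\beta\rangle))}. With `M = 1` this reduces to
#' [adder_moments()]; as every rate but the first grows large it approaches
#' the single-step result in \eqn{k_1}.
#'
#' @param params A [multi_step_params()].
#' @param law A [partition_law()].
#' @return A [moment_summary()] with `exact = TRUE`.
#' @export
multistep_moments <- function(params, law) {
  stopifnot(inherits(params, "multi_step_params"),
            inherits(law, "partition_law"))
  mu <- params$mu; ks <- params$rates; M <- params$M
  mb <- law$mean_beta
  Lb <- mean_log_beta(law)
  mean_s <- -mu / Lb * sum(1 / ks)
  gM <- mu * mean_s / (ks[M] * (1 - mb))
  g <- numeric(M)
  g[1] <- -(mu / ks[1])^2 / Lb + ks[M] / ks[1] * mb * gM
  if (M > 1)
    for (i in seq_len(M - 1))
      g[i + 1] <- -(mu / ks[i + 1])^2 / Lb + ks[i] / ks[i + 1] * g[i]
  # the recursion must close the cycle consistently at stage M
  stopifnot(abs(g[M] - gM) <= 1e-8 * abs(gM))
  moment_summary(mean_size = mean_s, second_moment = sum(g), exact = TRUE)
}

#' Closed-form moments for equal stage rates
#'
#' For equal per-stage rates \eqn{k_i = kM} the multi-step model has the
#' exact closed forms
#' \deqn{\bar{\langle s\rangle} = -\frac{\mu}{k\langle\log\beta\rangle},
#'   \qquad
#'   CV^2_s = -1 + \frac{1 + M + \langle\beta\rangle(M-1)}{2M}\,
#'   \frac{\langle\log\beta\rangle}{\langle\beta\rangle - 1},}
#' with noise strictly decreasing in M: from \eqn{\log 4 - 1 \approx 0.39}
#' at M = 1 down to the [multistep_cv2_limit()] floor (about 0.04 for a
#' symmetric deterministic split).
#'
#' @param mu Growth rate, > 0.
#' @param k Overall rate constant (stage rates are `k * M`), > 0.
#' @param M Number of stages, >= 1.
#' @param law A [partition_law()].
#' @return A [moment_summary()] with `exact = TRUE`.
#' @export
multistep_equal_rates <- function(mu, k, M, law) {
  stopifnot(mu > 0, k > 0, M >= 1, M == round(M),
            inherits(law, "partition_law"))
  mb <- law$mean_beta
  Lb <- mean_log_beta(law)
  mean_s <- -mu / (k * Lb)
  cv2 <- -1 + (1 + M + mb * (M - 1)) / (2 * M) * Lb / (mb - 1)
  moment_summary(mean_size = mean_s,
                 second_moment = (1 + cv2) * mean_s^2,
                 exact = TRUE)
}

#' Fundamental noise floor of the multi-step model
#'
#' The limit of the equal-rate size noise as the number of stages grows
#' without bound:
#' \deqn{\lim_{M\to\infty} CV^2_s = -1 +
#'   \frac{1+\langle\beta\rangle}{2}\,
#'   \frac{\langle\log\beta\rangle}{\langle\beta\rangle-1}.}
#' For a symmetric deterministic split this is
#' \eqn{\tfrac{3}{2}\log 2 - 1 \approx 0.04}; for small partitioning noise
#' it behaves as \eqn{0.04 + \tfrac{3}{4} CV^2_\beta}, i.e. staging
#' attenuates the partitioning-noise contribution to 3/4 of its
#' single-step value.
#'
#' @param law A [partition_law()].
#' @return The limiting \eqn{CV^2_s}.
#' @export
multistep_cv2_limit <- function(law) {
  stopifnot(inherits(law, "partition_law"))
  mb <- law$mean_beta
  -1 + (1 + mb) / 2 * mean_log_beta(law) / (mb - 1)
}
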