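#' Observed cell-size sample
#'
#' Bundle an observed sample of cell sizes (snapshot or lineage
#' time-average sample) with optional per-cycle added sizes and birth
#' sizes, which improve identifiability of the multi-step model.
#'
#' @param sizes Positive numeric vector of observed cell sizes.
#' @param added_sizes Optional positive vector of per-cycle added sizes
#'   (division size minus birth size).
#' @param birth_sizes Optional positive vector of sizes at birth.
#' @return Object of class `"size_sample"`.
#' @export
size_sample <- function(sizes, added_sizes = NULL, birth_sizes = NULL) {
  stopifnot(is.numeric(sizes), length(sizes) >= 1)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all sizes must be finite and > 0", call. = FALSE)
  if (length(sizes) < 30)
    warning("fewer than 30 sizes; moment estimates will be unstable",
            call. = FALSE)
  for (v in list(added_sizes, birth_sizes))
    if (!is.null(v) && (any(!is.finite(v)) || any(v <= 0)))
      stop("auxiliary samples must be finite and > 0", call. = FALSE)
  structure(list(sizes = as.numeric(sizes),
                 added_sizes = added_sizes, birth_sizes = birth_sizes),
            class = "size_sample")
}

# sample CV^2 with the unbiased variance estimator
#' @keywords internal
#' @noRd
.sample_cv2 <- function(x) var(x) / mean(x)^2

# <log beta> as a plain function of (cv2_beta, mean_beta)
#' @keywords internal
#' @noRd
.mean_log_beta_num <- function(x, mb) {
  if (x == 0) return(log(mb))
  z <- (1 - mb * (1 + x)) / x
  digamma(z) - digamma(z / mb)
}

# invert R(x) = <log beta>/(<beta>-1) for x = cv2_beta; R is increasing
#' @keywords internal
#' @noRd
.solve_cv2_beta <- function(R_target, mb) {
  R <- function(x) .mean_log_beta_num(x, mb) / (mb - 1)
  if (R_target <= R(0) + 1e-12) return(0)
  hi <- (1 - mb) / mb * (1 - 1e-9)
  uniroot(function(x) R(x) - R_target, lower = 1e-12, upper = hi,
          tol = 1e-12)$root
}

#' @keywords internal
#' @noRd
.as_size_sample <- function(sample) {
  if (inherits(sample, "size_sample")) sample else size_sample(sample)
}

#' Fit the single-step adder by moment matching
#'
#' Method-of-moments inversion of the exact adder formulas: the sample
#' noise \eqn{CV^2_s} is matched to
#' \eqn{-1 + \langle\log\beta\rangle/(\langle\beta\rangle-1)} (with the
#' digamma expression for \eqn{\langle\log\beta\rangle}) by
#' one-dimensional root finding in \eqn{CV^2_\beta}, and the sample mean
#' then gives \eqn{\mu/k = -\bar{s}\,\langle\log\beta\rangle}. A symmetric
#' split (\eqn{\langle\beta\rangle = 1/2}) is assumed unless `mean_beta` is
#' supplied.
#'
#' The single-step adder has a noise floor of
#' \eqn{\log 4 - 1 \approx 0.39} at perfect partitioning; samples with
#' smaller \eqn{CV^2_s} cannot be matched with any \eqn{CV^2_\beta \ge 0}
#' and are returned with `feasible = FALSE` (a multi-step model is then
#' the natural candidate, see [fit_multistep()]).
#'
#' @param sample A [size_sample()] or plain positive numeric vector.
#' @param mean_beta Assumed mean partition fraction (default 0.5).
#' @return Object of class `"shs_fit"` with elements `mu_over_k`, `M_hat`
#'   (fixed at 1), `cv2_beta_hat`, `feasible`, `objective`, `diagnostics`.
#' @export
fit_adder <- function(sample, mean_beta = 0.5) {
  sample <- .as_size_sample(sample)
  s <- sample$sizes
  m <- mean(s)
  cv2_s <- .sample_cv2(s)
  floor_cv2 <- -1 + log(mean_beta) / (mean_beta - 1)
  diagnostics <- list(sample_mean = m, sample_cv2 = cv2_s,
                      cv2_floor = floor_cv2)
  if (cv2_s < floor_cv2 - 1e-12) {
    out <- list(mu_over_k = -m * log(mean_beta), M_hat = 1L,
                cv2_beta_hat = NA_real_, feasible = FALSE,
                objective = (cv2_s - floor_cv2)^2,
                diagnostics = diagnostics)
  } else {
    x_hat <- .solve_cv2_beta((cv2_s + 1), mean_beta)
    Lb <- .mean_log_beta_num(x_hat, mean_beta)
    out <- list(mu_over_k = -m * Lb, M_hat = 1L, cv2_beta_hat = x_hat,
                feasible = TRUE, objective = 0,
                diagnostics = diagnostics)
  }
  class(out) <- "shs_fit"
  out
}

#' Fit the multi-step model by moment matching
#'
#' Grid search over the integer stage count M: for each candidate M the
#' equal-rate noise formula
#' \eqn{CV^2_s = -1 + \frac{1+M+\langle\beta\rangle(M-1)}{2M}
#' \frac{\langle\log\beta\rangle}{\langle\beta\rangle-1}}
#' is solved for \eqn{CV^2_\beta} from the sample noise, and the sample
#' mean gives \eqn{\mu/k}. The preferred M minimizes the squared mismatch
#' of an auxiliary moment:
#' \itemize{
#'   \item with added sizes, the Erlang prediction
#'     \eqn{CV^2_\Delta = 1/M};
#'   \item with birth sizes, the newborn-noise prediction of
#'     [newborn_cv2()] with `cv2_added = 1/M`;
#'   \item with sizes alone the model is not identifiable: `(M,
#'     CV^2_\beta)` trade off along the noise formula, so the full
#'     feasible ridge is returned in `diagnostics$ridge` with `M_hat = NA`
#'     and a warning, unless `cv2_beta_fixed` pins the partitioning noise.
#' }
#'
#' @param sample A [size_sample()] (or plain numeric vector of sizes);
#'   supply `added_sizes`/`birth_sizes` through [size_sample()].
#' @param m_max Largest stage count considered (default 200).
#' @param mean_beta Assumed mean partition fraction (default 0.5).
#' @param cv2_beta_fixed Optional known \eqn{CV^2_\beta}; when given, M is
#'   chosen to best match the sample noise at that partitioning noise.
#' @return Object of class `"shs_fit"`; `diagnostics$ridge` holds the
#'   per-M solutions `(M, cv2_beta, mu_over_k, objective, feasible)`.
#' @export
fit_multistep <- function(sample, m_max = 200L, mean_beta = 0.5,
                          cv2_beta_fixed = NULL) {
  sample <- .as_size_sample(sample)
  stopifnot(m_max >= 1, m_max == round(m_max))
  s <- sample$sizes
  m <- mean(s)
  cv2_s <- .sample_cv2(s)
  Ms <- seq_len(m_max)
  coefM <- (1 + Ms + mean_beta * (Ms - 1)) / (2 * Ms)

  if (!is.null(cv2_beta_fixed)) {
    stopifnot(cv2_beta_fixed >= 0)
    Lb <- .mean_log_beta_num(cv2_beta_fixed, mean_beta)
    cv2_pred <- -1 + coefM * Lb / (mean_beta - 1)
    obj <- (cv2_pred - cv2_s)^2
    ridge <- data.frame(M = Ms, cv2_beta = cv2_beta_fixed,
                        mu_over_k = -m * Lb, objective = obj,
                        feasible = TRUE)
    best <- which.min(obj)
    out <- list(mu_over_k = -m * Lb, M_hat = Ms[best],
                cv2_beta_hat = cv2_beta_fixed, feasible = TRUE,
                objective = obj[best],
                diagnostics = list(sample_mean = m, sample_cv2 = cv2_s,
                                   auxiliary = "cv2_beta_fixed",
                                   ridge = ridge))
    class(out) <- "shs_fit"
    return(out)
  }

  R_target <- (cv2_s + 1) / coefM
  R0 <- log(mean_beta) / (mean_beta - 1)
  feasible <- R_target >= R0 - 1e-12
  x_hat <- rep(NA_real_, m_max)
  muk <- rep(NA_real_, m_max)
  for (i in which(feasible)) {
    x_hat[i] <- .solve_cv2_beta(R_target[i], mean_beta)
    muk[i] <- -m * .mean_log_beta_num(x_hat[i], mean_beta)
  }
  ridge <- data.frame(M = Ms, cv2_beta = x_hat, mu_over_k = muk,
                      objective = NA_real_, feasible = feasible)
  diagnostics <- list(sample_mean = m, sample_cv2 = cv2_s)

  aux <- NULL
  if (!is.null(sample$added_sizes)) {
    obs <- .sample_cv2(sample$added_sizes)
    ridge$objective <- (obs - 1 / Ms)^2
    aux <- "added_size_cv2"
    diagnostics$added_cv2 <- obs
  } else if (!is.null(sample$birth_sizes)) {
    obs <- .sample_cv2(sample$birth_sizes)
    pred <- ifelse(feasible, newborn_cv2(ifelse(is.na(x_hat), 0, x_hat),
                                         1 / Ms), NA_real_)
    ridge$objective <- (obs - pred)^2
    aux <- "newborn_cv2"
    diagnostics$newborn_cv2 <- obs
  }
  diagnostics$auxiliary <- aux
  diagnostics$ridge <- ridge

  if (is.null(aux)) {
    warning("sizes alone do not identify (M, cv2_beta): they trade off ",
            "along the equal-rate noise formula; returning the feasible ",
            "ridge in diagnostics$ridge", call. = FALSE)
    out <- list(mu_over_k = NA_real_, M_hat = NA_integer_,
                cv2_beta_hat = NA_real_, feasible = any(feasible),
                objective = NA_real_, diagnostics = diagnostics)
  } else {
    cand <- which(feasible)
    if (length(cand) == 0) {
      out <- list(mu_over_k = NA_real_, M_hat = NA_integer_,
                  cv2_beta_hat = NA_real_, feasible = FALSE,
                  objective = NA_real_, diagnostics = diagnostics)
    } else {
      best <- cand[which.min(ridge$objective[cand])]
      out <- list(mu_over_k = muk[best], M_hat = Ms[best],
                  cv2_beta_hat = x_hat[best], feasible = TRUE,
                  objective = ridge$objective[best],
                  diagnostics = diagnostics)
    }
  }
  class(out) <- "shs_fit"
  out
}

#' @export
print.shs_fit <- function(x, ...) {
  cat("SHS moment-matching fit\n")
  cat(sprintf("  M_hat        : %s\n", format(x$M_hat)))
  cat(sprintf("  cv2_beta_hat : %s\n", format(x$cv2_beta_hat)))
  cat(sprintf("  mu/k         : %s\n", format(x$mu_over_k)))
  cat(sprintf("  feasible     : %s\n", x$feasible))
  if (!is.null(x$diagnostics$auxiliary))
    cat(sprintf("  auxiliary    : %s\n", x$diagnostics$auxiliary))
  invisible(x)
}
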