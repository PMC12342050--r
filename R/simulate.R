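#' Simulation configuration
#'
#' Bundles a model, a partition law, and run settings for
#' [simulate_lineage()] / [ensemble_snapshot()].
#'
#' @param model A [single_step_params()] or [multi_step_params()].
#' @param partition A [partition_law()].
#' @param s0 Initial cell size, > 0.
#' @param n_cycles Number of division cycles to simulate.
#' @param burn_in_cycles Cycles discarded before stationary statistics
#'   (default 100).
#' @param seed Integer seed; every draw in the run derives from it.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(model, partition, s0 = 1, n_cycles = 1000L,
                       burn_in_cycles = 100L, seed = 1L) {
  stopifnot(inherits(model, "single_step_params") ||
              inherits(model, "multi_step_params"),
            inherits(partition, "partition_law"),
            is.numeric(s0), length(s0) == 1L, s0 > 0,
            n_cycles >= 1, n_cycles == round(n_cycles),
            burn_in_cycles >= 0, burn_in_cycles == round(burn_in_cycles),
            n_cycles > burn_in_cycles,
            length(seed) == 1L, seed == round(seed))
  structure(list(model = model, partition = partition, s0 = s0,
                 n_cycles = as.integer(n_cycles),
                 burn_in_cycles = as.integer(burn_in_cycles),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Exact waiting time to the next size-triggered event
#'
#' Along an exponential size ramp \eqn{s(\tau) = s_0 e^{\mu\tau}} with event
#' hazard \eqn{k s^\alpha}, the integrated hazard inverts in closed form:
#' given a uniform draw \eqn{u}, the waiting time solving
#' \eqn{\int_0^{\Delta t} k (s_0 e^{\mu\tau})^\alpha d\tau = -\log u} is
#' \deqn{\Delta t = \frac{1}{\alpha\mu}\log\!\left(1 +
#'   \frac{\alpha\mu(-\log u)}{k s_0^\alpha}\right)}
#' for \eqn{\alpha > 0}, and \eqn{-\log(u)/k} for \eqn{\alpha = 0}. The
#' sampling is exact -- no thinning and no time discretization.
#'
#' @param s0 Size at the start of the interval, > 0 (vectorized).
#' @param mu Growth rate.
#' @param k Hazard rate constant.
#' @param alpha Hazard exponent, >= 0.
#' @param u Uniform(0,1) draw (vectorized).
#' @return Waiting time(s) until the event fires.
#' @export
next_event_time <- function(s0, mu, k, alpha, u) {
  stopifnot(all(s0 > 0), mu > 0, k > 0, alpha >= 0, all(u > 0), all(u < 1))
  E <- -log(u)
  if (alpha == 0) return(E / k)
  log1p(alpha * mu * E / (k * s0^alpha)) / (alpha * mu)
}

#' @keywords internal
#' @noRd
.simulate_single <- function(cfg) {
  m <- cfg$model; mu <- m$mu; k <- m$k; alpha <- m$alpha
  n <- cfg$n_cycles
  E <- rexp(n)
  betas <- sample_beta(cfg$partition, n)
  sb <- numeric(n); sdiv <- numeric(n); tau <- numeric(n)
  s <- cfg$s0
  if (alpha > 0) {
    inv_a <- 1 / alpha
    c0 <- alpha * mu / k
    for (i in seq_len(n)) {
      sd_i <- (s^alpha + c0 * E[i])^inv_a
      sb[i] <- s; sdiv[i] <- sd_i
      tau[i] <- log(sd_i / s) / mu
      s <- betas[i] * sd_i
    }
  } else {
    for (i in seq_len(n)) {
      tau[i] <- E[i] / k
      sd_i <- s * exp(mu * tau[i])
      sb[i] <- s; sdiv[i] <- sd_i
      s <- betas[i] * sd_i
    }
  }
  events <- data.frame(time = cumsum(tau),
                       type = "division",
                       size_pre = sdiv,
                       size_post = betas * sdiv,
                       stage = 1L)
  cycles <- data.frame(birth_size = sb, division_size = sdiv,
                       added_size = sdiv - sb, interdivision_time = tau,
                       beta = betas)
  list(events = events, cycles = cycles)
}

#' @keywords internal
#' @noRd
.simulate_multi <- function(cfg) {
  m <- cfg$model; mu <- m$mu; ks <- m$rates; M <- m$M
  n <- cfg$n_cycles
  E <- matrix(rexp(n * M), nrow = n)
  betas <- sample_beta(cfg$partition, n)
  ne <- n * M
  ev_t <- numeric(ne); ev_pre <- numeric(ne); ev_post <- numeric(ne)
  ev_stage <- integer(ne)
  sb <- numeric(n); sdiv <- numeric(n); tau <- numeric(n)
  s <- cfg$s0; t <- 0; idx <- 0L
  for (i in seq_len(n)) {
    sb[i] <- s; t0 <- t
    for (j in seq_len(M)) {
      dt <- log1p(mu * E[i, j] / (ks[j] * s)) / mu
      s_pre <- s * exp(mu * dt)
      t <- t + dt
      idx <- idx + 1L
      s_post <- if (j < M) s_pre else betas[i] * s_pre
      ev_t[idx] <- t; ev_pre[idx] <- s_pre; ev_post[idx] <- s_post
      ev_stage[idx] <- j
      s <- s_post
    }
    sdiv[i] <- ev_pre[idx]
    tau[i] <- t - t0
  }
  events <- data.frame(time = ev_t,
                       type = ifelse(ev_stage < M, "stage_transition",
                                     "division"),
                       size_pre = ev_pre,
                       size_post = ev_post,
                       stage = ev_stage)
  cycles <- data.frame(birth_size = sb, division_size = sdiv,
                       added_size = sdiv - sb, interdivision_time = tau,
                       beta = betas)
  list(events = events, cycles = cycles)
}

#' Simulate a single-cell lineage exactly
#'
#' Event-driven simulation of the SHS lineage: deterministic exponential
#' growth between events, division (and, for multi-step models, stage
#' transition) times drawn by closed-form inversion of the integrated
#' size-dependent hazard ([next_event_time()]), and a fresh partition
#' fraction drawn at each division. One daughter is followed per division.
#' All randomness derives from `config$seed`, so runs are reproducible.
#'
#' For multi-step models each cycle comprises the M-1 stage transitions
#' (stage i at hazard \eqn{k_i s}) followed by division at hazard
#' \eqn{k_M s}; size is continuous at stage transitions.
#'
#' @param config A [sim_config()].
#' @return Object of class `"shs_lineage"`: a list with
#'   \describe{
#'     \item{events}{data frame of events: `time`, `type`
#'       (`"division"`/`"stage_transition"`), `size_pre`, `size_post`,
#'       `stage` (stage of the segment ending at the event).}
#'     \item{cycles}{data frame of per-cycle records: `birth_size`,
#'       `division_size`, `added_size`, `interdivision_time`, `beta`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cfg <- sim_config(single_step_params(1, 1, 1), partition_law(0.5, 0),
#'                   n_cycles = 500, seed = 7)
#' sim <- simulate_lineage(cfg)
#' mean(sim$cycles$added_size)   # ~ mu/k
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  out <- if (inherits(config$model, "single_step_params"))
    .simulate_single(config) else .simulate_multi(config)
  out$config <- config
  class(out) <- "shs_lineage"
  out
}

#' @export
print.shs_lineage <- function(x, ...) {
  cat(sprintf("SHS lineage: %d events, %d division cycles, total time %.4g\n",
              nrow(x$events), nrow(x$cycles),
              x$events$time[nrow(x$events)]))
  invisible(x)
}

#' Ergodic time-average moments along a lineage
#'
#' Estimates stationary uncentered size moments by the time-weighted
#' integral \eqn{\frac{1}{T}\int s(t)^p\,dt}, using the exact per-segment
#' primitive \eqn{(s_{\mathrm{end}}^p - s_{\mathrm{start}}^p)/(p\mu)} of
#' exponential growth -- no grid discretization. Standard errors for the
#' mean, noise (\eqn{CV^2}) and skewness come from batch means over
#' `n_batches` contiguous time blocks, which absorbs the autocorrelation of
#' the lineage.
#'
#' @param sim An `"shs_lineage"` from [simulate_lineage()], or its `events`
#'   data frame (in which case `mu` and `s0` must be supplied).
#' @param orders Integer moment orders to estimate (default 1:3).
#' @param burn_in_time Time discarded from the start; defaults to the time
#'   of the configured burn-in cycle.
#' @param mu,s0 Growth rate and initial size; taken from the simulation
#'   config when `sim` is an `"shs_lineage"`.
#' @param n_batches Number of batches for standard errors (default 50).
#' @return A list of class `"shs_moment_estimate"`: `moments` (named
#'   vector), `mean_size`, `cv2`, `skewness` (if order 3 requested), their
#'   batch-means standard errors in `se`, and bookkeeping fields.
#' @export
time_average_moments <- function(sim, orders = 1:3, burn_in_time = NULL,
                                 mu = NULL, s0 = NULL, n_batches = 50L) {
  if (inherits(sim, "shs_lineage")) {
    events <- sim$events
    mu <- sim$config$model$mu
    s0 <- sim$config$s0
    if (is.null(burn_in_time)) {
      bc <- sim$config$burn_in_cycles
      div_times <- events$time[events$type == "division"]
      burn_in_time <- if (bc > 0) div_times[bc] else 0
    }
  } else {
    events <- sim
    stopifnot(!is.null(mu), !is.null(s0))
    if (is.null(burn_in_time)) burn_in_time <- 0
  }
  stopifnot(is.data.frame(events), nrow(events) >= 1,
            all(orders >= 1), all(orders == round(orders)))

  start_size <- c(s0, head(events$size_post, -1L))
  start_time <- c(0, head(events$time, -1L))
  keep <- start_time >= burn_in_time
  if (!any(keep)) stop("no trajectory left after burn-in", call. = FALSE)
  a <- start_size[keep]; b <- events$size_pre[keep]
  dt <- events$time[keep] - start_time[keep]
  total_time <- sum(dt)

  seg_int <- function(p) (b^p - a^p) / (p * mu)   # exact segment integral
  moments <- vapply(orders, function(p) sum(seg_int(p)) / total_time,
                    numeric(1))
  names(moments) <- paste0("m", orders)

  nb <- min(n_batches, length(dt))
  batch <- if (nb >= 2) cut(cumsum(dt), breaks = nb, labels = FALSE)
           else rep(1L, length(dt))
  bstat <- function(f) {
    vals <- vapply(sort(unique(batch)), function(g) {
      i <- batch == g
      f(a[i], b[i], sum(dt[i]))
    }, numeric(1))
    c(mean(vals), sd(vals) / sqrt(length(vals)))
  }
  bm <- function(av, bv, tt, p) sum((bv^p - av^p) / (p * mu)) / tt
  mom_se <- vapply(orders, function(p)
    bstat(function(av, bv, tt) bm(av, bv, tt, p))[2], numeric(1))
  names(mom_se) <- names(moments)
  has12 <- all(c(1, 2) %in% orders)
  mean_b <- if (1 %in% orders)
    bstat(function(av, bv, tt) bm(av, bv, tt, 1)) else c(NA, NA)
  cv2_b <- if (has12) bstat(function(av, bv, tt) {
    m1 <- bm(av, bv, tt, 1); m2 <- bm(av, bv, tt, 2)
    m2 / m1^2 - 1
  }) else c(NA, NA)
  out <- list(moments = moments,
              mean_size = if (1 %in% orders) moments[["m1"]] else NA_real_,
              cv2 = if (has12)
                moments[["m2"]] / moments[["m1"]]^2 - 1 else NULL,
              skewness = NULL,
              se = list(mean_size = mean_b[2], cv2 = cv2_b[2],
                        moments = mom_se),
              n_batches = nb, total_time = total_time,
              burn_in_time = burn_in_time)
  if (all(c(1, 2, 3) %in% orders)) {
    out$skewness <- .skewness_from_moments(moments[["m1"]], moments[["m2"]],
                                           moments[["m3"]])
    sk_b <- bstat(function(av, bv, tt)
      .skewness_from_moments(bm(av, bv, tt, 1), bm(av, bv, tt, 2),
                             bm(av, bv, tt, 3)))
    out$se$skewness <- sk_b[2]
  }
  class(out) <- "shs_moment_estimate"
  out
}

#' @export
print.shs_moment_estimate <- function(x, ...) {
  cat(sprintf("Time-average moment estimate over T = %.4g (%d batches)\n",
              x$total_time, x$n_batches))
  cat(sprintf("  mean: %.5g (se %.2g)\n", x$mean_size, x$se$mean_size))
  if (!is.null(x$cv2))
    cat(sprintf("  CV^2: %.5g (se %.2g)\n", x$cv2, x$se$cv2))
  if (!is.null(x$skewness))
    cat(sprintf("  skew: %.5g (se %.2g)\n", x$skewness, x$se$skewness))
  invisible(x)
}

#' @keywords internal
#' @noRd
.simulate_until <- function(model, law, s0, t_end) {
  mu <- model$mu
  s <- s0; t <- 0
  if (inherits(model, "single_step_params")) {
    k <- model$k; alpha <- model$alpha
    repeat {
      dt <- next_event_time(s, mu, k, alpha, runif(1))
      if (t + dt > t_end) return(s * exp(mu * (t_end - t)))
      s <- s * exp(mu * dt)
      t <- t + dt
      s <- sample_beta(law, 1) * s
    }
  } else {
    ks <- model$rates; M <- model$M
    j <- 1L
    repeat {
      dt <- next_event_time(s, mu, ks[j], 1, runif(1))
      if (t + dt > t_end) return(s * exp(mu * (t_end - t)))
      s <- s * exp(mu * dt)
      t <- t + dt
      if (j == M) {
        s <- sample_beta(law, 1) * s
        j <- 1L
      } else j <- j + 1L
    }
  }
}

#' Ensemble snapshot of cell sizes
#'
#' Runs `n_lineages` independent lineage simulations and returns the exact
#' size \eqn{s(t)} of each at the snapshot time, mirroring the
#' error-bar protocol of ensemble figure comparisons. Each lineage gets its
#' own RNG seed derived deterministically from `config$seed`, so results
#' are reproducible and independent of evaluation order.
#'
#' @param config A [sim_config()] (its `n_cycles`/`burn_in_cycles` are not
#'   used here; `t_snapshot` controls the run length).
#' @param n_lineages Number of independent lineages.
#' @param t_snapshot Snapshot time; should exceed the relaxation time of
#'   the size process for stationary statistics (caller's responsibility).
#' @return Numeric vector of `n_lineages` sizes at `t_snapshot`.
#' @export
ensemble_snapshot <- function(config, n_lineages, t_snapshot) {
  stopifnot(inherits(config, "sim_config"), n_lineages >= 1,
            t_snapshot >= 0)
  if (t_snapshot == 0) return(rep(config$s0, n_lineages))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_lineages)
  vapply(seq_len(n_lineages), function(i) {
    set.seed(seeds[i])
    .simulate_until(config$model, config$partition, config$s0, t_snapshot)
  }, numeric(1))
}

#' Sample stationary sizes along a lineage
#'
#' Draws cell sizes at `n` uniformly random times in the post-burn-in part
#' of a simulated lineage, interpolating exactly along the exponential
#' growth segments. The resulting sample follows the lineage time-average
#' (stationary) size distribution and is the natural input to the fitting
#' routines.
#'
#' @param sim An `"shs_lineage"` from [simulate_lineage()].
#' @param n Number of sizes to draw.
#' @param seed Optional integer seed for the sampling times.
#' @param burn_in_time Time discarded from the start; same default as
#'   [time_average_moments()].
#' @return Numeric vector of `n` sizes.
#' @export
lineage_size_sample <- function(sim, n, seed = NULL, burn_in_time = NULL) {
  stopifnot(inherits(sim, "shs_lineage"), n >= 1)
  events <- sim$events
  mu <- sim$config$model$mu
  if (is.null(burn_in_time)) {
    bc <- sim$config$burn_in_cycles
    div_times <- events$time[events$type == "division"]
    burn_in_time <- if (bc > 0) div_times[bc] else 0
  }
  if (!is.null(seed)) set.seed(seed)
  t_end <- events$time[nrow(events)]
  ts <- runif(n, burn_in_time, t_end)
  start_time <- c(0, head(events$time, -1L))
  start_size <- c(sim$config$s0, head(events$size_post, -1L))
  idx <- findInterval(ts, start_time)       # segment containing each time
  start_size[idx] * exp(mu * (ts - start_time[idx]))
}
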