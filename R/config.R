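#' Load and validate a run configuration
#'
#' Reads a JSON configuration describing a model, partition law and
#' simulation settings, validates it exhaustively (all schema violations
#' are reported at once, not just the first), and fills in defaults.
#' Recognised blocks:
#' \preformatted{
#' {
#'   "model":      {"mu": 1, "k": 1, "alpha": 1}   # single-step, or
#'                 {"mu": 1, "rates": [5, 5, ...]} # multi-step
#'   "partition":  {"mean": 0.5, "cv2": 0},
#'   "simulation": {"s0": 1, "n_cycles": 1000, "burn_in_cycles": 100},
#'   "seed": 0,
#'   "out_dir": ".",
#'   "log_level": "info"
#' }
#' }
#' `alpha` and `rates` are mutually exclusive. Unknown keys anywhere are
#' rejected. Defaults: `s0 = 1`, `burn_in_cycles = 100`, `seed = 0`,
#' `partition = {mean: 0.5, cv2: 0}`.
#'
#' @param path Path to a JSON file.
#' @return Object of class `"run_config"` (a validated, default-filled
#'   nested list).
#' @seealso [dump_config()] for the inverse; load -> dump -> load is the
#'   identity.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw)
}

#' Validate a configuration list
#'
#' @param raw A nested list as produced by parsing the JSON schema of
#'   [load_config()].
#' @return Object of class `"run_config"`.
#' @export
validate_config <- function(raw) {
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  known_top <- c("model", "partition", "simulation", "seed", "out_dir",
                 "log_level")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    note(paste0("unknown top-level key(s): ",
                paste(unknown, collapse = ", ")))

  if (is.null(raw$model) || !is.list(raw$model)) {
    note("missing required block: model")
    model <- NULL
  } else {
    model <- raw$model
    unknown <- setdiff(names(model), c("mu", "k", "alpha", "rates", "M"))
    if (length(unknown))
      note(paste0("unknown model key(s): ", paste(unknown, collapse = ", ")))
    if (is.null(model$mu) || !is.numeric(model$mu) || model$mu <= 0)
      note("model.mu must be a positive number")
    has_alpha <- !is.null(model$alpha) || !is.null(model$k)
    has_rates <- !is.null(model$rates)
    if (has_alpha && has_rates)
      note("model.alpha/model.k and model.rates are mutually exclusive")
    if (!has_alpha && !has_rates)
      note("model needs either (k, alpha) or rates")
    if (has_alpha && !has_rates) {
      if (is.null(model$k) || !is.numeric(model$k) || model$k <= 0)
        note("model.k must be a positive number")
      if (is.null(model$alpha)) model$alpha <- 1
      if (!is.numeric(model$alpha) || model$alpha < 0)
        note("model.alpha must be a number >= 0")
    }
    if (has_rates &&
        (!is.numeric(model$rates) || any(model$rates <= 0)))
      note("model.rates must be a vector of positive numbers")
  }

  partition <- raw$partition
  if (is.null(partition)) partition <- list(mean = 0.5, cv2 = 0)
  unknown <- setdiff(names(partition), c("mean", "cv2"))
  if (length(unknown))
    note(paste0("unknown partition key(s): ",
                paste(unknown, collapse = ", ")))
  if (is.null(partition$mean)) partition$mean <- 0.5
  if (is.null(partition$cv2)) partition$cv2 <- 0
  if (!is.numeric(partition$mean) || partition$mean <= 0 ||
      partition$mean >= 1)
    note("partition.mean must lie strictly inside (0, 1)")
  if (!is.numeric(partition$cv2) || partition$cv2 < 0) {
    note("partition.cv2 must be a number >= 0")
  } else if (is.numeric(partition$mean) && partition$mean > 0 &&
             partition$mean < 1 &&
             partition$cv2 >= (1 - partition$mean) / partition$mean) {
    note("partition.cv2 exceeds the beta feasibility bound (1-mean)/mean")
  }

  simulation <- raw$simulation
  if (is.null(simulation)) simulation <- list()
  unknown <- setdiff(names(simulation),
                     c("s0", "n_cycles", "burn_in_cycles"))
  if (length(unknown))
    note(paste0("unknown simulation key(s): ",
                paste(unknown, collapse = ", ")))
  if (is.null(simulation$s0)) simulation$s0 <- 1
  if (is.null(simulation$n_cycles)) simulation$n_cycles <- 1000
  if (is.null(simulation$burn_in_cycles)) simulation$burn_in_cycles <- 100
  if (!is.numeric(simulation$s0) || simulation$s0 <= 0)
    note("simulation.s0 must be a positive number")
  if (!is.numeric(simulation$n_cycles) || simulation$n_cycles < 1)
    note("simulation.n_cycles must be a positive integer")
  if (!is.numeric(simulation$burn_in_cycles) ||
      simulation$burn_in_cycles < 0)
    note("simulation.burn_in_cycles must be a non-negative integer")
  if (is.numeric(simulation$n_cycles) &&
      is.numeric(simulation$burn_in_cycles) &&
      simulation$n_cycles <= simulation$burn_in_cycles)
    note("simulation.n_cycles must exceed simulation.burn_in_cycles")

  seed <- if (is.null(raw$seed)) 0L else raw$seed
  if (!is.numeric(seed) || seed != round(seed))
    note("seed must be an integer")
  out_dir <- if (is.null(raw$out_dir)) "." else raw$out_dir
  log_level <- if (is.null(raw$log_level)) "info" else raw$log_level
  if (!is.character(log_level) ||
      !log_level %in% c("debug", "info", "warn", "error"))
    note("log_level must be one of debug/info/warn/error")

  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)

  # canonical numeric storage so load -> dump -> load is the identity
  for (f in c("mu", "k", "alpha", "rates"))
    if (!is.null(model[[f]])) model[[f]] <- as.numeric(model[[f]])
  partition$mean <- as.numeric(partition$mean)
  partition$cv2 <- as.numeric(partition$cv2)
  for (f in c("s0", "n_cycles", "burn_in_cycles"))
    simulation[[f]] <- as.numeric(simulation[[f]])

  cfg <- list(model = model, partition = partition,
              simulation = simulation, seed = as.integer(seed),
              out_dir = out_dir, log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration back to JSON
#'
#' @param config A `"run_config"` from [load_config()]/[validate_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Build model objects from a run configuration
#'
#' @param config A `"run_config"`.
#' @return A [sim_config()] ready for [simulate_lineage()].
#' @export
config_to_sim <- function(config) {
  stopifnot(inherits(config, "run_config"))
  model <- if (!is.null(config$model$rates))
    multi_step_params(config$model$mu, config$model$rates)
  else
    single_step_params(config$model$mu, config$model$k, config$model$alpha)
  sim_config(model,
             partition_law(config$partition$mean, config$partition$cv2),
             s0 = config$simulation$s0,
             n_cycles = config$simulation$n_cycles,
             burn_in_cycles = config$simulation$burn_in_cycles,
             seed = config$seed)
}

#' Read a one-column sizes CSV
#'
#' @param path CSV with a header row and one numeric column of sizes.
#' @return Numeric vector.
#' @export
read_sizes <- function(path) {
  df <- read.csv(path)
  as.numeric(df[[1]])
}

#' Generate the canonical synthetic fixtures
#'
#' Writes seeded synthetic datasets used by the documentation and the test
#' suite: per-cycle records for the deterministic-split adder, a
#' noisy-partition adder, an equal-rate five-stage model, and an ensemble
#' snapshot for a quadratic (sizer-like) hazard -- each as an RFC-4180 CSV
#' with a header row -- plus `manifest.json` recording the generating
#' parameters, seed and package version. Fixed seed gives byte-identical
#' output across runs.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed; per-fixture seeds derive from it.
#' @param n_cycles Cycles per lineage fixture.
#' @param n_snapshot Lineages in the snapshot fixture.
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixtures <- function(dir, seed = 1L, n_cycles = 4000L,
                          n_snapshot = 500L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 4L)
  paths <- list()
  specs <- list(
    adder_cycles = list(model = single_step_params(1, 1, 1),
                        partition = list(mean = 0.5, cv2 = 0)),
    adder_noisy_cycles = list(model = single_step_params(1, 1, 1),
                              partition = list(mean = 0.5, cv2 = 0.05)),
    multistep_m5_cycles = list(model = equal_rate_params(1, 1, 5),
                               partition = list(mean = 0.5, cv2 = 0.02)))
  manifest <- list(seed = seed,
                   package_version = as.character(packageVersion("cellsizer")),
                   fixtures = list())
  i <- 0L
  for (nm in names(specs)) {
    i <- i + 1L
    sp <- specs[[nm]]
    law <- partition_law(sp$partition$mean, sp$partition$cv2)
    cfg <- sim_config(sp$model, law, n_cycles = n_cycles,
                      burn_in_cycles = 100L, seed = sub[i])
    sim <- simulate_lineage(cfg)
    path <- file.path(dir, paste0(nm, ".csv"))
    write.csv(sim$cycles, path, row.names = FALSE)
    paths[[nm]] <- path
    manifest$fixtures[[nm]] <- list(
      file = basename(path), seed = sub[i], n_cycles = n_cycles,
      model = unclass(sp$model), partition = sp$partition,
      columns = c("birth_size", "division_size", "added_size",
                  "interdivision_time", "beta"))
  }
  snap_model <- single_step_params(1, 1, 2)
  snap_cfg <- sim_config(snap_model, partition_law(0.5, 0),
                         n_cycles = 10L, burn_in_cycles = 0L,
                         seed = sub[4L])
  sizes <- ensemble_snapshot(snap_cfg, n_snapshot, t_snapshot = 10)
  path <- file.path(dir, "alpha2_snapshot.csv")
  write.csv(data.frame(size = sizes), path, row.names = FALSE)
  paths$alpha2_snapshot <- path
  manifest$fixtures$alpha2_snapshot <- list(
    file = basename(path), seed = sub[4L], n_lineages = n_snapshot,
    t_snapshot = 10, model = unclass(snap_model),
    partition = list(mean = 0.5, cv2 = 0), columns = "size")
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$manifest <- mpath
  invisible(paths)
}
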