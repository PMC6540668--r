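#' Simulation configuration for synthetic flight-mill cohorts
#'
#' Generative parameters for [simulate_cohort()]. The defaults are the
#' calibrated study conditions (see [default_calibration()]): two treatments
#' of 111 bees balanced over three colonies; intertegular spans (ITS) drawn
#' from a truncated normal; logit-linear feeding and flight propensities in
#' ITS (the control flight-propensity curve passes through probabilities
#' 0.49 at 4 mm and 0.92 at 6 mm); lognormal feeding durations; per-circuit
#' flight velocities built from a per-bee baseline, an exponentially decaying
#' hyperactivity boost in the exposed group, and independent multiplicative
#' noise; and a two-phase memoryless per-circuit termination hazard (elevated
#' over the first `early_phase_circuits`, lower thereafter) that is much
#' higher under exposure. Sessions also end at the stoppage budget or the
#' session cap, whichever comes first.
#'
#' @param n_per_treatment Bees per treatment arm.
#' @param n_colonies Number of source colonies (bees are balanced across
#'   them within treatment).
#' @param its_mean,its_sd,its_min,its_max Truncated-normal ITS distribution
#'   (mm).
#' @param feed_intercept,feed_slope Logit-linear feeding propensity in ITS.
#' @param feed_meanlog_control,feed_meanlog_pesticide,feed_sdlog Lognormal
#'   feeding-duration parameters (s) per treatment.
#' @param fly_intercept,fly_slope Logit-linear flight propensity in ITS
#'   (control).
#' @param fly_treatment_offset Additive logit offset for the exposed group's
#'   flight propensity.
#' @param baseline_velocity_mps Mean per-bee baseline flight velocity (m/s).
#' @param bee_velocity_sd Between-bee SD of the baseline velocity (m/s).
#' @param velocity_noise_sd SD of the multiplicative per-circuit velocity
#'   noise.
#' @param hyperactivity_multiplier Initial fractional velocity boost in the
#'   exposed group (decays over circuits; 0 for control).
#' @param hyperactivity_decay_circuits e-folding scale (circuits) of the
#'   boost.
#' @param early_phase_circuits Length of the elevated-hazard phase.
#' @param hazard_early_control,hazard_late_control Per-circuit termination
#'   hazards for control bees in the early/late phase.
#' @param hazard_early_pesticide,hazard_late_pesticide The same for exposed
#'   bees.
#' @param its_hazard_slope_control,its_hazard_slope_pesticide Per-mm log
#'   reduction of the hazard with ITS (size-dependent endurance; the
#'   calibration puts it in the control arm only).
#' @param stoppage_rate Per-circuit probability of a flight stoppage.
#' @param stoppage_excess_mean_s Mean of the exponential excess over the
#'   20 s rest added to a stoppage circuit's interval.
#' @param tag_rating_probs Probabilities of tag ratings 1 and 2 among tested
#'   bees (rating 3 bees are rejected before testing and never appear).
#' @param technical_fail_prob Probability a session is lost to a technical
#'   failure.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_treatment = 111,
                       n_colonies = 3,
                       its_mean = 4.9, its_sd = 0.35,
                       its_min = 3.5, its_max = 6.5,
                       feed_intercept = -2.06, feed_slope = 1.0,
                       feed_meanlog_control = log(138) - 0.6^2 / 2,
                       feed_meanlog_pesticide = log(127) - 0.6^2 / 2,
                       feed_sdlog = 0.6,
                       fly_intercept = -5.00465, fly_slope = 1.24116,
                       fly_treatment_offset = 0.25,
                       baseline_velocity_mps = 0.63,
                       bee_velocity_sd = 0.08,
                       velocity_noise_sd = 0.12,
                       hyperactivity_multiplier = 0.42,
                       hyperactivity_decay_circuits = 900,
                       early_phase_circuits = 118,
                       hazard_early_control = 2.2e-3,
                       hazard_late_control = 1.5e-4,
                       hazard_early_pesticide = 4.7e-3,
                       hazard_late_pesticide = 1.45e-3,
                       its_hazard_slope_control = 0.8,
                       its_hazard_slope_pesticide = 0,
                       stoppage_rate = 5e-4,
                       stoppage_excess_mean_s = 10,
                       tag_rating_probs = c(0.795, 0.205),
                       technical_fail_prob = 4 / 180) {
  cfg <- as.list(environment())
  probs <- c(cfg$technical_fail_prob, cfg$tag_rating_probs, cfg$stoppage_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config: probabilities must be in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$tag_rating_probs) - 1) > 1e-8) {
    stop("sim_config: tag_rating_probs must sum to 1", call. = FALSE)
  }
  hz <- c(cfg$hazard_early_control, cfg$hazard_late_control,
          cfg$hazard_early_pesticide, cfg$hazard_late_pesticide)
  if (any(hz < 0)) stop("sim_config: hazards must be >= 0", call. = FALSE)
  if (cfg$n_per_treatment < 1 || cfg$n_colonies < 1) {
    stop("sim_config: need at least one bee and one colony", call. = FALSE)
  }
  if (cfg$its_min >= cfg$its_max || cfg$its_sd <= 0) {
    stop("sim_config: invalid ITS distribution", call. = FALSE)
  }
  if (cfg$baseline_velocity_mps <= 0 || cfg$velocity_noise_sd < 0 ||
      cfg$bee_velocity_sd < 0 || cfg$hyperactivity_multiplier < 0 ||
      cfg$hyperactivity_decay_circuits <= 0) {
    stop("sim_config: invalid velocity parameters", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' The calibrated default simulation configuration
#'
#' Returns the `sim_config` whose large-sample pipeline summaries match the
#' assay's reported anchors: a control flight-initiation probability near
#' 0.77 at 5 mm ITS, control/exposed mean total distances near 1834 m and
#' 659 m on the trimmed analysis set (an exposed-to-control ratio near
#' 0.36), mean velocities near 0.63 and 0.84 m/s, and long-flight (> 2000 s)
#' proportions near 0.81 and 0.04.
#'
#' @return A `sim_config`.
#' @export
default_calibration <- function() sim_config()

#' A no-treatment-effect simulation configuration
#'
#' Copies every treatment-dependent parameter of `base` from its exposed arm
#' to the control arm and removes the hyperactivity boost and propensity
#' offsets, so the two arms are exchangeable. Used for type-I-error checks
#' of downstream treatment effects.
#'
#' @param base A `sim_config` to neutralise.
#' @return A `sim_config` with no treatment differences.
#' @export
null_config <- function(base = default_calibration()) {
  base$hazard_early_control <- base$hazard_early_pesticide
  base$hazard_late_control <- base$hazard_late_pesticide
  base$its_hazard_slope_control <- base$its_hazard_slope_pesticide
  base$hyperactivity_multiplier <- 0
  base$fly_treatment_offset <- 0
  base$feed_meanlog_control <- base$feed_meanlog_pesticide
  base
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_per_treatment, "bees/treatment,",
      x$n_colonies, "colonies\n")
  invisible(x)
}

# truncated-normal draws by inverse-CDF (deterministic under set.seed)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a complete synthetic flight-mill cohort
#'
#' Generates a bee metadata table and revolution logs with the statistical
#' structure the pipeline expects: balanced treatment/colony assignment,
#' truncated-normal body sizes, size-dependent feeding and flight
#' propensities, per-circuit velocities with an exposure hyperactivity boost
#' decaying over circuits, stoppages drawn as > 20 s intervals, and session
#' termination by a two-phase per-circuit hazard, the stoppage budget, or
#' the session cap — whichever comes first.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical `(config, seed)` yield bit-identical
#'   cohorts.
#' @param protocol A [protocol_config()] supplying the circumference, the
#'   stoppage budget and the session cap.
#' @return An object of class `mill_cohort`: list with `bees` (a valid bee
#'   table), `logs` (long revolution-log tibble across all flying bees),
#'   `config` and `seed`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_treatment = 5), seed = 1)
#' sim$bees
#' @export
simulate_cohort <- function(config = default_calibration(), seed,
                            protocol = protocol_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    stop("simulate_cohort: an integer seed is required", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_trt <- config$n_per_treatment
  n_total <- 2L * n_trt
  width <- max(3L, nchar(as.character(n_trt)))
  bee_id <- c(sprintf(paste0("c%0", width, "d"), seq_len(n_trt)),
              sprintf(paste0("p%0", width, "d"), seq_len(n_trt)))
  treatment <- factor(rep(c("control", "pesticide"), each = n_trt),
                      levels = c("control", "pesticide"))
  colony_id <- paste0("colony", rep_len(seq_len(config$n_colonies), n_trt))
  colony_id <- c(colony_id, colony_id)   # balanced within each arm

  its <- round(rtrunc_norm(n_total, config$its_mean, config$its_sd,
                           config$its_min, config$its_max), 2)
  p_feed <- stats::plogis(config$feed_intercept + config$feed_slope * its)
  fed <- stats::runif(n_total) < p_feed
  meanlog <- ifelse(treatment == "control",
                    config$feed_meanlog_control, config$feed_meanlog_pesticide)
  feed_duration <- ifelse(fed,
                          round(stats::rlnorm(n_total, meanlog,
                                              config$feed_sdlog), 1), 0)
  tag_rating <- sample(c(1L, 2L), n_total, replace = TRUE,
                       prob = config$tag_rating_probs)
  technical_fail <- stats::runif(n_total) < config$technical_fail_prob
  wet_mass <- round(stats::rnorm(n_total, 240, 25), 1)
  wet_mass <- pmax(wet_mass, 100)

  offset <- ifelse(treatment == "pesticide", config$fly_treatment_offset, 0)
  p_fly <- stats::plogis(config$fly_intercept + config$fly_slope * its + offset)
  attempts <- fed & feed_duration > 0 & !technical_fail
  flies <- attempts & (stats::runif(n_total) < p_fly)

  bees <- tibble::tibble(
    bee_id = bee_id, colony_id = colony_id, treatment = treatment,
    its_mm = its, wet_mass_mg = wet_mass, tag_rating = tag_rating,
    fed = fed, feed_duration_s = feed_duration,
    technical_fail = technical_fail)

  logs <- vector("list", n_total)
  for (i in which(flies)) {
    logs[[i]] <- simulate_session(
      bee_id = bee_id[i],
      pesticide = treatment[i] == "pesticide",
      its = its[i], config = config, protocol = protocol)
  }
  logs <- dplyr::bind_rows(logs[!vapply(logs, is.null, logical(1))])
  if (nrow(logs) == 0) {
    logs <- tibble::tibble(bee_id = character(), circuit_index = integer(),
                           interval_s = double())
  }
  structure(list(bees = bees, logs = logs, config = config,
                 seed = as.integer(seed)),
            class = "mill_cohort")
}

# one flying bee's revolution log
simulate_session <- function(bee_id, pesticide, its, config, protocol) {
  h_early <- if (pesticide) config$hazard_early_pesticide else config$hazard_early_control
  h_late <- if (pesticide) config$hazard_late_pesticide else config$hazard_late_control
  slope <- if (pesticide) config$its_hazard_slope_pesticide else config$its_hazard_slope_control
  mod <- exp(-slope * (its - config$its_mean))
  h_early <- min(h_early * mod, 0.999)
  h_late <- min(h_late * mod, 0.999)

  early <- config$early_phase_circuits
  t_term <- if (h_early > 0) stats::rgeom(1, h_early) + 1 else Inf
  if (t_term > early) {
    t_term <- if (h_late > 0) early + stats::rgeom(1, h_late) + 1 else Inf
  }
  base_v <- max(stats::rnorm(1, config$baseline_velocity_mps,
                             config$bee_velocity_sd), 0.2)
  # generation bound: at this bee's fastest plausible pace the session cap
  # ends the session within v_max * cap / circumference circuits
  v_max <- base_v * (1 + config$hyperactivity_multiplier) *
    (1 + 6 * config$velocity_noise_sd)
  n_max <- min(t_term,
               ceiling(protocol$session_cap_s * v_max /
                         protocol$circumference_m) + 1)
  n_max <- max(n_max, 1)
  idx <- seq_len(n_max)
  boost <- if (pesticide) {
    1 + config$hyperactivity_multiplier *
      exp(-idx / config$hyperactivity_decay_circuits)
  } else rep(1, n_max)
  v <- base_v * boost * (1 + stats::rnorm(n_max, 0, config$velocity_noise_sd))
  v <- pmax(v, 0.05)
  interval <- protocol$circumference_m / v

  stop_flag <- stats::runif(n_max) < config$stoppage_rate
  if (any(stop_flag)) {
    interval[stop_flag] <- protocol$stoppage_threshold_s +
      stats::rexp(sum(stop_flag), 1 / config$stoppage_excess_mean_s)
  }
  # round to the stored precision before applying termination rules, so the
  # written log obeys the cap invariant exactly as validated on read-back
  interval <- round(interval, 4)
  # stoppage budget: the session ends on the (budget + 1)-th genuine stoppage
  genuine <- which(stop_flag & idx > 1)
  if (length(genuine) > protocol$max_stoppages) {
    n_max <- genuine[protocol$max_stoppages + 1]
    interval <- interval[seq_len(n_max)]
  }
  cum <- cumsum(interval)
  cap_at <- which(cum >= protocol$session_cap_s)
  if (length(cap_at) > 0) interval <- interval[seq_len(cap_at[1])]

  tibble::new_tibble(list(bee_id = rep(bee_id, length(interval)),
                          circuit_index = seq_along(interval),
                          interval_s = interval),
                     nrow = length(interval))
}

#' @export
print.mill_cohort <- function(x, ...) {
  cat("<mill_cohort>", nrow(x$bees), "bees,",
      dplyr::n_distinct(x$logs$bee_id), "flight sessions, seed", x$seed, "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the canonical CSV formats (one log file per bee under `dir/logs/`,
#' the bee table as `dir/bees.csv`) plus a provenance JSON recording the
#' configuration, seed and package version.
#'
#' @param cohort A `mill_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mill_cohort"))
  log_dir <- file.path(dir, "logs")
  dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
  write_bee_table(cohort$bees, file.path(dir, "bees.csv"))
  for (id in unique(cohort$logs$bee_id)) {
    write_revolution_log(cohort$logs[cohort$logs$bee_id == id, ],
                         file.path(log_dir, paste0(id, ".csv")))
  }
  prov <- list(
    config = unclass(cohort$config),
    seed = cohort$seed,
    package_version = as.character(utils::packageVersion("beemill")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
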