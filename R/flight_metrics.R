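#' Detect flight stoppages and the in-test window of a session
#'
#' A stoppage is a circuit whose interval strictly exceeds
#' `cfg$stoppage_threshold_s` (the enforced rest period, 20 s by default). A
#' qualifying first circuit is discounted: it is treated as an acclimatisation
#' circuit and does not count against the stoppage budget. The flight test
#' terminates at the earlier of (i) the circuit carrying the
#' `(max_stoppages + 1)`-th genuine stoppage and (ii) the circuit on which
#' cumulative duration reaches the session cap (that straddling circuit is
#' retained); circuits beyond the termination point are out-of-test and
#' ignored by all downstream metrics.
#'
#' @param log A validated revolution log (may be empty: a bee that never flew).
#' @param cfg A [protocol_config()].
#' @return An object of class `flight_segments`: a list with
#'   `stoppage_indices` (genuine in-test stoppages, at most
#'   `max_stoppages`), `excluded_indices` (populated by [clean_circuits()]),
#'   `n_in_test` (last in-test circuit index), `flew`, and `terminated_by`
#'   (`"none"`, `"stoppage_budget"` or `"session_cap"`).
#' @examples
#' log <- tibble::tibble(bee_id = "b1", circuit_index = 1:4,
#'                       interval_s = c(1.0, 1.2, 25.0, 1.1))
#' detect_stoppages(log, protocol_config())$stoppage_indices
#' @export
detect_stoppages <- function(log, cfg = protocol_config()) {
  n <- nrow(log)
  if (n == 0) {
    return(structure(list(stoppage_indices = integer(0),
                          excluded_indices = integer(0),
                          n_in_test = 0L, flew = FALSE,
                          terminated_by = "none"),
                     class = "flight_segments"))
  }
  iv <- log$interval_s
  over <- which(iv > cfg$stoppage_threshold_s)
  genuine <- over[over > 1L]   # first-circuit stoppage is discounted

  n_in_test <- n
  terminated_by <- "none"
  if (length(genuine) > cfg$max_stoppages) {
    n_in_test <- genuine[cfg$max_stoppages + 1L]
    terminated_by <- "stoppage_budget"
  }
  cum <- cumsum(iv)
  cap_idx <- which(cum >= cfg$session_cap_s)
  if (length(cap_idx) > 0 && cap_idx[1] < n_in_test) {
    n_in_test <- cap_idx[1]
    terminated_by <- "session_cap"
  } else if (length(cap_idx) > 0 && cap_idx[1] == n_in_test &&
             terminated_by == "none") {
    terminated_by <- "session_cap"
  }
  stoppages <- genuine[genuine <= n_in_test]
  stoppages <- utils::head(stoppages, cfg$max_stoppages)
  structure(list(stoppage_indices = as.integer(stoppages),
                 excluded_indices = integer(0),
                 n_in_test = as.integer(n_in_test),
                 flew = TRUE,
                 terminated_by = terminated_by),
            class = "flight_segments")
}

#' @export
print.flight_segments <- function(x, ...) {
  cat("<flight_segments> ",
      if (x$flew) paste0(x$n_in_test, " in-test circuits, ",
                         length(x$stoppage_indices), " stoppage(s), ",
                         length(x$excluded_indices), " excluded circuit(s)")
      else "did not fly", "\n", sep = "")
  invisible(x)
}

#' Mark circuits excluded from velocity analysis
#'
#' Velocity estimates are contaminated by the stimulated take-off after stand
#' removal and by arm coasting around stoppages, so the cleaning step excludes
#' (a) the first `post_start_exclusion` circuits of the session, (b) the
#' `post_stop_exclusion` circuits directly following each stoppage, and (c)
#' the `pre_stop_exclusion` circuit(s) directly preceding each stoppage. The
#' stoppage circuit itself is also excluded (its interval contains the rest
#' period, so it has no meaningful velocity). Windows are clipped to the
#' in-test range and overlaps are unioned. Excluded circuits still count
#' towards total distance and duration.
#'
#' @param log A validated revolution log.
#' @param segments The [detect_stoppages()] result for `log`.
#' @param cfg A [protocol_config()].
#' @return `segments` with `excluded_indices` populated (sorted, unique).
#' @export
clean_circuits <- function(log, segments, cfg = protocol_config()) {
  if (!segments$flew) return(segments)
  n <- segments$n_in_test
  excl <- seq_len(min(cfg$post_start_exclusion, n))
  for (k in segments$stoppage_indices) {
    win <- c(seq(k - cfg$pre_stop_exclusion, k - 1), k,
             seq(k + 1, k + cfg$post_stop_exclusion))
    excl <- c(excl, win[win >= 1 & win <= n])
  }
  segments$excluded_indices <- sort(unique(as.integer(excl)))
  segments
}

#' Compute endurance and velocity metrics for one flight session
#'
#' Endurance metrics are computed over all in-test circuits: total distance is
#' the circuit count times the arm circumference and total duration the sum of
#' all circuit intervals (stops included). Velocity metrics use only cleaned
#' circuits: per-circuit velocity is circumference / interval, mean velocity
#' is the cleaned distance divided by the cleaned duration, and maximum
#' velocity is the fastest cleaned circuit. When no cleaned circuit remains
#' the velocity fields are `NA` while endurance fields are still computed.
#'
#' @param log A validated revolution log.
#' @param segments Cleaned segments from [clean_circuits()]; if the
#'   `excluded_indices` have not been populated the session is cleaned first.
#' @param cfg A [protocol_config()].
#' @return A one-row tibble with columns `bee_id`, `n_circuits`,
#'   `total_distance_m`, `total_duration_s`, `mean_velocity_mps`,
#'   `max_velocity_mps`, `n_stoppages`, `flew`, `over_100m`, `over_2000s`,
#'   `completed_cap`, plus list-columns `per_circuit` (tibble of cleaned
#'   `circuit_index`, `velocity_mps`) and `binned` (the [bin_velocity()]
#'   result).
#' @export
compute_metrics <- function(log, segments = NULL, cfg = protocol_config()) {
  if (is.null(segments)) segments <- detect_stoppages(log, cfg)
  if (segments$flew && length(segments$excluded_indices) == 0 &&
      segments$n_in_test > 0) {
    segments <- clean_circuits(log, segments, cfg)
  }
  bee_id <- if (nrow(log) > 0) log$bee_id[1] else NA_character_
  n <- segments$n_in_test
  iv <- if (n > 0) log$interval_s[seq_len(n)] else double(0)
  total_distance <- n * cfg$circumference_m
  total_duration <- sum(iv)

  kept <- setdiff(seq_len(n), segments$excluded_indices)
  per_circuit <- tibble::new_tibble(
    list(circuit_index = as.integer(kept),
         velocity_mps = cfg$circumference_m / iv[kept]),
    nrow = length(kept))
  if (nrow(per_circuit) > 0) {
    mean_v <- (nrow(per_circuit) * cfg$circumference_m) / sum(iv[kept])
    max_v <- max(per_circuit$velocity_mps)
  } else {
    mean_v <- NA_real_
    max_v <- NA_real_
  }
  binned <- bin_velocity(per_circuit, cfg)
  tibble::new_tibble(list(
    bee_id = bee_id,
    n_circuits = as.integer(n),
    total_distance_m = total_distance,
    total_duration_s = total_duration,
    mean_velocity_mps = mean_v,
    max_velocity_mps = max_v,
    n_stoppages = length(segments$stoppage_indices),
    flew = segments$flew,
    over_100m = total_distance > cfg$distance_threshold_m,
    over_2000s = total_duration > cfg$endurance_split_s,
    completed_cap = total_duration >= cfg$session_cap_s,
    per_circuit = list(per_circuit),
    binned = list(binned)
  ), nrow = 1L)
}

#' Bin cleaned per-circuit velocities into fixed-width circuit blocks
#'
#' Bin `b` covers original circuit indices `((b - 1) * bin_width,
#' b * bin_width]`; its value is the mean cleaned velocity of circuits falling
#' in that range, or `NA` when the bin holds no cleaned circuit. Circuits
#' beyond `trajectory_window` are ignored. With the defaults this yields 18
#' bins of 50 circuits over the first 900 circuits.
#'
#' @param per_circuit A tibble with `circuit_index` (original indices) and
#'   `velocity_mps`, e.g. the `per_circuit` list-column of
#'   [compute_metrics()].
#' @param cfg A [protocol_config()].
#' @return A tibble with columns `bin` (1..n_bins), `circuit_mid` (bin
#'   midpoint in circuits), `mean_velocity_mps`, `n_circuits`.
#' @export
bin_velocity <- function(per_circuit, cfg = protocol_config()) {
  n_bins <- as.integer(cfg$trajectory_window / cfg$bin_width)
  out <- tibble::new_tibble(
    list(bin = seq_len(n_bins),
         circuit_mid = (seq_len(n_bins) - 0.5) * cfg$bin_width,
         mean_velocity_mps = rep(NA_real_, n_bins),
         n_circuits = rep(0L, n_bins)),
    nrow = n_bins)
  pc <- per_circuit[per_circuit$circuit_index <= cfg$trajectory_window, ]
  if (nrow(pc) == 0) return(out)
  b <- as.integer(ceiling(pc$circuit_index / cfg$bin_width))
  counts <- tabulate(b, nbins = n_bins)
  sums <- rep(0, n_bins)
  occupied <- sort(unique(b))
  sums[occupied] <- rowsum(pc$velocity_mps, b)[, 1]
  filled <- counts > 0
  out$mean_velocity_mps[filled] <- sums[filled] / counts[filled]
  out$n_circuits <- counts
  out
}

#' Process one flight session end-to-end
#'
#' Convenience wrapper: [detect_stoppages()], [clean_circuits()],
#' [compute_metrics()].
#'
#' @param log A validated revolution log for a single bee.
#' @param cfg A [protocol_config()].
#' @return The one-row metrics tibble of [compute_metrics()].
#' @export
process_session <- function(log, cfg = protocol_config()) {
  segments <- clean_circuits(log, detect_stoppages(log, cfg), cfg)
  compute_metrics(log, segments, cfg)
}

#' Process all sessions of a cohort
#'
#' @param logs A long tibble of revolution logs (`bee_id`, `circuit_index`,
#'   `interval_s`) covering any number of bees, e.g. from
#'   [read_revolution_logs()] or [simulate_cohort()].
#' @param bees Optional bee table; bees present here but absent from `logs`
#'   receive a did-not-fly metrics row, so the result has one row per bee.
#' @param cfg A [protocol_config()].
#' @return A metrics tibble, one row per bee (see [compute_metrics()]).
#' @export
process_cohort <- function(logs, bees = NULL, cfg = protocol_config()) {
  ids <- unique(logs$bee_id)
  by_bee <- split(tibble::as_tibble(logs), factor(logs$bee_id, levels = ids))
  rows <- lapply(by_bee, function(log) {
    process_session(validate_revolution_log(
      log, session_cap_s = cfg$session_cap_s), cfg)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(bees)) {
    missing_ids <- setdiff(bees$bee_id, ids)
    if (length(missing_ids) > 0) {
      empty <- dplyr::bind_rows(lapply(missing_ids, function(id) {
        row <- compute_metrics(
          tibble::tibble(bee_id = character(0), circuit_index = integer(0),
                         interval_s = double(0)),
          cfg = cfg)
        row$bee_id <- id
        row
      }))
      out <- dplyr::bind_rows(out, empty)
    }
    out <- out[match(bees$bee_id[bees$bee_id %in% out$bee_id], out$bee_id), ]
  }
  out
}
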