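#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

rev_log_cols <- c("bee_id", "circuit_index", "interval_s")

bee_table_cols <- c("bee_id", "colony_id", "treatment", "its_mm", "wet_mass_mg",
                    "tag_rating", "fed", "feed_duration_s", "technical_fail")

#' Validate a revolution log
#'
#' A revolution log is a tibble with columns `bee_id`, `circuit_index`,
#' `interval_s`: one row per completed circuit of the mill arm for a single
#' flight session, ordered by `circuit_index` (1-based and contiguous), with
#' each `interval_s` the strictly positive time in seconds the circuit took.
#'
#' @param log A data frame to validate.
#' @param session_cap_s Session cap used for the total-duration sanity check;
#'   the final circuit may straddle the cap, so the permitted total is the cap
#'   plus the final interval.
#' @return The validated log as a tibble, invisibly ordered by circuit index.
#' @export
validate_revolution_log <- function(log, session_cap_s = 3600) {
  missing <- setdiff(rev_log_cols, names(log))
  if (length(missing) > 0) {
    stop("revolution log: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  log <- tibble::as_tibble(log)[rev_log_cols]
  if (nrow(log) == 0) return(log)
  if (length(unique(log$bee_id)) != 1) {
    stop("revolution log: must contain a single bee_id", call. = FALSE)
  }
  if (is.unsorted(log$circuit_index)) {
    log <- log[order(log$circuit_index), ]
  }
  bad <- which(!is.finite(log$interval_s) | log$interval_s <= 0)
  if (length(bad) > 0) {
    stop("revolution log: non-positive or non-finite interval_s at row ",
         bad[1], " (circuit ", log$circuit_index[bad[1]], ")", call. = FALSE)
  }
  if (!identical(as.integer(log$circuit_index), seq_len(nrow(log)))) {
    exp_idx <- seq_len(nrow(log))
    gap <- which(as.integer(log$circuit_index) != exp_idx)[1]
    stop("revolution log: circuit_index must be contiguous from 1; first ",
         "irregularity at position ", gap, " (found ", log$circuit_index[gap],
         ", expected ", gap, ")", call. = FALSE)
  }
  total <- sum(log$interval_s)
  if (total > session_cap_s + log$interval_s[nrow(log)] + 1e-6) {
    stop("revolution log: total duration ", round(total, 1),
         " s exceeds the session cap plus the final circuit", call. = FALSE)
  }
  log
}

#' Read a revolution log CSV
#'
#' Expects a comma-separated, headered file with columns
#' `bee_id,circuit_index,interval_s` holding one flight session.
#'
#' @param path File path.
#' @param session_cap_s Passed to [validate_revolution_log()].
#' @return A validated revolution-log tibble.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("bee_id,circuit_index,interval_s",
#'              "b1,1,1.0", "b1,2,1.2", "b1,3,0.9"), tf)
#' read_revolution_log(tf)
#' @export
read_revolution_log <- function(path, session_cap_s = 3600) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(rev_log_cols, hdr)
  if (length(missing) > 0) {
    stop("revolution log: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  log <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           bee_id = readr::col_character(),
                           circuit_index = readr::col_integer(),
                           interval_s = readr::col_double(),
                           .default = readr::col_guess()
                         ))
  validate_revolution_log(log, session_cap_s = session_cap_s)
}

#' Write a revolution log CSV
#'
#' @param log A valid revolution log (see [validate_revolution_log()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_revolution_log <- function(log, path) {
  log <- validate_revolution_log(log)
  readr::write_csv(log, path)
  invisible(path)
}

#' Read all revolution logs from a directory
#'
#' Reads every `*.csv` file in `dir` as a single-session revolution log and
#' binds them into one long tibble.
#'
#' @param dir Directory of per-bee log CSVs.
#' @param session_cap_s Passed to [validate_revolution_log()].
#' @return A tibble with columns `bee_id`, `circuit_index`, `interval_s`.
#' @export
read_revolution_logs <- function(dir, session_cap_s = 3600) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) {
    return(tibble::tibble(bee_id = character(), circuit_index = integer(),
                          interval_s = double()))
  }
  purrr::map(files, read_revolution_log, session_cap_s = session_cap_s) %>%
    dplyr::bind_rows()
}

#' Read a bee metadata table
#'
#' One row per tested bee with columns `bee_id`, `colony_id`, `treatment`
#' (`control`/`pesticide`, case-insensitive), `its_mm` (intertegular span, a
#' body-size proxy), `wet_mass_mg` (mass including tag), `tag_rating` (1 =
#' ideal fit, 2 = unideal, 3 = unacceptable), `fed`, `feed_duration_s`, and
#' `technical_fail`.
#'
#' @param path File path to the CSV.
#' @return A tibble of validated bee records; `treatment` is a factor with
#'   levels `control`, `pesticide`.
#' @export
read_bee_table <- function(path) {
  bees <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            bee_id = readr::col_character(),
                            colony_id = readr::col_character(),
                            treatment = readr::col_character(),
                            its_mm = readr::col_double(),
                            wet_mass_mg = readr::col_double(),
                            tag_rating = readr::col_integer(),
                            fed = readr::col_logical(),
                            feed_duration_s = readr::col_double(),
                            technical_fail = readr::col_logical()
                          ))
  validate_bee_table(bees)
}

#' Validate a bee metadata table
#'
#' @param bees A data frame with the bee-table columns (see
#'   [read_bee_table()]).
#' @return The validated tibble with `treatment` as a factor.
#' @export
validate_bee_table <- function(bees) {
  missing <- setdiff(bee_table_cols, names(bees))
  if (length(missing) > 0) {
    stop("bee table: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bees <- tibble::as_tibble(bees)
  dup <- bees$bee_id[duplicated(bees$bee_id)]
  if (length(dup) > 0) {
    stop("bee table: duplicate bee_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  trt <- tolower(trimws(as.character(bees$treatment)))
  bad_trt <- setdiff(unique(trt), c("control", "pesticide"))
  if (length(bad_trt) > 0) {
    stop("bee table: unknown treatment token(s): ",
         paste(bad_trt, collapse = ", "), call. = FALSE)
  }
  bees$treatment <- factor(trt, levels = c("control", "pesticide"))
  if (!all(bees$tag_rating %in% c(1L, 2L, 3L))) {
    stop("bee table: tag_rating must be 1, 2 or 3", call. = FALSE)
  }
  if (any(!is.finite(bees$its_mm) | bees$its_mm <= 0) ||
      any(!is.finite(bees$wet_mass_mg) | bees$wet_mass_mg <= 0)) {
    stop("bee table: its_mm and wet_mass_mg must be positive", call. = FALSE)
  }
  if (any(!bees$fed & bees$feed_duration_s != 0)) {
    stop("bee table: feed_duration_s must be 0 for bees that did not feed",
         call. = FALSE)
  }
  if (any(bees$feed_duration_s < 0)) {
    stop("bee table: feed_duration_s must be >= 0", call. = FALSE)
  }
  bees
}

#' Write a bee metadata table
#' @param bees A valid bee table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bee_table <- function(bees, path) {
  bees <- validate_bee_table(bees)
  readr::write_csv(bees, path)
  invisible(path)
}

#' Write a flight-metrics table
#'
#' Serialises the scalar columns of a metrics table (as produced by
#' [process_cohort()] or [compute_metrics()]) to CSV in a stable column
#' order; list-columns holding per-circuit and binned velocities are dropped.
#'
#' @param metrics A metrics tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  scalar_cols <- c("bee_id", "n_circuits", "total_distance_m",
                   "total_duration_s", "mean_velocity_mps", "max_velocity_mps",
                   "n_stoppages", "flew", "over_100m", "over_2000s",
                   "completed_cap")
  if (nrow(metrics) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(logical(0)), length(scalar_cols)), scalar_cols))
    out$bee_id <- character(0)
  } else {
    missing <- setdiff(scalar_cols, names(metrics))
    if (length(missing) > 0) {
      stop("write_metrics_table: missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out <- metrics[scalar_cols]
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a flight-metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_metrics_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    bee_id = readr::col_character(),
                    n_circuits = readr::col_integer(),
                    n_stoppages = readr::col_integer(),
                    flew = readr::col_logical(),
                    over_100m = readr::col_logical(),
                    over_2000s = readr::col_logical(),
                    completed_cap = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}

#' Convert timestamped impulse records to a revolution log
#'
#' The Hall sensor natively reports inter-impulse intervals, which is the
#' canonical representation here; acquisition scripts that log absolute
#' timestamps instead can be converted by differencing. The first timestamp is
#' taken as the session start (circuit 1 spans start to first impulse is not
#' recoverable, so n timestamps after start yield n intervals against the
#' supplied origin).
#'
#' @param bee_id Identifier for the session.
#' @param timestamps_s Strictly increasing impulse times in seconds, the first
#'   being the session start reference.
#' @return A revolution-log tibble with `length(timestamps_s) - 1` circuits.
#' @export
timestamps_to_log <- function(bee_id, timestamps_s) {
  if (length(timestamps_s) < 2) {
    return(tibble::tibble(bee_id = character(), circuit_index = integer(),
                          interval_s = double()))
  }
  d <- diff(timestamps_s)
  if (any(d <= 0)) {
    stop("timestamps_to_log: timestamps must be strictly increasing",
         call. = FALSE)
  }
  tibble::tibble(bee_id = bee_id,
                 circuit_index = seq_along(d),
                 interval_s = as.double(d))
}
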