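cascade_steps <- c("started", "fed", "fed_over_60s", "no_technical_fail",
                   "tag_rating_1", "flew", "over_100m", "its_trimmed")

#' Apply the cohort filter cascade
#'
#' Reduces the tested cohort to the endurance/velocity analysis set through
#' the ordered inclusion steps: fed; fed for more than `feed_threshold_s`
#' seconds; no technical failure on the mill; ideal (rating 1) tag fit; flew;
#' flew further than the distance threshold; and finally symmetric trimming of
#' the body-size (ITS) extremes via [trim_its_extremes()]. Counts per
#' treatment are recorded at every step.
#'
#' @param bees A validated bee table (see [read_bee_table()]).
#' @param metrics A metrics table with at least `bee_id`, `flew`,
#'   `total_distance_m`, as produced by [process_cohort()]; every metrics row
#'   must match a bee record. Bees without a metrics row are treated as not
#'   having flown.
#' @param cfg A [protocol_config()]; supplies the distance threshold.
#' @param feed_threshold_s Feeding-duration inclusion threshold (s,
#'   exclusive).
#' @param trim_fraction Fraction trimmed from each ITS extreme at the final
#'   step.
#' @return An object of class `mill_cascade`: a list with `counts` (tibble of
#'   `step`, `control`, `pesticide`, `total`), `analysis_set` (the surviving
#'   joined tibble after trimming), `pre_trim` (survivors before trimming),
#'   `trim` (the [trim_its_extremes()] removal bookkeeping) and `stages`
#'   (the surviving joined tibble at every step, used by
#'   [run_flight_model_suite()]).
#' @examples
#' fx <- cascade_fixture()
#' apply_cascade(fx$bees, fx$metrics)$counts
#' @export
apply_cascade <- function(bees, metrics, cfg = protocol_config(),
                          feed_threshold_s = 60, trim_fraction = 0.10) {
  bees <- validate_bee_table(bees)
  orphan <- setdiff(metrics$bee_id, bees$bee_id)
  if (length(orphan) > 0) {
    stop("apply_cascade: metrics without a bee record: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  keep_cols <- intersect(c("bee_id", "flew", "total_distance_m",
                           "total_duration_s", "mean_velocity_mps",
                           "max_velocity_mps", "n_circuits", "over_2000s",
                           "completed_cap", "per_circuit", "binned"),
                         names(metrics))
  joined <- dplyr::left_join(bees, metrics[keep_cols], by = "bee_id")
  joined$flew <- !is.na(joined$flew) & joined$flew
  if (!"total_distance_m" %in% names(joined)) {
    joined$total_distance_m <- NA_real_
  }

  stages <- list(started = joined)
  stages$fed <- dplyr::filter(stages$started, .data$fed)
  stages$fed_over_60s <- dplyr::filter(stages$fed,
                                       .data$feed_duration_s > feed_threshold_s)
  stages$no_technical_fail <- dplyr::filter(stages$fed_over_60s,
                                            !.data$technical_fail)
  stages$tag_rating_1 <- dplyr::filter(stages$no_technical_fail,
                                       .data$tag_rating == 1L)
  stages$flew <- dplyr::filter(stages$tag_rating_1, .data$flew)
  stages$over_100m <- dplyr::filter(
    stages$flew,
    !is.na(.data$total_distance_m) &
      .data$total_distance_m > cfg$distance_threshold_m)

  trim <- trim_its_extremes(stages$over_100m, fraction = trim_fraction)
  stages$its_trimmed <- trim$kept

  counts <- purrr::map_dfr(cascade_steps, function(st) {
    d <- stages[[st]]
    tibble::tibble(
      step = st,
      control = sum(d$treatment == "control"),
      pesticide = sum(d$treatment == "pesticide"),
      total = nrow(d)
    )
  })
  structure(list(counts = counts,
                 analysis_set = stages$its_trimmed,
                 pre_trim = stages$over_100m,
                 trim = trim[c("removed", "k", "removal_counts")],
                 stages = stages),
            class = "mill_cascade",
            distance_threshold_m = cfg$distance_threshold_m)
}

#' @export
print.mill_cascade <- function(x, ...) {
  cat("<mill_cascade> filter cascade\n")
  print(x$counts, n = Inf)
  invisible(x)
}

#' Trim body-size extremes from an analysis set
#'
#' Pools the records across treatments, orders them by ITS (ties broken by
#' `bee_id` for determinism) and removes the `k` smallest and `k` largest,
#' where `k = round(fraction * n)` with half-up rounding. Pooled trimming is
#' what lets the per-treatment removal counts differ when the two treatments'
#' size distributions differ.
#'
#' @param records A tibble with `its_mm`, `bee_id` and `treatment`.
#' @param fraction Fraction trimmed from each extreme, in `[0, 0.5)`.
#' @return A list with `kept` (surviving rows, original order), `removed`
#'   (removed rows tagged `end = "low"/"high"`), `k`, and `removal_counts`
#'   (tibble of per-treatment low/high removals).
#' @export
trim_its_extremes <- function(records, fraction = 0.10) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 0.5) {
    stop("trim_its_extremes: fraction must be in [0, 0.5)", call. = FALSE)
  }
  n <- nrow(records)
  k <- floor(fraction * n + 0.5)  # half-up rounding
  if (k == 0) {
    return(list(kept = records,
                removed = records[0, ],
                k = 0L,
                removal_counts = tibble::tibble(treatment = character(0),
                                                low = integer(0),
                                                high = integer(0))))
  }
  if (2 * k >= n) {
    stop("trim_its_extremes: trimming 2k = ", 2 * k,
         " records would exhaust the ", n, " available", call. = FALSE)
  }
  ord <- order(records$its_mm, records$bee_id)
  low_idx <- ord[seq_len(k)]
  high_idx <- ord[seq(n - k + 1, n)]
  removed <- dplyr::bind_rows(
    dplyr::mutate(records[low_idx, ], end = "low"),
    dplyr::mutate(records[high_idx, ], end = "high")
  )
  kept <- records[sort(setdiff(seq_len(n), c(low_idx, high_idx))), ]
  removal_counts <- removed %>%
    dplyr::count(.data$treatment, .data$end) %>%
    tidyr::pivot_wider(names_from = "end", values_from = "n",
                       values_fill = 0L)
  for (col in c("low", "high")) {
    if (!col %in% names(removal_counts)) removal_counts[[col]] <- 0L
  }
  list(kept = kept, removed = removed, k = as.integer(k),
       removal_counts = removal_counts[c("treatment", "low", "high")])
}

#' Percent reduction of a treatment mean relative to control
#'
#' @param mean_control,mean_treated Group means (control must be non-zero).
#' @return `100 * (1 - mean_treated / mean_control)`.
#' @examples
#' distance_reduction_pct(1833.9, 659.1)
#' @export
distance_reduction_pct <- function(mean_control, mean_treated) {
  if (!is.finite(mean_control) || mean_control == 0) {
    stop("distance_reduction_pct: control mean must be non-zero",
         call. = FALSE)
  }
  100 * (1 - mean_treated / mean_control)
}

#' Foraging-area decline implied by a flight-distance reduction
#'
#' For a central-place forager the accessible foraging area scales with the
#' square of flight range, so a fractional reduction `r` in flight distance
#' implies a `1 - (1 - r)^2` fractional decline in area.
#'
#' @param reduction_pct Distance reduction in percent.
#' @return Area decline in percent.
#' @examples
#' forage_area_decline_pct(distance_reduction_pct(1833.9, 659.1))
#' @export
forage_area_decline_pct <- function(reduction_pct) {
  100 * (1 - (1 - reduction_pct / 100)^2)
}

#' Summarise treatment effects on the analysis set
#'
#' Per-treatment means with standard errors for total distance, duration and
#' mean velocity, the proportions flying beyond the endurance split and
#' completing the session cap, and the derived control-relative distance
#' reduction and foraging-area decline.
#'
#' @param analysis_set A joined tibble (bee covariates + metrics) with both
#'   treatments present, e.g. `apply_cascade(...)$analysis_set`.
#' @return An object of class `mill_effects`: list with `by_treatment` (a
#'   tibble) and scalars `distance_reduction_pct`, `area_decline_pct`.
#' @export
summarize_effects <- function(analysis_set) {
  if (nrow(analysis_set) == 0 ||
      dplyr::n_distinct(analysis_set$treatment) < 2) {
    stop("summarize_effects: need records from both treatments",
         call. = FALSE)
  }
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  by_trt <- analysis_set %>%
    dplyr::group_by(.data$treatment) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_distance_m = mean(.data$total_distance_m),
      se_distance_m = se(.data$total_distance_m),
      mean_duration_s = mean(.data$total_duration_s),
      se_duration_s = se(.data$total_duration_s),
      mean_velocity_mps = mean(.data$mean_velocity_mps, na.rm = TRUE),
      se_velocity_mps = se(.data$mean_velocity_mps),
      prop_over_2000s = mean(.data$over_2000s),
      prop_completed_cap = mean(.data$completed_cap),
      .groups = "drop"
    )
  mc <- by_trt$mean_distance_m[by_trt$treatment == "control"]
  mp <- by_trt$mean_distance_m[by_trt$treatment == "pesticide"]
  red <- distance_reduction_pct(mc, mp)
  structure(list(by_treatment = by_trt,
                 distance_reduction_pct = red,
                 area_decline_pct = forage_area_decline_pct(red)),
            class = "mill_effects")
}

#' @export
print.mill_effects <- function(x, ...) {
  cat("<mill_effects>\n")
  print(x$by_treatment)
  cat(sprintf("distance reduction: %.1f%%   foraging-area decline: %.1f%%\n",
              x$distance_reduction_pct, x$area_decline_pct))
  invisible(x)
}
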