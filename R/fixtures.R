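#' Deterministic filter-cascade fixture
#'
#' Builds a synthetic 222-bee cohort (111 per treatment over three colonies)
#' whose per-step outcome flags walk the filter cascade through exactly the
#' reference attrition counts: 222 bees at start, 209 fed, 180 fed over
#' 60 s, 176 without technical failure, 140 with ideal tags, 103 that flew,
#' 67 beyond 100 m, and 53 after trimming the body-size extremes (26
#' control / 27 exposed). The body sizes of the 67 endurance bees are laid
#' out so that pooled 10% trimming removes 6 small + 3 large control bees
#' and 1 small + 4 large exposed bees. Endurance metrics of the surviving
#' bees are centred near the reference treatment means (about 1834 m vs
#' 659 m total distance, 0.63 vs 0.84 m/s mean velocity, long-flight
#' proportions about 0.81 vs 0.04).
#'
#' The fixture is fully deterministic: repeated calls return identical
#' tables.
#'
#' @param cfg A [protocol_config()]; supplies the circumference used to make
#'   distances whole numbers of circuits.
#' @return A list with `bees` (valid bee table, 222 rows) and `metrics`
#'   (metrics table for the 103 flying bees).
#' @examples
#' fx <- cascade_fixture()
#' apply_cascade(fx$bees, fx$metrics)$counts
#' @export
cascade_fixture <- function(cfg = protocol_config()) {
  circ <- cfg$circumference_m

  # per-treatment attrition layout:
  #   control:  9 unfed, 16 short feed, 2 tech fail, 18 rating-2, 19 no-fly,
  #             12 under-threshold, 35 endurance (6 low / 26 mid / 3 high ITS)
  #   exposed:  4 unfed, 13 short feed, 2 tech fail, 18 rating-2, 18 no-fly,
  #             24 under-threshold, 32 endurance (1 low / 27 mid / 4 high ITS)
  layout <- list(
    control = c(unfed = 9, short_feed = 16, tech_fail = 2, rating2 = 18,
                no_fly = 19, under = 12, over = 35),
    pesticide = c(unfed = 4, short_feed = 13, tech_fail = 2, rating2 = 18,
                  no_fly = 18, under = 24, over = 32))
  its_over <- list(
    control = c(seq(4.00, 4.25, by = 0.05),            # trimmed low
                seq(4.61, 5.11, by = 0.02),            # analysis set
                c(6.30, 6.35, 6.40)),                  # trimmed high
    pesticide = c(4.30,
                  seq(4.68, 5.20, by = 0.02),
                  c(6.10, 6.15, 6.20, 6.25)))

  build_arm <- function(trt) {
    lay <- layout[[trt]]
    n <- sum(lay)
    prefix <- if (trt == "control") "C" else "P"
    group <- rep(names(lay), lay)
    its <- rep(4.90, n)
    its[group == "over"] <- its_over[[trt]]
    tibble::tibble(
      bee_id = sprintf("%s%03d", prefix, seq_len(n)),
      colony_id = paste0("colony", rep_len(1:3, n)),
      treatment = trt,
      its_mm = its,
      wet_mass_mg = 240,
      tag_rating = ifelse(group == "rating2", 2L, 1L),
      fed = group != "unfed",
      feed_duration_s = dplyr::case_when(group == "unfed" ~ 0,
                                         group == "short_feed" ~ 45,
                                         TRUE ~ 150),
      technical_fail = group == "tech_fail",
      group = group)
  }
  bees <- dplyr::bind_rows(build_arm("control"), build_arm("pesticide"))

  as_circuits <- function(d) as.integer(round(d / circ))
  metric_row <- function(ids, dist, dur, mv, xv) {
    n_circ <- as_circuits(dist)
    tibble::tibble(
      bee_id = ids, n_circuits = n_circ,
      total_distance_m = n_circ * circ, total_duration_s = dur,
      mean_velocity_mps = mv, max_velocity_mps = xv,
      n_stoppages = 0L, flew = TRUE,
      over_100m = n_circ * circ > cfg$distance_threshold_m,
      over_2000s = dur > cfg$endurance_split_s,
      completed_cap = dur >= cfg$session_cap_s)
  }

  flyer_ids <- function(trt, grp) {
    bees$bee_id[bees$treatment == trt & bees$group == grp]
  }
  # under-threshold flyers: 59 circuits (~50 m), early terminations
  under <- metric_row(c(flyer_ids("control", "under"),
                        flyer_ids("pesticide", "under")),
                      dist = 59 * circ, dur = 80, mv = 0.60, xv = 0.9)

  ctrl_over <- flyer_ids("control", "over")      # 6 low, 26 mid, 3 high
  pest_over <- flyer_ids("pesticide", "over")    # 1 low, 27 mid, 4 high
  ctrl_mid <- ctrl_over[7:32]
  pest_mid <- pest_over[2:28]

  ctrl_mid_metrics <- metric_row(
    ctrl_mid,
    dist = 1833.9 + seq(-125, 125, by = 10),
    dur = c(rep(cfg$session_cap_s, 17), 2500, 2700, 2900, 3100,
            1200, 1400, 1500, 1700, 1900),
    mv = 0.63 + seq(-0.125, 0.125, by = 0.01),
    xv = 1.34 + seq(-0.125, 0.125, by = 0.01))
  pest_mid_metrics <- metric_row(
    pest_mid,
    dist = 659.1 + seq(-130, 130, by = 10),
    dur = c(2200, seq(500, 1750, by = 50)),
    mv = 0.84 + seq(-0.13, 0.13, by = 0.01),
    xv = 1.52 + seq(-0.13, 0.13, by = 0.01))
  trimmed_metrics <- metric_row(
    c(ctrl_over[c(1:6, 33:35)], pest_over[c(1, 29:32)]),
    dist = c(700, 800, 900, 1000, 1100, 1200, 2400, 2500, 2600,
             450, 500, 550, 600, 650),
    dur = c(rep(1800, 6), rep(cfg$session_cap_s, 3), rep(700, 5)),
    mv = c(rep(0.58, 6), rep(0.70, 3), rep(0.80, 5)),
    xv = c(rep(1.1, 6), rep(1.5, 3), rep(1.4, 5)))

  metrics <- dplyr::bind_rows(under, ctrl_mid_metrics, pest_mid_metrics,
                              trimmed_metrics)
  bees$group <- NULL
  list(bees = validate_bee_table(bees), metrics = metrics)
}
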