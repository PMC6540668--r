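# Independent brute-force reference implementations used to cross-check the
# vectorised pipeline. Deliberately written as plain element-by-element scans.

oracle_stoppages <- function(iv, cfg = protocol_config()) {
  n <- length(iv)
  stops <- integer(0)
  count <- 0
  n_in <- n
  term <- "none"
  for (i in seq_len(n)) {
    if (i > 1 && iv[i] > cfg$stoppage_threshold_s) {
      count <- count + 1
      if (count <= cfg$max_stoppages) {
        stops <- c(stops, i)
      } else {
        n_in <- i
        term <- "stoppage_budget"
        break
      }
    }
  }
  cum <- 0
  for (i in seq_len(n_in)) {
    cum <- cum + iv[i]
    if (cum >= cfg$session_cap_s) {
      if (i < n_in || term == "none") term <- "session_cap"
      n_in <- i
      break
    }
  }
  list(stoppages = stops[stops <= n_in], n_in_test = n_in,
       terminated_by = term)
}

oracle_exclusions <- function(n_in, stoppages, cfg = protocol_config()) {
  excl <- integer(0)
  for (i in seq_len(min(cfg$post_start_exclusion, n_in))) excl <- c(excl, i)
  for (k in stoppages) {
    for (j in seq_len(cfg$pre_stop_exclusion)) {
      if (k - j >= 1) excl <- c(excl, k - j)
    }
    excl <- c(excl, k)
    for (j in seq_len(cfg$post_stop_exclusion)) {
      if (k + j <= n_in) excl <- c(excl, k + j)
    }
  }
  sort(unique(excl))
}

oracle_metrics <- function(iv, n_in, excluded, cfg = protocol_config()) {
  iv_in <- iv[seq_len(n_in)]
  kept <- setdiff(seq_len(n_in), excluded)
  v <- cfg$circumference_m / iv_in[kept]
  list(
    total_distance_m = n_in * cfg$circumference_m,
    total_duration_s = sum(iv_in),
    mean_velocity_mps = if (length(kept) > 0) {
      (length(kept) * cfg$circumference_m) / sum(iv_in[kept])
    } else NA_real_,
    max_velocity_mps = if (length(kept) > 0) max(v) else NA_real_
  )
}

oracle_bins <- function(per_circuit, cfg = protocol_config()) {
  n_bins <- cfg$trajectory_window / cfg$bin_width
  out <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) * cfg$bin_width
    hi <- b * cfg$bin_width
    sel <- per_circuit$circuit_index > lo & per_circuit$circuit_index <= hi
    if (any(sel)) out[b] <- mean(per_circuit$velocity_mps[sel])
  }
  out
}

# random session generator for oracle comparisons; intentionally produces
# sessions with stoppages, near-threshold ties, first-circuit stalls, and
# occasional slow sessions that run into the 60-min cap
random_intervals <- function(n) {
  iv <- stats::runif(n, 0.3, 3)
  long <- stats::runif(n) < 0.04
  iv[long] <- cfg_default$stoppage_threshold_s + stats::rexp(sum(long), 1 / 15)
  tie <- stats::runif(n) < 0.02
  iv[tie] <- cfg_default$stoppage_threshold_s     # exactly at threshold: not a stoppage
  if (n > 0 && stats::runif(1) < 0.3) iv[1] <- 25 # first-circuit stall
  if (n > 0 && stats::runif(1) < 0.1) iv <- iv * 10  # slow session, may hit cap
  iv
}

cfg_default <- protocol_config()

random_log <- function(n, bee_id = "bee") {
  tibble::tibble(bee_id = bee_id, circuit_index = seq_len(n),
                 interval_s = random_intervals(n))
}

# sequential-filter reference for the cohort cascade (pooled sort trim)
oracle_cascade <- function(bees, metrics, cfg = protocol_config(),
                           feed_threshold_s = 60, trim_fraction = 0.10) {
  flew <- metrics$bee_id[metrics$flew]
  dist <- stats::setNames(metrics$total_distance_m, metrics$bee_id)
  keep <- bees
  counts <- list(started = keep)
  keep <- keep[keep$fed, ]; counts$fed <- keep
  keep <- keep[keep$feed_duration_s > feed_threshold_s, ]
  counts$fed_over_60s <- keep
  keep <- keep[!keep$technical_fail, ]; counts$no_technical_fail <- keep
  keep <- keep[keep$tag_rating == 1, ]; counts$tag_rating_1 <- keep
  keep <- keep[keep$bee_id %in% flew, ]; counts$flew <- keep
  keep <- keep[!is.na(dist[keep$bee_id]) &
                 dist[keep$bee_id] > cfg$distance_threshold_m, ]
  counts$over_100m <- keep
  n <- nrow(keep)
  k <- floor(trim_fraction * n + 0.5)
  if (k > 0) {
    ord <- order(keep$its_mm, keep$bee_id)
    drop <- c(ord[seq_len(k)], ord[seq(n - k + 1, n)])
    keep <- keep[-drop, ]
  }
  counts$its_trimmed <- keep
  lapply(counts, function(d) d$bee_id)
}

# random mini-cohort (bees + metrics) for cascade oracle checks
random_mini_cohort <- function(n = 20) {
  fed <- stats::runif(n) < 0.85
  bees <- tibble::tibble(
    bee_id = sprintf("b%03d", sample.int(999, n)),
    colony_id = sample(paste0("colony", 1:3), n, replace = TRUE),
    treatment = sample(c("control", "pesticide"), n, replace = TRUE),
    its_mm = round(stats::runif(n, 4, 6), 2),
    wet_mass_mg = 240,
    tag_rating = sample(1:2, n, replace = TRUE),
    fed = fed,
    feed_duration_s = ifelse(fed, round(stats::runif(n, 10, 250), 1), 0),
    technical_fail = stats::runif(n) < 0.05)
  fliers <- bees$bee_id[stats::runif(n) < 0.7]
  metrics <- tibble::tibble(
    bee_id = fliers,
    flew = TRUE,
    total_distance_m = round(stats::runif(length(fliers), 10, 2400), 1),
    total_duration_s = stats::runif(length(fliers), 60, 3600),
    mean_velocity_mps = stats::runif(length(fliers), 0.4, 1),
    max_velocity_mps = stats::runif(length(fliers), 1, 2),
    over_2000s = FALSE, completed_cap = FALSE)
  list(bees = bees, metrics = metrics)
}
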