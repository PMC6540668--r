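#' Flight-mill protocol configuration
#'
#' Bundles the physical and protocol constants that every processing step
#' depends on: the circuit circumference of the mill arm, the inter-event
#' interval above which a circuit is scored as a flight stoppage, the stoppage
#' budget, the session cap, the circuit-exclusion windows used when cleaning
#' velocities, and the thresholds and binning used downstream.
#'
#' Defaults encode the assay protocol this package was built around: a
#' 0.848 m circumference mill, stoppages defined as circuits lasting more than
#' 20 s, five permitted stoppages, a 60-minute session cap, exclusion of the
#' first five circuits of the session and of each restart (plus the circuit
#' preceding a stoppage), a 100 m endurance inclusion threshold, a 2000 s
#' endurance split, and velocity trajectories binned as 18 blocks of 50
#' circuits over the first 900 circuits.
#'
#' @param circumference_m Metres travelled per circuit (mill arm circumference).
#' @param stoppage_threshold_s Circuit duration (s) strictly above which the
#'   circuit is scored as a flight stoppage.
#' @param max_stoppages Number of stoppages permitted before the flight test
#'   is terminated.
#' @param session_cap_s Maximum session duration in seconds, stops included.
#' @param post_start_exclusion Circuits excluded at the start of the session.
#' @param post_stop_exclusion Circuits excluded directly after each stoppage.
#' @param pre_stop_exclusion Circuits excluded directly before each stoppage.
#' @param distance_threshold_m Minimum total distance (m, exclusive) for a
#'   session to enter the endurance/velocity analysis.
#' @param endurance_split_s Duration (s, exclusive) defining the binary
#'   long-flight outcome.
#' @param bin_width Circuits per velocity bin.
#' @param trajectory_window Number of leading circuits entering the velocity
#'   trajectory analysis; must be a multiple of `bin_width`.
#'
#' @return An object of class `protocol_config` (a named list).
#' @examples
#' cfg <- protocol_config()
#' cfg$circumference_m
#' @export
protocol_config <- function(circumference_m = 0.848,
                            stoppage_threshold_s = 20,
                            max_stoppages = 5,
                            session_cap_s = 3600,
                            post_start_exclusion = 5,
                            post_stop_exclusion = 5,
                            pre_stop_exclusion = 1,
                            distance_threshold_m = 100,
                            endurance_split_s = 2000,
                            bin_width = 50,
                            trajectory_window = 900) {
  cfg <- list(
    circumference_m = circumference_m,
    stoppage_threshold_s = stoppage_threshold_s,
    max_stoppages = max_stoppages,
    session_cap_s = session_cap_s,
    post_start_exclusion = post_start_exclusion,
    post_stop_exclusion = post_stop_exclusion,
    pre_stop_exclusion = pre_stop_exclusion,
    distance_threshold_m = distance_threshold_m,
    endurance_split_s = endurance_split_s,
    bin_width = bin_width,
    trajectory_window = trajectory_window
  )
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num)) {
    stop("protocol_config: all fields must be finite numeric scalars: ",
         paste(names(cfg)[!num], collapse = ", "), call. = FALSE)
  }
  if (any(unlist(cfg) <= 0)) {
    stop("protocol_config: all fields must be strictly positive", call. = FALSE)
  }
  if (cfg$trajectory_window %% cfg$bin_width != 0) {
    stop("protocol_config: trajectory_window must be divisible by bin_width",
         call. = FALSE)
  }
  structure(cfg, class = "protocol_config")
}

#' Read a protocol configuration from a YAML or JSON file
#'
#' Fields absent from the file keep their [protocol_config()] defaults;
#' unknown fields are an error (they are almost always typos).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file of config fields.
#' @return A `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("read_protocol_config: unsupported extension '", ext, "'", call. = FALSE)
  )
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(protocol_config)))
  if (length(unknown) > 0) {
    stop("read_protocol_config: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(protocol_config, vals)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("<protocol_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Circuits needed to cover a distance
#'
#' Smallest whole number of circuits whose combined length reaches a target
#' distance; e.g. 118 circuits of a 0.848 m mill arm are needed to cover
#' 100 m.
#'
#' @param distance_m Target distance in metres (> 0).
#' @param circumference_m Metres per circuit (> 0).
#' @return Integer circuit count.
#' @examples
#' circuits_for_distance(100, 0.848)
#' @export
circuits_for_distance <- function(distance_m, circumference_m = 0.848) {
  if (!is.numeric(distance_m) || !is.numeric(circumference_m) ||
      any(distance_m <= 0) || any(circumference_m <= 0)) {
    stop("circuits_for_distance: inputs must be positive", call. = FALSE)
  }
  as.integer(ceiling(distance_m / circumference_m - 1e-9))
}
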