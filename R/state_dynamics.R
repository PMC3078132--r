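## Two-state segmentation of tilt-angle series into extended ("R",
## bellflower-like) and bent ("L", pinwheel-like) conformations, with
## hysteresis thresholds, dwell-time filtering, and transition detection.

STATE_EXTENDED <- "extended"
STATE_BENT <- "bent"
STATE_UNDECIDED <- "undecided"

#' Hysteresis classification of tilt-angle frames
#'
#' Two-threshold rule: the label switches to `"extended"` when theta rises
#' to `theta_up` or above, to `"bent"` when it falls to `theta_down` or
#' below, and otherwise keeps its previous value. Frames before the first
#' threshold crossing are `"undecided"`. The dead band between the
#' thresholds suppresses chatter when theta fluctuates near a single
#' boundary.
#'
#' @param theta numeric vector of tilt angles (degrees per frame).
#' @param theta_up upper threshold (degrees); entering at or above it labels
#'   the frame extended. Default 35.
#' @param theta_down lower threshold (degrees); at or below it labels the
#'   frame bent. Default 28. Must be strictly less than `theta_up`.
#' @return character vector of per-frame labels
#'   (`"extended"`, `"bent"`, `"undecided"`).
#' @export
classify_states <- function(theta, theta_up = 35, theta_down = 28) {
  if (!is_scalar_number(theta_up) || !is_scalar_number(theta_down) ||
      theta_down >= theta_up)
    pd_stop("thresholds must satisfy theta_down < theta_up",
            "configuration_error")
  theta <- as.numeric(theta)
  if (anyNA(theta)) pd_stop("theta contains NA", "contract_violation")
  n <- length(theta)
  labels <- character(n)
  cur <- STATE_UNDECIDED
  for (i in seq_len(n)) {
    if (theta[i] >= theta_up) cur <- STATE_EXTENDED
    else if (theta[i] <= theta_down) cur <- STATE_BENT
    labels[i] <- cur
  }
  labels
}

label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values,
             start = ends - r$lengths + 1L,
             end = ends,
             stringsAsFactors = FALSE)
}

## run duration convention: start-to-next-start; the last run extends to the
## final timestamp. This makes dwell times plus the undecided prefix sum
## exactly to the total duration.
run_durations <- function(runs, times) {
  n <- nrow(runs)
  starts <- times[runs$start]
  c(if (n > 1L) diff(starts), times[length(times)] - starts[n])
}

#' Dwell-time filtering and transition detection
#'
#' Label runs shorter than `min_dwell_ps` are merged into the flanking
#' state (shortest first), removing spurious blips; transitions are then
#' reported at the first frame of each surviving new run. Dwell times use
#' the start-to-next-start convention (the final run extends to the last
#' timestamp), so per-state dwell times plus any undecided prefix sum to the
#' total duration.
#'
#' @param labels per-frame labels from [classify_states()].
#' @param times frame times in ps, aligned with `labels`.
#' @param min_dwell_ps minimum dwell time (ps) for a run to survive
#'   (default 1000, i.e. 1 ns).
#' @return object of class `StateSegmentation`: list with `times`, `labels`
#'   (after merging), `transitions` (data frame `time_ps`, `from`, `to`),
#'   `dwell_times` (per-state list of ps), `min_dwell_ps`.
#' @export
detect_transitions <- function(labels, times, min_dwell_ps = 1000) {
  if (length(labels) != length(times))
    pd_stop("labels and times must be aligned", "contract_violation")
  if (length(labels) == 0L)
    pd_stop("empty segmentation input", "insufficient_data_error")
  decided <- labels != STATE_UNDECIDED
  first_dec <- if (any(decided)) which(decided)[1] else NA_integer_
  merged <- labels
  if (!is.na(first_dec)) {
    dl <- labels[decided]
    dt <- times[decided]
    runs <- label_runs(dl)
    repeat {
      if (nrow(runs) <= 1L) break
      dur <- run_durations(runs, dt)
      short <- which(dur < min_dwell_ps)
      if (length(short) == 0L) break
      k <- short[which.min(dur[short])]
      ## absorb into the neighbouring state (both flanks share a state in an
      ## alternating sequence; at the edges only one flank exists)
      absorb <- if (k == 1L) runs$state[2L] else runs$state[k - 1L]
      runs$state[k] <- absorb
      r <- rle(runs$state)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      runs <- data.frame(state = r$values,
                         start = runs$start[starts_i],
                         end = runs$end[ends_i],
                         stringsAsFactors = FALSE)
    }
    dl_merged <- rep(runs$state, runs$end - runs$start + 1L)
    merged[decided] <- dl_merged
    dur <- run_durations(runs, dt)
    transitions <- if (nrow(runs) > 1L)
      data.frame(time_ps = dt[runs$start[-1L]],
                 from = runs$state[-nrow(runs)],
                 to = runs$state[-1L],
                 stringsAsFactors = FALSE)
    else data.frame(time_ps = numeric(0), from = character(0),
                    to = character(0), stringsAsFactors = FALSE)
    dwell <- list(extended = dur[runs$state == STATE_EXTENDED],
                  bent = dur[runs$state == STATE_BENT])
  } else {
    transitions <- data.frame(time_ps = numeric(0), from = character(0),
                              to = character(0), stringsAsFactors = FALSE)
    dwell <- list(extended = numeric(0), bent = numeric(0))
  }
  structure(list(times = times, labels = merged, transitions = transitions,
                 dwell_times = dwell, min_dwell_ps = min_dwell_ps),
            class = "StateSegmentation")
}

#' @export
print.StateSegmentation <- function(x, ...) {
  cat(sprintf("<StateSegmentation> %d frames, %d transitions, min dwell %g ps\n",
              length(x$times), nrow(x$transitions), x$min_dwell_ps))
  invisible(x)
}

#' Classify and segment a tilt-angle series in one call
#'
#' @inheritParams classify_states
#' @inheritParams detect_transitions
#' @return a `StateSegmentation`.
#' @export
segment_states <- function(theta, times, theta_up = 35, theta_down = 28,
                           min_dwell_ps = 1000) {
  detect_transitions(classify_states(theta, theta_up, theta_down), times,
                     min_dwell_ps)
}

#' State occupancy fractions
#'
#' Fractions of decided frames spent in each state; they sum to 1.
#'
#' @param seg a `StateSegmentation`.
#' @return named numeric vector `c(extended = ..., bent = ...)`.
#' @export
occupancy <- function(seg) {
  decided <- seg$labels != STATE_UNDECIDED
  if (!any(decided))
    pd_stop("no decided frames: occupancy undefined", "insufficient_data_error")
  n <- sum(decided)
  c(extended = sum(seg$labels == STATE_EXTENDED) / n,
    bent = sum(seg$labels == STATE_BENT) / n)
}

#' Write a segmentation as TSV (+ JSON transition list)
#' @param seg a `StateSegmentation`.
#' @param theta the theta series the segmentation was computed from.
#' @param path output TSV path; the transition list goes to
#'   `paste0(path, ".transitions.json")`.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, theta, path) {
  utils::write.table(
    data.frame(time_ps = seg$times, theta_deg = theta, label = seg$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(seg$transitions,
                       paste0(path, ".transitions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
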