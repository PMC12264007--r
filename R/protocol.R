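#' Urodynamic filling/emptying protocol
#'
#' A `protocol_spec` is an ordered list of phases, each with a label, a
#' duration in seconds and a signed pump rate in ml/min (positive =
#' infusion, negative = withdrawal, zero = pump off), plus the sampling
#' rate of the pressure recording.
#'
#' The default protocol mirrors a urodynamically controlled micturition
#' experiment: 5 min baseline, 6 min 40 s filling at 90 ml/min (600 ml),
#' a hold, a further 1 min fill, a second hold, 7 min 40 s emptying at
#' 90 ml/min, and a 2 min 20 s washout.  The two holds default to 97 s
#' each so that the post-baseline experiment period is exactly 1254
#' frames at 1 Hz (80/20 split: 1004/250).
#'
#' @param phases data.frame with columns `label`, `duration_s`,
#'   `pump_rate_ml_min`.  Defaults to the protocol above.
#' @param sampling_rate_hz sampling rate of the simulated pressure trace
#'   (Hz); default 1.
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(phases = default_protocol_phases(),
                          sampling_rate_hz = 1) {
  stopifnot(is.data.frame(phases),
            all(c("label", "duration_s", "pump_rate_ml_min") %in% names(phases)))
  if (any(phases$duration_s <= 0)) {
    stop("phase durations must be > 0")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be > 0")
  }
  off <- phases$label %in% c("baseline", "hold1", "hold2", "washout")
  if (any(phases$pump_rate_ml_min[off] != 0)) {
    stop("pump_rate must be 0 in baseline/hold/washout phases")
  }
  fills <- phases$label %in% c("fill1", "fill2")
  if (any(phases$pump_rate_ml_min[fills] < 0)) {
    stop("negative pump rate in a fill phase")
  }
  structure(list(phases = phases, sampling_rate_hz = sampling_rate_hz),
            class = "protocol_spec")
}

#' @rdname protocol_spec
#' @export
default_protocol_phases <- function() {
  data.frame(
    label = c("baseline", "fill1", "hold1", "fill2", "hold2",
              "empty", "washout"),
    duration_s = c(300, 400, 97, 60, 97, 460, 140),
    pump_rate_ml_min = c(0, 90, 0, 90, 0, -90, 0),
    stringsAsFactors = FALSE
  )
}

#' Total protocol duration in seconds
#' @param protocol a `protocol_spec`
#' @return duration in seconds
#' @export
protocol_duration <- function(protocol) {
  sum(protocol$phases$duration_s)
}

#' Number of experiment-period frames (post-baseline) at the protocol
#' sampling rate
#' @param protocol a `protocol_spec`
#' @return frame count
#' @export
protocol_experiment_frames <- function(protocol) {
  ph <- protocol$phases
  post <- ph$label != "baseline"
  as.integer(round(sum(ph$duration_s[post]) * protocol$sampling_rate_hz))
}

#' Cumulative infused volume at the end of a phase
#'
#' Integrates the signed pump rate from the protocol start through the
#' end of the named phase.
#'
#' @param protocol a `protocol_spec`
#' @param through_phase label of the last phase to include
#' @return volume in ml (signed net)
#' @export
protocol_volume <- function(protocol, through_phase) {
  ph <- protocol$phases
  idx <- match(through_phase, ph$label)
  if (is.na(idx)) stop("unknown phase label: ", through_phase)
  sum(ph$pump_rate_ml_min[seq_len(idx)] / 60 * ph$duration_s[seq_len(idx)])
}

#' Per-sample phase labels on the protocol time grid
#' @param protocol a `protocol_spec`
#' @return character vector, one label per sample
#' @export
protocol_phase_labels <- function(protocol) {
  fs <- protocol$sampling_rate_hz
  n_per <- round(protocol$phases$duration_s * fs)
  rep(protocol$phases$label, times = n_per)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Urodynamic protocol:", nrow(x$phases), "phases,",
      protocol_duration(x), "s total at", x$sampling_rate_hz, "Hz\n")
  print(x$phases, row.names = FALSE)
  invisible(x)
}
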