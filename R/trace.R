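#' Simulate an intravesical bladder-pressure trace
#'
#' Pressure follows a compliance + viscoelastic model
#' \deqn{P(t) = P_0 + k V(t) + c R(t) + \epsilon(t)}
#' where \eqn{V(t)} integrates the signed pump rate (clamped at 0 ml) and
#' \eqn{R(t)} is a viscoelastic stress that builds while saline is being
#' infused and relaxes as \eqn{\exp(-\Delta t/\tau)} when the pump stops.
#' The relaxation reproduces the accommodation (pressure drop) seen
#' during hold periods of a cystometric fill at a high rate.
#'
#' The viscoelastic gain `c` is derived from `drop_frac`: the
#' steady-state viscoelastic contribution at the end of the first fill is
#' set to `drop_frac/(1-drop_frac)` of the compliance pressure reached
#' there, so a full relaxation during a long hold would drop pressure by
#' approximately `drop_frac` of its value at hold onset.
#'
#' @param protocol a [protocol_spec()]
#' @param params list with elements `P0` (resting pressure, cmH2O),
#'   `k` (compliance slope, cmH2O/ml), `tau` (viscoelastic relaxation
#'   time, s), `drop_frac` (fractional hold-onset accommodation drop) and
#'   `noise_sd` (cmH2O).  Missing elements take defaults
#'   `P0=10, k=0.03, tau=40, drop_frac=0.15, noise_sd=0.5`.
#' @param seed integer seed; the trace is bit-reproducible per seed.
#' @return object of class `bladder_trace`: list with `time_s`,
#'   `pressure_cmH2O`, `phase`, `sampling_rate_hz`,
#'   `reference_window_s` (30) and the realised `params`.
#' @export
simulate_bladder_pressure <- function(protocol = protocol_spec(),
                                      params = list(), seed = 1L) {
  p <- utils::modifyList(
    list(P0 = 10, k = 0.03, tau = 40, drop_frac = 0.15, noise_sd = 0.5),
    params)
  if (p$tau <= 0) stop("relaxation time constant tau must be > 0")
  if (p$k <= 0) stop("compliance k must be > 0")
  if (p$drop_frac < 0 || p$drop_frac >= 1) stop("drop_frac must be in [0,1)")

  fs <- protocol$sampling_rate_hz
  dt <- 1 / fs
  labels <- protocol_phase_labels(protocol)
  n <- length(labels)
  rate_ml_s <- rep(protocol$phases$pump_rate_ml_min / 60,
                   times = round(protocol$phases$duration_s * fs))

  # volume: integrate pump rate, never below empty
  V <- numeric(n)
  R <- numeric(n)
  decay <- exp(-dt / p$tau)
  v <- 0; r <- 0
  for (i in seq_len(n)) {
    u <- rate_ml_s[i]
    v <- max(0, v + u * dt)
    # exact discrete update of dR/dt = max(u,0) - R/tau over one step
    inflow <- max(u, 0)
    r <- r * decay + inflow * p$tau * (1 - decay)
    V[i] <- v
    R[i] <- r
  }

  # calibrate viscoelastic gain against the first fill's end state
  v_fill1 <- protocol_volume(protocol, "fill1")
  rate1 <- protocol$phases$pump_rate_ml_min[protocol$phases$label == "fill1"] / 60
  dur1 <- protocol$phases$duration_s[protocol$phases$label == "fill1"]
  R_fill1 <- rate1 * p$tau * (1 - exp(-dur1 / p$tau))
  c_gain <- if (R_fill1 > 0) {
    p$drop_frac / (1 - p$drop_frac) * (p$P0 + p$k * v_fill1) / R_fill1
  } else 0

  noise <- if (p$noise_sd > 0) {
    withr_seed(seed, stats::rnorm(n, 0, p$noise_sd))
  } else numeric(n)

  pressure <- p$P0 + p$k * V + c_gain * R + noise
  structure(list(
    time_s = seq(0, by = dt, length.out = n),
    pressure_cmH2O = pressure,
    phase = labels,
    sampling_rate_hz = fs,
    reference_window_s = 30,
    volume_ml = V,
    params = c(p, list(c_gain = c_gain, seed = seed))
  ), class = "bladder_trace")
}

# evaluate expr with a locally-scoped RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Percent change of bladder pressure relative to the first 30 s
#'
#' \deqn{\%BP(t) = 100 (P(t) - \bar P_{30}) / \bar P_{30}} with
#' \eqn{\bar P_{30}} the mean pressure over the first 30 s of recording.
#'
#' @param trace a `bladder_trace`
#' @return numeric vector, same length as the trace
#' @export
percent_bp <- function(trace) {
  stopifnot(inherits(trace, "bladder_trace"))
  fs <- trace$sampling_rate_hz
  n_ref <- round(trace$reference_window_s * fs)
  if (length(trace$pressure_cmH2O) < n_ref) {
    stop("trace must cover at least the ", trace$reference_window_s,
         " s reference window")
  }
  ref <- mean(trace$pressure_cmH2O[seq_len(n_ref)])
  if (ref <= 0) stop("degenerate reference: mean pressure over first 30 s <= 0")
  100 * (trace$pressure_cmH2O - ref) / ref
}

#' @export
print.bladder_trace <- function(x, ...) {
  cat(sprintf(
    "bladder_trace: %d samples at %g Hz, pressure %.1f-%.1f cmH2O\n",
    length(x$time_s), x$sampling_rate_hz,
    min(x$pressure_cmH2O), max(x$pressure_cmH2O)))
  invisible(x)
}
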