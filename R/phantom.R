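#' Power-Doppler image stack container
#'
#' A `pd_stack` holds a depth x width x time array of non-negative power
#' Doppler values together with acquisition metadata.  Rows index depth
#' (increasing downward, mirroring the ultrasound display), columns index
#' lateral width, the third dimension is time.
#'
#' @param data 3D numeric array (depth_px x width_px x frames), finite
#' @param pixel_pitch_mm pixel pitch in mm (default 0.1)
#' @param frame_rate_hz frame rate in Hz (default 1)
#' @param baseline_frames number of leading frames forming the baseline
#'   window (default 300 = 5 min at 1 Hz)
#' @param metadata free-form list (subject id, FOV, ...)
#' @return object of class `pd_stack`
#' @export
pd_stack <- function(data, pixel_pitch_mm = 0.1, frame_rate_hz = 1,
                     baseline_frames = 300, metadata = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("pd_stack data must be finite")
  if (baseline_frames >= dim(data)[3]) {
    stop("baseline_frames must be smaller than the frame count")
  }
  structure(list(data = data,
                 pixel_pitch_mm = pixel_pitch_mm,
                 frame_rate_hz = frame_rate_hz,
                 baseline_frames = as.integer(baseline_frames),
                 metadata = metadata),
            class = "pd_stack")
}

#' @export
print.pd_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("pd_stack: %d x %d px, %d frames at %g Hz (%g mm pitch, %d baseline frames)\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$pixel_pitch_mm,
              x$baseline_frames))
  invisible(x)
}

#' Gamma-shaped hemodynamic response kernel
#'
#' Unit-sum, non-negative kernel used to smear the pressure regressor
#' into a hemodynamic response.  fUSI hemodynamics are fast, so the
#' default peaks at 3 s and lasts 15 s.
#'
#' @param time_to_peak_s kernel mode (s)
#' @param length_s kernel support (s)
#' @param fs sampling rate (Hz)
#' @return numeric kernel summing to 1
#' @export
hrf_kernel <- function(time_to_peak_s = 3, length_s = 15, fs = 1) {
  t <- seq(0, length_s - 1 / fs, by = 1 / fs)
  shape <- 2
  rate <- (shape - 1) / time_to_peak_s   # mode of gamma = (shape-1)/rate
  k <- t^(shape - 1) * exp(-rate * t)
  k / sum(k)
}

#' Ground truth for a synthetic phantom
#'
#' Defines the planted structure a recovery test must find: disjoint
#' positively and negatively pressure-coupled pixel regions, per-pixel
#' coupling gains (percent signal change at unit normalized response),
#' the hemodynamic kernel, noise and drift settings.
#'
#' Default regions are two ellipses, each covering about 5% of the
#' grid — deliberately matched to the top-5% fraction the activation
#' analysis extracts, so that recovered masks and planted truth have
#' comparable support — sitting on an elevated vascular bed so that
#' planted pixels have vessel-like baseline signal.
#'
#' @param n_depth,n_width grid size in pixels (defaults 91 x 128,
#'   i.e. 9.1 mm x 12.8 mm at 0.1 mm pitch)
#' @param pos_mask,neg_mask optional logical matrices; defaults planted
#'   as described
#' @param gain_pos,gain_neg peak percent signal change of the planted
#'   regions (defaults +120 / -40, the regime of strongly coupled
#'   spinal-cord pixels)
#' @param hrf unit-sum kernel (default [hrf_kernel()]); pass `1` for an
#'   identity kernel
#' @param noise_sd white Gaussian noise SD as a *percentage of the
#'   per-pixel baseline* (default 5, i.e. each pixel fluctuates with SD
#'   5% of its own mean pD).  Power-Doppler variance scales with local
#'   power, so proportional noise is the physiological choice and makes
#'   the percent-change noise floor uniform across bright vessels and
#'   dim background alike
#' @param drift_amplitude amplitude of the shared low-frequency drift
#'   (pD units); defaults to 0 because any drift below the lowpass
#'   passband correlates with the slow pressure regressor and thereby
#'   couples *every* pixel to it, leaving no null for recovery tests
#' @param seed integer seed
#' @return object of class `phantom_truth`
#' @export
phantom_truth <- function(n_depth = 91, n_width = 128,
                          pos_mask = NULL, neg_mask = NULL,
                          gain_pos = 120, gain_neg = -40,
                          hrf = hrf_kernel(), noise_sd = 5,
                          drift_amplitude = 0, seed = 1L) {
  if (is.null(pos_mask)) {
    pos_mask <- ellipse_mask(n_depth, n_width,
                             center = c(0.28, 0.32), radii = c(0.114, 0.14))
  }
  if (is.null(neg_mask)) {
    neg_mask <- ellipse_mask(n_depth, n_width,
                             center = c(0.28, 0.68), radii = c(0.114, 0.14))
  }
  n_depth <- as.integer(n_depth); n_width <- as.integer(n_width)
  stopifnot(identical(dim(pos_mask), c(n_depth, n_width)),
            identical(dim(neg_mask), c(n_depth, n_width)))
  if (any(pos_mask & neg_mask)) stop("pos_mask and neg_mask overlap")
  if (abs(sum(hrf) - 1) > 1e-9) stop("hrf kernel must sum to 1")
  gains <- matrix(0, n_depth, n_width)
  gains[pos_mask] <- gain_pos
  gains[neg_mask] <- gain_neg
  structure(list(n_depth = n_depth, n_width = n_width,
                 pos_mask = pos_mask, neg_mask = neg_mask,
                 null_mask = !(pos_mask | neg_mask),
                 gains = gains, hrf_kernel = hrf,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 motion_truth = NULL, seed = as.integer(seed)),
            class = "phantom_truth")
}

# elliptical mask with fractional center/radii
ellipse_mask <- function(n_depth, n_width, center, radii) {
  r0 <- center[1] * n_depth; c0 <- center[2] * n_width
  ra <- radii[1] * n_depth;  rb <- radii[2] * n_width
  rr <- matrix(seq_len(n_depth), n_depth, n_width)
  cc <- matrix(seq_len(n_width), n_depth, n_width, byrow = TRUE)
  ((rr - r0) / ra)^2 + ((cc - c0) / rb)^2 <= 1
}

#' Convolve and normalize the pressure regressor
#'
#' Causal convolution of the %BP series with the hemodynamic kernel,
#' rescaled so the absolute peak is 1.
#'
#' @param pct_bp %BP series
#' @param hrf unit-sum kernel or scalar 1
#' @return normalized response series, same length
#' @export
hemodynamic_response <- function(pct_bp, hrf = hrf_kernel()) {
  if (length(hrf) == 1) {
    resp <- pct_bp * hrf
  } else {
    n <- length(pct_bp)
    resp <- stats::convolve(c(pct_bp, numeric(length(hrf))), rev(hrf),
                            type = "open")[seq_len(n)]
  }
  peak <- max(abs(resp))
  if (peak == 0) stop("flat pressure regressor: cannot normalize")
  resp / peak
}

#' Generate a synthetic pD phantom stack with planted coupling
#'
#' Per-pixel signal model:
#' \deqn{S(p,t) = B(p)\,(1 + g(p)\,h(t)/100) + d(t) + \epsilon(p,t)}
#' where `B` is a vascular baseline map (bright curvilinear vessels on a
#' dim background, planted regions on an elevated bed), `g` the coupling
#' gain in percent, `h` the hemodynamic response (kernel-convolved,
#' peak-normalized %BP), `d` a shared low-frequency drift and `eps`
#' white noise.  Deterministic per `truth$seed`.
#'
#' @param truth a [phantom_truth()]
#' @param bp a `bladder_trace` sampled at the stack frame rate
#' @param protocol the [protocol_spec()] used for `bp` (fixes the
#'   baseline window length)
#' @return list with elements `stack` (a [pd_stack()]), `truth` (with
#'   `baseline_map` and `response` attached)
#' @export
generate_phantom <- function(truth = phantom_truth(),
                             bp = NULL,
                             protocol = protocol_spec()) {
  if (is.null(bp)) {
    bp <- simulate_bladder_pressure(protocol, seed = truth$seed)
  }
  fs <- protocol$sampling_rate_hz
  n_t <- length(bp$time_s)
  nd <- truth$n_depth; nw <- truth$n_width

  resp <- hemodynamic_response(percent_bp(bp), truth$hrf_kernel)

  withr_seed(truth$seed, {
    B <- vascular_baseline_map(nd, nw, truth)
    signal <- array(0, dim = c(nd, nw, n_t))
    gain_t <- 1 + outer(as.vector(truth$gains), resp) / 100  # pix x t
    signal[] <- as.vector(B) * gain_t
    if (truth$drift_amplitude > 0) {
      freqs <- stats::runif(3, 0.002, 0.008)
      phases <- stats::runif(3, 0, 2 * pi)
      tgrid <- seq(0, by = 1 / fs, length.out = n_t)
      drift <- truth$drift_amplitude / 3 *
        colSums(sin(2 * pi * outer(freqs, tgrid) + phases))
      signal <- signal + rep(drift, each = nd * nw)
    }
    if (truth$noise_sd > 0) {
      signal <- signal + stats::rnorm(length(signal)) *
        as.vector(B) * (truth$noise_sd / 100)
    }
  })

  baseline_frames <- round(protocol$phases$duration_s[
    protocol$phases$label == "baseline"] * fs)
  stack <- pd_stack(signal, pixel_pitch_mm = 0.1, frame_rate_hz = fs,
                    baseline_frames = baseline_frames,
                    metadata = list(subject = "synthetic",
                                    fov_mm = c(nd, nw) * 0.1,
                                    seed = truth$seed))
  truth$baseline_map <- B
  truth$response <- resp
  list(stack = stack, truth = truth)
}

# curvilinear bright vessels over a dim background; planted regions get
# an elevated vascular bed so their baseline is vessel-like
vascular_baseline_map <- function(nd, nw, truth) {
  B <- matrix(15, nd, nw)
  # smooth multiplicative texture
  B <- B * (1 + 0.1 * smooth_noise_field(nd, nw, sigma = 4))
  n_vessels <- max(3L, round(nw / 20))
  rows <- matrix(seq_len(nd), nd, nw)
  for (v in seq_len(n_vessels)) {
    r0 <- stats::runif(1, 0.1, 0.9) * nd
    amp <- stats::runif(1, 0.1, 0.25) * nd
    per <- stats::runif(1, 0.5, 2)
    ph <- stats::runif(1, 0, 2 * pi)
    width <- stats::runif(1, 1, 2.5)
    peak <- stats::runif(1, 100, 180)
    center <- r0 + amp * sin(2 * pi * per * seq_len(nw) / nw + ph)
    prof <- exp(-(rows - rep(center, each = nd))^2 / (2 * width^2))
    B <- B + peak * prof
  }
  bed <- truth$pos_mask | truth$neg_mask
  B[bed] <- B[bed] + 80
  B
}

# isotropically smoothed white noise, standardized
smooth_noise_field <- function(nd, nw, sigma) {
  z <- matrix(stats::rnorm(nd * nw), nd, nw)
  half <- min(ceiling(3 * sigma), floor((min(nd, nw) - 1) / 2))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2,
                                               circular = TRUE))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2,
                                                 circular = TRUE)))
  (z - mean(z)) / stats::sd(z)
}

#' Noise SD giving a target coupling SNR
#'
#' With proportional noise, the SNR of a planted pixel is the SD of its
#' coupled percent-signal component, `|gain| * sd(response)`, divided by
#' the percent noise floor.  This helper inverts that definition at the
#' weakest planted gain, so `snr` is a floor over planted pixels.
#'
#' @param truth a [phantom_truth()]
#' @param resp normalized response series (see
#'   [hemodynamic_response()])
#' @param snr target signal-to-noise ratio
#' @return noise SD in percent of baseline (the [phantom_truth()]
#'   `noise_sd` convention)
#' @export
noise_sd_for_snr <- function(truth, resp, snr) {
  gmin <- min(abs(truth$gains[truth$gains != 0]))
  gmin * stats::sd(resp) / snr
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom_truth: %d x %d grid, %d pos / %d neg planted px, noise_sd=%g, seed=%d\n",
    x$n_depth, x$n_width, sum(x$pos_mask), sum(x$neg_mask),
    x$noise_sd, x$seed))
  invisible(x)
}
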