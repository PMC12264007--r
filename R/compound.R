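#' Simulate a block of compounded ultrafast frames
#'
#' Emulates one 400 ms block of 200 post-beamforming compound frames at
#' 500 Hz, as the sum of three components in the complex domain:
#' low-rank tissue clutter (spatially smooth modes with slowly varying
#' temporal weights and large amplitude), blood signal (vessel-mask
#' pixels rotating in phase at a per-pixel Doppler frequency), and
#' complex white noise.  Deterministic per seed.
#'
#' @param n_depth,n_width spatial grid (defaults 64 x 64; the full
#'   imaging grid is 91 x 128)
#' @param n_frames frames per block (default 200)
#' @param frame_rate_hz block frame rate (default 500)
#' @param tissue_rank number of tissue modes (default 5)
#' @param tissue_amp,blood_amp component amplitudes; tissue must
#'   dominate (defaults 100 and 1)
#' @param vessel_mask logical matrix of blood pixels; default a few
#'   vertical vessel segments covering ~4% of the grid
#' @param doppler_freq_hz range of per-pixel Doppler frequencies; all
#'   must be below Nyquist (`frame_rate_hz/2`)
#' @param noise_sd complex noise SD per real/imag part
#' @param seed integer seed
#' @return object of class `compound_block`: list with `frames`
#'   (complex array depth x width x frames), `tissue_rank`,
#'   `vessel_mask`, `doppler_freqs` (matrix, NA off-vessel),
#'   `frame_rate_hz`, `blood_amp`
#' @export
generate_compound_block <- function(n_depth = 64, n_width = 64,
                                    n_frames = 200, frame_rate_hz = 500,
                                    tissue_rank = 5, tissue_amp = 100,
                                    blood_amp = 1, vessel_mask = NULL,
                                    doppler_freq_hz = c(30, 150),
                                    noise_sd = 0.1, seed = 1L) {
  if (any(doppler_freq_hz >= frame_rate_hz / 2)) {
    stop("doppler frequency at or above Nyquist (", frame_rate_hz / 2, " Hz)")
  }
  if (tissue_rank > 0 && tissue_amp < blood_amp) {
    stop("tissue amplitude must be >= blood amplitude")
  }
  withr_seed(seed, {
    if (is.null(vessel_mask)) {
      vessel_mask <- matrix(FALSE, n_depth, n_width)
      for (v in 1:3) {
        col <- sample.int(n_width - 2, 1) + 1
        rows <- sort(sample.int(n_depth, 2))
        vessel_mask[rows[1]:rows[2], col + (-1:0)] <- TRUE
      }
    }
    npix <- n_depth * n_width
    t_idx <- seq_len(n_frames)
    # tissue: rank-limited, smooth in space, near-constant in time
    if (tissue_rank > 0) {
      U <- vapply(seq_len(tissue_rank),
                  function(k) as.vector(smooth_noise_field(n_depth, n_width,
                                                           sigma = 6)),
                  numeric(npix))
      amps <- tissue_amp * 0.3^(seq_len(tissue_rank) - 1)
      Vt <- vapply(seq_len(tissue_rank), function(k) {
        1 + 0.02 * sin(2 * pi * stats::runif(1, 0.5, 2) * t_idx / n_frames +
                         stats::runif(1, 0, 2 * pi))
      }, numeric(n_frames))
      tissue <- U %*% (amps * t(Vt))
    } else {
      tissue <- matrix(0, npix, n_frames)
    }
    phase0 <- matrix(stats::runif(npix, 0, 2 * pi), n_depth, n_width)
    freqs <- matrix(NA_real_, n_depth, n_width)
    freqs[vessel_mask] <- stats::runif(sum(vessel_mask),
                                       doppler_freq_hz[1], doppler_freq_hz[2])
    casorati <- tissue * (1 + 0i)
    if (any(vessel_mask)) {
      vidx <- which(vessel_mask)
      ph <- outer(freqs[vidx], t_idx / frame_rate_hz) * 2 * pi +
        phase0[vidx]
      casorati[vidx, ] <- casorati[vidx, ] + blood_amp * exp(1i * ph)
    }
    if (noise_sd > 0) {
      casorati <- casorati +
        complex(real = stats::rnorm(npix * n_frames, 0, noise_sd),
                imaginary = stats::rnorm(npix * n_frames, 0, noise_sd))
    }
  })
  structure(list(frames = array(casorati, dim = c(n_depth, n_width, n_frames)),
                 tissue_rank = tissue_rank, vessel_mask = vessel_mask,
                 doppler_freqs = freqs, frame_rate_hz = frame_rate_hz,
                 blood_amp = blood_amp),
            class = "compound_block")
}

#' SVD clutter filter: compound block to power-Doppler image
#'
#' Reshapes the block into its Casorati (space x time) matrix, removes
#' the `cutoff_rank` largest singular components (the slowly varying,
#' spatially coherent tissue clutter), and returns the per-pixel mean
#' squared magnitude of the residual — the power Doppler estimate, a
#' proxy for local blood volume.
#'
#' @param block a `compound_block`
#' @param cutoff_rank number of leading singular components to remove;
#'   must satisfy `0 <= cutoff_rank < n_frames` (default 20)
#' @return non-negative matrix (depth x width) of pD values
#' @export
svd_clutter_filter <- function(block, cutoff_rank = 20) {
  stopifnot(inherits(block, "compound_block"))
  d <- dim(block$frames)
  if (cutoff_rank < 0 || cutoff_rank >= d[3]) {
    stop("cutoff_rank must be in [0, n_frames)")
  }
  M <- matrix(block$frames, nrow = d[1] * d[2])
  if (cutoff_rank == 0) {
    pd <- rowMeans(Mod(M)^2)
  } else {
    s <- svd(M)
    k <- seq_len(cutoff_rank)
    clutter <- s$u[, k, drop = FALSE] %*%
      (s$d[k] * Conj(t(s$v[, k, drop = FALSE])))
    pd <- rowMeans(Mod(M - clutter)^2)
  }
  matrix(pd, d[1], d[2])
}
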