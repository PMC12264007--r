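# Compact fixtures: a shortened urodynamic protocol and small-grid
# phantoms so unit tests stay fast.  Full-scale defaults are exercised
# in test-acceptance.R.

short_protocol <- function() {
  protocol_spec(data.frame(
    label = c("baseline", "fill1", "hold1", "fill2", "hold2",
              "empty", "washout"),
    duration_s = c(60, 100, 40, 20, 40, 120, 40),
    pump_rate_ml_min = c(0, 90, 0, 90, 0, -90, 0),
    stringsAsFactors = FALSE))
}

small_phantom <- function(seed = 1L, noise_sd = 1, drift_amplitude = 0,
                          n_depth = 24L, n_width = 32L,
                          gain_pos = 120, gain_neg = -40,
                          hrf = hrf_kernel(), protocol = short_protocol()) {
  trace <- simulate_bladder_pressure(protocol, seed = seed)
  truth <- phantom_truth(n_depth = n_depth, n_width = n_width,
                         gain_pos = gain_pos, gain_neg = gain_neg,
                         hrf = hrf, noise_sd = noise_sd,
                         drift_amplitude = drift_amplitude, seed = seed)
  ph <- generate_phantom(truth, trace, protocol)
  list(stack = ph$stack, truth = ph$truth, trace = trace,
       protocol = protocol)
}

# static stack whose frames all equal one textured image
static_stack <- function(img, n_frames, baseline_frames = 3) {
  pd_stack(array(rep(img, n_frames), c(dim(img), n_frames)),
           baseline_frames = baseline_frames)
}

# deterministic smooth multi-blob test image
blob_image <- function(nr = 48, nc = 64, n_blobs = 5, seed = 42) {
  set.seed(seed)
  img <- matrix(0, nr, nc)
  for (k in seq_len(n_blobs)) {
    r0 <- runif(1, 0.25, 0.75) * nr; c0 <- runif(1, 0.25, 0.75) * nc
    s <- runif(1, 3, 7)
    img <- img + runif(1, 50, 150) *
      exp(-((row(img) - r0)^2 + (col(img) - c0)^2) / (2 * s^2))
  }
  img
}
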