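make_pct <- function(data, baseline_frames = 3, fs = 1) {
  d <- dim(data)
  structure(list(data = data,
                 baseline_mean_map = matrix(1, d[1], d[2]),
                 analysis_mask = matrix(TRUE, d[1], d[2]),
                 frame_rate_hz = fs, baseline_frames = baseline_frames),
            class = "pct_stack")
}

test_that("pearson_map matches the brute-force formula", {
  set.seed(21)
  n_t <- 13
  data <- array(rnorm(3 * 1 * n_t), c(3, 1, n_t))
  bp <- rnorm(n_t)
  pct <- make_pct(data, baseline_frames = 3)
  map <- pearson_map(pct, bp)
  win <- 4:n_t
  for (i in 1:3) {
    r_oracle <- pearson_oracle(data[i, 1, win], bp[win])
    expect_equal(map$r[i, 1], r_oracle, tolerance = 1e-12)
    expect_equal(map$z[i, 1], atanh(r_oracle), tolerance = 1e-12)
    expect_equal(map$p[i, 1],
                 cor.test(data[i, 1, win], bp[win])$p.value,
                 tolerance = 1e-10)
  }
  # exact correlates
  data2 <- array(0, c(2, 1, n_t))
  data2[1, 1, ] <- bp
  data2[2, 1, ] <- -bp + 5
  map2 <- pearson_map(make_pct(data2), bp)
  expect_equal(map2$r[1, 1], 1)
  expect_equal(map2$r[2, 1], -1)
  # zero-variance pixel leaves the analysis mask
  data3 <- data; data3[2, 1, ] <- 7
  map3 <- pearson_map(make_pct(data3), bp)
  expect_false(map3$analysis_mask[2, 1])
  expect_true(is.na(map3$r[2, 1]))
  expect_error(pearson_map(make_pct(data), bp, window = 1:2), ">= 3")
})

test_that("Fisher z is odd, increasing, and zero at zero", {
  r <- seq(-0.99, 0.99, by = 0.01)
  z <- atanh(r)
  expect_equal(atanh(0), 0)
  expect_true(all(diff(z) > 0))
  expect_equal(atanh(-r), -z)
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(numeric(0))$reject, logical(0))
  expect_true(all(bh_fdr(rep(0, 5))$reject))
  expect_false(any(bh_fdr(rep(1, 5))$reject))
  # worked example: exhaustive enumeration of k*alpha/m thresholds
  p <- c(0.001, 0.008, 0.039, 0.041)
  alpha <- 0.01
  ks <- which(sort(p) <= seq_along(p) * alpha / length(p))
  kstar <- if (length(ks)) max(ks) else 0
  oracle_reject <- rank(p) <= kstar
  got <- bh_fdr(p, alpha)
  expect_equal(got$reject, oracle_reject)
  expect_equal(sum(got$reject), 1)
  # q-values agree with the reference implementation
  set.seed(5)
  pr <- runif(40)^2
  expect_equal(bh_fdr(pr)$q, p.adjust(pr, "BH"), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("FDR is controlled on pure-noise phantoms", {
  # 200 replicates x 2000 null pixels: mean false-discovery proportion
  # must stay within alpha + 0.01
  set.seed(31)
  n_t <- 60
  fdp <- replicate(200, {
    X <- matrix(rnorm(2000 * n_t), 2000)
    y <- rnorm(n_t)
    r <- drop(cor(t(X), y))
    tstat <- r * sqrt((n_t - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n_t - 2)
    rej <- bh_fdr(p, 0.01)$reject
    if (any(rej)) 1 else 0   # all rejections are false here
  })
  expect_lte(mean(fdp) * 1, 0.02 / 0.01 * 0.01 + 0.01)
  expect_lte(mean(fdp), 0.02)
})

test_that("top_fraction_masks selects the advertised pixels", {
  set.seed(8)
  n_t <- 40
  bp <- cumsum(rnorm(n_t))
  n_px <- 60
  data <- array(rnorm(n_px * n_t, sd = 0.2), c(n_px, 1, n_t))
  # plant 12 strong positives, 9 strong negatives
  for (i in 1:12) data[i, 1, ] <- data[i, 1, ] + bp
  for (i in 13:21) data[i, 1, ] <- data[i, 1, ] - bp
  map <- pearson_map(make_pct(data, baseline_frames = 2), bp, window = 1:n_t)
  out <- top_fraction_masks(map, fraction = 0.1, alpha = 0.01)
  n_keep <- ceiling(0.1 * 60)
  expect_lte(sum(out$pos_mask), n_keep)
  expect_lte(sum(out$neg_mask), n_keep)
  expect_false(any(out$pos_mask & out$neg_mask))
  # sort-and-count oracle: the selected r values are the largest
  r_pos_sel <- sort(map$r[out$pos_mask])
  r_all_sig_pos <- sort(map$r[bh_fdr(map$p[map$analysis_mask])$reject &
                                map$r[map$analysis_mask] > 0], decreasing = TRUE)
  expect_equal(sort(r_pos_sel, decreasing = TRUE),
               r_all_sig_pos[seq_along(r_pos_sel)])
  expect_equal(out$thresholds$r_pos, min(r_pos_sel))
  # fraction = 1 keeps every significant positive pixel
  all_pos <- top_fraction_masks(map, fraction = 1, alpha = 0.01)
  sig <- bh_fdr(map$p[map$analysis_mask])$reject
  expect_equal(sum(all_pos$pos_mask),
               sum(sig & map$r[map$analysis_mask] > 0))
  # all-null map: empty masks with a warning
  null_map <- pearson_map(make_pct(array(rnorm(5 * n_t), c(5, 1, n_t)),
                                   baseline_frames = 2), bp, window = 1:n_t)
  expect_warning(empty <- top_fraction_masks(null_map), "no FDR")
  expect_equal(sum(empty$pos_mask) + sum(empty$neg_mask), 0)
})

test_that("activation masks recover planted regions (Jaccard >= 0.8, monotone in SNR)", {
  jac_at_snr <- function(snr, seed = 41) {
    pr <- short_protocol()
    trace <- simulate_bladder_pressure(pr, seed = seed)
    truth0 <- phantom_truth(n_depth = 24, n_width = 32, seed = seed,
                            drift_amplitude = 0)
    resp <- hemodynamic_response(percent_bp(trace), truth0$hrf_kernel)
    truth0$noise_sd <- noise_sd_for_snr(truth0, resp, snr)
    ph <- generate_phantom(truth0, trace, pr)
    pct <- percent_change(lowpass_filter(ph$stack))
    map <- pearson_map(pct, percent_bp(trace))
    map <- top_fraction_masks(map, fraction = 0.05, alpha = 0.01)
    (jaccard(map$pos_mask, truth0$pos_mask) +
        jaccard(map$neg_mask, truth0$neg_mask)) / 2
  }
  j <- vapply(c(0.5, 1, 2, 4), jac_at_snr, numeric(1))
  expect_gte(j[3], 0.8)              # SNR = 2 contract
  expect_true(all(diff(j) >= -0.02)) # graceful (near-monotone) degradation
})

test_that("region_timecourse averages with pixel-level SE", {
  sp <- small_phantom(seed = 43, noise_sd = 1)
  pct <- percent_change(sp$stack)
  single <- matrix(FALSE, 24, 32); single[3, 4] <- TRUE
  tc1 <- region_timecourse(pct, single)
  expect_equal(tc1$mean_pct, pct$data[3, 4, ])
  expect_equal(tc1$se_pct, rep(0, dim(pct$data)[3]))
  # uniform stack: constant mean, zero SE
  u <- make_pct(array(4, c(3, 3, 5)))
  tcu <- region_timecourse(u, matrix(TRUE, 3, 3))
  expect_equal(tcu$mean_pct, rep(4, 5))
  expect_error(region_timecourse(pct, matrix(FALSE, 24, 32)), "empty")
  # phantom: mean over truth pos region tracks %BP tightly at low noise
  sp2 <- small_phantom(seed = 44, noise_sd = 0.5)
  pct2 <- percent_change(lowpass_filter(sp2$stack))
  tc <- region_timecourse(pct2, sp2$truth$pos_mask)
  win <- seq(sp2$stack$baseline_frames + 1, dim(pct2$data)[3])
  expect_gte(cor(tc$mean_pct[win], percent_bp(sp2$trace)[win]), 0.95)
})

test_that("normalize_range hits its bounds exactly and is idempotent", {
  expect_equal(normalize_range(c(0, 5, 10), "01"), c(0, 0.5, 1))
  expect_equal(normalize_range(c(-2, 0, 2), "pm1"), c(-1, 0, 1))
  x <- c(0, 0.25, 0.9, 1)
  expect_equal(normalize_range(x, "01"), x)
  expect_error(normalize_range(rep(2, 5)), "constant")
})

test_that("group statistics use mean +- SE across subjects", {
  g <- peak_and_group_stats(list(peak = c(200, 206)))
  expect_equal(g$mean, 203)
  expect_equal(g$se, 3)   # sd/sqrt(2) = 4.2426/1.414
  one <- peak_and_group_stats(list(peak = 5))
  expect_equal(one$se, 0)
  expect_equal(one$mean, 5)
  # 4 simulated subjects: element-wise oracle
  set.seed(2)
  vals <- data.frame(a = rnorm(4), b = rnorm(4))
  g4 <- peak_and_group_stats(vals)
  expect_equal(g4$mean, c(mean(vals$a), mean(vals$b)))
  expect_equal(g4$se, c(sd(vals$a) / 2, sd(vals$b) / 2))
  expect_equal(attr(g4, "per_subject"), vals)
})

test_that("inside/outside bounds comparison splits activated pixels", {
  sp <- small_phantom(seed = 47, noise_sd = 0.5)
  pct <- percent_change(lowpass_filter(sp$stack))
  bp <- percent_bp(sp$trace)
  map <- top_fraction_masks(pearson_map(pct, bp))
  bounds <- matrix(FALSE, 24, 32)
  bounds[, 1:22] <- TRUE   # contains the pos ellipse, splits the neg one
  both <- compare_in_out_mask(pct, map, bounds)
  win <- seq(sp$stack$baseline_frames + 1, dim(pct$data)[3])
  expect_named(both, c("inside", "outside"))
  expect_gte(abs(cor(both$inside$mean_pct[win], bp[win])), 0.9)
  expect_gte(abs(cor(both$outside$mean_pct[win], bp[win])), 0.9)
  # full-grid bounds: outside side omitted
  expect_warning(inside_only <- compare_in_out_mask(pct, map,
                                                    matrix(TRUE, 24, 32)),
                 "outside")
  expect_named(inside_only, "inside")
  # empty activation: both omitted
  empty_map <- map
  empty_map$pos_mask[] <- FALSE; empty_map$neg_mask[] <- FALSE
  expect_warning(expect_warning(none <- compare_in_out_mask(pct, empty_map,
                                                            bounds)))
  expect_length(none, 0)
})

test_that("overlay rendering is deterministic and mask-faithful", {
  sp <- small_phantom(seed = 49, noise_sd = 0.5)
  pct <- percent_change(sp$stack)
  map <- top_fraction_masks(pearson_map(pct, percent_bp(sp$trace)))
  bg <- pct$baseline_mean_map
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  arr1 <- render_activation_overlay(bg, map$r, map$pos_mask, map$neg_mask, f1)
  render_activation_overlay(bg, map$r, map$pos_mask, map$neg_mask, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # overlay pixels coincide exactly with the recovered masks
  colored <- arr1[, , 1] != arr1[, , 2] | arr1[, , 2] != arr1[, , 3]
  expect_equal(colored, map$pos_mask | map$neg_mask)
  # empty masks: pure grayscale
  arr0 <- render_activation_overlay(bg, map$r, path = tempfile(fileext = ".png"))
  expect_equal(arr0[, , 1], arr0[, , 2])
  expect_equal(arr0[, , 2], arr0[, , 3])
  unlink(c(f1, f2))
})
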