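#' Pixel-wise Pearson correlation of %pD change with %BP
#'
#' Correlates every analyzed pixel's percent-change series with the
#' bladder-pressure regressor over a frame window (by default the
#' experiment period: every post-baseline frame).  Returns per-pixel
#' Pearson r, Fisher z = atanh(r), and a two-sided p-value from the
#' t-statistic \eqn{r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom.
#' Zero-variance pixels are dropped from the analysis mask.
#'
#' @param pct a `pct_stack` from [percent_change()]
#' @param bp numeric %BP series aligned to the stack frames (full
#'   length)
#' @param window integer frame indices to correlate over; default all
#'   post-baseline frames
#' @return object of class `activation_map`: list of matrices `r`, `z`,
#'   `p` (NA outside the mask), `analysis_mask`, and `n_time`
#' @export
pearson_map <- function(pct, bp, window = NULL) {
  stopifnot(inherits(pct, "pct_stack"))
  d <- dim(pct$data)
  if (length(bp) != d[3]) stop("bp must align with the stack frames")
  if (is.null(window)) window <- seq(pct$baseline_frames + 1, d[3])
  if (length(window) < 3) stop("window must contain >= 3 frames")
  y <- bp[window]
  if (stats::sd(y) == 0) stop("zero-variance bp regressor")
  n <- length(window)
  mask <- pct$analysis_mask
  flat <- matrix(pct$data, nrow = d[1] * d[2])[, window, drop = FALSE]
  X <- flat[mask, , drop = FALSE]
  Xc <- X - rowMeans(X)
  yc <- y - mean(y)
  sx <- sqrt(rowSums(Xc^2))
  ok <- sx > 0
  r_vec <- rep(NA_real_, nrow(X))
  r_vec[ok] <- (Xc[ok, , drop = FALSE] %*% yc) / (sx[ok] * sqrt(sum(yc^2)))
  r_vec <- pmin(pmax(r_vec, -1), 1)
  mask_idx <- which(mask)
  mask[mask_idx[!ok]] <- FALSE
  to_grid <- function(v) {
    g <- matrix(NA_real_, d[1], d[2])
    g[mask_idx] <- v
    g[!mask] <- NA_real_
    g
  }
  tstat <- r_vec * sqrt((n - 2) / pmax(1 - r_vec^2, .Machine$double.eps))
  p_vec <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = to_grid(r_vec), z = to_grid(atanh(r_vec)),
                 p = to_grid(p_vec), q = NULL,
                 pos_mask = NULL, neg_mask = NULL,
                 analysis_mask = mask, n_time = n, window = window),
            class = "activation_map")
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up procedure: with ordered p-values `p(1) <= ... <=
#' p(m)`, reject all `p(i)` with `i <= k*`, `k* = max{k : p(k) <=
#' k a / m}`.  Adjusted q-values are the monotone `p * m / rank`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs passed through)
#' @param alpha FDR level (default 0.01)
#' @return list with `reject` (logical) and `q` (adjusted values), both
#'   the length of `p`
#' @export
bh_fdr <- function(p, alpha = 0.01) {
  if (length(p) == 0) return(list(reject = logical(0), q = numeric(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  ok <- !is.na(p)
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  reject <- rep(FALSE, length(p))
  if (m > 0) {
    ord <- order(p[ok])
    ps <- p[ok][ord]
    ranks <- seq_len(m)
    qs <- rev(cummin(rev(ps * m / ranks)))
    qs <- pmin(qs, 1)
    kstar <- suppressWarnings(max(which(ps <= ranks * alpha / m)))
    rej_sorted <- if (is.finite(kstar)) ranks <= kstar else rep(FALSE, m)
    idx <- which(ok)[ord]
    q[idx] <- qs
    reject[idx] <- rej_sorted
  }
  list(reject = reject, q = q)
}

#' Threshold an activation map to its top-fraction correlates
#'
#' Among FDR-significant analyzed pixels, selects the
#' `ceiling(fraction * M)` pixels with the largest positive r as the
#' positive mask (M = analyzed pixel count) and analogously the most
#' negative r for the negative mask, reporting the attained r
#' thresholds.
#'
#' @param map an `activation_map` from [pearson_map()]
#' @param fraction top fraction to keep (default 0.05)
#' @param alpha FDR level (default 0.01)
#' @return the map with `q`, `pos_mask`, `neg_mask` filled in and an
#'   attribute-free list element `thresholds` (`r_pos`, `r_neg`, NA if
#'   the respective mask is empty)
#' @export
top_fraction_masks <- function(map, fraction = 0.05, alpha = 0.01) {
  stopifnot(inherits(map, "activation_map"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  mask_idx <- which(map$analysis_mask)
  M <- length(mask_idx)
  fdr <- bh_fdr(map$p[mask_idx], alpha)
  q <- matrix(NA_real_, nrow(map$p), ncol(map$p))
  q[mask_idx] <- fdr$q
  n_keep <- ceiling(fraction * M)
  r_vals <- map$r[mask_idx]
  pos_cand <- which(fdr$reject & r_vals > 0)
  neg_cand <- which(fdr$reject & r_vals < 0)
  if (length(pos_cand) == 0 && length(neg_cand) == 0) {
    warning("no FDR-significant pixels: masks are empty")
  }
  take <- function(cand, decreasing) {
    cand[order(r_vals[cand], decreasing = decreasing)][
      seq_len(min(n_keep, length(cand)))]
  }
  pos_sel <- take(pos_cand, TRUE)
  neg_sel <- take(neg_cand, FALSE)
  pos_mask <- neg_mask <- matrix(FALSE, nrow(map$p), ncol(map$p))
  pos_mask[mask_idx[pos_sel]] <- TRUE
  neg_mask[mask_idx[neg_sel]] <- TRUE
  map$q <- q
  map$pos_mask <- pos_mask
  map$neg_mask <- neg_mask
  map$thresholds <- list(
    r_pos = if (length(pos_sel)) min(r_vals[pos_sel]) else NA_real_,
    r_neg = if (length(neg_sel)) max(r_vals[neg_sel]) else NA_real_)
  map
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("activation_map: %d analyzed px over %d frames",
              sum(x$analysis_mask), x$n_time))
  if (!is.null(x$pos_mask)) {
    cat(sprintf("; masks %d pos / %d neg (r >= %.3f / <= %.3f)",
                sum(x$pos_mask), sum(x$neg_mask),
                x$thresholds$r_pos, x$thresholds$r_neg))
  }
  cat("\n")
  invisible(x)
}

#' Mean +- SE time-course over a pixel mask
#'
#' @param pct a `pct_stack`
#' @param mask non-empty logical matrix on the stack grid
#' @param mask_id label carried into the result
#' @return data.frame `t_s`, `mean_pct`, `se_pct` (SE over pixels) with
#'   attribute `mask_id`
#' @export
region_timecourse <- function(pct, mask, mask_id = "region") {
  stopifnot(inherits(pct, "pct_stack"), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  d <- dim(pct$data)
  flat <- matrix(pct$data, nrow = d[1] * d[2])[which(mask), , drop = FALSE]
  n <- nrow(flat)
  mean_pct <- colMeans(flat)
  se_pct <- if (n > 1) apply(flat, 2, stats::sd) / sqrt(n) else numeric(d[3])
  structure(data.frame(t_s = seq(0, by = 1 / pct$frame_rate_hz,
                                 length.out = d[3]),
                       mean_pct = mean_pct, se_pct = se_pct),
            mask_id = mask_id)
}

#' Min-max normalize a series onto [0,1] or [-1,1]
#'
#' Affine map attaining the target bounds exactly; errors on constant
#' input.
#'
#' @param x numeric series, non-constant
#' @param target `"01"` for `[0,1]` or `"pm1"` for `[-1,1]`
#' @return normalized series
#' @export
normalize_range <- function(x, target = c("01", "pm1")) {
  target <- match.arg(target)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) stop("constant series: degenerate range")
  u <- (x - rng[1]) / (rng[2] - rng[1])
  if (target == "01") u else 2 * u - 1
}

#' Across-subject summary of peak and correlation statistics
#'
#' Arithmetic mean and standard error (SD/sqrt(n); 0 for a single
#' subject) across subjects, retaining the per-subject values for dot
#' plots.
#'
#' @param values named list (or data.frame) mapping each statistic to a
#'   numeric vector with one entry per subject
#' @return data.frame with columns `statistic`, `mean`, `se`, `n`, and
#'   attribute `per_subject` (the input as a data.frame)
#' @export
peak_and_group_stats <- function(values) {
  values <- as.data.frame(values)
  if (nrow(values) < 1) stop("need at least one subject")
  out <- data.frame(
    statistic = names(values),
    mean = vapply(values, mean, numeric(1)),
    se = vapply(values, function(v) {
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    }, numeric(1)),
    n = nrow(values), row.names = NULL)
  structure(out, per_subject = values)
}

#' Compare activated signal inside vs outside an anatomical bounds mask
#'
#' Splits the activated pixels (positive and negative masks combined)
#' into those inside the bounds mask (e.g. the dorsal cord surface) and
#' those outside, returning the region time-course of each side.  An
#' empty side is omitted with a warning.
#'
#' @param pct a `pct_stack`
#' @param activation an `activation_map` with masks (see
#'   [top_fraction_masks()])
#' @param bounds_mask logical matrix on the same grid
#' @return list with elements `inside` and/or `outside`
#' @export
compare_in_out_mask <- function(pct, activation, bounds_mask) {
  stopifnot(inherits(activation, "activation_map"),
            !is.null(activation$pos_mask))
  act <- activation$pos_mask | activation$neg_mask
  stopifnot(identical(dim(act), dim(bounds_mask)))
  out <- list()
  inside <- act & bounds_mask
  outside <- act & !bounds_mask
  if (any(inside)) {
    out$inside <- region_timecourse(pct, inside, "activated_inside_bounds")
  } else warning("no activated pixels inside bounds; side omitted")
  if (any(outside)) {
    out$outside <- region_timecourse(pct, outside, "activated_outside_bounds")
  } else warning("no activated pixels outside bounds; side omitted")
  out
}
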