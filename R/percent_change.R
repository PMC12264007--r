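#' Percent signal change relative to the baseline window
#'
#' \deqn{\%\Delta SCBV(p,t) = 100\,(pD(p,t) - B(p)) / B(p)} with
#' \eqn{B(p)} the per-pixel mean pD over the baseline frames (the 5 min
#' preceding filling onset).  Pixels with non-positive baseline mean are
#' flagged and excluded from the analysis mask.
#'
#' @param stack a [pd_stack()] with at least 2 baseline frames
#' @return object of class `pct_stack`: list with `data` (percent, same
#'   shape as the input), `baseline_mean_map`, `analysis_mask` (logical
#'   matrix), `frame_rate_hz`, `baseline_frames`
#' @export
percent_change <- function(stack) {
  stopifnot(inherits(stack, "pd_stack"))
  if (stack$baseline_frames < 2) stop("need >= 2 baseline frames")
  d <- dim(stack$data)
  B <- apply(stack$data[, , seq_len(stack$baseline_frames), drop = FALSE],
             c(1, 2), mean)
  mask <- B > 0
  Bsafe <- ifelse(mask, B, 1)
  pct <- sweep(sweep(stack$data, c(1, 2), B, "-"), c(1, 2), Bsafe, "/") * 100
  pct[!mask] <- NA_real_
  structure(list(data = pct, baseline_mean_map = B, analysis_mask = mask,
                 frame_rate_hz = stack$frame_rate_hz,
                 baseline_frames = stack$baseline_frames),
            class = "pct_stack")
}

#' @export
print.pct_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("pct_stack: %d x %d px, %d frames (%d analyzed pixels)\n",
              d[1], d[2], d[3], sum(x$analysis_mask)))
  invisible(x)
}

#' Before/after summary of per-pixel temporal noise
#'
#' Reports the mean and standard error over pixels of the per-pixel
#' temporal standard deviation, for a raw and a filtered stack — the
#' standard way to quantify how much high-frequency power a
#' preprocessing chain removed.
#'
#' @param raw,filtered [pd_stack()]s of identical shape
#' @return data.frame with rows `raw` and `filtered` and columns
#'   `mean_sd`, `se_sd`, `n_pixels`
#' @export
noise_reduction_report <- function(raw, filtered) {
  stopifnot(inherits(raw, "pd_stack"), inherits(filtered, "pd_stack"),
            identical(dim(raw$data), dim(filtered$data)))
  if (dim(raw$data)[3] < 2) stop("need >= 2 frames")
  one <- function(s) {
    d <- dim(s$data)
    flat <- matrix(s$data, nrow = d[1] * d[2])
    sds <- apply(flat, 1, stats::sd)
    c(mean_sd = mean(sds), se_sd = stats::sd(sds) / sqrt(length(sds)),
      n_pixels = length(sds))
  }
  out <- rbind(raw = one(raw), filtered = one(filtered))
  as.data.frame(out)
}
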