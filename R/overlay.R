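#' Render a signed overlay on the mean vascular map
#'
#' Draws the baseline pD map in grayscale (optionally log-compressed,
#' the usual display for ultrasound vascular maps) and overlays signed
#' values (correlation r or SVM beta weights) inside the given masks:
#' warm colors for positive, cool for negative, with a two-sided
#' colorbar.  The raster is computed deterministically and written as a
#' PNG; identical inputs give a byte-identical file.
#'
#' @param background numeric matrix, e.g. the baseline mean map
#' @param overlay numeric matrix of signed values (same grid)
#' @param pos_mask,neg_mask logical matrices selecting overlay pixels;
#'   empty masks give a pure grayscale image
#' @param path output PNG path
#' @param log_background log-compress the background? (default TRUE)
#' @param scale_px integer pixel magnification of the written PNG
#' @return invisibly, the RGB raster (depth x width x 3, values 0-1)
#' @export
render_activation_overlay <- function(background, overlay,
                                      pos_mask = NULL, neg_mask = NULL,
                                      path, log_background = TRUE,
                                      scale_px = 4L) {
  stopifnot(is.matrix(background), identical(dim(background), dim(overlay)))
  if (is.null(pos_mask)) pos_mask <- matrix(FALSE, nrow(background), ncol(background))
  if (is.null(neg_mask)) neg_mask <- matrix(FALSE, nrow(background), ncol(background))
  bg <- background
  if (log_background) bg <- log1p(pmax(bg, 0))
  rng <- range(bg)
  gray <- if (rng[1] == rng[2]) bg * 0 else (bg - rng[1]) / (rng[2] - rng[1])
  rgb_arr <- array(rep(gray, 3), dim = c(dim(bg), 3))
  vmax <- max(abs(overlay[pos_mask | neg_mask]), 0)
  if (vmax > 0) {
    # warm ramp: black-red-yellow by magnitude; cool: black-blue-cyan
    apply_ramp <- function(mask, warm) {
      v <- pmin(abs(overlay[mask]) / vmax, 1)
      if (warm) {
        rgb_arr[cbind(which(mask, arr.ind = TRUE), 1)] <<- 0.5 + 0.5 * v
        rgb_arr[cbind(which(mask, arr.ind = TRUE), 2)] <<- v^2
        rgb_arr[cbind(which(mask, arr.ind = TRUE), 3)] <<- 0
      } else {
        rgb_arr[cbind(which(mask, arr.ind = TRUE), 1)] <<- 0
        rgb_arr[cbind(which(mask, arr.ind = TRUE), 2)] <<- v^2
        rgb_arr[cbind(which(mask, arr.ind = TRUE), 3)] <<- 0.5 + 0.5 * v
      }
    }
    if (any(pos_mask)) apply_ramp(pos_mask, warm = TRUE)
    if (any(neg_mask)) apply_ramp(neg_mask, warm = FALSE)
  }
  write_png_raster(rgb_arr, path, scale_px)
  invisible(rgb_arr)
}

# Minimal deterministic 8-bit RGB PNG writer (no timestamps, fixed zlib
# settings), so re-rendering identical inputs is byte-identical.
write_png_raster <- function(rgb_arr, path, scale_px = 1L) {
  d <- dim(rgb_arr)
  h <- d[1] * scale_px; w <- d[2] * scale_px
  px <- array(0L, dim = c(h, w, 3))
  ridx <- rep(seq_len(d[1]), each = scale_px)
  cidx <- rep(seq_len(d[2]), each = scale_px)
  for (ch in 1:3) {
    px[, , ch] <- as.integer(round(255 * pmin(pmax(
      rgb_arr[ridx, cidx, ch], 0), 1)))
  }
  # scanlines: filter byte 0 + RGB triples
  raw_rows <- vapply(seq_len(h), function(r) {
    as.raw(c(0L, as.vector(t(px[r, , ]))))
  }, raw(1 + 3 * w))
  idat <- zlib_compress(as.raw(raw_rows))
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(writeBin(length(data), raw(), size = 4, endian = "big"),
      body,
      writeBin(png_crc32(body), raw(), size = 4, endian = "big"))
  }
  ihdr <- c(writeBin(w, raw(), size = 4, endian = "big"),
            writeBin(h, raw(), size = 4, endian = "big"),
            as.raw(c(8, 2, 0, 0, 0)))   # 8-bit, RGB
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr),
           chunk("IDAT", idat),
           chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# PNG's IDAT wants a zlib (RFC1950) stream, which is exactly what R's
# memCompress(type = "gzip") emits (despite the argument name).
zlib_compress <- function(bytes) {
  memCompress(bytes, type = "gzip")
}

png_crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320 reflected poly
      } else bitwShiftR(c, 1)
    }
    tab[n + 1] <- c
  }
  tab
})

png_crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8), png_crc32_table[idx + 1])
  }
  bitwXor(crc, -1L)
}
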