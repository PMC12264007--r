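#' Minimal NIfTI-1 volume writer
#'
#' Writes a 2D/3D numeric array as an uncompressed or gzipped NIfTI-1
#' file (float64 by default, fixed 352-byte data offset, little
#' endian).  Axis order is depth(rows) x width(cols) x time, with row =
#' depth increasing downward to mirror the ultrasound display.  No R
#' NIfTI package is assumed; the format is written directly (verified
#' against nibabel) and round-trips bit-identically for double data.
#'
#' @param data numeric array (2 or 3 dimensions)
#' @param path output path; a `.gz` suffix selects gzip compression
#' @param pixdim per-axis spacing (mm, mm, s)
#' @param datatype `"float64"` (default, lossless for R doubles) or
#'   `"float32"`
#' @return `path`, invisibly
#' @export
write_nifti <- function(data, path, pixdim = c(0.1, 0.1, 1),
                        datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  stopifnot(length(d) %in% 1:3)
  code <- if (datatype == "float64") 64L else 16L
  bitpix <- if (datatype == "float64") 64L else 32L
  hdr <- rawConnection(raw(0), "wb")
  wi <- function(x, size) writeBin(as.integer(x), hdr, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), hdr, size = 4,
                             endian = "little")
  pad_to <- function(off) {
    cur <- seek(hdr)
    if (cur < off) writeBin(raw(off - cur), hdr)
  }
  wi(348, 4)                                       # sizeof_hdr
  pad_to(40)
  wi(c(length(d), d, rep(1L, 7 - length(d))), 2)   # dim[8]
  pad_to(70)
  wi(code, 2); wi(bitpix, 2); wi(0, 2)             # datatype, bitpix, slice_start
  wf(c(1, pixdim, rep(1, 7 - length(pixdim))))     # pixdim[8] (qfac 1)
  wf(352)                                          # vox_offset
  wf(1); wf(0)                                     # scl_slope, scl_inter
  wi(0, 2); writeBin(as.raw(c(0L, 10L)), hdr)      # slice_end/code, xyzt: mm|sec
  pad_to(344)
  writeBin(c(charToRaw("n+1"), as.raw(0)), hdr)    # magic
  header <- rawConnectionValue(hdr)
  close(hdr)
  stopifnot(length(header) == 348)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(raw(4), con)                            # no extensions
  writeBin(as.numeric(data), con, size = bitpix / 8, endian = "little")
  invisible(path)
}

#' Minimal NIfTI-1 volume reader
#'
#' Reads little-endian NIfTI-1 files with float32/float64 data (the
#' formats this package writes).
#'
#' @param path `.nii` or `.nii.gz` file
#' @return numeric array with the file's dimensions
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348) stop("unsupported NIfTI header (not little-endian?)")
  dims <- ri(40, 2, 8)
  ndim <- dims[1]
  d <- dims[2:(1 + ndim)]
  datatype <- ri(70, 2)
  size <- switch(as.character(datatype), "16" = 4L, "64" = 8L,
                 stop("unsupported NIfTI datatype code ", datatype))
  vox_offset <- rf(108)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  data <- readBin(con, "numeric", n = prod(d), size = size,
                  endian = "little")
  if (length(data) < prod(d)) stop("truncated NIfTI data in ", path)
  array(data, dim = d)
}

#' Save / load a pD stack as NIfTI plus JSON sidecar
#'
#' The image data go to `<stem>.nii.gz`; acquisition metadata
#' (`pixel_pitch_mm`, `frame_rate_hz`, `baseline_frames`, plus any extra
#' metadata) to `<stem>.json`.  The round trip is lossless.
#'
#' @param stack a [pd_stack()]
#' @param stem path stem (no extension)
#' @return `save_pd_stack`: the stem, invisibly.  `load_pd_stack`: the
#'   restored [pd_stack()].
#' @export
save_pd_stack <- function(stack, stem) {
  stopifnot(inherits(stack, "pd_stack"))
  write_nifti(stack$data, paste0(stem, ".nii.gz"),
              pixdim = c(stack$pixel_pitch_mm, stack$pixel_pitch_mm,
                         1 / stack$frame_rate_hz))
  sidecar <- c(list(pixel_pitch_mm = stack$pixel_pitch_mm,
                    frame_rate_hz = stack$frame_rate_hz,
                    baseline_frames = stack$baseline_frames),
               stack$metadata)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' @rdname save_pd_stack
#' @export
load_pd_stack <- function(stem) {
  nii <- paste0(stem, ".nii.gz")
  if (!file.exists(nii)) nii <- paste0(stem, ".nii")
  sidecar_path <- paste0(stem, ".json")
  if (!file.exists(sidecar_path)) stop("missing sidecar: ", sidecar_path)
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("pixel_pitch_mm", "frame_rate_hz", "baseline_frames")) {
    if (is.null(sidecar[[key]])) {
      stop("sidecar is missing required key '", key, "'")
    }
  }
  data <- read_nifti(nii)
  meta <- sidecar[setdiff(names(sidecar),
                          c("pixel_pitch_mm", "frame_rate_hz",
                            "baseline_frames"))]
  pd_stack(data, pixel_pitch_mm = sidecar$pixel_pitch_mm,
           frame_rate_hz = sidecar$frame_rate_hz,
           baseline_frames = sidecar$baseline_frames, metadata = meta)
}

#' Save / load a bladder-pressure trace as CSV
#'
#' Columns `time_s`, `pressure_cmH2O`, `phase`.  On load, the time grid
#' is validated (strictly increasing, no duplicates); a trace sampled
#' faster than `target_hz` is linearly resampled onto that rate's
#' uniform grid.
#'
#' @param trace a `bladder_trace`
#' @param path CSV path
#' @param target_hz optional resampling rate on load
#' @return `save_bp_csv`: the path, invisibly.  `load_bp_csv`: a
#'   `bladder_trace`.
#' @export
save_bp_csv <- function(trace, path) {
  stopifnot(inherits(trace, "bladder_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s,
                              pressure_cmH2O = trace$pressure_cmH2O,
                              phase = trace$phase),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_bp_csv
#' @export
load_bp_csv <- function(path, target_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "pressure_cmH2O") %in% names(df))) {
    stop("CSV must have columns time_s and pressure_cmH2O")
  }
  t <- df$time_s
  if (anyDuplicated(t)) stop("duplicate timestamps")
  if (any(diff(t) <= 0)) stop("non-monotone time grid")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("non-uniform time grid")
  }
  fs <- 1 / stats::median(dt)
  pressure <- df$pressure_cmH2O
  phase <- if ("phase" %in% names(df)) df$phase else rep(NA_character_,
                                                         length(t))
  if (!is.null(target_hz) && abs(fs - target_hz) > 1e-9) {
    tt <- seq(t[1], t[length(t)], by = 1 / target_hz)
    pressure <- stats::approx(t, pressure, xout = tt)$y
    phase <- phase[pmin(findInterval(tt, t), length(t))]
    t <- tt
    fs <- target_hz
  }
  structure(list(time_s = t, pressure_cmH2O = pressure, phase = phase,
                 sampling_rate_hz = fs, reference_window_s = 30,
                 params = list()),
            class = "bladder_trace")
}

#' Save an SVR model as JSON (+ beta map as NIfTI)
#'
#' @param model an `svm_model`
#' @param stem path stem
#' @param pixel_index,dim optional grid projection for the beta map
#' @return the stem, invisibly
#' @export
save_svm_model <- function(model, stem, pixel_index = NULL, dim = NULL) {
  obj <- unclass(model)
  jsonlite::write_json(obj, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(pixel_index) && !is.null(dim)) {
    write_nifti(beta_map(model, pixel_index, dim),
                paste0(stem, "_beta.nii.gz"))
  }
  invisible(stem)
}
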