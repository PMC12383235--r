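# Readers/writers for the interchange formats: MRC2014 volumes,
# multi-page float TIFF + JSON sidecar for AFM series, CSV for traces,
# curves and measurements, JSON for reports.  Physical calibration is
# mandatory everywhere: a file without voxel size / sampling metadata
# is an error, never a silent pixel-unit fallback.

#' Write a density field as MRC2014
#'
#' Mode-2 (float32) MRC with the voxel size in the header cell
#' dimensions (Angstrom, the EM convention).
#'
#' @param field A [density_field()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(field, path) {
  stopifnot(inherits(field, "density_field"))
  g <- field$grid
  d <- dim(g)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2L)                                  # mode 2: float32
  wi(c(0L, 0L, 0L))                       # nstart
  wi(d)                                   # mx my mz
  wf(d * field$voxel_size * 10)           # cella, Angstrom
  wf(c(90, 90, 90))                       # cellb
  wi(c(1L, 2L, 3L))                       # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))          # dmin dmax dmean
  wi(1L)                                  # ispg
  wi(0L)                                  # nsymbt
  wi(rep(0L, 2))                          # extra 25-26
  writeChar("MRC ", con, 4, eos = NULL)   # exttyp
  wi(20140L)                              # nversion
  wi(rep(0L, 21))                         # remaining extra
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(g)))            # rms
  wi(1L)                                  # nlabl
  lab <- sprintf("%-80s", "abmorph synthetic density")
  writeChar(lab, con, 80, eos = NULL)
  writeChar(strrep(" ", 80 * 9), con, 80 * 9, eos = NULL)
  writeBin(as.numeric(g), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume or image
#'
#' @param path MRC file (mode 0, 1 or 2, little-endian).
#' @return A [density_field()]; nz = 1 files collapse to 2D.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)
  m <- ri(3)
  cella <- rf(3)
  seek(con, 0)
  hdr <- readBin(con, "raw", 1024)
  if (any(m <= 0) || any(cella <= 0))
    stop("MRC header lacks cell dimensions: calibration is mandatory")
  voxel_nm <- cella[1] / m[1] / 10
  seek(con, 1024 + ri_ext(hdr))
  n <- prod(d)
  g <- switch(as.character(mode),
              "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
              "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
              "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
              stop("unsupported MRC mode: ", mode))
  dim(g) <- d
  if (d[3] == 1) g <- g[, , 1]
  density_field(g, voxel_nm)
}

# extended-header length (nsymbt, word 24, byte offset 92)
ri_ext <- function(hdr) {
  readBin(hdr[93:96], "integer", 1, size = 4, endian = "little")
}

#' Write an AFM height-map series as multi-page float TIFF + sidecar
#'
#' Heights are stored in micrometres (so values stay inside the unit
#' range the float TIFF writer requires); the JSON sidecar records the
#' pixel size, frame interval, timestamps and height units.
#'
#' @param series A [height_map_series()].
#' @param path Output `.tif` path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_afm_series <- function(series, path) {
  stopifnot(inherits(series, "height_map_series"))
  # stored value = (height_nm + offset) / scale, keeping slightly
  # negative (noise) heights inside the unit range the writer needs
  offset_nm <- 100
  scale_nm <- 1000
  pages <- lapply(series$frames, function(f) (f + offset_nm) / scale_nm)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_nm = series$pixel_size,
               frame_interval_min = series$frame_interval,
               timestamps_min = series$timestamps,
               height_offset_nm = offset_nm,
               height_scale_nm = scale_nm)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an AFM height-map series (TIFF + JSON sidecar)
#'
#' @param path `.tif` path written by [write_afm_series()]; the sidecar
#'   `<path>.json` must exist (no pixel-unit fallback).
#' @return A [height_map_series()] with heights in nm.
#' @export
read_afm_series <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar '", sidecar, "': calibration is mandatory")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("pixel_size_nm", "frame_interval_min", "timestamps_min")
  if (!all(need %in% names(meta)))
    stop("sidecar lacks calibration fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  offset <- if (is.null(meta$height_offset_nm)) 0 else meta$height_offset_nm
  scale <- if (is.null(meta$height_scale_nm)) 1 else meta$height_scale_nm
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * scale - offset
  })
  height_map_series(frames, meta$pixel_size_nm, meta$frame_interval_min,
                    meta$timestamps_min)
}

#' Write a current trace as CSV + JSON metadata header
#'
#' @param trace A [current_trace()].
#' @param path Output `.csv`; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  utils::write.csv(data.frame(time_ms = trace$t_ms,
                              current_pA = trace$i_pA,
                              voltage_mV = trace$v_mV),
                   path, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = trace$sampling_rate,
                            filter_cutoff_hz = trace$filter_cutoff),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a current trace CSV (+ JSON metadata)
#'
#' @param path `.csv` with columns time_ms, current_pA, voltage_mV;
#'   `<path>.json` must hold the sampling metadata.
#' @return A [current_trace()].
#' @export
read_trace_csv <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON metadata '", sidecar, "': sampling rate is mandatory")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz))
    stop("metadata lacks sampling_rate_hz")
  df <- utils::read.csv(path)
  need <- c("time_ms", "current_pA", "voltage_mV")
  if (!all(need %in% names(df)))
    stop("trace CSV lacks columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (!nrow(df)) stop("no samples in '", path, "'")
  fc <- if (is.null(meta$filter_cutoff_hz)) NA_real_ else meta$filter_cutoff_hz
  current_trace(df$time_ms, df$current_pA, df$voltage_mV,
                meta$sampling_rate_hz, fc)
}

#' Write / read a kinetic curve CSV
#'
#' Columns `time_h` (or `time_min`) and `fluorescence_au`.
#'
#' @param curve A [kinetic_curve()].
#' @param path CSV path.
#' @return `path` / a [kinetic_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "kinetic_curve"))
  df <- data.frame(t = curve$t, fluorescence_au = curve$f)
  names(df)[1] <- paste0("time_", curve$t_units)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  tcol <- grep("^time_(h|min)$", names(df), value = TRUE)
  if (length(tcol) != 1 || !"fluorescence_au" %in% names(df))
    stop("curve CSV needs time_h/time_min and fluorescence_au columns")
  kinetic_curve(df[[tcol]], df$fluorescence_au, sub("time_", "", tcol))
}

#' Write an analysis report as JSON with embedded configuration
#'
#' Every report embeds the resolved [run_config()] (constants and
#' conventions) and the package version, so outputs are reproducible
#' from their own metadata.
#'
#' @param x Named list of results.
#' @param path Output JSON path.
#' @param config A [run_config()].
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, config = run_config()) {
  stopifnot(inherits(config, "abmorph_config"))
  jsonlite::write_json(c(x, list(config = unclass(config))), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-particle measurements as CSV
#'
#' One row per particle: id, t_label, length_nm, mean_diameter_nm,
#' height_nm, border_flag, branch_flag (missing fields allowed as NA).
#'
#' @param df Measurements data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
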