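#' Write a continuous recording as flat binary plus JSON sidecar
#'
#' Samples are quantized to little-endian 16-bit integers at
#' \code{uv_per_count} microvolts per count and written sample-major
#' (frame by frame, channels interleaved) to \code{<prefix>.bin}; the
#' sidecar \code{<prefix>.json} records the schema version, sampling rate,
#' dimensions, scaling, and the channel-to-layer map. Samples exceeding
#' the 16-bit range are clipped with a warning.
#'
#' @param rec a \code{continuous_recording}.
#' @param prefix output path prefix (without extension).
#' @param uv_per_count quantization step (uV per integer count).
#' @return the prefix, invisibly.
#' @export
write_recording <- function(rec, prefix, uv_per_count = 0.1) {
  stopifnot(inherits(rec, "continuous_recording"))
  counts <- round(rec$samples / uv_per_count)
  if (any(abs(counts) > 32767)) {
    warning("samples exceed 16-bit range; clipping")
    counts <- pmin(pmax(counts, -32768), 32767)
  }
  sidecar <- list(schema_version = 1L,
                  sampling_rate = rec$sampling_rate,
                  n_channels = ncol(rec$samples),
                  n_samples = nrow(rec$samples),
                  uv_per_count = uv_per_count,
                  t_start_s = rec$t_start_s,
                  dtype = "int16", byte_order = "little",
                  filtered = isTRUE(rec$filtered),
                  layer_of_channel = if (!is.null(rec$probe))
                    as.character(rec$probe$layer) else NULL,
                  shank_of_channel = if (!is.null(rec$probe))
                    as.integer(rec$probe$shank) else NULL)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(counts)), con, size = 2L, endian = "little")
  invisible(prefix)
}

#' Read a continuous recording written by \code{\link{write_recording}}
#'
#' Validates the sidecar schema and that the binary payload length matches
#' the declared dimensions, then reconstructs the trace in microvolts
#' (stored counts times \code{uv_per_count}).
#'
#' @param prefix path prefix (without extension).
#' @return a \code{continuous_recording}.
#' @export
read_recording <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (is.null(side$schema_version) || side$schema_version != 1L)
    stop("unknown recording schema version")
  needed <- c("sampling_rate", "n_channels", "n_samples", "uv_per_count")
  if (!all(needed %in% names(side)))
    stop("sidecar missing required fields")
  n_total <- side$n_samples * side$n_channels
  bin_path <- paste0(prefix, ".bin")
  if (file.info(bin_path)$size != 2 * n_total)
    stop("binary length does not match sidecar dimensions")
  con <- file(bin_path, "rb")
  on.exit(close(con))
  counts <- readBin(con, "integer", n = n_total, size = 2L, signed = TRUE,
                    endian = "little")
  samples <- matrix(counts * side$uv_per_count, nrow = side$n_samples,
                    ncol = side$n_channels, byrow = TRUE)
  probe <- NULL
  if (!is.null(side$layer_of_channel))
    probe <- data.frame(channel = seq_len(side$n_channels),
                        shank = if (!is.null(side$shank_of_channel))
                          side$shank_of_channel else 1L,
                        layer = side$layer_of_channel)
  new_continuous_recording(samples, side$sampling_rate,
                           t_start_s = if (!is.null(side$t_start_s))
                             side$t_start_s else 0,
                           probe = probe,
                           filtered = isTRUE(side$filtered))
}

#' Write / read event tables as CSV
#'
#' Plain UTF-8 comma-separated tables with a header row; event times are
#' seconds from recording start.
#'
#' @param x data.frame.
#' @param path file path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
write_events_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
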