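# Minimal multi-page 16-bit grayscale TIFF codec (uncompressed, little-endian)
# plus the JSON sidecar carrying the acquisition geometry. Hand-written
# because no TIFF package is available in the supported R stack; the writer
# emits baseline TIFF 6.0 that tifffile/ImageJ read, and the reader accepts
# any uncompressed single-sample 16-bit stack (one or more strips per page).

.w16 <- function(x) writeBin(as.integer(ifelse(x > 32767L, x - 65536L, x)),
                             raw(), size = 2L, endian = "little")
.w32 <- function(x) writeBin(as.integer(ifelse(x > 2147483647, x - 4294967296, x)),
                             raw(), size = 4L, endian = "little")

.ifd_entry <- function(tag, type, count, value_raw) {
  # value_raw must already be 4 bytes (value or offset)
  c(.w16(tag), .w16(type), .w32(count), value_raw)
}

.short_val <- function(x) c(.w16(x), as.raw(c(0, 0)))

#' Write frames as a multi-page 16-bit TIFF
#'
#' Values are clamped to `[0, 65535]` and rounded. One strip per page,
#' no compression, little-endian byte order.
#'
#' @param frames list of numeric matrices (identical dimensions).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(frames, path) {
  if (!is.list(frames) || length(frames) == 0L)
    stop_invalid("frames", "must be a non-empty list of matrices")
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  npix <- nr * nc; nbytes <- 2L * npix
  n <- length(frames)

  # layout: 8-byte header | page data blocks | IFDs
  data_off <- 8 + (seq_len(n) - 1) * nbytes
  ifd_len <- 2 + 9 * 12 + 4
  ifd_off <- 8 + n * nbytes + (seq_len(n) - 1) * ifd_len

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.w16(42), con)
  writeBin(.w32(ifd_off[1]), con)

  for (i in seq_len(n)) {
    v <- round(as.numeric(t(frames[[i]])))      # row-major strip order
    v <- pmin(pmax(v, 0), 65535)
    writeBin(.w16(v), con)
  }

  for (i in seq_len(n)) {
    entries <- c(
      .ifd_entry(256L, 4L, 1L, .w32(nc)),           # ImageWidth
      .ifd_entry(257L, 4L, 1L, .w32(nr)),           # ImageLength
      .ifd_entry(258L, 3L, 1L, .short_val(16L)),    # BitsPerSample
      .ifd_entry(259L, 3L, 1L, .short_val(1L)),     # Compression: none
      .ifd_entry(262L, 3L, 1L, .short_val(1L)),     # Photometric: BlackIsZero
      .ifd_entry(273L, 4L, 1L, .w32(data_off[i])),  # StripOffsets
      .ifd_entry(277L, 3L, 1L, .short_val(1L)),     # SamplesPerPixel
      .ifd_entry(278L, 4L, 1L, .w32(nr)),           # RowsPerStrip
      .ifd_entry(279L, 4L, 1L, .w32(nbytes))        # StripByteCounts
    )
    nxt <- if (i < n) ifd_off[i + 1] else 0
    writeBin(c(.w16(9L), entries, .w32(nxt)), con)
  }
  invisible(path)
}

#' Read a multi-page 16-bit grayscale TIFF
#'
#' Supports uncompressed, single-sample, 16-bit pages in either byte order,
#' with one or more strips per page.
#'
#' @param path file path.
#' @return A list of integer matrices.
#' @export
read_tiff16 <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("TIFF file not found: %s", path))
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 8) stop_io("not a TIFF file (too short)")
  order_tag <- rawToChar(bytes[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop_io("not a TIFF file (bad byte-order mark)")

  u16 <- function(off) readBin(bytes[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(bytes[(off + 1):(off + 4)], "integer", size = 4,
                 endian = endian)
    if (v < 0) v + 4294967296 else v
  }
  if (u16(2) != 42) stop_io("not a TIFF file (bad magic)")

  read_values <- function(entry_off) {
    type <- u16(entry_off + 2); count <- u32(entry_off + 4)
    size <- c(1, 1, 2, 4)[type]    # BYTE, ASCII, SHORT, LONG
    if (is.na(size)) stop_io("unsupported TIFF field type")
    rd <- if (size == 2) u16 else if (size == 4) u32 else
      function(o) as.integer(bytes[o + 1])
    total <- size * count
    base <- if (total <= 4) entry_off + 8 else u32(entry_off + 8)
    vapply(seq_len(count) - 1L, function(k) rd(base + k * size), numeric(1))
  }

  frames <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n_entries <- u16(ifd)
    tags <- list()
    for (j in seq_len(n_entries) - 1L) {
      off <- ifd + 2 + j * 12
      tags[[as.character(u16(off))]] <- read_values(off)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop_io("TIFF page missing required tags")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stop_io("compressed TIFF not supported")
    if (!is.null(tags[["258"]]) && any(tags[["258"]] != 16))
      stop_io("only 16-bit TIFF supported")
    nc <- tags[["256"]]; nr <- tags[["257"]]
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    pix <- unlist(lapply(seq_along(offs), function(s) {
      readBin(bytes[(offs[s] + 1):(offs[s] + cnts[s])], "integer",
              n = cnts[s] / 2, size = 2, signed = FALSE, endian = endian)
    }))
    if (length(pix) != nr * nc) stop_io("TIFF strip data does not match dims")
    frames[[length(frames) + 1L]] <- matrix(pix, nrow = nr, ncol = nc,
                                            byrow = TRUE)
    ifd <- u32(ifd + 2 + n_entries * 12)
  }
  frames
}

#' Write a frame stack to disk (TIFF + JSON sidecar)
#'
#' Writes `<prefix>.tif` (multi-page 16-bit TIFF) and `<prefix>.json` with the
#' acquisition geometry: SID, detector pitch, ROI (0-based, pixel-center
#' convention), DRR reference position, field long-axis angle, timestamps and
#' provenance.
#'
#' @param stack a [frame_stack()].
#' @param prefix output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_frame_stack <- function(stack, prefix) {
  if (!inherits(stack, "frame_stack"))
    stop_invalid("stack", "must be a frame_stack object")
  write_tiff16(stack$frames, paste0(prefix, ".tif"))
  meta <- list(
    sid_cm = stack$sid_cm,
    detector_pitch_mm = stack$detector_pitch_mm,
    roi = stack$roi,
    reference_position_mm = stack$reference_position_mm,
    field_long_axis_deg = stack$field_long_axis_deg,
    timestamps_s = stack$timestamps,
    patient_id = stack$patient_id,
    fraction = stack$fraction,
    field = stack$field,
    pixel_convention = "0-based indices, positions at pixel centers",
    units = list(position = "mm at isocenter plane", pitch = "mm/pixel",
                 sid = "cm")
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param prefix path prefix (expects `<prefix>.tif` and `<prefix>.json`).
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(prefix) {
  tif <- paste0(prefix, ".tif"); sidecar <- paste0(prefix, ".json")
  if (!file.exists(tif)) stop_io(sprintf("missing frame stack: %s", tif))
  if (!file.exists(sidecar))
    stop_io(sprintf("missing sidecar metadata: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  frames <- read_tiff16(tif)
  frame_stack(
    frames = frames,
    sid_cm = meta$sid_cm,
    detector_pitch_mm = meta$detector_pitch_mm,
    roi = meta$roi,
    reference_position_mm = meta$reference_position_mm,
    field_long_axis_deg = meta$field_long_axis_deg %||% 0,
    timestamps = meta$timestamps_s,
    patient_id = meta$patient_id %||% NA_character_,
    fraction = meta$fraction %||% NA_integer_,
    field = meta$field %||% NA_character_
  )
}
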