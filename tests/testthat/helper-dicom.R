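# Minimal explicit-VR little-endian DICOM writer used only to build test
# fixtures in code (the package itself is read-only for DICOM).

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                    endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                    endian = "little")

dcm_pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

dcm_element <- function(group, elem, vr, value_raw) {
  value_raw <- dcm_pad_even(value_raw,
                            if (vr %in% c("DS", "CS", "LO"))
                              charToRaw(" ") else as.raw(0L))
  hdr <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(hdr, as.raw(c(0, 0)), dcm_raw_u32(length(value_raw)), value_raw)
  } else {
    c(hdr, dcm_raw_u16(length(value_raw)), value_raw)
  }
}

dcm_ds <- function(group, elem, values) {
  dcm_element(group, elem, "DS",
              charToRaw(paste(format(values, digits = 10, trim = TRUE),
                              collapse = "\\")))
}

dcm_us <- function(group, elem, value) {
  dcm_element(group, elem, "US", dcm_raw_u16(value))
}

# stored is an [x, y] integer matrix of stored pixel values (int16)
write_dicom_slice <- function(path, stored, spacing_xy = c(1, 1),
                              position = c(0, 0, 0), slope = 1,
                              intercept = 0) {
  ts <- dcm_element(2L, 16L, "UI", charToRaw("1.2.840.10008.1.2.1"))
  meta_body <- ts
  meta <- c(dcm_element(2L, 0L, "UL", dcm_raw_u32(length(meta_body))),
            meta_body)
  px <- writeBin(as.integer(stored), raw(), size = 2L, endian = "little")
  body <- c(
    dcm_ds(0x20L, 0x32L, position),
    dcm_ds(0x20L, 0x37L, c(1, 0, 0, 0, 1, 0)),
    dcm_us(0x28L, 0x10L, ncol(stored)),          # Rows
    dcm_us(0x28L, 0x11L, nrow(stored)),          # Columns
    dcm_ds(0x28L, 0x30L, c(spacing_xy[2], spacing_xy[1])),  # row, col
    dcm_us(0x28L, 0x100L, 16L),
    dcm_us(0x28L, 0x101L, 16L),
    dcm_us(0x28L, 0x103L, 1L),
    dcm_ds(0x28L, 0x1052L, intercept),
    dcm_ds(0x28L, 0x1053L, slope),
    dcm_element(0x7fe0L, 0x10L, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

write_dicom_series_fixture <- function(dir, volume_stored, spacing = c(1, 1, 1),
                                       origin = c(0, 0, 0), slope = 1,
                                       intercept = 0, z_positions = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nz <- dim(volume_stored)[3]
  if (is.null(z_positions)) z_positions <- origin[3] + (0:(nz - 1)) * spacing[3]
  for (k in seq_len(nz)) {
    write_dicom_slice(
      file.path(dir, sprintf("slice%03d.dcm", k)),
      volume_stored[, , k], spacing_xy = spacing[1:2],
      position = c(origin[1:2], z_positions[k]),
      slope = slope, intercept = intercept)
  }
  dir
}
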