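# Minimal DICOM series reader: uncompressed, explicit-VR little-endian CT
# slices only. Enough of Part 10 is parsed to recover geometry, the rescale
# slope/intercept and the pixel data; everything else is skipped. Encapsulated
# transfer syntaxes and undefined-length sequences are refused.

dcm_u16 <- function(b, pos) {
  as.integer(b[pos]) + 256L * as.integer(b[pos + 1L])
}

dcm_u32 <- function(b, pos) {
  sum(as.numeric(b[pos + 0:3]) * c(1, 256, 65536, 16777216))
}

DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# walk the element stream from byte offset `pos` (1-based), collecting the
# tags in `want` (names "ggggeeee") until the buffer ends
dcm_parse_elements <- function(b, pos, want, path) {
  out <- list()
  n <- length(b)
  while (pos + 7 <= n + 1 && pos <= n) {
    group <- dcm_u16(b, pos); elem <- dcm_u16(b, pos + 2L)
    vr <- rawToChar(b[pos + 4:5])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt DICOM element stream in ", path)
    if (vr %in% DCM_LONG_VRS) {
      len <- dcm_u32(b, pos + 8L)
      hdr_len <- 12L
    } else {
      len <- dcm_u16(b, pos + 6L)
      hdr_len <- 8L
    }
    if (len == 4294967295)
      stop("undefined-length elements (sequences) are not supported: ", path)
    key <- sprintf("%04x%04x", group, elem)
    if (key %in% want) {
      val_raw <- b[(pos + hdr_len):(pos + hdr_len + len - 1L)]
      out[[key]] <- list(vr = vr, raw = val_raw)
    }
    pos <- pos + hdr_len + len
  }
  out
}

dcm_val_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$raw))
}

dcm_val_ds <- function(el, default = NULL) {
  s <- dcm_val_str(el)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_val_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", n = length(el$raw) %/% 2L, size = 2L,
          signed = FALSE, endian = "little")
}

read_dicom_slice <- function(path) {
  b <- readBin(path, "raw", n = file.size(path))
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path)
  want <- c("00020010",                      # transfer syntax
            "00280010", "00280011",          # rows, columns
            "00280100", "00280103",          # bits allocated, pixel rep
            "00280030", "00200032", "00200037",
            "00281052", "00281053",
            "7fe00010")
  els <- dcm_parse_elements(b, 133L, want, path)
  ts <- dcm_val_str(els[["00020010"]])
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax '", ts,
         "' (explicit VR little endian only): ", path)
  rows <- dcm_val_us(els[["00280010"]]); cols <- dcm_val_us(els[["00280011"]])
  bits <- dcm_val_us(els[["00280100"]])
  pixrep <- dcm_val_us(els[["00280103"]])
  if (is.null(rows) || is.null(cols) || is.null(els[["7fe00010"]]))
    stop("missing image geometry or pixel data in ", path)
  if (is.null(bits) || bits != 16L)
    stop("only 16-bit pixel data is supported: ", path)
  orient <- dcm_val_ds(els[["00200037"]], c(1, 0, 0, 0, 1, 0))
  if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-9)
    stop("non-axis-aligned slice orientation in ", path,
         "; axis-aligned grids only")
  px <- readBin(els[["7fe00010"]]$raw, "integer", n = rows * cols,
                size = 2L, signed = identical(pixrep, 1L), endian = "little")
  if (length(px) != rows * cols)
    stop("pixel data length mismatch in ", path)
  slope <- dcm_val_ds(els[["00281053"]], 1)[1]
  intercept <- dcm_val_ds(els[["00281052"]], 0)[1]
  spacing <- dcm_val_ds(els[["00280030"]], c(1, 1))  # row spacing, col spacing
  ipp <- dcm_val_ds(els[["00200032"]], c(0, 0, 0))
  # DICOM pixel order is row-major (column index fastest), so filling an
  # R matrix [x = col, y = row] directly preserves the raster
  hu <- matrix(px * slope + intercept, nrow = cols, ncol = rows)
  list(hu = hu, spacing_xy = c(spacing[2], spacing[1]), position = ipp)
}

#' Read a DICOM series as an image volume
#'
#' Reads every `.dcm`/`.DCM` file (or all files, if none carry the extension)
#' in `dir`, applies each slice's rescale slope and intercept to obtain HU,
#' sorts slices by their z position and checks the stack is uniformly spaced
#' and axis-aligned.
#'
#' @param dir directory holding one slice per file.
#' @param gap_tol tolerance (mm) on inter-slice gap uniformity.
#' @return an [image_volume()].
#' @export
read_dicom_series <- function(dir, gap_tol = 1e-4) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) files <- list.files(dir, full.names = TRUE)
  if (length(files) == 0L) stop("no DICOM files in ", dir)
  slices <- lapply(files, read_dicom_slice)
  z <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  d1 <- dim(slices[[1]]$hu)
  same <- vapply(slices, function(s) identical(dim(s$hu), d1), TRUE)
  if (!all(same)) stop("slices in ", dir, " differ in matrix size")
  if (length(slices) > 1L) {
    gaps <- diff(z)
    if (any(gaps <= 0)) stop("duplicate or unsorted slice positions in ", dir)
    if (max(gaps) - min(gaps) > gap_tol)
      stop("inconsistent slice spacing in ", dir, ": gaps range ",
           format(min(gaps)), " to ", format(max(gaps)), " mm")
    dz <- mean(gaps)
  } else dz <- 1
  vox <- array(0, c(d1, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  sp_xy <- slices[[1]]$spacing_xy
  origin <- c(slices[[1]]$position[1:2], z[1])
  image_volume(vox, spacing = c(sp_xy, dz), origin = origin)
}
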