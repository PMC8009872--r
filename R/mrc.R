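# MRC2014 reader/writer. Mode 2 (float32) is the native write format;
# modes 0 (int8), 1 (int16) and 6 (uint16) are readable. Little-endian.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 file
#'
#' @param path file path.
#' @return 2D matrix or 3D array with attribute `pixel_size` (Angstrom,
#'   from `cella/mx`); malformed or truncated files raise an error naming
#'   the failing byte offset.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", MRC_HEADER_BYTES)
  if (length(hdr_raw) < MRC_HEADER_BYTES) {
    stop_bisectr("malformed MRC header: only %d of %d bytes at offset 0",
                 length(hdr_raw), MRC_HEADER_BYTES)
  }
  ints <- readBin(hdr_raw, "integer", 56, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]
  floats <- readBin(hdr_raw[41:64], "numeric", 6, size = 4, endian = "little")
  xlen <- floats[1]
  if (!identical(hdr_raw[209:211], charToRaw("MAP"))) {
    stop_bisectr("malformed MRC header: missing MAP tag at byte offset 208")
  }
  if (nx <= 0 || ny <= 0 || nz <= 0) {
    stop_bisectr("malformed MRC header: non-positive dimensions at byte offset 0")
  }
  nsymbt <- ints[24]
  if (nsymbt > 0) {
    skipped <- readBin(con, "raw", nsymbt)
    if (length(skipped) < nsymbt) {
      stop_bisectr("truncated extended header at byte offset %d",
                   MRC_HEADER_BYTES + length(skipped))
    }
  }
  n <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, signed = TRUE, endian = "little"),
    "1" = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    stop_bisectr("unsupported MRC mode %d (supported: 0, 1, 2, 6)", mode))
  if (length(data) < n) {
    bytes_per <- c("0" = 1, "1" = 2, "2" = 4, "6" = 2)[[as.character(mode)]]
    stop_bisectr("truncated MRC data: got %.0f of %.0f values (byte offset %.0f)",
                 length(data), n,
                 MRC_HEADER_BYTES + nsymbt + length(data) * bytes_per)
  }
  out <- if (nz == 1) matrix(data, nx, ny) else array(data, c(nx, ny, nz))
  attr(out, "pixel_size") <- if (mx > 0 && xlen > 0) xlen / mx else 1
  out
}

#' Write an MRC2014 file (mode 2, float32)
#'
#' @param data 2D matrix or 3D array.
#' @param path output path.
#' @param pixel_size Angstrom/voxel (defaults to the data's attribute or 1).
#' @return `path`, invisibly. Round-trips written by this writer preserve
#'   float32 data bitwise and the pixel size exactly.
#' @export
write_mrc <- function(data, path, pixel_size = NULL) {
  pixel_size <- pixel_size %||% attr(data, "pixel_size") %||% 1
  d <- dim(data) %||% c(length(data), 1L, 1L)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- as.numeric(data)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode
  wi(c(0, 0, 0))             # nxstart
  wi(d)                      # mx my mz
  wf(d * pixel_size)         # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(0, 0))                # ispg, nsymbt
  wi(rep(0, 25))             # extra
  wf(c(0, 0, 0))             # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(sd(vals))
  wi(1)                      # nlabl
  lab <- sprintf("%-80s", "bisectr")
  writeBin(charToRaw(substr(lab, 1, 80)), con)
  writeBin(raw(9 * 80), con)
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(path)
}
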