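#' Read and write 24-bit BMP images
#'
#' The sorting machine stores station images as uncompressed 24-bit Windows
#' BMP files, one folder per camera. These functions implement exactly that
#' dialect (BITMAPINFOHEADER, BI_RGB, bottom-up rows, BGR byte order, rows
#' padded to 4 bytes); PNG fixtures are handled by [read_image()].
#'
#' @param img an [rgb_image].
#' @param path file path.
#' @return `read_bmp` returns an [rgb_image]; `write_bmp` returns `path`
#'   invisibly.
#' @export
write_bmp <- function(img, path) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  h <- nrow(img); w <- ncol(img)
  rowbytes <- w * 3L
  pad <- (4L - rowbytes %% 4L) %% 4L
  datasize <- (rowbytes + pad) * h
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("BM"), con)
  u32(54L + datasize); u32(0L); u32(54L)                 # file header
  u32(40L); u32(w); u32(h); u16(1L); u16(24L)            # info header
  u32(0L); u32(datasize); u32(2835L); u32(2835L); u32(0L); u32(0L)
  # bottom-up rows, BGR
  body <- raw(datasize)
  padr <- raw(pad)
  pos <- 1L
  for (r in h:1) {
    px <- rbind(img[r, , 3], img[r, , 2], img[r, , 1])  # B,G,R interleave
    row <- as.raw(as.vector(px))
    body[pos:(pos + rowbytes - 1L)] <- row
    pos <- pos + rowbytes
    if (pad) { body[pos:(pos + pad - 1L)] <- padr; pos <- pos + pad }
  }
  writeBin(body, con)
  invisible(path)
}

#' @rdname write_bmp
#' @export
read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop_cocoon("read_bmp: not a BMP file: ", path, class = "format_error")
  le <- function(idx) sum(as.integer(raw[idx]) * 256^(seq_along(idx) - 1))
  offset <- le(11:14)
  w <- le(19:22); h <- le(23:26)
  bpp <- le(29:30); comp <- le(31:34)
  if (bpp != 24 || comp != 0)
    stop_cocoon("read_bmp: only uncompressed 24-bit BMP supported: ", path,
                class = "format_error")
  rowbytes <- w * 3L
  stride <- rowbytes + (4L - rowbytes %% 4L) %% 4L
  out <- array(0L, dim = c(h, w, 3))
  for (r in seq_len(h)) {
    start <- offset + (h - r) * stride
    row <- as.integer(raw[(start + 1):(start + rowbytes)])
    m <- matrix(row, nrow = 3)  # B,G,R
    out[r, , 1] <- m[3, ]; out[r, , 2] <- m[2, ]; out[r, , 3] <- m[1, ]
  }
  rgb_image(out)
}

#' Read a station image (BMP or PNG)
#'
#' @param path file path ending in `.bmp` or `.png`.
#' @return an [rgb_image].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(read_bmp(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
    return(rgb_image(round(a[, , 1:3] * 255)))
  }
  stop_cocoon("read_image: unsupported extension: ", path, class = "format_error")
}
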