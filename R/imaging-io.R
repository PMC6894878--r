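## Raster readers/writers. PNG goes through the png package; TIFF is a
## minimal in-package codec for uncompressed baseline TIFF (the common
## single-resolution export), with multi-IFD support so one level of a
## pyramidal export can be read.

#' Read a raster image
#'
#' Reads an 8- or 16-bit PNG or uncompressed TIFF into a [RasterImage-class].
#' Grayscale inputs are replicated across the three RGB channels; an alpha
#' channel is dropped; 16-bit data are linearly rescaled to 8-bit
#' (`round(x / 257)`), since the method is defined on stain color, not
#' absolute intensity. For multi-page (pyramidal) TIFFs, `level` selects the
#' image file directory to read.
#'
#' @param path file path; format is decided by the file's magic bytes.
#' @param id identifier to attach; defaults to the file name.
#' @param level 1-based IFD index for multi-page TIFF (default first).
#' @return A [RasterImage-class].
#' @examples
#' p <- tempfile(fileext = ".png")
#' writeImage(rasterImage(array(128L, c(8, 8, 3)), id = "x"), p)
#' img <- readImage(p)
#' @export
readImage <- function(path, id = NULL, level = 1L) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  magic <- readBin(path, "raw", n = 4L)
  px <- if (length(magic) >= 4L &&
            identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    .readPngPixels(path)
  } else if (length(magic) >= 2L &&
             (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
              identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    .readTiffPixels(path, level = level)
  } else {
    stop("unsupported raster format (not PNG or TIFF): ", path)
  }
  rasterImage(px, id = id)
}

.readPngPixels <- function(path) {
  arr <- tryCatch(png::readPNG(path), error = function(e)
    stop("corrupt or unreadable PNG: ", path, " (", conditionMessage(e), ")"))
  # readPNG returns doubles in [0,1]; 16-bit depth is already folded in.
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  nc <- dim(arr)[3]
  if (nc > 4L) stop("unsupported channel count (", nc, ") in ", path)
  px <- switch(as.character(nc),
    "1" = array(arr[, , 1], c(dim(arr)[1:2], 3L)),
    "2" = array(arr[, , 1], c(dim(arr)[1:2], 3L)),  # gray + alpha
    "3" = arr,
    "4" = arr[, , 1:3, drop = FALSE])
  array(as.integer(round(px * 255)), dim(px))
}

#' Write a raster image
#'
#' Writes 8-bit RGB as PNG or uncompressed baseline TIFF, chosen by the file
#' extension. The read/write round trip is bit-exact.
#'
#' @param image a [RasterImage-class].
#' @param path destination; extension `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path) {
  stopifnot(is(image, "RasterImage"))
  ext <- tolower(sub(".*\\.", "", path))
  px <- image@pixels
  if (ext == "png") {
    png::writePNG(array(px / 255, dim(px)), path)
  } else if (ext %in% c("tif", "tiff")) {
    .writeTiffPixels(px, path)
  } else {
    stop("unsupported output format: .", ext)
  }
  invisible(path)
}

## --- minimal TIFF codec (uncompressed, 8/16-bit, gray or RGB) ------------

.tiffTypeSize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

.readTiffPixels <- function(path, level = 1L) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("corrupt TIFF (truncated header): ", path)
  le <- identical(raw[1:2], as.raw(c(0x49, 0x49)))
  endian <- if (le) "little" else "big"
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                               size = 4, endian = endian)
  if (u16(2) != 42L) stop("corrupt TIFF (bad magic): ", path)
  ifd <- u32(4)
  lev <- 1L
  while (lev < level) {
    n <- u16(ifd)
    ifd <- u32(ifd + 2L + 12L * n)
    if (ifd == 0L) stop("TIFF has fewer than ", level, " levels: ", path)
    lev <- lev + 1L
  }
  n <- u16(ifd)
  tags <- list()
  for (k in seq_len(n)) {
    off <- ifd + 2L + 12L * (k - 1L)
    tag <- u16(off); typ <- u16(off + 2L); cnt <- u32(off + 4L)
    sz <- .tiffTypeSize[as.character(typ)]
    if (is.na(sz)) next
    nbytes <- sz * cnt
    voff <- if (nbytes <= 4L) off + 8L else u32(off + 8L)
    vals <- if (typ == 3L) {
      vapply(seq_len(cnt), function(i) u16(voff + 2L * (i - 1L)), 0L)
    } else if (typ == 4L) {
      vapply(seq_len(cnt), function(i) u32(voff + 4L * (i - 1L)), 0L)
    } else if (typ == 1L) {
      as.integer(raw[(voff + 1):(voff + cnt)])
    } else NULL
    if (!is.null(vals)) tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, ": ", path)
      default
    } else v
  }
  W <- need(256L); H <- need(257L)
  bits <- need(258L, 8L); spp <- need(277L, 1L)
  comp <- need(259L, 1L)
  if (comp != 1L)
    stop("unsupported TIFF compression scheme (", comp, "); ",
         "only uncompressed baseline TIFF is supported: ", path)
  if (spp > 4L) stop("unsupported channel count (", spp, ") in ", path)
  if (!all(bits == bits[1]) || !bits[1] %in% c(8L, 16L))
    stop("unsupported TIFF bit depth: ", path)
  bits <- bits[1]
  offs <- need(273L)
  rps <- need(278L, H)
  counts <- need(279L, ceiling(H / rps) * rps * W * spp * (bits / 8L))
  data <- raw(0)
  for (k in seq_along(offs))
    data <- c(data, raw[(offs[k] + 1):(offs[k] + counts[k])])
  npx <- H * W * spp
  vals <- if (bits == 8L) {
    as.integer(data[seq_len(npx)])
  } else {
    v <- readBin(data, "integer", n = npx, size = 2, signed = FALSE,
                 endian = endian)
    as.integer(round(v / 257))
  }
  # data are row-major, channel-interleaved
  arr <- aperm(array(vals, c(spp, W, H)), c(3, 2, 1))
  if (spp == 1L) arr <- array(arr, c(H, W, 3L))
  else if (spp == 2L) arr <- array(arr[, , 1L], c(H, W, 3L))
  else if (spp == 4L) arr <- arr[, , 1:3, drop = FALSE]
  arr
}

.writeTiffPixels <- function(px, path) {
  H <- dim(px)[1]; W <- dim(px)[2]
  data <- as.raw(aperm(px, c(3, 2, 1)))  # row-major, interleaved
  tags <- list(  # tag, type, count, value(s)
    list(256L, 4L, 1L, W), list(257L, 4L, 1L, H),
    list(258L, 3L, 3L, c(8L, 8L, 8L)), list(259L, 3L, 1L, 1L),
    list(262L, 3L, 1L, 2L),                  # RGB photometric
    list(273L, 4L, 1L, NA),                  # strip offset, patched below
    list(277L, 3L, 1L, 3L), list(278L, 4L, 1L, H),
    list(279L, 4L, 1L, length(data)))
  n <- length(tags)
  # layout: 8-byte header | IFD (2 + 12n + 4) | out-of-line values | data
  ifdSize <- 2L + 12L * n + 4L
  extraOff <- 8L + ifdSize
  extras <- raw(0)
  entries <- raw(0)
  for (t in tags) {
    typ <- t[[2]]; cnt <- t[[3]]; val <- t[[4]]
    sz <- .tiffTypeSize[as.character(typ)] * cnt
    entry <- c(writeBin(t[[1]], raw(), size = 2, endian = "little"),
               writeBin(typ, raw(), size = 2, endian = "little"),
               writeBin(cnt, raw(), size = 4, endian = "little"))
    if (t[[1]] == 273L) val <- extraOff + 0L  # patched after extras known
    enc <- if (typ == 3L) {
      do.call(c, lapply(as.integer(val), writeBin, raw(), size = 2,
                        endian = "little"))
    } else {
      do.call(c, lapply(as.integer(val), writeBin, raw(), size = 4,
                        endian = "little"))
    }
    if (sz <= 4L) {
      entry <- c(entry, enc, raw(4L - sz))
    } else {
      entry <- c(entry, writeBin(extraOff + length(extras), raw(), size = 4,
                                 endian = "little"))
      extras <- c(extras, enc)
    }
    entries <- c(entries, entry)
  }
  dataOff <- extraOff + length(extras)
  # patch strip offset (6th tag): value bytes at position 8 of its entry
  idx <- (6L - 1L) * 12L + 8L
  entries[(idx + 1):(idx + 4)] <- writeBin(dataOff, raw(), size = 4,
                                           endian = "little")
  out <- c(as.raw(c(0x49, 0x49)),
           writeBin(42L, raw(), size = 2, endian = "little"),
           writeBin(8L, raw(), size = 4, endian = "little"),
           writeBin(n, raw(), size = 2, endian = "little"),
           entries,
           writeBin(0L, raw(), size = 4, endian = "little"),
           extras, data)
  writeBin(out, path)
  invisible(path)
}

#' Write a label map as a color-coded PNG
#'
#' Uses the conventional palette: background blue, artefact black, RBC red,
#' WBC purple, fibrin pink; unclassified pixels white.
#'
#' @param labels a [LabelMap-class] whose legend uses the canonical class
#'   names (`background`, `artefact`, `rbc`, `wbc`, `fibrin`).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeLabelMapPng <- function(labels, path) {
  stopifnot(is(labels, "LabelMap"))
  pal <- rbind(unclassified = c(255, 255, 255),
               background = c(60, 90, 220), artefact = c(0, 0, 0),
               rbc = c(205, 40, 40), wbc = c(120, 60, 170),
               fibrin = c(240, 170, 190), tissue = c(205, 40, 40))
  key <- c("unclassified", labels@legend)
  unknown <- setdiff(key, rownames(pal))
  if (length(unknown))
    stop("no palette entry for class(es): ", paste(unknown, collapse = ", "))
  codes <- labels@labels + 1L
  arr <- array(0, c(dim(codes), 3L))
  for (ch in 1:3)
    arr[, , ch] <- matrix(pal[key, ch][codes], nrow(codes)) / 255
  png::writePNG(arr, path)
  invisible(path)
}
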