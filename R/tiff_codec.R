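# Minimal baseline TIFF codec.
#
# Parameter maps and image stacks are stored as 32-bit IEEE-float TIFFs,
# which must round-trip arbitrary values (including the -1 direction
# sentinel) bit-exactly. The codec covers exactly what the package needs:
# uncompressed single-sample images, grayscale, strip layout, multi-page,
# both byte orders on read; writing is always little-endian float32, one
# strip per page. Anything else (compression, tiles, palettes, multiple
# samples) is rejected with a clear error.

.TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

.read_ifd_values <- function(con, endian, type, count, raw4) {
  size <- .TIFF_TYPE_SIZE[type]
  total <- size * count
  get <- function(raw) {
    rc <- rawConnection(raw)
    on.exit(close(rc))
    switch(as.character(type),
      "1" = as.integer(readBin(rc, "integer", count, size = 1, signed = FALSE)),
      "3" = readBin(rc, "integer", count, size = 2, signed = FALSE,
                    endian = endian),
      "4" = readBin(rc, "integer", count, size = 4, endian = endian),
      "11" = readBin(rc, "double", count, size = 4, endian = endian),
      "12" = readBin(rc, "double", count, size = 8, endian = endian),
      stop("unsupported TIFF tag type ", type))
  }
  if (total <= 4L) {
    get(raw4[seq_len(max(total, 1L))])
  } else {
    rc2 <- rawConnection(raw4)
    off <- readBin(rc2, "integer", 1, size = 4, endian = endian)
    close(rc2)
    seek(con, off)
    get(readBin(con, "raw", total))
  }
}

# Reads all pages of a grayscale TIFF; returns list of numeric matrices
# (row, column) plus the sample format actually stored.
read_tiff_pages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4L)
  endian <- if (identical(hdr[1:2], charToRaw("II"))) "little"
            else if (identical(hdr[1:2], charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path)
  magic <- if (endian == "little")
    as.integer(hdr[3]) + 256L * as.integer(hdr[4])
  else as.integer(hdr[4]) + 256L * as.integer(hdr[3])
  if (magic != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
  pages <- list()
  while (ifd_off != 0L) {
    seek(con, ifd_off)
    n_tags <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                      endian = endian)
    tags <- vector("list", n_tags)
    for (k in seq_len(n_tags)) {
      id <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                    endian = endian)
      type <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                      endian = endian)
      count <- readBin(con, "integer", 1, size = 4, endian = endian)
      raw4 <- readBin(con, "raw", 4L)
      tags[[k]] <- list(id = id, type = type, count = count, raw4 = raw4)
    }
    next_off <- readBin(con, "integer", 1, size = 4, endian = endian)
    tag <- function(id, default = NULL) {
      hit <- Filter(function(t) t$id == id, tags)
      if (length(hit) == 0L) return(default)
      .read_ifd_values(con, endian, hit[[1]]$type, hit[[1]]$count,
                       hit[[1]]$raw4)
    }
    width <- tag(256L); height <- tag(257L)
    if (is.null(width) || is.null(height))
      stop("TIFF page missing dimensions")
    bits <- tag(258L, 1L)[1]
    if (tag(259L, 1L) != 1L)
      stop("compressed TIFF not supported; re-save uncompressed")
    if (tag(277L, 1L) != 1L)
      stop("only single-sample (grayscale) TIFF supported")
    fmt <- tag(339L, 1L)[1]      # 1 = unsigned int, 3 = IEEE float
    offs <- tag(273L); counts <- tag(279L)
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    buf <- raw(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      buf <- c(buf, readBin(con, "raw", counts[s]))
    }
    rc <- rawConnection(buf)
    npix <- width * height
    vals <- if (fmt == 3L) {
      if (!bits %in% c(32L, 64L)) stop("unsupported float depth ", bits)
      readBin(rc, "double", npix, size = bits %/% 8L, endian = endian)
    } else if (fmt %in% c(1L, 2L)) {
      signed <- fmt == 2L
      if (!bits %in% c(8L, 16L, 32L)) stop("unsupported bit depth ", bits)
      as.numeric(readBin(rc, "integer", npix, size = bits %/% 8L,
                         signed = signed || bits == 32L, endian = endian))
    } else stop("unsupported TIFF sample format ", fmt)
    close(rc)
    if (length(vals) != npix) stop("truncated TIFF strip data")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height, ncol = width,
                                          byrow = TRUE)
    ifd_off <- next_off
  }
  pages
}

# Writes matrices (row, column) as a multi-page little-endian float32 TIFF,
# one strip per page.
write_tiff_pages <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) > 0L)
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  sizes <- vapply(pages, function(m) 4L * length(m), integer(1))
  data_off <- integer(length(pages)); ifd_off <- integer(length(pages))
  cur <- 8L
  for (k in seq_along(pages)) {
    data_off[k] <- cur
    ifd_off[k] <- cur + sizes[k]
    cur <- ifd_off[k] + ifd_size
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L); w32(ifd_off[1])
  for (k in seq_along(pages)) {
    m <- pages[[k]]
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    entry <- function(id, type, count, value) {
      w16(id); w16(type); w32(count)
      if (type == 3L) { w16(value); w16(0L) } else w32(value)
    }
    w16(n_tags)
    entry(256L, 3L, 1L, ncol(m))            # ImageWidth
    entry(257L, 3L, 1L, nrow(m))            # ImageLength
    entry(258L, 3L, 1L, 32L)                # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression: none
    entry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off[k])        # StripOffsets
    entry(278L, 3L, 1L, nrow(m))            # RowsPerStrip
    entry(279L, 4L, 1L, sizes[k])           # StripByteCounts
    entry(339L, 3L, 1L, 3L)                 # SampleFormat: IEEE float
    w32(if (k < length(pages)) ifd_off[k + 1L] else 0L)
  }
  invisible(path)
}
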