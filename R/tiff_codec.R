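# Minimal baseline TIFF codec.
#
# No TIFF package is available in the supported dependency set, so the
# package carries its own reader/writer for the narrow profile it needs:
# grayscale, uncompressed, 8- or 16-bit unsigned, one strip set per IFD,
# one IFD per channel, little- or big-endian on read, little-endian on
# write. OME-XML metadata travels in the first IFD's ImageDescription.

# ---- byte helpers -----------------------------------------------------------

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(rbind(x %% 256L, x %/% 256L)))
}
u32le <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  as.raw(c(rbind(b0, b1, b2, b3)))
}

# TIFF directory entry: tag, type, count, 4-byte value field (raw)
tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4L)
  c(u16le(tag), u16le(type), u32le(count),
    value_raw, rep(as.raw(0L), 4L - length(value_raw)))
}

entry_short <- function(tag, v) tiff_entry(tag, 3L, 1L, u16le(v))
entry_long  <- function(tag, v) tiff_entry(tag, 4L, 1L, u32le(v))

# ---- writer -----------------------------------------------------------------

#' Write a multi-page grayscale TIFF
#'
#' Intensities are quantised to unsigned 16-bit (rounded, clipped to
#' 0..65535). One page per matrix; `description` (e.g. OME-XML) is attached
#' to the first page.
#'
#' @param path output file.
#' @param pages list of numeric matrices, all the same shape.
#' @param description optional character scalar stored as ImageDescription.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, pages, description = NULL) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  for (p in pages) {
    check_matrix(p, "page")
    if (nrow(p) != h || ncol(p) != w) stop_lq("all pages must share one shape")
  }
  n <- length(pages)
  strip_bytes <- w * h * 2L
  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(enc2utf8(description)), as.raw(0L))
    if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))  # word align
  }
  data_start <- 8L
  strip_off <- data_start + (seq_len(n) - 1L) * strip_bytes
  desc_off <- data_start + n * strip_bytes
  ifd_start <- desc_off + length(desc_raw)

  make_ifd <- function(i, next_off) {
    entries <- list(
      entry_long(256L, w),                       # ImageWidth
      entry_long(257L, h),                       # ImageLength
      entry_short(258L, 16L),                    # BitsPerSample
      entry_short(259L, 1L),                     # Compression = none
      entry_short(262L, 1L)                      # Photometric = BlackIsZero
    )
    if (i == 1L && !is.null(desc_raw))
      entries <- c(entries, list(tiff_entry(270L, 2L, length(desc_raw), u32le(desc_off))))
    entries <- c(entries, list(
      entry_long(273L, strip_off[i]),            # StripOffsets
      entry_short(277L, 1L),                     # SamplesPerPixel
      entry_long(278L, h),                       # RowsPerStrip
      entry_long(279L, strip_bytes),             # StripByteCounts
      entry_short(339L, 1L)                      # SampleFormat = uint
    ))
    c(u16le(length(entries)), do.call(c, entries), u32le(next_off))
  }
  ifd_sizes <- integer(n)
  for (i in seq_len(n)) {
    n_entries <- 10L + as.integer(i == 1L && !is.null(desc_raw))
    ifd_sizes[i] <- 2L + n_entries * 12L + 4L
  }
  ifd_off <- ifd_start + cumsum(c(0L, ifd_sizes))[seq_len(n)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(42L), u32le(ifd_off[1L])), con)
  for (p in pages) {
    q <- pmin(pmax(round(p), 0), 65535)
    writeBin(u16le(as.vector(t(q))), con)   # row-major
  }
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  for (i in seq_len(n)) {
    next_off <- if (i < n) ifd_off[i + 1L] else 0L
    writeBin(make_ifd(i, next_off), con)
  }
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

#' Read a grayscale TIFF
#'
#' Supports the baseline profile written by [write_tiff()] plus common
#' variants: either endianness, 8- or 16-bit unsigned samples, multiple
#' strips per page.
#'
#' @param path TIFF file.
#' @return list with `pages` (list of numeric matrices) and `description`
#'   (character or `NULL`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop_lq("file not found: ", path)
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 8L) stop_lq("not a TIFF file: ", path)
  order <- rawToChar(r[1:2])
  big <- switch(order, II = FALSE, MM = TRUE, stop_lq("not a TIFF file: ", path))
  rd <- function(off, nbytes) {  # unsigned int at 1-based offset
    b <- as.integer(r[off:(off + nbytes - 1L)])
    if (big) b <- rev(b)
    sum(b * 256^(seq_along(b) - 1L))
  }
  if (rd(3L, 2L) != 42L) stop_lq("not a baseline TIFF: ", path)

  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  read_values <- function(type, count, field_off) {
    sz <- type_size[type]
    total <- sz * count
    src <- if (total <= 4L) field_off else rd(field_off, 4L) + 1L
    vapply(seq_len(count), function(k) rd(src + (k - 1L) * sz, sz), 0)
  }

  pages <- list(); description <- NULL
  ifd_off <- rd(5L, 4L)
  while (ifd_off != 0L) {
    base <- ifd_off + 1L
    n_entries <- rd(base, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eoff <- base + 2L + (e - 1L) * 12L
      tag <- rd(eoff, 2L); type <- rd(eoff + 2L, 2L); count <- rd(eoff + 4L, 4L)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        field_off = eoff + 8L)
    }
    g <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      read_values(t$type, t$count, t$field_off)
    }
    w <- g(256L); h <- g(257L)
    if (is.null(w) || is.null(h)) stop_lq("TIFF page missing dimensions")
    bits <- g(258L, 8L)[1L]
    if (!bits %in% c(8L, 16L)) stop_lq("unsupported BitsPerSample: ", bits)
    if (g(259L, 1L)[1L] != 1L) stop_lq("compressed TIFF not supported")
    if (g(277L, 1L)[1L] != 1L) stop_lq("multi-sample TIFF not supported")
    offs <- g(273L); cnts <- g(279L)
    if (is.null(offs) || is.null(cnts)) stop_lq("TIFF page missing strip layout")
    buf <- raw(0)
    for (s in seq_along(offs)) buf <- c(buf, r[(offs[s] + 1L):(offs[s] + cnts[s])])
    npx <- w * h
    vals <- if (bits == 8L) {
      as.numeric(as.integer(buf[seq_len(npx)]))
    } else {
      b <- as.integer(buf[seq_len(2L * npx)])
      lo <- b[seq(1L, 2L * npx, 2L)]; hi <- b[seq(2L, 2L * npx, 2L)]
      if (big) as.numeric(hi + 256 * lo) else as.numeric(lo + 256 * hi)
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    dsc <- tags[["270"]]
    if (is.null(description) && !is.null(dsc)) {
      src <- if (type_size[dsc$type] * dsc$count <= 4L) dsc$field_off
             else rd(dsc$field_off, 4L) + 1L
      bytes <- r[src:(src + dsc$count - 1L)]
      bytes <- bytes[bytes != as.raw(0L)]
      description <- rawToChar(bytes)
    }
    ifd_off <- rd(base + 2L + n_entries * 12L, 4L)
  }
  list(pages = pages, description = description)
}

# ---- OME-XML ---------------------------------------------------------------

ome_ns <- "http://www.openmicroscopy.org/Schemas/OME/2016-06"

# Minimal OME-XML for an n-channel 2-D image with named channels and a
# physical pixel size. Only the subset the reader consumes is emitted.
build_ome_xml <- function(channel_names, size_y, size_x, pixel_size_um) {
  ch <- paste(sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
                      seq_along(channel_names) - 1L, channel_names),
              collapse = "")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="', ome_ns, '">',
    '<Image ID="Image:0" Name="scene">',
    sprintf(paste0('<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="uint16" ',
                   'SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="1" SizeT="1" ',
                   'PhysicalSizeX="%.10g" PhysicalSizeXUnit="µm" ',
                   'PhysicalSizeY="%.10g" PhysicalSizeYUnit="µm">'),
            size_x, size_y, length(channel_names), pixel_size_um, pixel_size_um),
    ch, '</Pixels></Image></OME>')
}

# Parse channel names / pixel size out of an OME-XML ImageDescription.
# Returns NULL when the description is not OME-XML.
parse_ome_xml <- function(description) {
  if (is.null(description) || !grepl("<OME", description, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  ns <- c(ome = xml2::xml_ns(doc)[[1L]] %||% ome_ns)
  px <- xml2::xml_find_first(doc, ".//ome:Pixels", ns)
  if (inherits(px, "xml_missing")) return(NULL)
  psx <- xml2::xml_attr(px, "PhysicalSizeX")
  chn <- xml2::xml_attr(xml2::xml_find_all(px, ".//ome:Channel", ns), "Name")
  list(pixel_size_um = if (!is.na(psx)) as.numeric(psx) else NULL,
       channel_names = if (length(chn) && !anyNA(chn)) chn else NULL)
}
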