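# Animated GIF89a export and a block-level GIF reader. Frames are encoded
# with a fixed 9-bit LZW stream (literal pixel codes with periodic clear
# codes — a valid LZW stream every decoder accepts, chosen so the whole
# encoder stays vectorised R). Colours are quantised to the exact set of
# colours used when there are at most 256, otherwise to the 6x6x6 colour
# cube.

le16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))

build_palette <- function(rasters) {
  keys <- unique(unlist(lapply(rasters, function(img) {
    unique(as.vector(img[, , 1]) * 65536L + as.vector(img[, , 2]) * 256L + as.vector(img[, , 3]))
  })))
  if (length(keys) <= 256L) {
    keys <- sort(keys)
    pal <- cbind(keys %/% 65536L, (keys %/% 256L) %% 256L, keys %% 256L)
    index_of <- function(img) {
      k <- as.vector(img[, , 1]) * 65536L + as.vector(img[, , 2]) * 256L + as.vector(img[, , 3])
      match(k, keys) - 1L
    }
  } else {
    lv <- as.integer(round(seq(0, 255, length.out = 6)))
    pal <- cbind(rep(lv, each = 36L), rep(rep(lv, each = 6L), times = 6L), rep(lv, times = 36L))
    index_of <- function(img) {
      qi <- function(ch) pmin(5L, pmax(0L, as.integer(round(as.vector(img[, , ch]) / 51))))
      qi(1) * 36L + qi(2) * 6L + qi(3)
    }
  }
  list(pal = pal, index_of = index_of)
}

# fixed-9-bit LZW stream: clear code 256, end-of-information 257; a clear is
# re-emitted every 250 literals so the decoder's table never forces a code
# width above 9 bits
lzw_fixed_stream <- function(indices) {
  clear <- 256L; eoi <- 257L
  n <- length(indices)
  chunks <- split(indices, ceiling(seq_len(max(n, 1L)) / 250L)[seq_len(n)])
  codes <- integer(0)
  for (ch in chunks) codes <- c(codes, clear, ch)
  if (!n) codes <- clear
  codes <- c(codes, eoi)
  bits <- matrix(0L, nrow = 9L, ncol = length(codes))
  for (b in 0:8) bits[b + 1L, ] <- bitwAnd(bitwShiftR(codes, b), 1L)
  bitvec <- as.integer(bits)                     # column-major: LSB-first per code
  pad <- (8L - length(bitvec) %% 8L) %% 8L
  packBits(c(bitvec, integer(pad)), type = "raw")  # first bit -> LSB of byte
}

sub_blocks <- function(bytes) {
  out <- raw(0)
  n <- length(bytes)
  pos <- 1L
  while (pos <= n) {
    take <- min(255L, n - pos + 1L)
    out <- c(out, as.raw(take), bytes[pos:(pos + take - 1L)])
    pos <- pos + take
  }
  c(out, as.raw(0L))
}

#' Export rasters as an animated GIF
#'
#' Encodes the frames with a shared global colour table and per-frame delay.
#' GIF stores delays in hundredths of a second, so `delay_ms` below 10 is
#' rejected.
#'
#' @param rasters non-empty list of integer rasters `[h, w, 3]`, all the
#'   same dimensions.
#' @param delay_ms per-frame delay in milliseconds (>= 10).
#' @param loop loop the animation indefinitely.
#' @param path optional output path.
#' @return raw vector of GIF bytes (invisibly when written to `path`).
#' @export
export_gif <- function(rasters, delay_ms = 100L, loop = TRUE, path = NULL) {
  if (!is.list(rasters) || !length(rasters)) {
    cm_abort("chemmorph_empty_input_error", "need at least one raster")
  }
  delay_ms <- as.numeric(delay_ms)
  if (!is.finite(delay_ms) || delay_ms < 10) {
    cm_abort("chemmorph_domain_error", "delay_ms must be >= 10 (GIF delay resolution is 10 ms)")
  }
  dims <- vapply(rasters, function(r) dim(r)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    cm_abort("chemmorph_domain_error", "all rasters must share the same dimensions")
  }
  h <- dims[1, 1]; w <- dims[2, 1]
  q <- build_palette(rasters)
  pal <- q$pal
  gct <- array(0L, dim = c(256L, 3L))
  gct[seq_len(nrow(pal)), ] <- pal
  delay_cs <- as.integer(round(delay_ms / 10))

  out <- c(charToRaw("GIF89a"),
           le16(w), le16(h),
           as.raw(0xF7),            # GCT present, 8 bits/pixel, 256 entries
           as.raw(0L),              # background colour index
           as.raw(0L),              # pixel aspect ratio
           as.raw(as.integer(t(gct))))
  if (loop) {
    out <- c(out, as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(0x03, 0x01)), le16(0L), as.raw(0L))
  }
  for (img in rasters) {
    idx <- q$index_of(img)                       # column-major = [row, col]
    idx <- as.integer(t(matrix(idx, nrow = h)))  # GIF wants row-major scanlines
    out <- c(out,
             as.raw(c(0x21, 0xF9, 0x04, 0x04)),  # GCE, disposal: do not dispose
             le16(delay_cs), as.raw(c(0L, 0L)),
             as.raw(0x2C), le16(0L), le16(0L), le16(w), le16(h), as.raw(0L),
             as.raw(8L),                         # LZW minimum code size
             sub_blocks(lzw_fixed_stream(idx)))
  }
  out <- c(out, as.raw(0x3B))
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

#' Inspect a GIF byte stream
#'
#' Block-level parse of a GIF87a/89a file: reports dimensions, frame count,
#' per-frame delays and whether a netscape looping extension is present.
#' Used to verify exported animations without an external decoder.
#'
#' @param x raw vector of GIF bytes or a file path.
#' @return list with `width`, `height`, `n_frames`, `delays_ms`, `loop`.
#' @export
gif_info <- function(x) {
  bytes <- if (is.raw(x)) x else readBin(x, "raw", n = file.info(x)$size)
  u8 <- function(i) as.integer(bytes[i])
  u16 <- function(i) u8(i) + 256L * u8(i + 1L)
  if (length(bytes) < 13L || rawToChar(bytes[1:4]) != "GIF8") {
    cm_abort("chemmorph_format_error", "not a GIF stream")
  }
  width <- u16(7L); height <- u16(9L)
  flags <- u8(11L)
  pos <- 14L
  if (bitwAnd(flags, 0x80L) > 0L) {
    pos <- pos + 3L * bitwShiftL(2L, bitwAnd(flags, 0x07L))
  }
  n_frames <- 0L; delays <- integer(); loop <- FALSE; pending_delay <- NA_integer_
  skip_subblocks <- function(p) {
    repeat {
      sz <- u8(p)
      p <- p + 1L
      if (sz == 0L) return(p)
      p <- p + sz
    }
  }
  while (pos <= length(bytes)) {
    marker <- u8(pos)
    if (marker == 0x3B) break
    if (marker == 0x21) {
      label <- u8(pos + 1L)
      if (label == 0xF9) {
        pending_delay <- u16(pos + 4L) * 10L
      }
      if (label == 0xFF && u8(pos + 2L) == 11L &&
          rawToChar(bytes[(pos + 3L):(pos + 13L)]) == "NETSCAPE2.0") {
        loop <- TRUE
      }
      pos <- skip_subblocks(pos + 2L)
    } else if (marker == 0x2C) {
      lflags <- u8(pos + 9L)
      pos <- pos + 10L
      if (bitwAnd(lflags, 0x80L) > 0L) {
        pos <- pos + 3L * bitwShiftL(2L, bitwAnd(lflags, 0x07L))
      }
      pos <- pos + 1L                # LZW minimum code size byte
      pos <- skip_subblocks(pos)
      n_frames <- n_frames + 1L
      delays <- c(delays, if (is.na(pending_delay)) 0L else pending_delay)
      pending_delay <- NA_integer_
    } else {
      cm_abort("chemmorph_format_error",
               sprintf("unexpected GIF block marker 0x%02X", marker))
    }
  }
  list(width = width, height = height, n_frames = n_frames,
       delays_ms = delays, loop = loop)
}
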