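# Minimal RIFF/AVI support for uncompressed grayscale streams.
#
# Scope: 'DIB ' (BI_RGB) video with 8-bit palettized or 24-bit RGB frames,
# which is what lossless grayscale microscopy exports use. Frames are stored
# bottom-up with rows padded to 4 bytes, per the DIB convention.

read_avi_frames <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 12 || rawToChar(raw[1:4]) != "RIFF" ||
      rawToChar(raw[9:12]) != "AVI ") {
    stop("not an AVI file: ", path, call. = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$bitcount <- NA_integer_
  state$width <- NA_integer_
  state$height <- NA_integer_
  state$frames <- list()
  walk_avi_chunks(raw, 13L, length(raw), state)
  if (length(state$frames) == 0) {
    stop("AVI contains no decodable uncompressed frames: ", path, call. = FALSE)
  }
  state$frames
}

u32le <- function(raw, off) {
  sum(as.integer(raw[off:(off + 3L)]) * c(1, 256, 65536, 16777216))
}

walk_avi_chunks <- function(raw, pos, end, state) {
  while (pos + 8L <= end + 1L) {
    fourcc <- rawToChar(raw[pos:(pos + 3L)])
    size <- u32le(raw, pos + 4L)
    body <- pos + 8L
    if (fourcc == "LIST") {
      walk_avi_chunks(raw, body + 4L, body + size - 1L, state)
    } else if (fourcc == "strf" && is.na(state$bitcount)) {
      state$width <- u32le(raw, body + 4L)
      h <- u32le(raw, body + 8L)
      if (h > 2^31) h <- h - 2^32  # top-down DIBs store negative height
      state$height <- abs(h)
      state$topdown <- h < 0
      state$bitcount <- u32le(raw, body + 14L) %% 65536
      compression <- u32le(raw, body + 16L)
      if (compression != 0) {
        stop("compressed AVI streams are not supported (BI_RGB only)",
             call. = FALSE)
      }
      if (!state$bitcount %in% c(8L, 24L)) {
        stop("unsupported AVI bit depth: ", state$bitcount, call. = FALSE)
      }
    } else if (grepl("^..d[bc]$", fourcc) && size > 0) {
      state$frames[[length(state$frames) + 1L]] <-
        decode_dib_frame(raw[body:(body + size - 1L)], state)
    }
    pos <- body + size + (size %% 2L)  # chunks are word-aligned
  }
}

decode_dib_frame <- function(bytes, state) {
  w <- state$width
  h <- state$height
  bpp <- state$bitcount %/% 8L
  stride <- ((w * bpp + 3L) %/% 4L) * 4L
  if (length(bytes) < stride * h) {
    stop("truncated AVI frame data", call. = FALSE)
  }
  vals <- as.integer(bytes)
  m <- matrix(0, nrow = h, ncol = w)
  for (r in seq_len(h)) {
    row_off <- (r - 1L) * stride
    # bottom-up storage: DIB row r is image row h - r + 1
    img_row <- if (isTRUE(state$topdown)) r else h - r + 1L
    if (bpp == 1L) {
      m[img_row, ] <- vals[row_off + seq_len(w)]
    } else {
      m[img_row, ] <- vals[row_off + (seq_len(w) - 1L) * 3L + 1L]  # B of BGR
    }
  }
  m
}

#' Write a frame stack as an uncompressed grayscale AVI
#'
#' Stores frames as 8-bit palettized DIB ('DIB ' codec, BI_RGB) — a lossless
#' container for 8-bit data. Intensities must lie in 0..255.
#'
#' @param stack A [frame_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_avi <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  mx <- max(vapply(stack$frames, max, numeric(1)))
  if (mx > 255) stop("AVI writer is 8-bit; intensities exceed 255",
                     call. = FALSE)
  h <- nrow(stack$frames[[1]])
  w <- ncol(stack$frames[[1]])
  nf <- length(stack$frames)
  stride <- ((w + 3L) %/% 4L) * 4L
  frame_bytes <- stride * h

  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  tag <- function(x) writeChar(x, con, nchars = 4, eos = NULL)

  con <- file(path, "wb")
  on.exit(close(con))

  strf_size <- 40L + 256L * 4L
  hdrl_size <- 4L + (8L + 56L) +
    (8L + 4L + (8L + 56L) + (8L + strf_size))
  movi_size <- 4L + nf * (8L + frame_bytes)
  riff_size <- 4L + (8L + hdrl_size) + (8L + movi_size)

  tag("RIFF"); u32(riff_size); tag("AVI ")
  tag("LIST"); u32(hdrl_size); tag("hdrl")
  tag("avih"); u32(56)
  u32(round(stack$config$frame_interval_min * 60e6))  # usec per frame
  u32(frame_bytes); u32(0); u32(0x10)                 # rate, padding, HASINDEX off
  u32(nf); u32(0); u32(1); u32(frame_bytes)
  u32(w); u32(h); u32(0); u32(0); u32(0); u32(0)
  tag("LIST"); u32(4L + (8L + 56L) + (8L + strf_size)); tag("strl")
  tag("strh"); u32(56)
  tag("vids"); tag("DIB ")
  u32(0); u32(0); u32(0)                              # flags, prio, initial
  u32(1); u32(1)                                      # scale, rate (1 fps nominal)
  u32(0); u32(nf); u32(frame_bytes); u32(-1); u32(0)
  u16(0); u16(0); u16(w); u16(h)
  tag("strf"); u32(strf_size)
  u32(40); u32(w); u32(h); u16(1); u16(8)             # BITMAPINFOHEADER, 8-bit
  u32(0); u32(frame_bytes); u32(0); u32(0); u32(256); u32(256)
  # gray identity palette, RGBQUAD order (B, G, R, reserved)
  writeBin(as.raw(rep(0:255, each = 4) * rep(c(1, 1, 1, 0), 256)), con)
  tag("LIST"); u32(movi_size); tag("movi")
  for (f in stack$frames) {
    tag("00db"); u32(frame_bytes)
    buf <- raw(frame_bytes)
    for (r in seq_len(h)) {
      buf[(r - 1L) * stride + seq_len(w)] <-
        as.raw(round(f[h - r + 1L, ]))                # bottom-up rows
    }
    writeBin(buf, con)
  }
  invisible(path)
}
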