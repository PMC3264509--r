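# Deterministic scene rasterisation. Rasters are integer arrays
# [height, width, 3] with channels 0..255. The rasteriser draws filled
# discs for atoms, thick lines for bonds, rings for atomic shells and
# polylines for annotation outlines, with per-element alpha blending; no
# antialiasing, so output is bit-reproducible and palettes stay small for
# GIF export. Text labels are an SVG-only feature.

#' Create a blank raster
#' @param width,height pixel dimensions.
#' @param color background RGB triple.
#' @return integer array `[height, width, 3]`.
#' @export
blank_raster <- function(width, height, color = c(255L, 255L, 255L)) {
  color <- check_rgb(color)
  arr <- array(0L, dim = c(height, width, 3L))
  for (ch in 1:3) arr[, , ch] <- color[ch]
  arr
}

clamp255 <- function(x) pmin(pmax(as.integer(round(x)), 0L), 255L)

#' Scale the brightness of a raster
#'
#' Multiplies every channel by `factor` and clamps to 0..255. Factor 1
#' leaves the image unchanged; factors above 1 lighten it towards a
#' watermark, factor 0 gives black.
#'
#' @param image integer raster array `[h, w, 3]` (or `[h, w]` greyscale).
#' @param factor non-negative multiplier.
#' @return raster of the same shape.
#' @export
apply_brightness <- function(image, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor < 0) {
    cm_abort("chemmorph_domain_error", "brightness factor must be >= 0")
  }
  out <- clamp255(image * factor)
  dim(out) <- dim(image)
  out
}

blend_px <- function(img, rows, cols, color, opacity) {
  if (!length(rows)) return(img)
  for (ch in 1:3) {
    idx <- cbind(rows, cols, ch)
    img[idx] <- clamp255((1 - opacity) * img[idx] + opacity * color[ch])
  }
  img
}

disc_px <- function(w, h, cx, cy, r) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(cbind(integer(), integer()))
  gx <- x0:x1; gy <- y0:y1
  px <- rep(gx, each = length(gy)); py <- rep(gy, times = length(gx))
  keep <- (px - cx)^2 + (py - cy)^2 <= r^2
  cbind(py[keep], px[keep])
}

ring_px <- function(w, h, cx, cy, r, width) {
  rr <- r + width / 2
  x0 <- max(1L, floor(cx - rr)); x1 <- min(w, ceiling(cx + rr))
  y0 <- max(1L, floor(cy - rr)); y1 <- min(h, ceiling(cy + rr))
  if (x0 > x1 || y0 > y1) return(cbind(integer(), integer()))
  gx <- x0:x1; gy <- y0:y1
  px <- rep(gx, each = length(gy)); py <- rep(gy, times = length(gx))
  dist <- sqrt((px - cx)^2 + (py - cy)^2)
  keep <- abs(dist - r) <= width / 2
  cbind(py[keep], px[keep])
}

segment_px <- function(w, h, p1, p2, width) {
  pad <- width / 2 + 1
  x0 <- max(1L, floor(min(p1[1], p2[1]) - pad)); x1 <- min(w, ceiling(max(p1[1], p2[1]) + pad))
  y0 <- max(1L, floor(min(p1[2], p2[2]) - pad)); y1 <- min(h, ceiling(max(p1[2], p2[2]) + pad))
  if (x0 > x1 || y0 > y1) return(cbind(integer(), integer()))
  gx <- x0:x1; gy <- y0:y1
  px <- rep(gx, each = length(gy)); py <- rep(gy, times = length(gx))
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  len2 <- dx^2 + dy^2
  t <- if (len2 > 0) pmin(pmax(((px - p1[1]) * dx + (py - p1[2]) * dy) / len2, 0), 1) else 0
  qx <- p1[1] + t * dx; qy <- p1[2] + t * dy
  keep <- (px - qx)^2 + (py - qy)^2 <= (width / 2)^2
  cbind(py[keep], px[keep])
}

resize_nearest <- function(img, w, h) {
  hi <- dim(img)[1]; wi <- dim(img)[2]
  ri <- pmin(hi, pmax(1L, round(seq_len(h) * hi / h)))
  ci <- pmin(wi, pmax(1L, round(seq_len(w) * wi / w)))
  img[ri, ci, , drop = FALSE]
}

read_background <- function(bg, width, height) {
  if (!file.exists(bg$image_path)) {
    cm_abort("chemmorph_domain_error", sprintf("background image not found: %s", bg$image_path))
  }
  img <- png::readPNG(bg$image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  hw <- dim(img)[1:2]
  img <- clamp255(img[, , 1:3, drop = FALSE] * 255)
  dim(img) <- c(hw, 3L)
  img <- resize_nearest(img, width, height)
  apply_brightness(img, bg$brightness)
}

#' Rasterise a drawing
#'
#' @param d a `chem_drawing`.
#' @param style a [render_style()]; `style$center` fixes the scene point at
#'   the canvas centre.
#' @return integer raster array `[height, width, 3]`.
#' @export
render_raster <- function(d, style = render_style()) {
  validate_drawing(d)
  w <- style$width; h <- style$height
  img <- if (!is.null(d$background)) read_background(d$background, w, h) else
    blank_raster(w, h)
  tfm <- scene_to_px(style, d)
  a <- d$atoms; b <- d$bonds
  s <- style$scale

  for (key in names(d$shells)) {
    row <- match(as.integer(key), a$id)
    if (is.na(row)) next
    sh <- d$shells[[key]]
    p <- tfm(a$x[row], a$y[row])
    for (ri in seq_along(sh$radii)) {
      f <- if (length(sh$radii) > 1L) (ri - 1) / (length(sh$radii) - 1) else 0
      col <- clamp255((1 - f) * sh$inner + f * sh$outer)
      img <- blend_px(img, ring_px(w, h, p[1], p[2], sh$radii[ri] * s, style$bond_width)[, 1],
                      ring_px(w, h, p[1], p[2], sh$radii[ri] * s, style$bond_width)[, 2],
                      col, a$opacity[row])
    }
  }

  off <- style$double_bond_offset
  for (i in seq_len(nrow(b))) {
    r1 <- match(b$a1[i], a$id); r2 <- match(b$a2[i], a$id)
    p1 <- as.numeric(tfm(a$x[r1], a$y[r1])); p2 <- as.numeric(tfm(a$x[r2], a$y[r2]))
    col <- c(b$red[i], b$green[i], b$blue[i])
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    len <- sqrt(dx^2 + dy^2)
    nrm <- if (len > 0) c(-dy, dx) / len else c(0, 0)
    draw_seg <- function(im, q1, q2, wd = style$bond_width) {
      px <- segment_px(w, h, q1, q2, wd)
      blend_px(im, px[, 1], px[, 2], col, b$opacity[i])
    }
    img <- switch(b$kind[i],
      single = draw_seg(img, p1, p2),
      wedge = draw_seg(img, p1, p2, style$bond_width * 2),
      hash = draw_seg(img, p1, p2, style$bond_width * 2),
      double = draw_seg(draw_seg(img, p1 - off / 2 * nrm, p2 - off / 2 * nrm),
                        p1 + off / 2 * nrm, p2 + off / 2 * nrm),
      aromatic = draw_seg(draw_seg(img, p1, p2), p1 + off * nrm, p2 + off * nrm),
      triple = draw_seg(draw_seg(draw_seg(img, p1, p2),
                                 p1 - off * nrm, p2 - off * nrm),
                        p1 + off * nrm, p2 + off * nrm))
  }

  r_atom <- style$font_size / 3
  for (i in seq_len(nrow(a))) {
    p <- tfm(a$x[i], a$y[i])
    px <- disc_px(w, h, p[1], p[2], r_atom)
    img <- blend_px(img, px[, 1], px[, 2], c(a$red[i], a$green[i], a$blue[i]), a$opacity[i])
  }

  for (an in d$annotations) {
    if (is.null(an$outline) || nrow(an$outline) < 2L) next
    op <- if (is.null(an$opacity)) 1 else an$opacity
    p <- tfm(an$outline[, 1], an$outline[, 2])
    closed <- an$shape %in% c("ellipse", "club", "banana")
    idx <- if (closed) c(seq_len(nrow(p)), 1L) else seq_len(nrow(p))
    for (k in seq_len(length(idx) - 1L)) {
      px <- segment_px(w, h, p[idx[k], ], p[idx[k + 1L], ], style$bond_width)
      img <- blend_px(img, px[, 1], px[, 2], c(0L, 0L, 0L), op)
    }
  }
  img
}

#' Rasterise a list of morph frames with a shared transform
#'
#' All frames are rendered at the same canvas size and with the same
#' scene-to-pixel transform (centred on the union of the frames' bounding
#' boxes), so the animation is spatially aligned. Backgrounds are
#' brightness-adjusted and composited beneath each frame.
#'
#' @param frames non-empty list of `chem_drawing` objects.
#' @param style a [render_style()].
#' @return list of integer rasters, all of identical dimensions.
#' @export
render_frames <- function(frames, style = render_style()) {
  if (!length(frames)) cm_abort("chemmorph_empty_input_error", "no frames to render")
  if (is.null(style$center)) {
    bbs <- vapply(frames, drawing_bbox, numeric(4), pad = 0)
    bb <- c(min(bbs[1, ]), min(bbs[2, ]), max(bbs[3, ]), max(bbs[4, ]))
    style$center <- c((bb[1] + bb[3]) / 2, (bb[2] + bb[4]) / 2)
  }
  lapply(frames, render_raster, style = style)
}
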