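# Deterministic SVG rendering of drawings. All numbers are formatted %.3f
# and attributes are emitted in a fixed order, so identical input yields
# byte-identical output. Scene y increases upward; the canvas y axis is
# flipped at render time.

#' Rendering style
#'
#' @param bond_width stroke width of bond lines, pixels.
#' @param double_bond_offset separation between the parallel lines of a
#'   double/triple/aromatic bond, pixels.
#' @param font_size atom-label font size, pixels.
#' @param formula_form `"long"` (every atom labelled, C and H included) or
#'   `"short"` (skeletal convention: carbon labels and carbon-bound H labels
#'   suppressed, heteroatoms shown with their implicit-hydrogen count).
#' @param show_isotopes show mass / atomic numbers as super-/subscripts.
#' @param width,height canvas size in pixels.
#' @param scale scene-units to pixels factor.
#' @param center optional scene point `c(x, y)` mapped to the canvas centre;
#'   when `NULL` the drawing's bounding-box centre is used. Frame renderers
#'   set this so all frames of an animation share one transform.
#' @return an object of class `render_style`.
#' @export
render_style <- function(bond_width = 2, double_bond_offset = 4, font_size = 14,
                         formula_form = c("short", "long"),
                         show_isotopes = FALSE, width = 320L, height = 240L,
                         scale = 40, center = NULL) {
  formula_form <- match.arg(formula_form)
  width <- as.integer(width); height <- as.integer(height)
  if (any(c(bond_width, double_bond_offset, font_size, scale) <= 0) ||
      is.na(width) || width < 1L || is.na(height) || height < 1L) {
    cm_abort("chemmorph_domain_error", "style dimensions must be positive")
  }
  structure(list(bond_width = bond_width, double_bond_offset = double_bond_offset,
                 font_size = font_size, formula_form = formula_form,
                 show_isotopes = show_isotopes, width = width, height = height,
                 scale = scale, center = center),
            class = "render_style")
}

fmt <- function(x) sprintf("%.3f", x)

scene_center <- function(d) {
  bb <- drawing_bbox(d, pad = 0)
  c((bb[1] + bb[3]) / 2, (bb[2] + bb[4]) / 2)
}

# scene -> pixel transform (y flipped)
scene_to_px <- function(style, d) {
  ctr <- if (is.null(style$center)) scene_center(d) else as.numeric(style$center)
  s <- style$scale
  w <- style$width; h <- style$height
  function(x, y) {
    cbind(w / 2 + s * (x - ctr[1]), h / 2 - s * (y - ctr[2]))
  }
}

rgb_attr <- function(r, g, b) sprintf("rgb(%d,%d,%d)", r, g, b)

STANDARD_VALENCE <- c(H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L,
                      P = 3L, S = 2L, Cl = 1L, Br = 1L, I = 1L)

implicit_h_count <- function(d, row) {
  el <- d$atoms$element[row]
  val <- STANDARD_VALENCE[el]
  if (is.na(val)) return(0L)
  id <- d$atoms$id[row]
  b <- d$bonds
  touching <- b$a1 == id | b$a2 == id
  if (!any(touching)) return(max(0L, as.integer(val)))
  ord <- c(single = 1, double = 2, triple = 3, wedge = 1, hash = 1, aromatic = 1.5)
  used <- round(sum(ord[b$kind[touching]]))
  max(0L, as.integer(val) - as.integer(used))
}

atom_label_visible <- function(d, row, form) {
  el <- d$atoms$element[row]
  if (form == "long") return(TRUE)
  if (el == "C") return(FALSE)
  if (el == "H") {
    # suppress hydrogens bound to carbon (skeletal convention)
    id <- d$atoms$id[row]
    b <- d$bonds
    nb <- c(b$a2[b$a1 == id], b$a1[b$a2 == id])
    if (length(nb) && all(d$atoms$element[match(nb, d$atoms$id)] == "C")) return(FALSE)
  }
  TRUE
}

svg_bond_lines <- function(p1, p2, kind, stroke, opacity, style) {
  w <- style$bond_width
  off <- style$double_bond_offset
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  len <- sqrt(dx^2 + dy^2)
  nx <- if (len > 0) -dy / len else 0
  ny <- if (len > 0) dx / len else 0
  line <- function(a, b, extra = "") {
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s%s/>',
            fmt(a[1]), fmt(a[2]), fmt(b[1]), fmt(b[2]), stroke, fmt(w), extra,
            if (opacity < 1) sprintf(' opacity="%s"', fmt(opacity)) else "")
  }
  shift <- function(p, k) c(p[1] + k * nx, p[2] + k * ny)
  switch(kind,
    single = line(p1, p2),
    double = paste0(line(shift(p1, -off / 2), shift(p2, -off / 2)),
                    line(shift(p1, off / 2), shift(p2, off / 2))),
    triple = paste0(line(p1, p2),
                    line(shift(p1, -off), shift(p2, -off)),
                    line(shift(p1, off), shift(p2, off))),
    aromatic = paste0(line(p1, p2),
                      line(shift(p1, off), shift(p2, off),
                           sprintf(' stroke-dasharray="%s,%s"', fmt(2 * w), fmt(2 * w)))),
    wedge = {
      h <- off  # half-width of the wide end
      sprintf('<polygon points="%s,%s %s,%s %s,%s" fill="%s"%s/>',
              fmt(p1[1]), fmt(p1[2]),
              fmt(p2[1] + h * nx), fmt(p2[2] + h * ny),
              fmt(p2[1] - h * nx), fmt(p2[2] - h * ny), stroke,
              if (opacity < 1) sprintf(' opacity="%s"', fmt(opacity)) else "")
    },
    hash = {
      n_rungs <- 6L
      h <- off
      paste0(vapply(seq_len(n_rungs), function(k) {
        f <- k / n_rungs
        q <- c(p1[1] + f * dx, p1[2] + f * dy)
        hw <- f * h
        line(c(q[1] - hw * nx, q[2] - hw * ny), c(q[1] + hw * nx, q[2] + hw * ny))
      }, character(1)), collapse = "")
    })
}

smooth_closed_path <- function(p) {
  # closed quadratic-Bezier path through the midpoints of consecutive
  # outline points, with the points themselves as control points
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  mid <- (p + p[nxt, , drop = FALSE]) / 2
  seg <- vapply(seq_len(n), function(i) {
    j <- nxt[i]
    sprintf("Q %s %s %s %s", fmt(p[j, 1]), fmt(p[j, 2]), fmt(mid[j, 1]), fmt(mid[j, 2]))
  }, character(1))
  paste0("M ", fmt(mid[1, 1]), " ", fmt(mid[1, 2]), " ",
         paste(seg[c(2:n, 1L)], collapse = " "), " Z")
}

svg_annotation <- function(an, i, tf, style) {
  op <- if (is.null(an$opacity)) 1 else an$opacity
  opattr <- if (op < 1) sprintf(' opacity="%s"', fmt(op)) else ""
  fill <- if (!is.null(an$gradient)) sprintf("url(#anngrad%d)", i) else "none"
  if (an$shape == "text") {
    anchor <- if (!is.null(an$outline)) tf(an$outline[1, 1], an$outline[1, 2]) else tf(0, 0)
    return(sprintf('<text x="%s" y="%s" font-size="%s" fill="rgb(0,0,0)"%s>%s</text>',
                   fmt(anchor[1]), fmt(anchor[2]), fmt(style$font_size), opattr,
                   xml_escape(if (is.null(an$label)) "" else an$label)))
  }
  p <- tf(an$outline[, 1], an$outline[, 2])
  if (an$shape == "ellipse") {
    cx <- (min(p[, 1]) + max(p[, 1])) / 2; cy <- (min(p[, 2]) + max(p[, 2])) / 2
    rx <- (max(p[, 1]) - min(p[, 1])) / 2; ry <- (max(p[, 2]) - min(p[, 2])) / 2
    return(sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s" fill="%s" stroke="rgb(0,0,0)" stroke-width="%s"%s/>',
                   fmt(cx), fmt(cy), fmt(rx), fmt(ry), fill, fmt(style$bond_width), opattr))
  }
  if (an$shape %in% c("club", "banana")) {
    return(sprintf('<path d="%s" fill="%s" stroke="rgb(0,0,0)" stroke-width="%s"%s/>',
                   smooth_closed_path(p), fill, fmt(style$bond_width), opattr))
  }
  pts <- paste(sprintf("%s,%s", fmt(p[, 1]), fmt(p[, 2])), collapse = " ")
  sprintf('<polyline points="%s" fill="%s" stroke="rgb(0,0,0)" stroke-width="%s"%s/>',
          pts, fill, fmt(style$bond_width), opattr)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Render a drawing to SVG
#'
#' Emits one text element per displayed atom label (in short form, carbon
#' labels and carbon-bound hydrogens are suppressed and heteroatoms carry
#' their implicit-H count), 1/2/3 parallel lines for single/double/triple
#' bonds, a filled triangle for a wedge, a ruled triangle for a hash, a
#' solid+dashed pair for an aromatic bond, concentric gradient-filled
#' circles for atomic shells, gradient-fillable annotation shapes, and
#' super-/subscripted isotope labels when `show_isotopes` is set. Opacity
#' attributes are carried through for the morph cross-dissolve. The output
#' is deterministic: identical input gives byte-identical SVG.
#'
#' @param d a `chem_drawing`.
#' @param style a [render_style()].
#' @return a single SVG document string.
#' @export
render_svg <- function(d, style = render_style()) {
  validate_drawing(d)
  tfm <- scene_to_px(style, d)
  tf <- function(x, y) tfm(x, y)[1, ]
  a <- d$atoms; b <- d$bonds
  s <- style$scale
  parts <- character()

  # defs: shell radial gradients + annotation linear gradients
  defs <- character()
  for (key in names(d$shells)) {
    sh <- d$shells[[key]]
    defs <- c(defs, sprintf(
      '<radialGradient id="shellgrad%s"><stop offset="0" stop-color="%s"/><stop offset="1" stop-color="%s"/></radialGradient>',
      key, rgb_attr(sh$inner[1], sh$inner[2], sh$inner[3]),
      rgb_attr(sh$outer[1], sh$outer[2], sh$outer[3])))
  }
  for (i in seq_along(d$annotations)) {
    gr <- d$annotations[[i]]$gradient
    if (!is.null(gr)) {
      defs <- c(defs, sprintf(
        '<linearGradient id="anngrad%d"><stop offset="0" stop-color="%s"/><stop offset="1" stop-color="%s"/></linearGradient>',
        i, rgb_attr(gr[[1]][1], gr[[1]][2], gr[[1]][3]),
        rgb_attr(gr[[2]][1], gr[[2]][2], gr[[2]][3])))
    }
  }
  if (length(defs)) parts <- c(parts, "<defs>", defs, "</defs>")

  # shells beneath everything else
  for (key in names(d$shells)) {
    row <- match(as.integer(key), a$id)
    if (is.na(row)) next
    sh <- d$shells[[key]]
    p <- tf(a$x[row], a$y[row])
    rmax <- max(sh$radii) * s
    op <- a$opacity[row]
    opattr <- if (op < 1) sprintf(' opacity="%s"', fmt(op)) else ""
    parts <- c(parts, sprintf('<circle cx="%s" cy="%s" r="%s" fill="url(#shellgrad%s)"%s/>',
                              fmt(p[1]), fmt(p[2]), fmt(rmax), key, opattr))
    for (r in sh$radii) {
      parts <- c(parts, sprintf('<circle cx="%s" cy="%s" r="%s" fill="none" stroke="rgb(0,0,0)" stroke-width="%s"%s/>',
                                fmt(p[1]), fmt(p[2]), fmt(r * s), fmt(style$bond_width / 2), opattr))
    }
  }

  # bonds
  for (i in seq_len(nrow(b))) {
    r1 <- match(b$a1[i], a$id); r2 <- match(b$a2[i], a$id)
    p1 <- tf(a$x[r1], a$y[r1]); p2 <- tf(a$x[r2], a$y[r2])
    parts <- c(parts, svg_bond_lines(p1, p2, b$kind[i],
                                     rgb_attr(b$red[i], b$green[i], b$blue[i]),
                                     b$opacity[i], style))
  }

  # atom labels
  for (i in seq_len(nrow(a))) {
    if (!atom_label_visible(d, i, style$formula_form)) next
    p <- tf(a$x[i], a$y[i])
    label <- a$element[i]
    if (style$formula_form == "short" && !a$element[i] %in% c("C", "H")) {
      nh <- implicit_h_count(d, i)
      if (nh >= 1L) label <- paste0(label, "H", if (nh > 1L) nh else "")
    }
    tspans <- ""
    if (style$show_isotopes) {
      if (!is.na(a$mass_number[i])) {
        tspans <- paste0(tspans, sprintf('<tspan baseline-shift="super" font-size="%s">%d</tspan>',
                                         fmt(style$font_size * 0.6), a$mass_number[i]))
      }
      if (!is.na(a$atomic_number_display[i])) {
        tspans <- paste0(tspans, sprintf('<tspan baseline-shift="sub" font-size="%s">%d</tspan>',
                                         fmt(style$font_size * 0.6), a$atomic_number_display[i]))
      }
    }
    chg <- ""
    if (a$charge[i] != 0L) {
      sign <- if (a$charge[i] > 0L) "+" else "-"
      mag <- abs(a$charge[i])
      chg <- sprintf('<tspan baseline-shift="super" font-size="%s">%s%s</tspan>',
                     fmt(style$font_size * 0.6),
                     if (mag > 1L) mag else "", sign)
    }
    opattr <- if (a$opacity[i] < 1) sprintf(' opacity="%s"', fmt(a$opacity[i])) else ""
    parts <- c(parts, sprintf(
      '<text x="%s" y="%s" text-anchor="middle" dominant-baseline="middle" font-size="%s" fill="%s"%s>%s%s%s</text>',
      fmt(p[1]), fmt(p[2]), fmt(style$font_size),
      rgb_attr(a$red[i], a$green[i], a$blue[i]), opattr,
      tspans, xml_escape(label), chg))
  }

  # annotations on top
  for (i in seq_along(d$annotations)) {
    parts <- c(parts, svg_annotation(d$annotations[[i]], i, tfm, style))
  }

  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="', style$width,
         '" height="', style$height, '" viewBox="0 0 ', style$width, ' ',
         style$height, '">', paste(parts, collapse = ""), "</svg>")
}
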