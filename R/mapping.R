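# Geometric engines for morphing: affine (three-point) maps, projective
# (four-point) maps built by the unit-squares method, and region
# tessellation into square or triangular cells.
#
# Corner ordering convention for quads: counter-clockwise starting at the
# bottom-left, i.e. the unit square is (0,0), (1,0), (1,1), (0,1).

DEGENERACY_EPS <- 1e-12

as_points <- function(p, n, what) {
  p <- as.matrix(p)
  if (nrow(p) != n || ncol(p) != 2L || any(!is.finite(p))) {
    cm_abort("chemmorph_domain_error",
             sprintf("%s must be a finite %d x 2 point matrix", what, n))
  }
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  p
}

signed_area2 <- function(p) {
  # twice the signed area of triangle p[1:3, ]
  (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
    (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
}

#' Construct an affine map from its six coefficients
#'
#' Maps `(x, y) -> (a x + b y + c, d x + e y + f)`. The linear part must be
#' invertible.
#'
#' @param a,b,c,d,e,f real coefficients.
#' @return an object of class `affine_map` with field `m`, the 2 x 3
#'   coefficient matrix `rbind(c(a, b, c), c(d, e, f))`.
#' @export
affine_map <- function(a, b, c, d, e, f) {
  m <- rbind(c(a, b, c), c(d, e, f))
  if (any(!is.finite(m))) cm_abort("chemmorph_domain_error", "affine coefficients must be finite")
  if (abs(a * e - b * d) < DEGENERACY_EPS) {
    cm_abort("chemmorph_degenerate_error", "affine map is singular (det ~ 0)")
  }
  structure(list(m = m), class = "affine_map")
}

#' Recover the affine map sending three points to three points
#'
#' Three non-collinear source points and their targets determine a unique
#' affine transform; it is recovered by solving the 3 x 3 linear system
#' `[x y 1] B = dst` for each output coordinate.
#'
#' @param src,dst 3 x 2 point matrices.
#' @return an `affine_map` sending each `src` row to the matching `dst` row.
#' @export
affine_from_triplet <- function(src, dst) {
  src <- as_points(src, 3L, "src")
  dst <- as_points(dst, 3L, "dst")
  if (abs(signed_area2(src)) / 2 < DEGENERACY_EPS) {
    cm_abort("chemmorph_degenerate_error", "source points are collinear")
  }
  A <- cbind(src, 1)
  B <- solve(A, dst)          # 3 x 2; columns are (a, b, c) and (d, e, f)
  affine_map(B[1, 1], B[2, 1], B[3, 1], B[1, 2], B[2, 2], B[3, 2])
}

#' Construct a projective map from a 3 x 3 homography matrix
#'
#' Maps `(x, y)` to
#' `((h11 x + h12 y + h13) / w, (h21 x + h22 y + h23) / w)` with
#' `w = h31 x + h32 y + h33`; the matrix is normalised so `h33 = 1`.
#'
#' @param H invertible 3 x 3 matrix with `H[3, 3]` nonzero.
#' @return an object of class `projective_map` with field `H`.
#' @export
projective_map <- function(H) {
  H <- as.matrix(H)
  if (!all(dim(H) == c(3L, 3L)) || any(!is.finite(H))) {
    cm_abort("chemmorph_domain_error", "H must be a finite 3 x 3 matrix")
  }
  if (abs(H[3, 3]) < DEGENERACY_EPS) {
    cm_abort("chemmorph_degenerate_error", "homography cannot be normalised (h33 ~ 0)")
  }
  H <- H / H[3, 3]
  if (abs(det(H)) < DEGENERACY_EPS) {
    cm_abort("chemmorph_degenerate_error", "homography is singular")
  }
  dimnames(H) <- NULL
  structure(list(H = H), class = "projective_map")
}

UNIT_SQUARE <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

check_quad <- function(quad, what) {
  quad <- as_points(quad, 4L, what)
  # no three consecutive corners collinear
  for (i in 1:4) {
    tri <- quad[c(i, i %% 4 + 1, (i + 1) %% 4 + 1), , drop = FALSE]
    if (abs(signed_area2(tri)) / 2 < DEGENERACY_EPS) {
      cm_abort("chemmorph_degenerate_error",
               sprintf("%s has three collinear corners", what))
    }
  }
  quad
}

#' Map the unit square onto a quadrilateral (unit-squares method)
#'
#' The classic square-to-quad construction: the projective map taking the
#' unit-square corners (0,0), (1,0), (1,1), (0,1) to the quad corners in
#' order is written in closed form from corner differences. When the quad is
#' a parallelogram the perspective terms vanish (`h31 = h32 = 0`) and the
#' map degenerates to the affine one.
#'
#' @param quad 4 x 2 corner matrix, counter-clockwise from bottom-left.
#' @return a `projective_map`.
#' @export
square_to_quad <- function(quad) {
  quad <- check_quad(quad, "quad")
  x <- quad[, 1]; y <- quad[, 2]
  sx <- x[1] - x[2] + x[3] - x[4]
  sy <- y[1] - y[2] + y[3] - y[4]
  if (abs(sx) < DEGENERACY_EPS && abs(sy) < DEGENERACY_EPS) {
    # parallelogram: affine case
    H <- rbind(c(x[2] - x[1], x[4] - x[1], x[1]),
               c(y[2] - y[1], y[4] - y[1], y[1]),
               c(0, 0, 1))
    return(projective_map(H))
  }
  dx1 <- x[2] - x[3]; dx2 <- x[4] - x[3]
  dy1 <- y[2] - y[3]; dy2 <- y[4] - y[3]
  den <- dx1 * dy2 - dx2 * dy1
  if (abs(den) < DEGENERACY_EPS) {
    cm_abort("chemmorph_degenerate_error", "quad is degenerate (zero corner determinant)")
  }
  g <- (sx * dy2 - dx2 * sy) / den
  h <- (dx1 * sy - sx * dy1) / den
  H <- rbind(c(x[2] - x[1] + g * x[2], x[4] - x[1] + h * x[4], x[1]),
             c(y[2] - y[1] + g * y[2], y[4] - y[1] + h * y[4], y[1]),
             c(g, h, 1))
  projective_map(H)
}

#' Projective map between two quadrilaterals (four-point mapping)
#'
#' Factors through the unit square: the map is
#' `square_to_quad(dst)` composed with the inverse of
#' `square_to_quad(src)`, so each source corner lands exactly on its target
#' corner.
#'
#' @param src,dst 4 x 2 corner matrices, counter-clockwise from bottom-left.
#' @return a `projective_map`.
#' @export
projective_from_quads <- function(src, dst) {
  Hs <- square_to_quad(src)
  Hd <- square_to_quad(dst)
  projective_map(Hd$H %*% solve(Hs$H))
}

#' Apply a 2D map to points
#'
#' @param map an `affine_map` or `projective_map`.
#' @param p a length-2 point or an n x 2 matrix of points.
#' @return transformed point(s), same shape as the input.
#' @export
apply_map <- function(map, p) {
  vec <- is.null(dim(p))
  pm <- if (vec) matrix(as.numeric(p), 1L, 2L) else as.matrix(p)
  if (ncol(pm) != 2L || any(!is.finite(pm))) {
    cm_abort("chemmorph_domain_error", "points must be finite (x, y) pairs")
  }
  if (inherits(map, "affine_map")) {
    out <- cbind(pm, 1) %*% t(map$m)
  } else if (inherits(map, "projective_map")) {
    hp <- cbind(pm, 1) %*% t(map$H)
    w <- hp[, 3]
    if (any(abs(w) < DEGENERACY_EPS)) {
      cm_abort("chemmorph_horizon_error",
               "point maps to the horizon (projective denominator ~ 0)")
    }
    out <- hp[, 1:2, drop = FALSE] / w
  } else {
    cm_abort("chemmorph_domain_error", "map must be an affine_map or projective_map")
  }
  if (vec) c(x = out[1, 1], y = out[1, 2]) else out
}

#' Invert a 2D map
#'
#' @param map an `affine_map` or `projective_map`.
#' @return the inverse map, of the same class.
#' @export
invert_map <- function(map) {
  if (inherits(map, "affine_map")) {
    A <- map$m[, 1:2]; t0 <- map$m[, 3]
    Ai <- solve(A)
    ti <- -Ai %*% t0
    affine_map(Ai[1, 1], Ai[1, 2], ti[1], Ai[2, 1], Ai[2, 2], ti[2])
  } else if (inherits(map, "projective_map")) {
    projective_map(solve(map$H))
  } else {
    cm_abort("chemmorph_domain_error", "map must be an affine_map or projective_map")
  }
}

#' Tessellate a rectangle into squares or triangles
#'
#' Square mode tiles the box with an n x n grid of axis-aligned cells;
#' triangle mode splits each grid cell along its main diagonal
#' (bottom-left to top-right), giving 2 n^2 triangles. Vertices are laid out
#' row-major from the bottom-left corner; cell vertex indices are
#' counter-clockwise.
#'
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)`, non-degenerate.
#' @param mode `"squares"` or `"triangles"`.
#' @param n grid resolution per axis (>= 1).
#' @return an object of class `region_mesh`: list with `vertices`
#'   ((n+1)^2 x 2 matrix) and `cells` (list of index vectors, 1-based).
#' @export
tessellate_region <- function(bbox, mode = c("squares", "triangles"), n = 1L) {
  mode <- match.arg(mode)
  bbox <- as.numeric(bbox)
  n <- as.integer(n)
  if (length(bbox) != 4L || any(!is.finite(bbox)) ||
      bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    cm_abort("chemmorph_domain_error", "bbox must be a non-degenerate (xmin, ymin, xmax, ymax)")
  }
  if (is.na(n) || n < 1L) cm_abort("chemmorph_domain_error", "grid resolution n must be >= 1")
  xs <- seq(bbox[1], bbox[3], length.out = n + 1L)
  ys <- seq(bbox[2], bbox[4], length.out = n + 1L)
  vertices <- cbind(rep(xs, times = n + 1L), rep(ys, each = n + 1L))
  vid <- function(i, j) (j - 1L) * (n + 1L) + i  # column i, row j, 1-based
  cells <- vector("list", if (mode == "squares") n * n else 2L * n * n)
  k <- 0L
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      bl <- vid(i, j); br <- vid(i + 1L, j)
      tr <- vid(i + 1L, j + 1L); tl <- vid(i, j + 1L)
      if (mode == "squares") {
        k <- k + 1L
        cells[[k]] <- c(bl, br, tr, tl)
      } else {
        cells[[k + 1L]] <- c(bl, br, tr)
        cells[[k + 2L]] <- c(bl, tr, tl)
        k <- k + 2L
      }
    }
  }
  structure(list(vertices = vertices, cells = cells, mode = mode, n = n),
            class = "region_mesh")
}

#' Area of every cell in a mesh
#'
#' @param mesh a `region_mesh`.
#' @return numeric vector of unsigned polygon areas (shoelace formula).
#' @export
mesh_cell_areas <- function(mesh) {
  vapply(mesh$cells, function(idx) {
    p <- mesh$vertices[idx, , drop = FALSE]
    nn <- nrow(p)
    nxt <- c(2:nn, 1L)
    abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])) / 2
  }, numeric(1))
}
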