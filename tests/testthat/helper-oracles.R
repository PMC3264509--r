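# Shared generators and independent oracles used across the suite.

FIXTURE_ELEMENTS <- c("C", "H", "O", "N", "Cl")

# Random connected drawing with V2000-expressible fields (coordinates on the
# 1e-4 grid the 10.4 format preserves, integer charges).
random_drawing <- function(n, with_charges = TRUE) {
  els <- sample(FIXTURE_ELEMENTS, n, replace = TRUE)
  atoms <- data.frame(
    id = seq_len(n) - 1L, element = els,
    x = round(runif(n, 0, 50), 4), y = round(runif(n, -25, 25), 4),
    charge = if (with_charges) sample(-1:1, n, replace = TRUE, prob = c(.1, .8, .1)) else integer(n),
    stringsAsFactors = FALSE)
  bonds <- if (n > 1L) {
    data.frame(a1 = 1:(n - 1L),
               a2 = vapply(2:n, function(i) sample.int(i - 1L, 1L) - 1L, integer(1)),
               kind = sample(c("single", "double", "triple", "wedge", "hash", "aromatic"),
                             n - 1L, replace = TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(bonds)) {
    bonds <- bonds[!duplicated(paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))), ]
  }
  drawing(atoms = atoms, bonds = if (is.null(bonds)) list() else bonds)
}

# Jittered copy of a drawing (same elements/ids, displaced positions) —
# every atom should pair under auto_correspond.
jitter_drawing <- function(d, sd = 0.05) {
  d$atoms$x <- round(d$atoms$x + rnorm(nrow(d$atoms), 0, sd), 4)
  d$atoms$y <- round(d$atoms$y + rnorm(nrow(d$atoms), 0, sd), 4)
  d
}

# Independent 6x6 dense solve for the affine coefficients (a,b,c,d,e,f).
affine_oracle <- function(src, dst) {
  A <- matrix(0, 6, 6)
  rhs <- numeric(6)
  for (i in 1:3) {
    A[2 * i - 1, 1:3] <- c(src[i, 1], src[i, 2], 1)
    A[2 * i, 4:6] <- c(src[i, 1], src[i, 2], 1)
    rhs[2 * i - 1] <- dst[i, 1]
    rhs[2 * i] <- dst[i, 2]
  }
  solve(A, rhs)
}

# Independent direct-linear-transform solve (8x8) for the homography,
# normalised to h33 = 1.
dlt_oracle <- function(src, dst) {
  A <- matrix(0, 8, 8)
  rhs <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    rhs[2 * i - 1] <- u
    rhs[2 * i] <- v
  }
  h <- solve(A, rhs)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

# Random convex quad: perturbed unit square, scaled and translated,
# counter-clockwise from bottom-left.
random_quad <- function() {
  base <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  q <- base + matrix(runif(8, -0.25, 0.25), 4, 2)
  s <- runif(1, 0.5, 4)
  sweep(q * s, 2, runif(2, -5, 5), "+")
}

expect_drawing_fields_equal <- function(a, b, coord_tol = 5e-5) {
  testthat::expect_equal(nrow(a$atoms), nrow(b$atoms))
  testthat::expect_equal(a$atoms$element, b$atoms$element)
  testthat::expect_lt(max(abs(a$atoms$x - b$atoms$x), 0), coord_tol)
  testthat::expect_lt(max(abs(a$atoms$y - b$atoms$y), 0), coord_tol)
  testthat::expect_equal(a$atoms$charge, b$atoms$charge)
  testthat::expect_equal(nrow(a$bonds), nrow(b$bonds))
  key <- function(d) {
    b_ <- d$bonds
    ord <- order(pmin(b_$a1, b_$a2), pmax(b_$a1, b_$a2), b_$kind)
    paste(pmin(b_$a1, b_$a2), pmax(b_$a1, b_$a2), b_$kind)[ord]
  }
  testthat::expect_equal(key(a), key(b))
}

bond_length <- function(d, id1, id2) {
  i <- match(id1, d$atoms$id); j <- match(id2, d$atoms$id)
  sqrt((d$atoms$x[i] - d$atoms$x[j])^2 + (d$atoms$y[i] - d$atoms$y[j])^2)
}

bond_angle <- function(d, tip1, center, tip2) {
  i <- match(tip1, d$atoms$id); c_ <- match(center, d$atoms$id); j <- match(tip2, d$atoms$id)
  v1 <- c(d$atoms$x[i] - d$atoms$x[c_], d$atoms$y[i] - d$atoms$y[c_])
  v2 <- c(d$atoms$x[j] - d$atoms$x[c_], d$atoms$y[j] - d$atoms$y[c_])
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
}
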