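# Built-in deterministic test structures. Geometries use bond length 1.0
# scene units; water uses the 104.5 degree H-O-H angle. Element colours
# follow the usual CPK-style convention (C black, H grey, O red, N blue,
# Br dark red, Cl green).

ELEMENT_COLORS <- list(C = c(0L, 0L, 0L), H = c(128L, 128L, 128L),
                       O = c(255L, 0L, 0L), N = c(0L, 0L, 255L),
                       Cl = c(0L, 170L, 0L), Br = c(165L, 42L, 42L))

el_color <- function(el) {
  col <- ELEMENT_COLORS[[el]]
  if (is.null(col)) c(0L, 0L, 0L) else col
}

fx_atoms <- function(els, xs, ys, charges = NULL) {
  n <- length(els)
  cols <- t(vapply(els, el_color, integer(3)))
  data.frame(id = seq_len(n) - 1L, element = els, x = xs, y = ys,
             charge = if (is.null(charges)) integer(n) else as.integer(charges),
             red = cols[, 1], green = cols[, 2], blue = cols[, 3],
             opacity = rep(1, n), stringsAsFactors = FALSE)
}

fx_bonds <- function(a1, a2, kind = "single") {
  data.frame(a1 = as.integer(a1), a2 = as.integer(a2),
             kind = rep_len(kind, length(a1)), stringsAsFactors = FALSE)
}

water_drawing <- function() {
  half <- (104.5 / 2) * pi / 180
  drawing(atoms = fx_atoms(c("O", "H", "H"),
                           c(0, -sin(half), sin(half)),
                           c(0, -cos(half), -cos(half))),
          bonds = fx_bonds(c(0L, 0L), c(1L, 2L)))
}

methane_drawing <- function() {
  drawing(atoms = fx_atoms(c("C", "H", "H", "H", "H"),
                           c(0, 0, 1, 0, -1), c(0, 1, 0, -1, 0)),
          bonds = fx_bonds(rep(0L, 4L), 1:4))
}

chain_drawing <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) cm_abort("chemmorph_domain_error", "chain length n must be >= 1")
  xs <- (seq_len(n) - 1L) * cos(pi / 6)
  ys <- ((seq_len(n) - 1L) %% 2L) * sin(pi / 6)
  bonds <- if (n > 1L) fx_bonds(0:(n - 2L), 1:(n - 1L)) else empty_bond_df()
  drawing(atoms = fx_atoms(rep("C", n), xs, ys), bonds = bonds)
}

# SN2 endpoints: hydroxide attacks CH3Br opposite the leaving bromide; the
# methyl umbrella inverts through the trigonal transition state.
sn2_drawing <- function(stage) {
  if (stage == "pre") {
    atoms <- fx_atoms(c("C", "H", "H", "H", "Br", "O", "H"),
                      c(0, -0.4, -0.4, -1.0, 1.5, -3.0, -3.8),
                      c(0, 0.9, -0.9, 0, 0, 0, 0.6),
                      charges = c(0, 0, 0, 0, 0, -1, 0))
    bonds <- fx_bonds(c(0L, 0L, 0L, 0L, 5L), c(1L, 2L, 3L, 4L, 6L))
  } else if (stage == "ts") {
    atoms <- fx_atoms(c("C", "H", "H", "H", "Br", "O", "H"),
                      c(0, 0, 0, -0.2, 1.8, -1.8, -2.6),
                      c(0, 1.0, -1.0, 0.3, 0, 0, 0.6))
    bonds <- fx_bonds(c(0L, 0L, 0L, 0L, 0L, 5L), c(1L, 2L, 3L, 4L, 5L, 6L),
                      kind = c("single", "single", "single", "hash", "hash", "single"))
  } else {
    atoms <- fx_atoms(c("C", "H", "H", "H", "Br", "O", "H"),
                      c(0, 0.4, 0.4, 1.0, 3.0, -1.5, -2.3),
                      c(0, 0.9, -0.9, 0, 0, 0, 0.6),
                      charges = c(0, 0, 0, 0, -1, 0, 0))
    bonds <- fx_bonds(c(0L, 0L, 0L, 0L, 5L), c(1L, 2L, 3L, 5L, 6L))
  }
  drawing(atoms = atoms, bonds = bonds)
}

#' Built-in deterministic structures
#'
#' Generates the fixed example structures used throughout the package:
#' \describe{
#'   \item{water}{bent H2O, O at the origin, O-H bond length 1.0, H-O-H
#'     angle 104.5 degrees;}
#'   \item{methane}{2D cross depiction of CH4, C-H length 1.0;}
#'   \item{chain}{an `n`-carbon zigzag chain (n atoms, n-1 bonds), bond
#'     length 1.0;}
#'   \item{sn2_pre, sn2_ts, sn2_post}{the three stages of a bimolecular
#'     nucleophilic substitution (hydroxide + bromomethane): nucleophile
#'     approach, trigonal transition state with partial (hashed) bonds, and
#'     leaving-group departure — endpoints for a two-step reaction morph;}
#'   \item{stretch_pair, scissor_pair}{a water molecule together with its
#'     symmetrically stretched / scissored geometry, as a
#'     `list(source, target)` pair.}
#' }
#'
#' @param name fixture name (see above).
#' @param n chain length for `chain` (>= 1).
#' @param amplitude displacement for the vibration pairs: bond-length change
#'   in scene units for `stretch_pair`, angle change in radians for
#'   `scissor_pair`.
#' @return a `chem_drawing`, or a list of two drawings for the pair
#'   fixtures.
#' @export
generate_fixture <- function(name = c("water", "methane", "chain", "sn2_pre",
                                      "sn2_ts", "sn2_post", "stretch_pair",
                                      "scissor_pair"),
                             n = NULL, amplitude = NULL) {
  name <- match.arg(name)
  switch(name,
    water = water_drawing(),
    methane = methane_drawing(),
    chain = {
      if (is.null(n)) cm_abort("chemmorph_domain_error", "chain fixture needs n")
      chain_drawing(n)
    },
    sn2_pre = sn2_drawing("pre"),
    sn2_ts = sn2_drawing("ts"),
    sn2_post = sn2_drawing("post"),
    stretch_pair = {
      amp <- if (is.null(amplitude)) 0.2 else amplitude
      w <- water_drawing()
      list(source = w,
           target = vibration_preset(w, "symmetric_stretch", amp)$steps[[1]]$target)
    },
    scissor_pair = {
      amp <- if (is.null(amplitude)) 0.15 else amplitude
      w <- water_drawing()
      list(source = w,
           target = vibration_preset(w, "scissoring", amp)$steps[[1]]$target)
    })
}
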