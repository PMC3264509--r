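# Chemical-drawing data model.
#
# A drawing is stored column-wise: atoms and bonds are data frames so that
# large structures (the capacity is 100000 atoms) are built and transformed
# in vectorised operations. Single-atom/-bond objects exist as lightweight
# S3 records for the add_* API.

#' Maximum number of atoms in a drawing
#'
#' Hard capacity of the drawing model; operations that would push a drawing
#' past this limit fail with a `chemmorph_capacity_error`.
#' @export
ATOM_CAPACITY <- 100000L

#' Create a 2D point
#'
#' Points are plain numeric vectors `c(x, y)` in scene units, y increasing
#' upward. This constructor validates finiteness.
#'
#' @param x,y finite real coordinates.
#' @return numeric vector of length 2.
#' @export
point2 <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      !is.finite(x) || !is.finite(y)) {
    cm_abort("chemmorph_domain_error", "point coordinates must be finite numbers")
  }
  c(x = as.numeric(x), y = as.numeric(y))
}

#' Atomic shell depiction style
#'
#' Concentric circles around an atom symbolising electron shells, optionally
#' filled with a two-stop colour gradient from the innermost to the outermost
#' radius.
#'
#' @param radii strictly increasing positive radii in scene units.
#' @param inner,outer RGB triples (0--255) for the gradient stops.
#' @return an object of class `chem_shell`.
#' @export
shell_style <- function(radii, inner = c(255L, 255L, 255L), outer = c(160L, 160L, 255L)) {
  radii <- as.numeric(radii)
  if (length(radii) < 1L || any(!is.finite(radii)) || any(radii <= 0)) {
    cm_abort("chemmorph_domain_error", "shell radii must be positive finite numbers")
  }
  if (is.unsorted(radii, strictly = TRUE)) {
    cm_abort("chemmorph_domain_error", "shell radii must be strictly increasing")
  }
  structure(list(radii = radii, inner = check_rgb(inner), outer = check_rgb(outer)),
            class = "chem_shell")
}

check_rgb <- function(color) {
  color <- as.integer(round(color))
  if (length(color) != 3L || any(is.na(color)) || any(color < 0L) || any(color > 255L)) {
    cm_abort("chemmorph_domain_error", "color must be an RGB triple with channels in 0..255")
  }
  color
}

check_opacity <- function(opacity) {
  opacity <- as.numeric(opacity)
  if (length(opacity) != 1L || !is.finite(opacity) || opacity < 0 || opacity > 1) {
    cm_abort("chemmorph_domain_error", "opacity must lie in [0, 1]")
  }
  opacity
}

#' Create an atom
#'
#' @param id non-negative integer identifier, unique within a drawing.
#' @param element element symbol, e.g. `"C"`, `"Cl"`.
#' @param x,y position in scene units.
#' @param charge formal charge (integer).
#' @param mass_number optional isotope mass number (positive integer).
#' @param atomic_number_display optional atomic number to display alongside
#'   the symbol (positive integer). When both are set the mass number must be
#'   at least the atomic number.
#' @param color RGB triple, 0--255 per channel.
#' @param opacity real in `[0, 1]`; used by the morph cross-dissolve.
#' @param shell optional [shell_style()].
#' @return an object of class `chem_atom`.
#' @export
atom <- function(id, element, x, y, charge = 0L, mass_number = NULL,
                 atomic_number_display = NULL, color = c(0L, 0L, 0L),
                 opacity = 1, shell = NULL) {
  id <- as.integer(id)
  if (is.na(id) || id < 0L) cm_abort("chemmorph_domain_error", "atom id must be a non-negative integer")
  if (!is.character(element) || length(element) != 1L || !nzchar(element)) {
    cm_abort("chemmorph_domain_error", "element symbol must be a non-empty string")
  }
  p <- point2(x, y)
  if (!is.null(mass_number)) {
    mass_number <- as.integer(mass_number)
    if (is.na(mass_number) || mass_number < 1L) {
      cm_abort("chemmorph_domain_error", "mass_number must be a positive integer")
    }
  }
  if (!is.null(atomic_number_display)) {
    atomic_number_display <- as.integer(atomic_number_display)
    if (is.na(atomic_number_display) || atomic_number_display < 1L) {
      cm_abort("chemmorph_domain_error", "atomic_number_display must be a positive integer")
    }
  }
  if (!is.null(mass_number) && !is.null(atomic_number_display) &&
      mass_number < atomic_number_display) {
    cm_abort("chemmorph_domain_error", "mass_number must be >= atomic_number_display")
  }
  if (!is.null(shell) && !inherits(shell, "chem_shell")) {
    cm_abort("chemmorph_domain_error", "shell must be a shell_style() object")
  }
  structure(list(id = id, element = element, x = unname(p[1]), y = unname(p[2]),
                 charge = as.integer(charge), mass_number = mass_number,
                 atomic_number_display = atomic_number_display,
                 color = check_rgb(color), opacity = check_opacity(opacity),
                 shell = shell),
            class = "chem_atom")
}

BOND_KINDS <- c("single", "double", "triple", "wedge", "hash", "aromatic")

#' Create a bond
#'
#' @param a1,a2 endpoint atom ids (must differ; must exist in the owning
#'   drawing when the bond is added).
#' @param kind one of `"single"`, `"double"`, `"triple"`, `"wedge"`,
#'   `"hash"`, `"aromatic"`.
#' @param color RGB triple.
#' @param opacity real in `[0, 1]`.
#' @return an object of class `chem_bond`.
#' @export
bond <- function(a1, a2, kind = "single", color = c(0L, 0L, 0L), opacity = 1) {
  a1 <- as.integer(a1); a2 <- as.integer(a2)
  if (is.na(a1) || is.na(a2)) cm_abort("chemmorph_domain_error", "bond endpoints must be atom ids")
  if (a1 == a2) cm_abort("chemmorph_self_bond_error", sprintf("bond joins atom %d to itself", a1))
  kind <- match.arg(kind, BOND_KINDS)
  structure(list(a1 = a1, a2 = a2, kind = kind, color = check_rgb(color),
                 opacity = check_opacity(opacity)),
            class = "chem_bond")
}

ANNOTATION_SHAPES <- c("arrow", "bracket", "ellipse", "club", "banana", "text")

#' Create an annotation
#'
#' Non-structural drawing components: arrows, brackets, ellipses, and the
#' club/banana shapes used to symbolise orbitals, plus free text.
#'
#' @param shape one of `"arrow"`, `"bracket"`, `"ellipse"`, `"club"`,
#'   `"banana"`, `"text"`.
#' @param outline matrix of points (n x 2) tracing the shape; required
#'   non-empty for every shape except `"text"` (for text it anchors the label).
#' @param gradient optional list of two RGB triples (fill gradient stops).
#' @param label optional text string.
#' @return an object of class `chem_annotation`.
#' @export
annotation <- function(shape, outline = NULL, gradient = NULL, label = NULL) {
  shape <- match.arg(shape, ANNOTATION_SHAPES)
  if (!is.null(outline)) {
    outline <- as.matrix(outline)
    if (ncol(outline) != 2L || any(!is.finite(outline))) {
      cm_abort("chemmorph_domain_error", "annotation outline must be a finite n x 2 matrix")
    }
    storage.mode(outline) <- "double"
    dimnames(outline) <- NULL
  }
  if (shape != "text" && (is.null(outline) || nrow(outline) == 0L)) {
    cm_abort("chemmorph_domain_error",
             sprintf("annotation shape '%s' requires a non-empty outline", shape))
  }
  if (!is.null(gradient)) {
    gradient <- list(check_rgb(gradient[[1]]), check_rgb(gradient[[2]]))
  }
  structure(list(shape = shape, outline = outline, gradient = gradient, label = label),
            class = "chem_annotation")
}

#' Background image specification
#'
#' A raster image composited beneath the drawing. Brightness 1 leaves the
#' image unchanged; values above 1 lighten it towards a watermark.
#'
#' @param image_path path to a PNG image.
#' @param brightness non-negative channel multiplier.
#' @return an object of class `chem_background`.
#' @export
background_spec <- function(image_path, brightness = 1) {
  brightness <- as.numeric(brightness)
  if (length(brightness) != 1L || !is.finite(brightness) || brightness < 0) {
    cm_abort("chemmorph_domain_error", "brightness must be a non-negative number")
  }
  structure(list(image_path = as.character(image_path), brightness = brightness),
            class = "chem_background")
}

empty_atom_df <- function() {
  data.frame(id = integer(), element = character(), x = numeric(), y = numeric(),
             charge = integer(), mass_number = integer(),
             atomic_number_display = integer(),
             red = integer(), green = integer(), blue = integer(),
             opacity = numeric(), stringsAsFactors = FALSE)
}

empty_bond_df <- function() {
  data.frame(a1 = integer(), a2 = integer(), kind = character(),
             red = integer(), green = integer(), blue = integer(),
             opacity = numeric(), stringsAsFactors = FALSE)
}

atom_to_row <- function(a) {
  data.frame(id = a$id, element = a$element, x = a$x, y = a$y, charge = a$charge,
             mass_number = if (is.null(a$mass_number)) NA_integer_ else a$mass_number,
             atomic_number_display = if (is.null(a$atomic_number_display)) NA_integer_ else a$atomic_number_display,
             red = a$color[1], green = a$color[2], blue = a$color[3],
             opacity = a$opacity, stringsAsFactors = FALSE)
}

bond_to_row <- function(b) {
  data.frame(a1 = b$a1, a2 = b$a2, kind = b$kind,
             red = b$color[1], green = b$color[2], blue = b$color[3],
             opacity = b$opacity, stringsAsFactors = FALSE)
}

normalise_atom_df <- function(df) {
  if (!all(c("id", "element", "x", "y") %in% names(df))) {
    cm_abort("chemmorph_domain_error", "atom table needs columns id, element, x, y")
  }
  out <- empty_atom_df()[rep(1L, 0L), ]
  n <- nrow(df)
  out <- data.frame(
    id = as.integer(df$id), element = as.character(df$element),
    x = as.numeric(df$x), y = as.numeric(df$y),
    charge = if ("charge" %in% names(df)) as.integer(df$charge) else integer(n) ,
    mass_number = if ("mass_number" %in% names(df)) as.integer(df$mass_number) else rep(NA_integer_, n),
    atomic_number_display = if ("atomic_number_display" %in% names(df)) as.integer(df$atomic_number_display) else rep(NA_integer_, n),
    red = if ("red" %in% names(df)) as.integer(df$red) else integer(n),
    green = if ("green" %in% names(df)) as.integer(df$green) else integer(n),
    blue = if ("blue" %in% names(df)) as.integer(df$blue) else integer(n),
    opacity = if ("opacity" %in% names(df)) as.numeric(df$opacity) else rep(1, n),
    stringsAsFactors = FALSE)
  out
}

normalise_bond_df <- function(df) {
  if (!all(c("a1", "a2") %in% names(df))) {
    cm_abort("chemmorph_domain_error", "bond table needs columns a1, a2")
  }
  n <- nrow(df)
  data.frame(
    a1 = as.integer(df$a1), a2 = as.integer(df$a2),
    kind = if ("kind" %in% names(df)) as.character(df$kind) else rep("single", n),
    red = if ("red" %in% names(df)) as.integer(df$red) else integer(n),
    green = if ("green" %in% names(df)) as.integer(df$green) else integer(n),
    blue = if ("blue" %in% names(df)) as.integer(df$blue) else integer(n),
    opacity = if ("opacity" %in% names(df)) as.numeric(df$opacity) else rep(1, n),
    stringsAsFactors = FALSE)
}

#' Create a chemical drawing
#'
#' The scene container: an ordered atom table, bond table, annotation list and
#' optional background. Atoms and bonds may be given as lists of [atom()] /
#' [bond()] objects or directly as data frames (columns `id`, `element`, `x`,
#' `y` and optionally `charge`, `mass_number`, `atomic_number_display`, `red`,
#' `green`, `blue`, `opacity`; bonds: `a1`, `a2`, `kind`, colour channels,
#' `opacity`) — the data-frame form is the efficient path for large scenes.
#'
#' @param atoms list of `chem_atom` or a data frame.
#' @param bonds list of `chem_bond` or a data frame.
#' @param annotations list of [annotation()] objects.
#' @param background optional [background_spec()].
#' @return an object of class `chem_drawing`.
#' @export
drawing <- function(atoms = list(), bonds = list(), annotations = list(),
                    background = NULL) {
  shells <- list()
  if (is.data.frame(atoms)) {
    adf <- if (nrow(atoms)) normalise_atom_df(atoms) else empty_atom_df()
  } else {
    adf <- if (length(atoms)) do.call(rbind, lapply(atoms, atom_to_row)) else empty_atom_df()
    for (a in atoms) if (!is.null(a$shell)) shells[[as.character(a$id)]] <- a$shell
  }
  if (is.data.frame(bonds)) {
    bdf <- if (nrow(bonds)) normalise_bond_df(bonds) else empty_bond_df()
  } else {
    bdf <- if (length(bonds)) do.call(rbind, lapply(bonds, bond_to_row)) else empty_bond_df()
  }
  d <- structure(list(atoms = adf, bonds = bdf, shells = shells,
                      annotations = annotations, background = background),
                 class = "chem_drawing")
  validate_drawing(d)
  d
}

#' Validate a drawing's invariants
#'
#' Checks unique atom ids, the 100000-atom capacity, bond endpoint
#' resolution, bond kinds, opacity ranges and finite coordinates. Called by
#' every constructor/mutator; exported for defensive use on deserialised
#' scenes.
#'
#' @param d a `chem_drawing`.
#' @return `d`, invisibly, or an error.
#' @export
validate_drawing <- function(d) {
  if (!inherits(d, "chem_drawing")) cm_abort("chemmorph_domain_error", "not a chem_drawing")
  a <- d$atoms; b <- d$bonds
  if (anyDuplicated(a$id)) cm_abort("chemmorph_duplicate_id_error", "duplicate atom ids in drawing")
  if (nrow(a) > ATOM_CAPACITY) {
    cm_abort("chemmorph_capacity_error",
             sprintf("drawing has %d atoms; capacity is %d", nrow(a), ATOM_CAPACITY))
  }
  if (nrow(a) && (any(!is.finite(a$x)) || any(!is.finite(a$y)))) {
    cm_abort("chemmorph_domain_error", "non-finite atom coordinates")
  }
  if (nrow(a) && (any(a$opacity < 0) || any(a$opacity > 1))) {
    cm_abort("chemmorph_domain_error", "atom opacity outside [0, 1]")
  }
  if (nrow(b)) {
    if (any(b$a1 == b$a2)) cm_abort("chemmorph_self_bond_error", "bond joins an atom to itself")
    missing_ids <- setdiff(c(b$a1, b$a2), a$id)
    if (length(missing_ids)) {
      cm_abort("chemmorph_dangling_bond_error",
               sprintf("bond endpoint(s) not in drawing: %s",
                       paste(missing_ids, collapse = ", ")))
    }
    if (any(!b$kind %in% BOND_KINDS)) cm_abort("chemmorph_domain_error", "unknown bond kind")
    if (any(b$opacity < 0) || any(b$opacity > 1)) {
      cm_abort("chemmorph_domain_error", "bond opacity outside [0, 1]")
    }
  }
  invisible(d)
}

#' Number of atoms / bonds in a drawing
#' @param d a `chem_drawing`.
#' @return integer count.
#' @export
n_atoms <- function(d) nrow(d$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(d) nrow(d$bonds)

#' Add an atom to a drawing
#'
#' @param d a `chem_drawing`.
#' @param a a `chem_atom` from [atom()].
#' @return the extended drawing; the input is not modified.
#' @export
add_atom <- function(d, a) {
  if (!inherits(a, "chem_atom")) cm_abort("chemmorph_domain_error", "a must be a chem_atom")
  if (nrow(d$atoms) + 1L > ATOM_CAPACITY) {
    cm_abort("chemmorph_capacity_error",
             sprintf("cannot add atom: capacity of %d atoms reached", ATOM_CAPACITY))
  }
  if (a$id %in% d$atoms$id) {
    cm_abort("chemmorph_duplicate_id_error", sprintf("atom id %d already used", a$id))
  }
  d$atoms <- rbind(d$atoms, atom_to_row(a))
  if (!is.null(a$shell)) d$shells[[as.character(a$id)]] <- a$shell
  d
}

#' Add a bond to a drawing
#'
#' @param d a `chem_drawing`.
#' @param b a `chem_bond` from [bond()].
#' @return the extended drawing.
#' @export
add_bond <- function(d, b) {
  if (!inherits(b, "chem_bond")) cm_abort("chemmorph_domain_error", "b must be a chem_bond")
  if (b$a1 == b$a2) cm_abort("chemmorph_self_bond_error", sprintf("bond joins atom %d to itself", b$a1))
  absent <- setdiff(c(b$a1, b$a2), d$atoms$id)
  if (length(absent)) {
    cm_abort("chemmorph_dangling_bond_error",
             sprintf("bond endpoint(s) not in drawing: %s", paste(absent, collapse = ", ")))
  }
  d$bonds <- rbind(d$bonds, bond_to_row(b))
  d
}

#' Find the leftmost atom (the coupling atom)
#'
#' Returns the id of the atom with the smallest x-coordinate. Ties are broken
#' by the smallest y, then by the lowest id, giving a total deterministic
#' order. This atom is the coupling atom used when attaching an imported
#' structure onto an existing one.
#'
#' @param d a `chem_drawing` with at least one atom.
#' @return atom id (integer).
#' @export
leftmost_atom <- function(d) {
  a <- d$atoms
  if (!nrow(a)) cm_abort("chemmorph_empty_drawing_error", "drawing has no atoms")
  a$id[order(a$x, a$y, a$id)][1L]
}

#' Translate a drawing
#'
#' Shifts every atom position and annotation outline point by `delta`;
#' topology, colours and the background are unchanged.
#'
#' @param d a `chem_drawing`.
#' @param delta numeric `c(dx, dy)` in scene units.
#' @return the translated drawing.
#' @export
translate_drawing <- function(d, delta) {
  delta <- as.numeric(delta)
  if (length(delta) != 2L || any(!is.finite(delta))) {
    cm_abort("chemmorph_domain_error", "delta must be a finite (dx, dy) pair")
  }
  d$atoms$x <- d$atoms$x + delta[1]
  d$atoms$y <- d$atoms$y + delta[2]
  d$annotations <- lapply(d$annotations, function(an) {
    if (!is.null(an$outline)) {
      an$outline[, 1] <- an$outline[, 1] + delta[1]
      an$outline[, 2] <- an$outline[, 2] + delta[2]
    }
    an
  })
  d
}

#' @export
print.chem_drawing <- function(x, ...) {
  cat(sprintf("<chem_drawing: %d atoms, %d bonds, %d annotations%s>\n",
              n_atoms(x), n_bonds(x), length(x$annotations),
              if (!is.null(x$background)) ", background" else ""))
  if (n_atoms(x)) {
    tab <- table(x$atoms$element)
    cat("  formula:", paste0(names(tab), ifelse(tab > 1L, tab, ""), collapse = ""), "\n")
  }
  invisible(x)
}
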