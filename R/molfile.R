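# MDL MOL V2000 connection-table import/export and the insert/attach
# behaviour built on it. The fixed-column layout is written bit-exactly
# (%10.4f coordinates, %3d counts); charges travel as "M  CHG" property
# lines and isotopes as "M  ISO". z coordinates are read and discarded
# (this is a 2D model) and written as 0.0000.

#' Standard bond length used when attaching structures
#'
#' When a guest structure is attached onto a host atom, the guest is
#' translated so that its coupling atom sits this many scene units in +x of
#' the target atom.
#' @export
STANDARD_BOND_LENGTH <- 1.5

#' Molfile interchange limit
#'
#' V2000 connection tables are set up for at most 999 atoms and 999 bonds;
#' [write_molfile()] emits a `chemmorph_compatibility_warning` (but still
#' writes) beyond this.
#' @export
MOLFILE_LIMIT <- 999L

mol_kind_from_type <- function(type, stereo) {
  kind <- rep(NA_character_, length(type))
  kind[type == 1L] <- "single"
  kind[type == 2L] <- "double"
  kind[type == 3L] <- "triple"
  kind[type == 4L] <- "aromatic"
  kind[type == 1L & stereo == 1L] <- "wedge"
  kind[type == 1L & stereo == 6L] <- "hash"
  kind
}

mol_type_from_kind <- function(kind) {
  type <- integer(length(kind))
  type[kind %in% c("single", "wedge", "hash")] <- 1L
  type[kind == "double"] <- 2L
  type[kind == "triple"] <- 3L
  type[kind == "aromatic"] <- 4L
  type
}

mol_stereo_from_kind <- function(kind) {
  stereo <- integer(length(kind))
  stereo[kind == "wedge"] <- 1L
  stereo[kind == "hash"] <- 6L
  stereo
}

# legacy counts-field charge codes (atom block column 37-39)
LEGACY_CHARGE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

field_int <- function(lines, from, to, what) {
  s <- trimws(substr(lines, from, to))
  v <- suppressWarnings(as.integer(s))
  if (any(is.na(v) & nzchar(s)) || any(!nzchar(s))) {
    cm_abort("chemmorph_format_error", sprintf("non-numeric %s field in molfile", what))
  }
  v
}

field_num <- function(lines, from, to, what) {
  s <- trimws(substr(lines, from, to))
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) {
    cm_abort("chemmorph_format_error", sprintf("non-numeric %s field in molfile", what))
  }
  v
}

#' Read an MDL MOL V2000 connection table
#'
#' Parses the three header lines, the counts line (which must carry the
#' `V2000` version tag), the fixed-column atom and bond blocks and the
#' `M  CHG` / `M  ISO` property lines, terminated by `M  END`. Atom order in
#' the file maps the 1-based MOL indices onto drawing ids `0..n-1`. Bond
#' types 1/2/3 become single/double/triple, 4 aromatic; bond-stereo 1 and 6
#' on a single bond become wedge and hash.
#'
#' @param x a file path, a single string containing the molfile text, or a
#'   character vector of lines.
#' @return an object of class `chem_molfile`: a list with `title`,
#'   `program_line`, `comment` and `drawing` (a `chem_drawing`).
#' @export
read_molfile <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else as.character(x)
  if (length(lines) < 4L) cm_abort("chemmorph_format_error", "molfile shorter than header + counts line")
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE)) {
    cm_abort("chemmorph_unsupported_version_error", "V3000 connection tables are not supported")
  }
  if (!grepl("V2000", counts, fixed = TRUE)) {
    cm_abort("chemmorph_format_error", "counts line lacks the V2000 version tag")
  }
  na <- field_int(counts, 1L, 3L, "atom count")
  nb <- field_int(counts, 4L, 6L, "bond count")
  need <- 4L + na + nb
  if (length(lines) < need) {
    cm_abort("chemmorph_format_error",
             sprintf("molfile truncated: counts line declares %d atoms / %d bonds", na, nb))
  }
  atom_lines <- if (na) lines[5L:(4L + na)] else character()
  bond_lines <- if (nb) lines[(5L + na):(4L + na + nb)] else character()
  rest <- if (length(lines) > need) lines[(need + 1L):length(lines)] else character()
  if (!any(grepl("^M  END", rest))) {
    cm_abort("chemmorph_format_error", "molfile lacks the M  END terminator")
  }
  rest <- rest[seq_len(which(grepl("^M  END", rest))[1L] - 1L)]

  if (na) {
    atom_lines <- formatC(atom_lines, width = 39L, flag = "-")
    if (any(!nzchar(trimws(substr(atom_lines, 32L, 34L))))) {
      cm_abort("chemmorph_format_error", "atom block line lacks an element symbol")
    }
    x_ <- field_num(atom_lines, 1L, 10L, "atom x")
    y_ <- field_num(atom_lines, 11L, 20L, "atom y")
    field_num(atom_lines, 21L, 30L, "atom z")  # read and discarded (2D model)
    sym <- trimws(substr(atom_lines, 32L, 34L))
    ccode <- trimws(substr(atom_lines, 37L, 39L))
    charge <- integer(na)
    has_legacy <- nzchar(ccode) & ccode %in% names(LEGACY_CHARGE)
    charge[has_legacy] <- LEGACY_CHARGE[ccode[has_legacy]]
    adf <- data.frame(id = seq_len(na) - 1L, element = sym, x = x_, y = y_,
                      charge = charge, stringsAsFactors = FALSE)
  } else adf <- empty_atom_df()

  if (nb) {
    a1 <- field_int(bond_lines, 1L, 3L, "bond atom 1")
    a2 <- field_int(bond_lines, 4L, 6L, "bond atom 2")
    type <- field_int(bond_lines, 7L, 9L, "bond type")
    st <- trimws(substr(bond_lines, 10L, 12L))
    stereo <- ifelse(nzchar(st), suppressWarnings(as.integer(st)), 0L)
    stereo[is.na(stereo)] <- 0L
    kind <- mol_kind_from_type(type, stereo)
    if (any(is.na(kind))) {
      cm_abort("chemmorph_format_error",
               sprintf("unsupported bond type(s): %s",
                       paste(unique(type[is.na(kind)]), collapse = ", ")))
    }
    if (any(a1 < 1L | a1 > na | a2 < 1L | a2 > na)) {
      cm_abort("chemmorph_format_error", "bond references an atom index outside the atom block")
    }
    bdf <- data.frame(a1 = a1 - 1L, a2 = a2 - 1L, kind = kind, stringsAsFactors = FALSE)
  } else bdf <- empty_bond_df()

  # property block: M  CHG supersedes legacy charge codes; M  ISO sets isotopes
  parse_pairs <- function(line) {
    n <- as.integer(substr(line, 7L, 9L))
    vals <- matrix(NA_integer_, n, 2L)
    for (k in seq_len(n)) {
      off <- 10L + (k - 1L) * 8L
      vals[k, 1L] <- as.integer(substr(line, off, off + 3L))
      vals[k, 2L] <- as.integer(substr(line, off + 4L, off + 7L))
    }
    vals
  }
  chg_lines <- rest[grepl("^M  CHG", rest)]
  if (length(chg_lines)) {
    adf$charge <- 0L
    for (ln in chg_lines) {
      p <- parse_pairs(ln)
      adf$charge[p[, 1L]] <- p[, 2L]
    }
  }
  iso_lines <- rest[grepl("^M  ISO", rest)]
  if (length(iso_lines) && nrow(adf)) {
    adf$mass_number <- NA_integer_
    for (ln in iso_lines) {
      p <- parse_pairs(ln)
      adf$mass_number[p[, 1L]] <- p[, 2L]
    }
  }

  structure(list(title = if (length(lines) >= 1L) lines[1L] else "",
                 program_line = if (length(lines) >= 2L) lines[2L] else "",
                 comment = if (length(lines) >= 3L) lines[3L] else "",
                 drawing = drawing(atoms = adf, bonds = bdf)),
            class = "chem_molfile")
}

as_drawing <- function(x) {
  if (inherits(x, "chem_molfile")) x$drawing
  else if (inherits(x, "chem_drawing")) x
  else cm_abort("chemmorph_domain_error", "expected a chem_drawing or chem_molfile")
}

#' Write an MDL MOL V2000 connection table
#'
#' Coordinates are emitted in 10.4 fixed format with z = 0.0000; charges as
#' `M  CHG` lines and isotope mass numbers as `M  ISO` lines. When the
#' drawing exceeds the 999-atom or 999-bond interchange limit a
#' `chemmorph_compatibility_warning` is signalled, but the file is written in
#' full — staying within the limit is left to the user.
#'
#' @param doc a `chem_molfile` or a bare `chem_drawing`.
#' @param path optional output path.
#' @return the molfile text as a single string (invisibly when written to
#'   `path`).
#' @export
write_molfile <- function(doc, path = NULL) {
  d <- as_drawing(doc)
  validate_drawing(d)
  title <- if (inherits(doc, "chem_molfile")) doc$title else ""
  prog <- if (inherits(doc, "chem_molfile")) doc$program_line else "  chemmorph"
  comment <- if (inherits(doc, "chem_molfile")) doc$comment else ""
  a <- d$atoms; b <- d$bonds
  na <- nrow(a); nb <- nrow(b)
  over <- c(if (na > MOLFILE_LIMIT) sprintf("%d atoms", na),
            if (nb > MOLFILE_LIMIT) sprintf("%d bonds", nb))
  if (length(over)) {
    cm_warn("chemmorph_compatibility_warning",
            sprintf("molfile exceeds the V2000 limit of %d atoms and %d bonds (%s)",
                    MOLFILE_LIMIT, MOLFILE_LIMIT, paste(over, collapse = ", ")),
            n_atoms = na, n_bonds = nb)
  }
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  # drawing ids may be arbitrary; MOL indices are 1-based positions in file order
  idx <- seq_len(na)
  names(idx) <- as.character(a$id)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, rep(0, na), a$element)
  bond_lines <- if (nb) {
    sprintf("%3d%3d%3d%3d  0  0  0",
            idx[as.character(b$a1)], idx[as.character(b$a2)],
            mol_type_from_kind(b$kind), mol_stereo_from_kind(b$kind))
  } else character()
  prop_pairs <- function(tag, which_rows, values) {
    out <- character()
    while (length(which_rows)) {
      take <- seq_len(min(8L, length(which_rows)))
      out <- c(out, paste0(sprintf("M  %s%3d", tag, length(take)),
                           paste(sprintf("%4d%4d", which_rows[take], values[take]),
                                 collapse = "")))
      which_rows <- which_rows[-take]; values <- values[-take]
    }
    out
  }
  props <- character()
  chg_rows <- which(a$charge != 0L)
  if (length(chg_rows)) props <- c(props, prop_pairs("CHG", chg_rows, a$charge[chg_rows]))
  iso_rows <- which(!is.na(a$mass_number))
  if (length(iso_rows)) props <- c(props, prop_pairs("ISO", iso_rows, a$mass_number[iso_rows]))
  text <- paste(c(title, prog, comment, counts, atom_lines, bond_lines,
                  props, "M  END"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

renumber_after <- function(host, guest) {
  offset <- if (n_atoms(host)) max(host$atoms$id) + 1L else 0L
  old <- guest$atoms$id
  new <- offset + seq_along(old) - 1L
  map <- new
  names(map) <- as.character(old)
  guest$atoms$id <- new
  if (n_bonds(guest)) {
    guest$bonds$a1 <- unname(map[as.character(guest$bonds$a1)])
    guest$bonds$a2 <- unname(map[as.character(guest$bonds$a2)])
  }
  if (length(guest$shells)) names(guest$shells) <- as.character(unname(map[names(guest$shells)]))
  list(guest = guest, map = map)
}

combine_drawings <- function(host, guest) {
  if (n_atoms(host) + n_atoms(guest) > ATOM_CAPACITY) {
    cm_abort("chemmorph_capacity_error",
             sprintf("combined drawing would have %d atoms; capacity is %d",
                     n_atoms(host) + n_atoms(guest), ATOM_CAPACITY))
  }
  host$atoms <- rbind(host$atoms, guest$atoms)
  host$bonds <- rbind(host$bonds, guest$bonds)
  host$shells <- c(host$shells, guest$shells)
  host$annotations <- c(host$annotations, guest$annotations)
  host
}

#' Attach an imported structure onto an existing atom
#'
#' The guest's coupling atom — its atom with the smallest x-coordinate — is
#' placed one standard bond length (1.5 scene units) in +x of `target_atom`,
#' the guest's ids are renumbered to follow the host's, and a new single bond
#' joins the target atom to the coupling atom.
#'
#' @param host a `chem_drawing`.
#' @param guest a `chem_molfile` (or `chem_drawing`) to attach.
#' @param target_atom id of the host atom to couple onto.
#' @return the combined `chem_drawing`.
#' @export
attach_molfile <- function(host, guest, target_atom) {
  g <- as_drawing(guest)
  if (!n_atoms(g)) cm_abort("chemmorph_empty_drawing_error", "guest structure has no atoms")
  target_atom <- as.integer(target_atom)
  trow <- match(target_atom, host$atoms$id)
  if (is.na(trow)) {
    cm_abort("chemmorph_dangling_bond_error",
             sprintf("target atom %d not in host drawing", target_atom))
  }
  coupling_old <- leftmost_atom(g)
  crow <- match(coupling_old, g$atoms$id)
  delta <- c(host$atoms$x[trow] + STANDARD_BOND_LENGTH - g$atoms$x[crow],
             host$atoms$y[trow] - g$atoms$y[crow])
  g <- translate_drawing(g, delta)
  rn <- renumber_after(host, g)
  out <- combine_drawings(host, rn$guest)
  out$bonds <- rbind(out$bonds,
                     bond_to_row(bond(target_atom, unname(rn$map[as.character(coupling_old)]))))
  validate_drawing(out)
  out
}

#' Insert an imported structure without bonding it
#'
#' Pure insertion: the guest is translated by `offset`, its ids renumbered to
#' follow the host's, and its atoms/bonds appended. No bond between host and
#' guest is created.
#'
#' @param host a `chem_drawing`.
#' @param guest a `chem_molfile` (or `chem_drawing`).
#' @param offset numeric `c(dx, dy)` translation applied to the guest.
#' @return the combined `chem_drawing`.
#' @export
insert_molfile <- function(host, guest, offset = c(0, 0)) {
  g <- as_drawing(guest)
  g <- translate_drawing(g, offset)
  rn <- renumber_after(host, g)
  out <- combine_drawings(host, rn$guest)
  validate_drawing(out)
  out
}
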