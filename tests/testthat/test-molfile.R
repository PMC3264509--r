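# Hand-written V2000 methane block, columns laid out per the published
# fixed-column format (x: 1-10, y: 11-20, z: 21-30, symbol: 32-34).
METHANE_MOL <- paste(c(
  "methane",
  "  editor",
  "",
  "  5  4  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000   -1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -1.0000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0  0  0  0",
  "  1  3  1  0  0  0  0",
  "  1  4  1  0  0  0  0",
  "  1  5  1  0  0  0  0",
  "M  END"), collapse = "\n")

test_that("V2000 parsing recovers every field of a hand-written block", {
  doc <- read_molfile(METHANE_MOL)
  expect_s3_class(doc, "chem_molfile")
  expect_equal(doc$title, "methane")
  d <- doc$drawing
  expect_equal(n_atoms(d), 5L)
  expect_equal(n_bonds(d), 4L)
  expect_equal(d$atoms$id, 0:4)
  expect_equal(d$atoms$element, c("C", "H", "H", "H", "H"))
  expect_equal(d$atoms$x, c(0, 0, 1, 0, -1))
  expect_equal(d$atoms$y, c(0, 1, 0, -1, 0))
  expect_equal(d$bonds$a1, rep(0L, 4))
  expect_equal(d$bonds$a2, 1:4)
  expect_true(all(d$bonds$kind == "single"))
})

test_that("minimal, malformed and V3000 inputs are classified", {
  empty <- paste(c("", "", "", "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END"),
                 collapse = "\n")
  d <- read_molfile(empty)$drawing
  expect_equal(n_atoms(d), 0L)
  expect_equal(n_bonds(d), 0L)

  # counts line says 3 atoms but the block has 2
  short <- paste(c("", "", "", "  3  0  0  0  0  0  0  0  0  0999 V2000",
                   "    0.0000    0.0000    0.0000 C   0  0",
                   "    1.0000    0.0000    0.0000 C   0  0",
                   "M  END"), collapse = "\n")
  expect_error(read_molfile(short), class = "chemmorph_format_error")

  expect_error(read_molfile(sub("V2000", "V3000", empty)),
               class = "chemmorph_unsupported_version_error")
  expect_error(read_molfile(sub("V2000", "     ", empty)),
               class = "chemmorph_format_error")
  expect_error(read_molfile(sub("  0  0", "  x  0", empty)),
               class = "chemmorph_format_error")
  expect_error(read_molfile(sub("M  END", "", empty)),
               class = "chemmorph_format_error")
})

test_that("bond types, stereo, charges and isotopes map both ways", {
  d <- drawing(
    atoms = list(atom(0L, "C", 0, 0), atom(1L, "N", 1, 0, charge = 1L),
                 atom(2L, "O", 2, 0, charge = -1L),
                 atom(3L, "Cl", 3, 0, mass_number = 37L),
                 atom(4L, "C", 4, 0), atom(5L, "C", 5, 0), atom(6L, "C", 6, 0)),
    bonds = list(bond(0L, 1L, "single"), bond(1L, 2L, "double"),
                 bond(2L, 3L, "triple"), bond(3L, 4L, "aromatic"),
                 bond(4L, 5L, "wedge"), bond(5L, 6L, "hash")))
  txt <- write_molfile(d)
  rt <- read_molfile(txt)$drawing
  expect_equal(rt$bonds$kind, c("single", "double", "triple", "aromatic", "wedge", "hash"))
  expect_equal(rt$atoms$charge, c(0L, 1L, -1L, 0L, 0L, 0L, 0L))
  expect_equal(rt$atoms$mass_number[4], 37L)
  expect_true(any(grepl("^M  CHG", strsplit(txt, "\n")[[1]])))
  expect_true(any(grepl("^M  ISO", strsplit(txt, "\n")[[1]])))
})

test_that("empty drawings and random drawings survive the write/read roundtrip", {
  txt <- write_molfile(drawing())
  expect_match(txt, "  0  0", fixed = TRUE)
  expect_equal(n_atoms(read_molfile(txt)$drawing), 0L)

  set.seed(11)
  for (rep in 1:10) {
    d <- random_drawing(50)
    rt <- read_molfile(write_molfile(d))$drawing
    expect_drawing_fields_equal(rt, d)
  }
})

test_that("writer stays within the fixed-column layout", {
  set.seed(3)
  d <- random_drawing(200)
  lines <- strsplit(write_molfile(d), "\n")[[1]]
  atom_lines <- lines[5:204]
  expect_true(all(nchar(atom_lines) == 69L))
  expect_equal(unique(substr(atom_lines, 21, 30)), "    0.0000")  # z written as 0
  bond_lines <- lines[grepl("^[ 0-9]{12}( {2}0){3}$", lines)]
  expect_equal(length(bond_lines), n_bonds(d))
})

test_that("the interchange warning fires above 999 atoms or bonds, not below", {
  big <- generate_fixture("chain", n = 1000L)        # 1000 atoms, 999 bonds
  w <- capture_warnings(write_molfile(big))
  expect_length(w, 1L)
  expect_match(w, "1000 atoms")

  ok <- generate_fixture("chain", n = 999L)          # 999 atoms, 998 bonds
  expect_no_warning(write_molfile(ok))
})

test_that("an independent cheminformatics parser reads our output identically", {
  tf <- tempfile(fileext = ".sdf")
  writeLines(c(write_molfile(generate_fixture("methane")), "$$$$"), tf)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))
  counts <- ChemmineR::atomcount(sdf[[1]])
  expect_equal(as.vector(counts[c("C", "H")]), c(1L, 4L))
  bb <- ChemmineR::bondblock(sdf[[1]])
  expect_equal(nrow(bb), 4L)
  expect_true(all(bb[, 3] == 1))
})

test_that("attachment couples through the guest's leftmost atom", {
  host <- drawing(atoms = list(atom(0L, "C", 0, 0)))
  guest <- drawing(atoms = list(atom(0L, "O", 10, 10)))
  out <- attach_molfile(host, guest, 0L)
  expect_equal(n_atoms(out), 2L)
  expect_equal(n_bonds(out), 1L)
  o_row <- match("O", out$atoms$element)
  expect_equal(out$atoms$x[o_row], 1.5)
  expect_equal(out$atoms$y[o_row], 0)

  # the coupling atom is the guest atom with the smallest x-coordinate
  guest <- drawing(atoms = list(atom(0L, "C", 5, 0), atom(1L, "N", 2, 0),
                                atom(2L, "C", 8, 0)),
                   bonds = list(bond(0L, 1L), bond(0L, 2L)))
  out <- attach_molfile(host, guest, 0L)
  new_bond <- out$bonds[nrow(out$bonds), ]
  expect_equal(new_bond$a1, 0L)
  expect_equal(out$atoms$element[match(new_bond$a2, out$atoms$id)], "N")
  expect_equal(out$atoms$x[match(new_bond$a2, out$atoms$id)], 1.5)
  # attach adds exactly |guest bonds| + 1 bonds
  expect_equal(n_bonds(out), n_bonds(guest) + 1L)

  expect_error(attach_molfile(host, drawing(), 0L),
               class = "chemmorph_empty_drawing_error")
  expect_error(attach_molfile(host, guest, 99L),
               class = "chemmorph_dangling_bond_error")
})

test_that("insertion adds content without creating bonds and respects capacity", {
  host <- drawing()
  water <- generate_fixture("water")
  out <- insert_molfile(host, water, c(0, 0))
  expect_equal(n_atoms(out), 3L)
  expect_equal(n_bonds(out), 2L)

  host2 <- insert_molfile(generate_fixture("methane"), water, c(5, 5))
  expect_equal(n_bonds(host2), 4L + 2L)          # no junction bond appears
  expect_equal(n_atoms(host2), 5L + 3L)
  expect_true(!anyDuplicated(host2$atoms$id))

  big <- generate_fixture("chain", n = 60000L)
  once <- insert_molfile(drawing(), big)
  expect_error(insert_molfile(once, big), class = "chemmorph_capacity_error")
})
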