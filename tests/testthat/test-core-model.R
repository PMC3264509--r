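test_that("atoms and bonds accumulate with validated ids", {
  d <- drawing()
  d <- add_atom(d, atom(0L, "C", 0, 0))
  expect_equal(n_atoms(d), 1L)

  # sequential bulk insertion keeps every id, counted by an explicit loop
  for (i in 1:499) d <- add_atom(d, atom(i, "C", i * 0.1, 0))
  expect_equal(n_atoms(d), 500L)
  expect_equal(sort(d$atoms$id), 0:499)

  expect_error(add_atom(d, atom(10L, "N", 1, 1)), class = "chemmorph_duplicate_id_error")

  d2 <- add_bond(d, bond(0L, 1L))
  expect_equal(n_bonds(d2), 1L)
  expect_error(bond(0L, 0L), class = "chemmorph_self_bond_error")
  expect_error(add_bond(d2, bond(0L, 9999L)), class = "chemmorph_dangling_bond_error")
})

test_that("field invariants are enforced at construction", {
  expect_error(atom(0L, "", 0, 0), class = "chemmorph_domain_error")
  expect_error(atom(0L, "C", Inf, 0), class = "chemmorph_domain_error")
  expect_error(atom(0L, "C", 0, 0, opacity = 1.2), class = "chemmorph_domain_error")
  expect_error(atom(0L, "C", 0, 0, mass_number = 12, atomic_number_display = 17),
               class = "chemmorph_domain_error")
  expect_silent(atom(0L, "Cl", 0, 0, mass_number = 37, atomic_number_display = 17))
  expect_error(shell_style(c(2, 1)), class = "chemmorph_domain_error")
  expect_error(shell_style(numeric()), class = "chemmorph_domain_error")
  expect_error(annotation("arrow"), class = "chemmorph_domain_error")
  expect_error(background_spec("x.png", brightness = -1), class = "chemmorph_domain_error")
})

test_that("leftmost atom uses smallest x with y-then-id tie-breaks", {
  d <- drawing(atoms = list(atom(7L, "C", 3, 7)))
  expect_equal(leftmost_atom(d), 7L)

  d <- drawing(atoms = list(atom(0L, "C", 2.0, 0), atom(1L, "C", -1.5, 0),
                            atom(2L, "C", 0.0, 0)))
  expect_equal(leftmost_atom(d), 1L)

  d <- drawing(atoms = list(atom(0L, "C", 0, 1), atom(1L, "C", 0, -2)))
  expect_equal(leftmost_atom(d), 1L)

  # equal x and y: lowest id wins
  d <- drawing(atoms = list(atom(5L, "C", 0, 0), atom(3L, "C", 0, 0)))
  expect_equal(leftmost_atom(d), 3L)

  expect_error(leftmost_atom(drawing()), class = "chemmorph_empty_drawing_error")
})

test_that("leftmost atom agrees with an exhaustive scan on random drawings", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:1000, 1)
    d <- random_drawing(n)
    # brute force: scan every atom, track the best under the stated order
    best <- 1L
    a <- d$atoms
    for (i in seq_len(n)) {
      if (a$x[i] < a$x[best] ||
          (a$x[i] == a$x[best] && (a$y[i] < a$y[best] ||
                                   (a$y[i] == a$y[best] && a$id[i] < a$id[best])))) best <- i
    }
    expect_equal(leftmost_atom(d), a$id[best])
  }
})

test_that("translation shifts coordinates and preserves geometry", {
  d <- drawing(atoms = list(atom(0L, "C", 1, 2)))
  d0 <- translate_drawing(d, c(0, 0))
  expect_equal(d0$atoms$x, 1)
  expect_equal(d0$atoms$y, 2)

  d1 <- translate_drawing(d, c(3, -1))
  expect_equal(d1$atoms$x, 4)
  expect_equal(d1$atoms$y, 1)

  set.seed(7)
  d <- random_drawing(40)
  delta <- c(2.5, -3.75)
  back <- translate_drawing(translate_drawing(d, delta), -delta)
  expect_lt(max(abs(back$atoms$x - d$atoms$x)), 1e-12)
  expect_lt(max(abs(back$atoms$y - d$atoms$y)), 1e-12)

  # pairwise inter-atom distances are invariant under translation
  moved <- translate_drawing(d, c(123.4, -56.7))
  dist0 <- dist(cbind(d$atoms$x, d$atoms$y))
  dist1 <- dist(cbind(moved$atoms$x, moved$atoms$y))
  expect_lt(max(abs(dist0 - dist1)), 1e-9)

  # annotation outlines move with the atoms
  d2 <- drawing(atoms = list(atom(0L, "C", 0, 0)),
                annotations = list(annotation("arrow", rbind(c(0, 0), c(1, 1)))))
  d2 <- translate_drawing(d2, c(1, 1))
  expect_equal(d2$annotations[[1]]$outline, rbind(c(1, 1), c(2, 2)))
})

test_that("JSON scene format roundtrips every model field", {
  d <- drawing(
    atoms = list(atom(0L, "O", 0.5, -1.25, charge = -1L, color = c(255L, 0L, 0L),
                      opacity = 0.75, shell = shell_style(c(0.3, 0.6),
                                                          c(255L, 255L, 255L),
                                                          c(0L, 0L, 255L))),
                 atom(1L, "Cl", 2, 3, mass_number = 37L, atomic_number_display = 17L)),
    bonds = list(bond(0L, 1L, "wedge", color = c(0L, 128L, 0L), opacity = 0.5)),
    annotations = list(annotation("club", rbind(c(0, 0), c(1, 0), c(1, 1)),
                                  gradient = list(c(255L, 0L, 0L), c(0L, 0L, 255L)),
                                  label = NULL),
                       annotation("text", rbind(c(0, 0)), label = "TS")),
    background = background_spec("bg.png", brightness = 1.8))
  rt <- read_scene(write_scene(d))
  expect_equal(rt$atoms, d$atoms)
  expect_equal(rt$bonds, d$bonds)
  expect_equal(rt$shells[["0"]]$radii, c(0.3, 0.6))
  expect_equal(rt$annotations[[1]]$outline, d$annotations[[1]]$outline)
  expect_equal(rt$annotations[[1]]$gradient[[2]], c(0L, 0L, 255L))
  expect_equal(rt$annotations[[2]]$label, "TS")
  expect_equal(rt$background$brightness, 1.8)

  expect_error(read_scene('{"atoms": []}'), class = "chemmorph_format_error")
})
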