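test_that("identical drawings correspond to themselves completely", {
  d <- generate_fixture("methane")
  corr <- auto_correspond(d, d)
  expect_equal(corr$atom_pairs[, 1], corr$atom_pairs[, 2])
  expect_equal(sort(corr$atom_pairs[, 1]), d$atoms$id)
  expect_equal(corr$bond_pairs[, 1], corr$bond_pairs[, 2])
  expect_length(corr$unmatched_source_atoms, 0L)
  expect_length(corr$unmatched_target_atoms, 0L)
  expect_length(corr$unmatched_source_bonds, 0L)
  expect_length(corr$unmatched_target_bonds, 0L)
})

test_that("pairing is element-grouped nearest-position, verified by brute force", {
  w1 <- generate_fixture("water")
  w2 <- w1
  w2$atoms$x[1] <- w2$atoms$x[1] + 0.1            # displace O
  corr <- auto_correspond(w1, w2)
  ap <- corr$atom_pairs
  expect_equal(ap[ap[, 1] == 0L, 2], 0L)          # O pairs with O
  # brute force over both H assignments: pick the smaller total distance
  h_src <- w1$atoms[w1$atoms$element == "H", ]
  h_tgt <- w2$atoms[w2$atoms$element == "H", ]
  d11 <- sqrt((h_src$x[1] - h_tgt$x[1])^2 + (h_src$y[1] - h_tgt$y[1])^2)
  d12 <- sqrt((h_src$x[1] - h_tgt$x[2])^2 + (h_src$y[1] - h_tgt$y[2])^2)
  d21 <- sqrt((h_src$x[2] - h_tgt$x[1])^2 + (h_src$y[2] - h_tgt$y[1])^2)
  d22 <- sqrt((h_src$x[2] - h_tgt$x[2])^2 + (h_src$y[2] - h_tgt$y[2])^2)
  best <- if (d11 + d22 <= d12 + d21) cbind(h_src$id, h_tgt$id) else
    cbind(h_src$id, rev(h_tgt$id))
  expect_equal(ap[ap[, 1] %in% h_src$id, , drop = FALSE], best)

  # CH4 -> CH3Cl: C pairs, three H pair, one H and the Cl stay unmatched
  ch4 <- generate_fixture("methane")
  ch3cl <- ch4
  ch3cl$atoms$element[3] <- "Cl"
  corr <- auto_correspond(ch4, ch3cl)
  expect_equal(corr$atom_pairs[corr$atom_pairs[, 1] == 0L, 2], 0L)
  expect_length(corr$unmatched_source_atoms, 1L)
  expect_equal(ch4$atoms$element[match(corr$unmatched_source_atoms, ch4$atoms$id)], "H")
  expect_equal(ch3cl$atoms$element[match(corr$unmatched_target_atoms, ch3cl$atoms$id)], "Cl")
})

test_that("pairing is symmetric up to role swap for generic positions", {
  set.seed(21)
  for (rep in 1:10) {
    a <- random_drawing(15)
    b <- jitter_drawing(random_drawing(15), 0)
    fwd <- auto_correspond(a, b)$atom_pairs
    rev_ <- auto_correspond(b, a)$atom_pairs
    expect_equal(fwd[order(fwd[, 1]), ],
                 rev_[order(rev_[, 2]), c(2, 1), drop = FALSE])
  }
})

test_that("atom interpolation is linear with endpoint identity", {
  a0 <- atom(0L, "C", 0, 0, color = c(0L, 0L, 0L))
  a1 <- atom(0L, "N", 2, 0, color = c(255L, 0L, 0L))
  expect_equal(interpolate_atom(a0, a1, 0), a0)
  expect_equal(interpolate_atom(a0, a1, 1), a1)
  mid <- interpolate_atom(a0, a1, 0.5)
  expect_equal(c(mid$x, mid$y), c(1, 0))
  q <- interpolate_atom(a0, a1, 0.25)
  expect_equal(q$color, c(64L, 0L, 0L))   # round(0.25 * 255)
  expect_equal(q$element, "C")            # label switches at t = 0.5
  expect_equal(interpolate_atom(a0, a1, 0.5)$element, "N")
  expect_error(interpolate_atom(a0, a1, 1.5), class = "chemmorph_domain_error")
})

test_that("frames hit the t-grid exactly and cross-dissolve unmatched elements", {
  one0 <- drawing(atoms = list(atom(0L, "C", 0, 0)))
  one1 <- drawing(atoms = list(atom(0L, "C", 4, 0)))
  fr <- make_frames(morph_step(one0, one1, n_frames = 5))
  expect_equal(vapply(fr, function(f) f$atoms$x, numeric(1)), 0:4)

  two <- make_frames(morph_step(one0, one1, n_frames = 2))
  expect_equal(two[[1]]$atoms$x, 0)
  expect_equal(two[[2]]$atoms$x, 4)

  ch4 <- generate_fixture("methane")
  ch3cl <- ch4
  ch3cl$atoms$element[3] <- "Cl"
  fr <- make_frames(morph_step(ch4, ch3cl, n_frames = 3))
  mid <- fr[[2]]
  cl_row <- match("Cl", mid$atoms$element)
  h_unmatched <- setdiff(which(mid$atoms$element == "H"),
                         match(c(1L, 3L, 4L), mid$atoms$id))
  expect_equal(mid$atoms$opacity[cl_row], 0.5)
  leaving_h <- mid$atoms$opacity[mid$atoms$id == 2L]
  expect_equal(leaving_h, 0.5)
  # opacity conservation: fading H + appearing Cl sum to 1 at every t
  expect_equal(mid$atoms$opacity[cl_row] + leaving_h, 1)
  # endpoints contain no ghosts
  expect_equal(n_atoms(fr[[1]]), 5L)
  expect_equal(n_atoms(fr[[3]]), 5L)
  expect_false("Cl" %in% fr[[1]]$atoms$element)
  expect_false(2L %in% fr[[3]]$atoms$id && fr[[3]]$atoms$element[fr[[3]]$atoms$id == 2L] == "H")
})

test_that("paired atoms move monotonically along their segment", {
  set.seed(31)
  src <- random_drawing(30)
  tgt <- jitter_drawing(src, 0.5)
  step <- morph_step(src, tgt, n_frames = 11)
  fr <- make_frames(step)
  ap <- step$correspondence$atom_pairs
  for (k in seq_along(fr)) {
    t <- (k - 1) / 10
    a <- fr[[k]]$atoms
    for (r in seq_len(nrow(ap))) {
      i <- match(ap[r, 1], src$atoms$id)
      j <- match(ap[r, 2], tgt$atoms$id)
      expected <- c((1 - t) * src$atoms$x[i] + t * tgt$atoms$x[j],
                    (1 - t) * src$atoms$y[i] + t * tgt$atoms$y[j])
      got_row <- match(ap[r, 1], a$id)
      expect_lt(max(abs(c(a$x[got_row], a$y[got_row]) - expected)), 1e-12)
    }
  }
})

test_that("region modes warp annotation outlines through the mesh", {
  out0 <- rbind(c(1, 1), c(2, 1), c(2, 2))
  src <- drawing(atoms = list(atom(0L, "C", 0, 0), atom(1L, "C", 4, 4)),
                 annotations = list(annotation("arrow", out0)))
  tgt <- translate_drawing(src, c(3, 0))
  for (mode in c("triangles", "squares")) {
    fr <- make_frames(morph_step(src, tgt, n_frames = 3, mapping_mode = mode))
    warped <- fr[[2]]$annotations[[1]]$outline
    # pure translation: the piecewise map is the half-way translation exactly
    expect_lt(max(abs(warped - (out0 + rep(c(1.5, 0), each = 3)))), 1e-8)
  }
})

test_that("sequences chain with shared junctions and merged frames", {
  w <- generate_fixture("water")
  s <- generate_fixture("stretch_pair")$target
  st1 <- morph_step(w, s, n_frames = 5)
  st2 <- morph_step(s, w, n_frames = 5)
  fr <- run_sequence(morph_sequence(list(st1, st2)))
  expect_length(fr, 9L)                          # 5 + 5 - 1
  expect_length(run_sequence(morph_sequence(list(st1))), 5L)

  mism <- morph_step(translate_drawing(s, c(1, 0)), w, n_frames = 5)
  expect_error(run_sequence(morph_sequence(list(st1, mism))),
               class = "chemmorph_chain_error")

  set.seed(41)
  for (rep in 1:5) {
    n_steps <- sample(2:5, 1)
    frames_per <- sample(2:8, n_steps, replace = TRUE)
    ds <- list(random_drawing(10))
    for (i in seq_len(n_steps)) ds[[i + 1L]] <- jitter_drawing(ds[[i]], 0.1)
    steps <- lapply(seq_len(n_steps), function(i) {
      morph_step(ds[[i]], ds[[i + 1L]], n_frames = frames_per[i])
    })
    fr <- run_sequence(morph_sequence(steps))
    expect_length(fr, sum(frames_per) - (n_steps - 1L))
  }
})

test_that("vibration presets displace geometry by exactly the amplitude", {
  w <- generate_fixture("water")

  still <- vibration_preset(w, "symmetric_stretch", amplitude = 0)
  for (f in run_sequence(still)) {
    expect_lt(max(abs(f$atoms$x - w$atoms$x)), 1e-12)
    expect_lt(max(abs(f$atoms$y - w$atoms$y)), 1e-12)
  }

  sym <- vibration_preset(w, "symmetric_stretch", amplitude = 0.2)
  disp <- sym$steps[[1]]$target
  expect_equal(bond_length(disp, 0L, 1L), 1.2, tolerance = 1e-9)
  expect_equal(bond_length(disp, 0L, 2L), 1.2, tolerance = 1e-9)

  asym <- vibration_preset(w, "asymmetric_stretch", amplitude = 0.2)
  disp <- asym$steps[[1]]$target
  lens <- sort(c(bond_length(disp, 0L, 1L), bond_length(disp, 0L, 2L)))
  expect_equal(lens, c(0.8, 1.2), tolerance = 1e-9)

  sci <- vibration_preset(w, "scissoring", amplitude = 0.1)
  disp <- sci$steps[[1]]$target
  ang0 <- bond_angle(w, 1L, 0L, 2L)
  expect_equal(bond_angle(disp, 1L, 0L, 2L), ang0 + 0.1, tolerance = 1e-9)
  expect_equal(bond_length(disp, 0L, 1L), 1, tolerance = 1e-9)
  expect_equal(bond_length(disp, 0L, 2L), 1, tolerance = 1e-9)

  # oscillation returns to the source at both ends
  fr <- run_sequence(sym)
  expect_equal(fr[[1]]$atoms$x, w$atoms$x)
  expect_equal(fr[[length(fr)]]$atoms$x, w$atoms$x)

  expect_error(vibration_preset(generate_fixture("methane"), "scissoring"),
               class = "chemmorph_topology_error")
})
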