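# The morphing engine: correspondence between two drawings, stepwise
# shape + colour interpolation, chained sequences, and triatomic vibration
# presets. Paired elements move along straight segments; unmatched elements
# cross-dissolve (opacity fade) or shrink, so the share of one image fades
# out while the other fades in.

#' Automatically correspond two drawings
#'
#' Pairs the atom and bond areas of two drawings so only they are morphed.
#' Atoms are grouped by element symbol; within each element, source/target
#' atoms are paired greedily by nearest Euclidean distance (global minimum
#' first; ties by lowest source id, then lowest target id). Leftover atoms
#' go to the unmatched lists. A bond is paired when both its endpoint atoms
#' are paired with the endpoints of a target bond and the kinds are
#' compatible: identical kind, or any kind when exactly one candidate bond
#' connects the mapped endpoints.
#'
#' @param source,target `chem_drawing` objects.
#' @return an object of class `chem_correspondence`: list with
#'   `atom_pairs` (m x 2 matrix of source/target ids), `bond_pairs`
#'   (k x 2 matrix of 1-based bond row indices), and the four unmatched
#'   vectors `unmatched_source_atoms`, `unmatched_target_atoms`,
#'   `unmatched_source_bonds`, `unmatched_target_bonds`.
#' @export
auto_correspond <- function(source, target) {
  sa <- source$atoms; ta <- target$atoms
  pairs <- matrix(integer(), 0L, 2L)
  for (el in sort(unique(c(sa$element, ta$element)))) {
    si <- which(sa$element == el)
    ti <- which(ta$element == el)
    if (!length(si) || !length(ti)) next
    dmat <- outer(seq_along(si), seq_along(ti), function(i, j) {
      sqrt((sa$x[si[i]] - ta$x[ti[j]])^2 + (sa$y[si[i]] - ta$y[ti[j]])^2)
    })
    while (length(si) && length(ti)) {
      # global nearest pair; deterministic tie-break by source id then target id
      best <- which(dmat == min(dmat), arr.ind = TRUE)
      if (nrow(best) > 1L) {
        ord <- order(sa$id[si[best[, 1]]], ta$id[ti[best[, 2]]])
        best <- best[ord[1L], , drop = FALSE]
      }
      i <- best[1, 1]; j <- best[1, 2]
      pairs <- rbind(pairs, c(sa$id[si[i]], ta$id[ti[j]]))
      si <- si[-i]; ti <- ti[-j]
      dmat <- dmat[-i, -j, drop = FALSE]
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  atom_map <- pairs[, 2]
  names(atom_map) <- as.character(pairs[, 1])

  sb <- source$bonds; tb <- target$bonds
  bond_pairs <- matrix(integer(), 0L, 2L)
  taken_t <- logical(nrow(tb))
  tb_key <- if (nrow(tb)) paste(pmin(tb$a1, tb$a2), pmax(tb$a1, tb$a2)) else character()
  for (bi in seq_len(nrow(sb))) {
    m1 <- atom_map[as.character(sb$a1[bi])]
    m2 <- atom_map[as.character(sb$a2[bi])]
    if (is.na(m1) || is.na(m2)) next
    cand <- which(!taken_t & tb_key == paste(min(m1, m2), max(m1, m2)))
    if (!length(cand)) next
    same <- cand[tb$kind[cand] == sb$kind[bi]]
    pick <- if (length(same)) same[1L] else if (length(cand) == 1L) cand else NA_integer_
    if (is.na(pick)) next
    bond_pairs <- rbind(bond_pairs, c(bi, pick))
    taken_t[pick] <- TRUE
  }

  structure(list(
    atom_pairs = pairs,
    bond_pairs = bond_pairs,
    unmatched_source_atoms = setdiff(sa$id, pairs[, 1]),
    unmatched_target_atoms = setdiff(ta$id, pairs[, 2]),
    unmatched_source_bonds = setdiff(seq_len(nrow(sb)), bond_pairs[, 1]),
    unmatched_target_bonds = setdiff(seq_len(nrow(tb)), bond_pairs[, 2])),
    class = "chem_correspondence")
}

#' Interpolate between two atoms
#'
#' Position, colour and opacity are interpolated linearly in `t`; RGB
#' channels are rounded to integers at output. The element label (and
#' charge/isotope fields) switch from the source atom to the target atom at
#' `t = 0.5`, since textual interpolation is not meaningful.
#'
#' @param a0,a1 `chem_atom` objects.
#' @param t interpolation parameter in `[0, 1]`.
#' @return a `chem_atom`.
#' @export
interpolate_atom <- function(a0, a1, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0 || t > 1) {
    cm_abort("chemmorph_domain_error", "t must lie in [0, 1]")
  }
  lead <- if (t < 0.5) a0 else a1
  atom(id = lead$id, element = lead$element,
       x = (1 - t) * a0$x + t * a1$x,
       y = (1 - t) * a0$y + t * a1$y,
       charge = lead$charge, mass_number = lead$mass_number,
       atomic_number_display = lead$atomic_number_display,
       color = round((1 - t) * a0$color + t * a1$color),
       opacity = (1 - t) * a0$opacity + t * a1$opacity,
       shell = lead$shell)
}

#' Define one morphing step
#'
#' A parameterised transition between two drawings over `n_frames` frames;
#' frame `k` uses parameter `t_k = k / (n_frames - 1)`.
#'
#' @param source,target `chem_drawing` objects.
#' @param n_frames number of frames (>= 2), endpoints included.
#' @param correspondence a `chem_correspondence`, or `NULL` to pair
#'   automatically with [auto_correspond()].
#' @param mapping_mode `"pointwise"` (atoms/bonds move along straight
#'   segments), `"triangles"` or `"squares"` (annotation outlines and the
#'   background region are additionally warped through a piecewise mesh
#'   mapping between the two drawings' bounding boxes).
#' @param easing `"linear"` or `"ping_pong"` (t runs 0 -> 1 -> 0 across the
#'   step, for oscillating animations).
#' @param fade_mode `"dissolve"` (unmatched elements hold position and fade)
#'   or `"shrink"` (their geometry additionally contracts toward its
#'   centroid as it fades).
#' @param mesh_n grid resolution of the warp mesh in region modes.
#' @return an object of class `morph_step`.
#' @export
morph_step <- function(source, target, n_frames = 10L, correspondence = NULL,
                       mapping_mode = c("pointwise", "triangles", "squares"),
                       easing = c("linear", "ping_pong"),
                       fade_mode = c("dissolve", "shrink"), mesh_n = 4L) {
  mapping_mode <- match.arg(mapping_mode)
  easing <- match.arg(easing)
  fade_mode <- match.arg(fade_mode)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) {
    cm_abort("chemmorph_domain_error", "n_frames must be an integer >= 2")
  }
  validate_drawing(source); validate_drawing(target)
  if (is.null(correspondence)) correspondence <- auto_correspond(source, target)
  structure(list(source = source, target = target,
                 correspondence = correspondence, n_frames = n_frames,
                 mapping_mode = mapping_mode, easing = easing,
                 fade_mode = fade_mode, mesh_n = as.integer(mesh_n)),
            class = "morph_step")
}

check_correspondence <- function(corr, source, target) {
  ap <- corr$atom_pairs
  if (nrow(ap)) {
    if (!all(ap[, 1] %in% source$atoms$id) || !all(ap[, 2] %in% target$atoms$id)) {
      cm_abort("chemmorph_correspondence_error",
               "correspondence references atom ids absent from the drawings")
    }
    if (anyDuplicated(ap[, 1]) || anyDuplicated(ap[, 2])) {
      cm_abort("chemmorph_correspondence_error", "an atom id is paired more than once")
    }
  }
  bp <- corr$bond_pairs
  if (nrow(bp)) {
    if (any(bp[, 1] < 1L) || any(bp[, 1] > nrow(source$bonds)) ||
        any(bp[, 2] < 1L) || any(bp[, 2] > nrow(target$bonds))) {
      cm_abort("chemmorph_correspondence_error",
               "correspondence references bond indices outside the drawings")
    }
  }
  invisible(corr)
}

drawing_bbox <- function(d, pad = 0.5) {
  xs <- d$atoms$x; ys <- d$atoms$y
  for (an in d$annotations) {
    if (!is.null(an$outline)) { xs <- c(xs, an$outline[, 1]); ys <- c(ys, an$outline[, 2]) }
  }
  if (!length(xs)) return(c(-1, -1, 1, 1))
  c(min(xs) - pad, min(ys) - pad, max(xs) + pad, max(ys) + pad)
}

# Piecewise warp of points through per-cell maps between two meshes laid
# over the source and the interpolated bounding box. Points outside every
# cell fall back to the whole-bbox map.
warp_points <- function(pts, mesh_src, mesh_dst, mode) {
  if (!nrow(pts)) return(pts)
  out <- pts
  vs <- mesh_src$vertices; vd <- mesh_dst$vertices
  maps <- lapply(seq_along(mesh_src$cells), function(ci) {
    idx <- mesh_src$cells[[ci]]
    if (mode == "triangles") {
      affine_from_triplet(vs[idx, , drop = FALSE], vd[idx, , drop = FALSE])
    } else {
      projective_from_quads(vs[idx, , drop = FALSE], vd[idx, , drop = FALSE])
    }
  })
  cell_of <- function(p) {
    for (ci in seq_along(mesh_src$cells)) {
      q <- vs[mesh_src$cells[[ci]], , drop = FALSE]
      if (p[1] >= min(q[, 1]) - 1e-9 && p[1] <= max(q[, 1]) + 1e-9 &&
          p[2] >= min(q[, 2]) - 1e-9 && p[2] <= max(q[, 2]) + 1e-9) {
        if (mode == "squares") return(ci)
        # triangle membership via barycentric sign test
        s1 <- signed_area2(rbind(q[1, ], q[2, ], p))
        s2 <- signed_area2(rbind(q[2, ], q[3, ], p))
        s3 <- signed_area2(rbind(q[3, ], q[1, ], p))
        if ((s1 >= -1e-9 && s2 >= -1e-9 && s3 >= -1e-9) ||
            (s1 <= 1e-9 && s2 <= 1e-9 && s3 <= 1e-9)) return(ci)
      }
    }
    NA_integer_
  }
  for (i in seq_len(nrow(pts))) {
    ci <- cell_of(pts[i, ])
    if (!is.na(ci)) out[i, ] <- apply_map(maps[[ci]], pts[i, ])
  }
  out
}

shrink_outline <- function(outline, s) {
  ctr <- colMeans(outline)
  sweep(sweep(outline, 2, ctr, "-") * s, 2, ctr, "+")
}

frame_at <- function(step, t) {
  src <- step$source; tgt <- step$target
  corr <- step$correspondence
  sa <- src$atoms; ta <- tgt$atoms
  ap <- corr$atom_pairs
  tmap <- if (nrow(ap)) ap[, 2] else integer()
  names(tmap) <- if (nrow(ap)) as.character(ap[, 1]) else character()

  id_offset <- if (nrow(sa)) max(sa$id) + 1L else 0L
  rows <- list(); shells <- list()

  # source-side atoms in their original order: paired interpolate, unmatched fade
  for (i in seq_len(nrow(sa))) {
    tid <- tmap[as.character(sa$id[i])]
    row <- sa[i, , drop = FALSE]
    if (!is.na(tid)) {
      j <- match(tid, ta$id)
      lead <- if (t < 0.5) sa[i, ] else ta[j, ]
      row$element <- lead$element
      row$charge <- lead$charge
      row$mass_number <- lead$mass_number
      row$atomic_number_display <- lead$atomic_number_display
      row$x <- (1 - t) * sa$x[i] + t * ta$x[j]
      row$y <- (1 - t) * sa$y[i] + t * ta$y[j]
      row$red <- as.integer(round((1 - t) * sa$red[i] + t * ta$red[j]))
      row$green <- as.integer(round((1 - t) * sa$green[i] + t * ta$green[j]))
      row$blue <- as.integer(round((1 - t) * sa$blue[i] + t * ta$blue[j]))
      row$opacity <- (1 - t) * sa$opacity[i] + t * ta$opacity[j]
      sh <- if (t < 0.5) src$shells[[as.character(sa$id[i])]] else tgt$shells[[as.character(tid)]]
      if (!is.null(sh)) shells[[as.character(row$id)]] <- sh
    } else {
      if (t >= 1) next   # fully dissolved at the endpoint
      row$opacity <- sa$opacity[i] * (1 - t)
      sh <- src$shells[[as.character(sa$id[i])]]
      if (!is.null(sh)) shells[[as.character(row$id)]] <- sh
    }
    rows[[length(rows) + 1L]] <- row
  }
  # unmatched target atoms fade in under fresh ids (kept out of frame 0)
  new_tid <- integer(); names(new_tid) <- character()
  if (t > 0) {
    for (uid in corr$unmatched_target_atoms) {
      j <- match(uid, ta$id)
      row <- ta[j, , drop = FALSE]
      row$id <- id_offset + length(new_tid)
      row$opacity <- ta$opacity[j] * t
      new_tid[as.character(uid)] <- row$id
      sh <- tgt$shells[[as.character(uid)]]
      if (!is.null(sh)) shells[[as.character(row$id)]] <- sh
      rows[[length(rows) + 1L]] <- row
    }
  }
  adf <- if (length(rows)) do.call(rbind, rows) else empty_atom_df()

  # bonds: paired interpolate; unmatched fade with their endpoints
  sb <- src$bonds; tb <- tgt$bonds
  bp <- corr$bond_pairs
  bmap <- if (nrow(bp)) bp[, 2] else integer()
  names(bmap) <- if (nrow(bp)) as.character(bp[, 1]) else character()
  brow_list <- list()
  for (bi in seq_len(nrow(sb))) {
    tj <- bmap[as.character(bi)]
    row <- sb[bi, , drop = FALSE]
    if (!is.na(tj)) {
      row$kind <- if (t < 0.5) sb$kind[bi] else tb$kind[tj]
      row$red <- as.integer(round((1 - t) * sb$red[bi] + t * tb$red[tj]))
      row$green <- as.integer(round((1 - t) * sb$green[bi] + t * tb$green[tj]))
      row$blue <- as.integer(round((1 - t) * sb$blue[bi] + t * tb$blue[tj]))
      row$opacity <- (1 - t) * sb$opacity[bi] + t * tb$opacity[tj]
    } else {
      if (t >= 1) next
      # drop if an endpoint vanished from the frame
      if (!(sb$a1[bi] %in% adf$id) || !(sb$a2[bi] %in% adf$id)) next
      row$opacity <- sb$opacity[bi] * (1 - t)
    }
    brow_list[[length(brow_list) + 1L]] <- row
  }
  if (t > 0) {
    for (tj in corr$unmatched_target_bonds) {
      e1 <- tb$a1[tj]; e2 <- tb$a2[tj]
      # endpoints may be paired target atoms (use their source-side frame id)
      # or unmatched target atoms (use their fresh id)
      resolve <- function(e) {
        if (length(new_tid) && as.character(e) %in% names(new_tid)) return(new_tid[[as.character(e)]])
        k <- if (nrow(ap)) match(e, ap[, 2]) else NA_integer_
        if (!is.na(k)) return(ap[k, 1])
        NA_integer_
      }
      f1 <- resolve(e1); f2 <- resolve(e2)
      if (is.na(f1) || is.na(f2)) next
      row <- tb[tj, , drop = FALSE]
      row$a1 <- f1; row$a2 <- f2
      row$opacity <- tb$opacity[tj] * t
      brow_list[[length(brow_list) + 1L]] <- row
    }
  }
  bdf <- if (length(brow_list)) do.call(rbind, brow_list) else empty_bond_df()

  # annotations: region modes warp outlines through the mesh pair;
  # pointwise cross-dissolves them in place
  src_ann <- src$annotations
  tgt_ann <- tgt$annotations
  warp <- NULL
  if (step$mapping_mode != "pointwise") {
    mode <- step$mapping_mode
    bb_s <- drawing_bbox(src)
    bb_t <- drawing_bbox(tgt)
    bb_i <- (1 - t) * bb_s + t * bb_t
    mesh_s <- tessellate_region(bb_s, mode, step$mesh_n)
    mesh_i <- tessellate_region(bb_i, mode, step$mesh_n)
    warp <- function(outline) warp_points(outline, mesh_s, mesh_i, mode)
  }
  anns <- list()
  for (an in src_ann) {
    a2 <- an
    if (!is.null(a2$outline)) {
      if (!is.null(warp)) a2$outline <- warp(a2$outline)
      if (step$fade_mode == "shrink") a2$outline <- shrink_outline(a2$outline, 1 - t)
    }
    a2$opacity <- 1 - t
    if (t < 1) anns[[length(anns) + 1L]] <- a2
  }
  for (an in tgt_ann) {
    a2 <- an
    if (!is.null(a2$outline) && step$fade_mode == "shrink") {
      a2$outline <- shrink_outline(a2$outline, t)
    }
    a2$opacity <- t
    if (t > 0) anns[[length(anns) + 1L]] <- a2
  }

  bg <- if (t < 0.5) src$background else tgt$background
  fr <- structure(list(atoms = adf, bonds = bdf, shells = shells,
                       annotations = anns, background = bg),
                  class = "chem_drawing")
  rownames(fr$atoms) <- NULL; rownames(fr$bonds) <- NULL
  fr
}

#' Generate the frames of a morphing step
#'
#' Frame `k` (k = 0 .. n_frames-1) is computed at parameter
#' `t = k / (n_frames - 1)` (passed through the easing curve). Paired atoms
#' and bonds are interpolated in position and colour; unmatched source
#' elements are rendered at opacity `1 - t` and unmatched target elements at
#' opacity `t`, so frame 0 equals the source and the last frame equals the
#' target.
#'
#' @param step a [morph_step()].
#' @return list of `n_frames` `chem_drawing` objects.
#' @export
make_frames <- function(step) {
  if (!inherits(step, "morph_step")) cm_abort("chemmorph_domain_error", "step must be a morph_step")
  check_correspondence(step$correspondence, step$source, step$target)
  n <- step$n_frames
  ts <- (seq_len(n) - 1L) / (n - 1L)
  if (step$easing == "ping_pong") ts <- 1 - abs(2 * ts - 1)
  lapply(ts, function(t) frame_at(step, t))
}

#' Chain morphing steps into a sequence
#'
#' @param steps list of [morph_step()] objects; consecutive steps must chain
#'   (step i's target is step i+1's source).
#' @return an object of class `morph_sequence`.
#' @export
morph_sequence <- function(steps) {
  if (!length(steps) || !all(vapply(steps, inherits, logical(1), "morph_step"))) {
    cm_abort("chemmorph_domain_error", "steps must be a non-empty list of morph_step objects")
  }
  structure(list(steps = steps), class = "morph_sequence")
}

junction_matches <- function(a, b, tol = 1e-9) {
  if (n_atoms(a) != n_atoms(b)) return(FALSE)
  if (!setequal(a$atoms$id, b$atoms$id)) return(FALSE)
  oa <- a$atoms[order(a$atoms$id), ]
  ob <- b$atoms[order(b$atoms$id), ]
  all(abs(oa$x - ob$x) <= tol) && all(abs(oa$y - ob$y) <= tol) &&
    all(oa$element == ob$element)
}

#' Run a morphing sequence
#'
#' Concatenates the frames of every step, dropping the duplicated junction
#' frame between consecutive steps, so the total frame count is
#' `sum(n_frames) - (n_steps - 1)`.
#'
#' @param seq a [morph_sequence()].
#' @return list of `chem_drawing` frames.
#' @export
run_sequence <- function(seq) {
  if (!inherits(seq, "morph_sequence")) cm_abort("chemmorph_domain_error", "seq must be a morph_sequence")
  steps <- seq$steps
  for (i in seq_len(length(steps) - 1L)) {
    if (!junction_matches(steps[[i]]$target, steps[[i + 1L]]$source)) {
      cm_abort("chemmorph_chain_error",
               sprintf("steps %d and %d do not chain: junction drawings differ", i, i + 1L))
    }
  }
  frames <- list()
  for (i in seq_along(steps)) {
    fr <- make_frames(steps[[i]])
    if (i > 1L) fr <- fr[-1L]
    frames <- c(frames, fr)
  }
  frames
}

bent_triatomic_topology <- function(d) {
  if (n_atoms(d) != 3L || n_bonds(d) != 2L) {
    cm_abort("chemmorph_topology_error", "vibration presets require a triatomic with two bonds")
  }
  ids <- d$atoms$id
  deg <- vapply(ids, function(i) sum(d$bonds$a1 == i) + sum(d$bonds$a2 == i), integer(1))
  if (sum(deg == 2L) != 1L || any(deg > 2L)) {
    cm_abort("chemmorph_topology_error", "vibration presets require one 2-bonded central atom")
  }
  central <- ids[deg == 2L]
  terminals <- ids[deg == 1L]
  list(central = central, terminals = terminals)
}

#' Molecular-vibration animation presets
#'
#' Builds the displaced geometry for a bent triatomic (A-B-A type) and wraps
#' it in a two-step oscillating sequence (equilibrium -> displaced ->
#' equilibrium):
#' \describe{
#'   \item{symmetric_stretch}{both bonds lengthen by `amplitude` along their
#'     own axes;}
#'   \item{asymmetric_stretch}{the first bond lengthens and the second
#'     shortens by `amplitude`;}
#'   \item{scissoring}{the bond angle opens by `amplitude` radians (each
#'     terminal rotates outward by half of it) at fixed bond lengths.}
#' }
#' Terminal order follows increasing atom id.
#'
#' @param molecule a `chem_drawing`: three atoms, one central atom bonded to
#'   the two others.
#' @param mode one of `"symmetric_stretch"`, `"asymmetric_stretch"`,
#'   `"scissoring"`.
#' @param amplitude bond-length change in scene units, or angle change in
#'   radians for scissoring.
#' @param n_frames frames per half-oscillation (each of the two steps).
#' @return a `morph_sequence` of two steps.
#' @export
vibration_preset <- function(molecule, mode = c("symmetric_stretch",
                                                "asymmetric_stretch",
                                                "scissoring"),
                             amplitude = 0.2, n_frames = 9L) {
  mode <- match.arg(mode)
  if (!is.numeric(amplitude) || !is.finite(amplitude)) {
    cm_abort("chemmorph_domain_error", "amplitude must be a finite number")
  }
  topo <- bent_triatomic_topology(molecule)
  a <- molecule$atoms
  ci <- match(topo$central, a$id)
  term <- sort(topo$terminals)
  displaced <- molecule
  for (k in 1:2) {
    ti <- match(term[k], a$id)
    v <- c(a$x[ti] - a$x[ci], a$y[ti] - a$y[ci])
    len <- sqrt(sum(v^2))
    u <- v / len
    if (mode == "symmetric_stretch") {
      new <- c(a$x[ci], a$y[ci]) + (len + amplitude) * u
    } else if (mode == "asymmetric_stretch") {
      dl <- if (k == 1L) amplitude else -amplitude
      new <- c(a$x[ci], a$y[ci]) + (len + dl) * u
    } else {
      # rotate each terminal outward by half the angle change, away from the
      # other terminal (sign from the cross product with the bisector)
      oi <- match(term[if (k == 1L) 2L else 1L], a$id)
      w <- c(a$x[oi] - a$x[ci], a$y[oi] - a$y[ci])
      cross <- u[1] * w[2] - u[2] * w[1]
      phi <- -sign(cross) * amplitude / 2
      rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
      new <- c(a$x[ci], a$y[ci]) + len * as.vector(rot %*% u)
    }
    displaced$atoms$x[ti] <- new[1]
    displaced$atoms$y[ti] <- new[2]
  }
  morph_sequence(list(
    morph_step(molecule, displaced, n_frames = n_frames),
    morph_step(displaced, molecule, n_frames = n_frames)))
}
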