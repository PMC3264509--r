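---
title: "Morphing chemical depictions: models, mappings and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphing chemical depictions: models, mappings and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemmorph)
```

## The drawing model

`chemmorph` models a 2D chemical scene the way a structure editor does
internally: an ordered table of atoms (element symbol, real-valued
position in scene units with y increasing upward, formal charge, optional
isotope mass number and displayed atomic number, RGB colour, opacity,
optional concentric electron-shell rings with a two-stop gradient), an
ordered table of bonds (six kinds: single, double, triple, wedge, hash,
aromatic), free annotation shapes, and an optional background image with a
brightness multiplier (values above 1 push the image toward a watermark).

Two hard numbers shape the model. The atom capacity is 100000: any
operation that would push a drawing past it raises a capacity error
rather than degrading. And the MOL V2000 connection-table format is set up
for at most 999 atoms and 999 bonds; since the drawing model deliberately
allows far more, the writer emits a classed compatibility warning above
the limit but still writes the file — keeping exported files exchangeable
with other programs is left to the user, which is why this is a warning
and not an error.

Scene coordinates are kept real-valued (MOL files already carry reals) and
no pixel grid is imposed; the y axis is flipped only at render time.
Opacity is part of the model rather than the renderer because the morph
engine's cross-dissolve is defined in terms of it.

## MOL V2000 interchange and attachment

The reader accepts the fixed-column layout (coordinates in columns 1–30,
symbol in 32–34; bond block `a1 a2 type stereo`), maps bond types 1/2/3/4
to single/double/triple/aromatic and stereo flags 1/6 on single bonds to
wedge/hash, reads charges from both the legacy atom-block field and
`M  CHG` property lines (the property lines supersede, as modern readers
do), and takes isotopes from `M  ISO`. z coordinates are read and
discarded — this is a 2D model — and written back as 0.0000. The writer
emits `%10.4f` coordinates, so a roundtrip preserves positions to
±5×10⁻⁵.

Attachment of an imported structure follows the coupling-atom rule: the
guest couples through its atom with the smallest x-coordinate. That rule
alone does not fix where the guest lands or what bond joins it, so the
package adopts the simplest deterministic realisation: the coupling atom is
translated to one standard bond length — 1.5 scene units, a typical
drawn C–C distance at this scene scale — in +x of the target atom, and a
single bond is created. Ties on x are broken by smallest y, then lowest
id; a total order is required for the operation to be reproducible.
Insertion is the bond-free variant of the same id-renumbering merge.

## Mappings

Region-based morphing needs 2D transforms recovered from point
correspondences:

* **Three-point (affine).** The unique map `(x, y) → (ax + by + c,
  dx + ey + f)` through three non-collinear correspondences, recovered by
  solving `[x y 1] B = dst` (two 3×3 solves). Degeneracy is declared when
  the source triangle area falls below 10⁻¹²; at the package's working
  scene scale (coordinates of order 1–100) this rejects genuinely
  collinear input without tripping on round-off.
* **Four-point (projective).** Built by the unit-squares method: every
  square→quad homography is written in closed form from corner
  differences, and a general quad→quad map is the composition
  `square_to_quad(dst) ∘ square_to_quad(src)⁻¹`. When the target quad is a
  parallelogram the perspective terms vanish exactly (h₃₁ = h₃₂ = 0) and
  the construction reduces to the affine map — a property the tests
  assert. Corner convention: counter-clockwise from bottom-left. The
  recovered maps are cross-checked in the test suite against independent
  dense 6×6 / 8×8 direct-linear-transform solves at 10⁻⁹.

Region meshes tessellate a bounding box into an n×n grid of squares, or
split each square along its main diagonal into two triangles. Grid
splitting was chosen over Delaunay triangulation of the atom positions:
the warped content is annotation outlines and background, for which a
regular grid is equally expressive, fully deterministic and free of
degenerate-configuration corner cases; a Delaunay mode would be a natural
extension.

## The morph engine

A morph step between drawings A and B renders `n_frames ≥ 2` frames at
parameters `t = k/(n_frames − 1)`. Its parts:

* **Correspondence.** Atoms are grouped by element symbol and paired
  greedily by smallest Euclidean distance (global minimum first, ties by
  lowest source id then target id); the editor this design follows
  recognises atom and bond areas automatically, but publishes no matching
  algorithm, so this deterministic nearest-position rule was adopted, with
  a user-supplied correspondence accepted wherever an automatic one is
  computed. The greedy global-minimum rule makes the pairing symmetric
  under role swap for generic positions. Bonds pair when both endpoint
  atoms pair and the kinds agree (or any kind when exactly one candidate
  remains).
* **Interpolation.** Positions and opacity linear in t; colours linear per
  RGB channel with rounding at output. Element labels, charges and isotope
  fields cannot be meaningfully interpolated, so they switch from source
  to target at t = 0.5.
* **Cross-dissolve.** Unmatched source elements hold their position and
  fade with opacity 1−t; unmatched target elements fade in with opacity t
  (their ids are offset past the source ids to keep frames valid). The
  complementary opacities sum to 1 at every t. At t = 0 and t = 1 the
  vanished side is dropped entirely, so the first frame *is* the source
  and the last *is* the target, exactly, on positions and colours. An
  alternative `shrink` fade mode additionally contracts annotation
  outlines toward their centroid by 1−t, for the reading of a fading
  element "reducing in dimensions".
* **Easing.** `linear`, or `ping_pong` (t runs 0→1→0 inside one step) for
  oscillating motion.

Sequences chain steps whose junction drawings agree (atom ids, elements,
positions to 10⁻⁹ — anything looser would let animation discontinuities
pass silently); the duplicated junction frame is dropped, giving
`Σ n_frames − (steps − 1)` frames in total.

Vibration presets displace a bent triatomic's geometry exactly: symmetric
stretch lengthens both bonds by the amplitude (scene units) along their own
axes, asymmetric stretch lengthens one and shortens the other, scissoring
rotates each terminal outward by half the amplitude (radians) about the
central atom so the bond angle opens by exactly the amplitude at fixed
bond lengths. The preset returns a two-step sequence (equilibrium →
displaced → equilibrium) so the exported animation oscillates. Default
amplitudes (0.2 units stretch, 0.15 rad scissor) are chosen to be clearly
visible at bond length 1 without overlapping labels; they are user
parameters, not physical constants — the morphing is purely visual, not a
normal-mode analysis.

Whether bond areas should be warped as 2D regions rather than by endpoint
interpolation is left open by the source design; pointwise endpoint
interpolation is the default here because bonds follow their atoms by
construction, and the region modes apply to annotation outlines and
background, where there is no anchoring geometry.

## Rendering

SVG output is the high-fidelity path: deterministic string emission with
`%.3f` formatting and fixed attribute order (byte-identical output for
identical input is asserted over 200 random drawings), one text element
per displayed label, 1/2/3 parallel lines for bond multiplicity, filled
and ruled triangles for wedge/hash, radial-gradient shells and
linear-gradient annotation fills. The short formula form follows standard
skeletal convention — carbon labels and carbon-bound hydrogens are
suppressed, heteroatoms show an implicit-hydrogen count from standard
valences — since "long" and "short" are named but not defined by the
source design.

The rasteriser draws discs, thick lines, rings and polylines with alpha
blending and **no antialiasing**. That is deliberate: frames are
bit-reproducible and use few colours, which suits GIF palettes. It does
not draw text labels; raster frames feed animations where atom identity is
carried by colour, while SVG carries labels. Backgrounds are
brightness-adjusted (`clamp(round(c·factor), 0, 255)`) and composited
beneath the scene.

GIF export is implemented in the package because no installed R package
writes animated GIF. Frames share a global 256-entry palette (the exact
colour set when ≤ 256 colours are used, otherwise the 6×6×6 colour cube)
and are encoded as a fixed-9-bit LZW stream — literal pixel codes with a
clear code re-emitted every 250 literals, which every conforming decoder
accepts and which keeps the encoder fully vectorised. The cost is file
size (roughly a byte per pixel), irrelevant at animation scale. A
block-level GIF parser (`gif_info()`) verifies structure from R; the test
suite additionally decodes exported files with an independent Python
decoder and compares pixels.

## Fixtures: what they emulate and what they do not

The built-in fixtures are the study material: water (O–H 1.0 units,
H–O–H 104.5°), a cross-form methane, an n-carbon zigzag chain (used to
probe the capacity and interchange limits), the three SN2 stages
(hydroxide approaching bromomethane, a trigonal transition state with
hashed partial bonds, and the products — same atom multiset throughout, so
every atom pairs across the sequence), and stretched/scissored water
pairs. They are exact constructed geometries: they exercise parsing,
matching, interpolation and rendering completely, but they are small,
clean and perfectly matchable. Real imported molfiles can bring
near-degenerate coordinates, exotic elements and structures whose best
correspondence is not nearest-position; a green suite here does not
certify the greedy matcher as chemically optimal on such input, only as
deterministic and geometrically correct.

Randomised tests use drawings of up to 50 atoms (1000 for the leftmost-atom
scan), 1000 random mapping instances per family, and 500 roundtrip
drawings; these sizes make every property run comfortably in a default
test session while being far past the dimensionality where the linear
algebra could hide a systematic error.

## Known limitations

* Correspondence is greedy nearest-position within element groups — not a
  minimum-cost assignment; an optimal matcher (Hungarian algorithm) would
  be a drop-in refinement behind the same interface.
* Raster output has no text or antialiasing; wedge/hash render as thick
  lines in raster (full shapes in SVG).
* Backgrounds are PNG-only, matching the installed image I/O.
* V3000, multi-record SDF and R-group/S-group blocks are out of scope, as
  is any physically derived vibration frequency or force constant.
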