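# chemmorph

Headless 2D chemical structure drawing, MOL V2000 interchange and
morphing-based animation for R.

Chemistry teaching and presentation tools often need *dynamic* depictions —
a water molecule scissoring, an SN2 nucleophile sliding in as the leaving
group departs — but structure editors are interactive GUI programs.
`chemmorph` packages the computational core of such an editor as a library:
it models 2D chemical drawings, exchanges them as MDL MOL V2000 connection
tables, and generates animation frames by **morphing** one depiction into
another. It is aimed at chemistry educators and tool builders who want
reproducible, scriptable structure animations (SVG frames or animated GIFs)
without a GUI.

## The model in brief

A drawing is a scene of atoms (element, position, charge, isotope labels,
colour, opacity, optional electron-shell rings), bonds
(single/double/triple/wedge/hash/aromatic), annotation shapes (arrows,
brackets, orbital-style club/banana outlines) and an optional background
image; capacity is capped at 100000 atoms.

Morphing between drawings *A* and *B* proceeds in steps. An automatic
correspondence pairs atom and bond areas — atoms grouped by element and
matched greedily by nearest position, bonds matched when both endpoints
pair — so only chemically meaningful areas transform. Frame *k* of *n* uses
*t = k/(n−1)*; paired elements interpolate linearly in shape and colour,

> p(t) = (1−t)·p₀ + t·p₁,  c(t) = round((1−t)·c₀ + t·c₁),

while unmatched elements cross-dissolve (source opacity 1−t, target
opacity t). Region-based modes warp annotation outlines piecewise: the
bounding box is tessellated into triangles (each mapped by the unique
**affine transform** fixed by its three vertex correspondences) or squares
(each mapped by the **projective transform** built by the unit-squares
method, factoring every square→quad map through the unit square; a
parallelogram target degenerates to the affine case, h₃₁ = h₃₂ = 0).
Steps chain into sequences (shared junction frames are merged), and
triatomic vibration presets (symmetric/asymmetric stretch, scissoring)
build the displaced geometry for oscillating animations.

File exchange uses MOL V2000 connection tables with the classic
fixed-column layout. Imported structures can be *inserted* (no bond) or
*attached*: the guest couples through its **leftmost atom** (smallest
x-coordinate, ties broken by y then id), placed one standard bond length
(1.5 units) in +x of the target atom. Writing more than 999 atoms or bonds
— the V2000 interchange limit — emits a compatibility warning but still
writes the file.

## Worked example

```r
library(chemmorph)

water <- generate_fixture("water")
print(water)
#> <chem_drawing: 3 atoms, 2 bonds, 0 annotations>
#>   formula: H2O

leftmost_atom(water)   # the coupling atom used for attachment
#> [1] 1

vib <- vibration_preset(water, "scissoring", amplitude = 0.15, n_frames = 9)
frames <- run_sequence(vib)
length(frames)
#> [1] 17

rasters <- render_frames(frames, render_style(width = 240, height = 180, scale = 60))
export_gif(rasters, delay_ms = 60, path = "water_scissor.gif")
str(gif_info("water_scissor.gif"))
#> List of 5
#>  $ width    : int 240
#>  $ height   : int 180
#>  $ n_frames : int 17
#>  $ delays_ms: int [1:17] 60 60 60 60 60 60 60 60 60 60 ...
#>  $ loop     : logi TRUE
```

The 17 frames are the two chained 9-frame steps (equilibrium → opened by
0.15 rad → equilibrium) with the duplicated junction frame merged:
9 + 9 − 1. `gif_info()` confirms the exported GIF decodes to exactly those
frames at the requested 60 ms delay. The same pipeline runs from the shell:

```sh
chemmorph vibrate water.mol --preset scissoring --amplitude 0.15 \
    --frames 9 --out frames/ --gif water_scissor.gif
```

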