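---
title: "voxelflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxelflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelflow)
```

This vignette documents the models and algorithms behind voxelflow, the
conventions and numerical choices the implementation commits to, and what
the synthetic phantoms do and do not establish about real data.

## The data model

A `Volume` is a dense raster over 1–3 spatial axes with 1–4 channels and
one of three element formats: `u8`, `u16`, `f32`. Two conventions run
through everything:

* **Normalized intensity space.** Integer formats represent intensities in
  [0, 1]: a `u8` value $x$ reads as $x/255$, `u16` as $x/65535$. All
  filters operate in this space; conversions back to integer formats round
  half up and clamp. Consequently
  `convertType(convertType(v, "f32"), "u8")` is the identity on `u8`
  input — a property the tests assert.
* **Clamp-to-edge addressing.** Out-of-range coordinates clamp to the
  nearest edge element, everywhere: point sampling, every neighbourhood
  filter, trilinear interpolation in the renderer, and halo filling during
  tiling. A single border policy is what makes the tiled-equals-untiled
  guarantee exact (see below).

Indexing is 1-based with x fastest in memory, matching R's array
convention; the channel plane is the trailing axis. `f32` volumes are held
in single precision (values are snapped to the nearest 32-bit float on
construction) so that the file format's 4-byte storage round-trips
bit-exactly. The snapping error is at most one part in $2^{24}$, which is
why several tests compare decimal literals at a tolerance of `1e-6`
rather than exactly.

Swizzle masks (`"bgr"`, `"rrr1"`, …) are a read-time argument to
`sampleVoxel`, not a stored property of the volume; the alphabet is
`r g b a 0 1`, with `1` denoting full scale. A stored swizzle would make
two bitwise-identical volumes sample differently, which complicates
caching for no expressive gain.

## The dataflow graph

Graphs are validated at mutation time: `connect` refuses datatype
mismatches (the datatype is the "colour" of the connector), occupied
in-ports, and any edge that would close a cycle — the cycle check is a
reachability search from the destination back to the source, and the error
message names the offending path. `setParam` marks the node and its
downstream reachable closure dirty and returns exactly that set.

`executeGraph` evaluates dirty nodes once each in a deterministic
topological order (Kahn's algorithm; ties broken by node insertion order,
so reports are reproducible). Two containment rules were genuinely open
design questions:

* a node whose required input is unconnected fails *individually*; the
  run continues for unrelated subgraphs;
* a node-level error skips only the failed node's downstream cone, which
  stays dirty for the next run. Siblings are unaffected.

Per-node wall-clock timing is recorded in the execution report and shown
by `show()`; it is informational and never part of a test assertion, since
it is machine-dependent.

## The kernel library

**Distance transform.** The separable exact algorithm: a preparation pass
writes squared distance 0 where the normalized value is $\ge t$ (the
*solidity threshold*, default 0.5) and a sentinel elsewhere, then one 1D
pass per axis computes the lower envelope of the parabolas
$q \mapsto (x-q)^2 + f(q)$, then a square root — four passes. The result
is the exact Euclidean distance, so the implementation is checked against
an $O(n^2)$ brute-force nearest-solid scan (100 random 8³ volumes, max
abs error $\le 10^{-5}$) and for axis-order independence. Numerical
choices: the "infinity" is a finite sentinel, $\sum_i d_i^2 + 1$, strictly
above any achievable squared distance, so an all-empty volume yields a
well-defined field (sentinel distance everywhere) instead of infinities.
The $\ge t$ boundary convention is shared with `thresholdVolume` so the
two nodes agree about what "solid" means.

**Median and region filters.** The median is the exact 14th order
statistic of the 27 clamped neighbours. A GPU implementation would use a
sorting network for speed; semantically that is just a sort, so the
reference here selects via `nth_element` and is tested against full
sorts. Min/max/average region filters reduce the clamped $(2r+1)^3$ box.
The neighbourhood is a box, not a ball — with a box, separable reasoning
about halo widths stays exact.

**Convolution.** Separable correlation with one odd-length 1D kernel per
axis. The Gaussian preset samples $e^{-x^2/2\sigma^2}$ at integer offsets
to radius $\lceil 3\sigma\rceil$ (beyond which the tail mass is below
0.3%) and renormalizes to sum 1, so constant volumes are exactly
preserved including at borders.

**Derivatives and curvature.** Gradients are central differences with unit
spacing (one-sided halves at the borders, a consequence of clamping).
`surfaceNormals` returns $-\nabla v/|\nabla v|$ — pointing out of bright
material, the direction a renderer wants — and the zero vector where the
gradient vanishes. Curvature is *mean* curvature,
$H = \tfrac12\,\nabla\!\cdot(\nabla v/|\nabla v|)$, computed by central
differences on the normalized gradient field and defined as 0 where
$|\nabla v| < 10^{-6}$ (normalized units per voxel). The choice among
mean/Gaussian/principal curvature was open; mean curvature is what
diverging-colour curvature renderings conventionally show, and it has a
crisp validation: on a radial distance field the level sets are spheres
and $H = 1/r$, which the tests confirm to 2% at $r = 10$ voxels (the
residual is the central-difference discretization error).

**Element-wise arithmetic** follows IEEE 754: division by zero produces
infinities, $0/0$ propagates NaN, nothing traps. Filters that can
meaningfully preserve the element format do (median); filters whose
output is inherently continuous return `f32`.

## Tiling

`planTiles` chooses core extents greedily, axis by axis with x first: each
axis takes the largest core such that core-plus-halo times the minimal
footprint of the remaining axes stays within the voxel budget. Cores
partition the volume exactly in raster order; the plan is a pure function
of its arguments. `runTiled` extracts core+halo (clipped at the volume
border, where the kernel's own clamping reproduces the untiled behaviour),
runs the kernel, and pastes back only the core.

The correctness contract is the *declared radius*: tiled equals untiled
exactly when the halo covers the kernel's true neighbourhood radius, and
`runTiled` refuses a smaller halo. Non-local kinds — the distance
transform (whole-line passes) and intensity rescaling (global min/max) —
declare no radius and are rejected; running them tiled could silently
produce wrong borders, and an error is the only honest interface. The
equivalence is enforced in the test suite across every registered kind
with a declared radius on randomized dims and budgets.

## The renderer

The camera is right-handed with perspective projection and rays through
pixel centres; volumes occupy $[0,\text{dims}]$ in voxel units and are
sampled trilinearly over voxel centres with clamp-to-edge. Default step:
0.5 voxels — small enough that halving it changes a smooth translucent
rendering by a few percent (a convergence property in the tests), large
enough to keep CPU renders interactive at test sizes.

Translucent mode composites front-to-back,
$$C \mathrel{+}= (1-A)\,\alpha_i c_i,\qquad A \mathrel{+}= (1-A)\,\alpha_i,$$
with early exit when $A > 0.999$; this recurrence is algebraically equal
to the back-to-front closed form
$\sum_i c_i \alpha_i \prod_{j<i}(1-\alpha_j)$, and the test suite checks
the two against each other on a thousand random sample sequences. The
opacity transfer is deliberately the simplest consistent choice,
$\alpha = \mathrm{clamp}(v \cdot \text{opacityScale} \cdot \text{step}, 0, 1)$,
documented as replaceable; published screenshots of comparable render
modes do not pin down their transfer functions, so image-level checks
here are property-based (silhouette presence, background exactness,
step-halving stability), never pixel-exact.

Solid modes stop at the first sample at or above the threshold and shade
with a headlight Lambert term from the interpolated gradient (plus a 0.1
ambient floor so silhouettes facing away from the light remain visible);
`solid_curvature` colours the hit by mean curvature on a blue–white–red
diverging ramp scaled by the volume's maximum |H|; `edge_step` renders
binary occupancy. Anaglyph stereo renders twice with the eye displaced
$\pm$ half the eye separation along the camera's right axis and encodes
the left eye's luminance in red, the right eye's in green+blue — the
common convention for red/cyan glasses.

## Live-coded kernels

Snippets are a restricted arithmetic expression dialect over the element
value `v` (or pixel coordinates `x`, `y`, `width`, `height` for 2D
generators), with `+ - * / ^ pow min max abs clamp exp log sqrt`. This
replaces a GPU shading language with a host-evaluable equivalent of
identical element-wise semantics: `min`/`max` are vectorized per element
(R's `pmin`/`pmax`), and evaluation happens on whole arrays at once, so a
snippet costs one vectorized expression, not a per-voxel interpreter loop.

Parameters are declared as `param name = default` header lines; free
variables that appear undeclared are *induced* as parameters with default
0, mirroring automatic interface induction in interactive node editors.
Compilation is pure: a parse error or a disallowed construct (any function
outside the whitelist, indexing, function definitions, namespace access —
hence also all I/O) raises a diagnostic and produces no partial kernel.
The sandbox is a whitelist over the parsed AST, evaluated in an
environment whose parent is empty, so a snippet cannot reach any R
binding that was not explicitly granted.

## File format and plugins

The native `.vxvf` container is little-endian with a fixed 12-byte
prefix, per-axis extents, payload lengths, and a ZStandard-compressed
payload; the full byte layout is in `?writeVolume`. Version compatibility
is two-way by construction: the header carries an "extra bytes" count
that version-1 readers skip, so newer writers may append fields, and
writers never emit fields old readers require. Readers validate magic,
version, dtype code, axis/channel plausibility, header-vs-payload length
consistency, and payload truncation, each with a distinct error.

Format auto-detection probes content before extensions — a native file
with a lying `.png` extension is still read natively — and plugins are
consulted in registration order. Two bundled plugins mirror the usual
pair: a medical-imaging plugin delegating to established NIfTI/TIFF
readers, and a minimal PNG plugin intended as the template for user
plugins. Writing established formats from scratch was a non-goal;
delegation is the point of the plugin interface.

## Synthetic phantoms: what they do and do not show

Real MRI data cannot be redistributed, so the test fixtures are generated:

* `makeSpherePhantom` — a two-level ball plus optional clamped Gaussian
  noise; its discrete ball volume has a counting oracle.
* `makeHeadPhantom` — three nested ellipsoidal tissue classes over a dark
  background: skull/skin shell at nominal intensity 0.95, a thin CSF
  layer at 0.35, a textured brain core at 0.65 ± 0.05 (a deterministic
  low-frequency modulation), background 0.05, plus optional noise. It
  returns the ground-truth label volume (0 background, 1 CSF, 2 brain,
  3 skull/skin, ordered by increasing intensity).

The class intensities were fixed once so that the bands stay disjoint
under the brain texture and retain ≥ 0.1 normalized margin to the
segmentation thresholds after rescaling; the ellipsoid radii (outer
semi-axes at 0.42 of each extent; shell boundaries at relative radii 0.88
and 0.80) give shell thicknesses of a few voxels at the default 64³, in
rough proportion to a head scan. Noise is i.i.d. Gaussian, clamped to
[0, 1].

These phantoms establish *mechanical* correctness: that the shipped
segmentation pipeline (band extraction → Gaussian smoothing → threshold →
mask → per-voxel labelling snippet) recovers a perfectly separable
labelling exactly, and that agreement degrades monotonically as noise
grows. They do not show robustness to what real scans add — partial
volume effects at tissue boundaries, bias fields, anisotropic voxels,
spatially correlated noise, anatomical variability — so a pass here is a
statement about the pipeline machinery, not about clinical segmentation
accuracy. On the noise-free phantom the labelling is driven by
thresholding the raw normalized intensities into the disjoint bands, so
100% agreement is the designed outcome; the smoothed mask determines the
skull-stripped volume, where sub-voxel boundary shifts from smoothing are
acceptable.

## Problem sizes and budgets

Test and acceptance sizes were chosen to keep the whole suite fast while
leaving every algorithmic branch exercised: brute-force oracles run at 8³
(the $O(n^2)$ scan is the bottleneck, not the transform), filter oracles
at 6–14³, tiling equivalence on ~22 randomized dim/budget combinations,
renders at ≤ 96² pixels, and the segmentation pipeline at the phantom
default of 64³. The separable transform itself is $O(n)$ per pass and
handles scan-sized volumes (e.g. 256×256×176) untiled in core memory;
nothing in the implementation is specific to the small test sizes.

## Known limitations

* Voxels are isotropic and unitless; there is no physical-spacing
  metadata, so distances are in voxel units (no anisotropic distance
  transform).
* No 4D/time-series volumes; channels are the only extra axis.
* The renderer is a CPU reference implementation: correct and testable,
  not real-time; lighting is a single headlight Lambert term.
* Tiling is in-memory decomposition only — it bounds per-kernel working
  set, not total memory (no out-of-core processing).
* The snippet dialect is scalar expressions over one volume plus scalar
  parameters; multi-input snippets and control flow are out of scope —
  use graph nodes for composition instead.
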