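---
title: "Pixel-wise segmentation with a dual-output CNN and distance-map watershed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-wise segmentation with a dual-output CNN and distance-map watershed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbseg)
```

## The problem and the model

Many experimental images — packed granular particles, foam bubbles, thin
structural lattices — contain repeated regions that are easy to identify by
eye but hard to segment algorithmically, because lighting, focus, texture
and viewing angle vary across the field and because neighboring regions
touch. `bbseg` treats this as a *per-pixel* learning problem. For every
pixel it predicts two quantities with a single small convolutional network:

* a **class probability** $p \in [0, 1]$ that the pixel lies inside any
  region ("innie" vs. "outie"), trained with binary cross-entropy;
* a **capped distance to the nearest region edge** $d \in [0, d_{\max}]$
  (in pixels), trained with mean absolute error.

The two losses are summed with equal weight. MAE is used for the distance
head because the *small* distances — the ones that delineate edges and the
valleys between touching regions — are exactly what the downstream assembly
consumes; a squared loss would let the easy capped plateau dominate.

The distance target for a pixel inside region $k$ is the Euclidean
(center-to-center) distance to the nearest pixel whose label *differs* from
$k$ — background **or another region** — capped at $d_{\max}$ (default 10).
The "different ID, not just background" definition is essential: where two
regions meet, both sides of the contact carry $d \le 1$, creating the
valley that the watershed later splits. Distances are regressed in raw
pixel units; the cap means that in the interior of any region wider than
$2 d_{\max}$ the target is constant, so the network only needs precision
near edges.

A segmentation of a new image is assembled in three steps: threshold the
probability map at `prob_threshold` (ties pass, default 0.5), seed markers
from the connected plateau of the predicted distance map
($d \ge$ `marker_level`), and flood the foreground on the inverted distance
map so that every foreground pixel joins exactly one marker's basin.

## Network input: multi-scale patch stacks

The network never sees whole images. Its input for one pixel is a stack of
$S$ concentric square windows at integer scales $s_1 < s_2 < \dots$
(default 1, 3, 9, 27), each of side `patch_side * s` pixels and each
reduced to `patch_side` × `patch_side` (default 25) by $s \times s$ block
averaging. The stack gives the network simultaneous access
to fine edge detail and broad context at a fixed, small input size, and
lets the same architecture serve images of any size. Windows that extend
beyond the image are filled by edge replication — replication avoids
inventing dark borders that the network would happily learn as a spurious
edge feature. Block-mean down-sampling was chosen over decimation because
it antialiases and is exact for constant regions.

Before patch extraction every image is normalized to zero mean and unit
variance (a constant image maps to zeros), which makes training robust to
brightness differences between images. RGB images are converted to Rec.
601 luma by default (`rgb_mode=luma`); `rgb_mode=keep3` keeps the three
channels and triples the stack depth instead. The choice is recorded in
the parameter file.

## Architecture

The network has fifteen counted layers: three blocks of
[3×3 conv, 3×3 conv, 2×2 max-pool], four dense layers, and two single-unit
heads (sigmoid for class, linear for distance). Blocks 2 and 3 add a skip
connection from their input, projected by a 1×1 convolution plus pooling
where shapes differ — the standard residual-style option. With 25-pixel
patches the spatial plan is

```
25 --(same, same, pool)--> 12 --(same, same, pool)--> 6
   --(valid, same, pool)--> 2
```

so the tensor entering the flatten is 2×2×96 with the default widths
(24, 48, 96); the dense widths taper 384 → 96 → 48 → 16. The published
constraint fixes the layer count, the 2×2×96 bottleneck, four dense
layers and the two heads; the per-layer padding needed to reach 2×2 from
25 is underdetermined, so the plan above is a named constant of this
package and `shape_plan()` asserts it at build time (any plan reaching the
same bottleneck would conform). Hidden activations are ReLU. The forward
and backward passes are exact reverse-mode implementations (im2col + GEMM)
compiled with RcppArmadillo; gradients are verified against finite
differences in the test suite.

## Training-set construction and the budget algebra

Eligible pixels are those inside the (optional) area-of-interest mask.
From the $M$ eligible pixels a fraction $F \in (0,1]$ is drawn
(`fraction`), and the draw is presented to the network $E$ times
(`epochs`), giving $T = E \cdot \mathrm{round}(F M)$ sample presentations;
$EF = T/M$ is the collapse variable that governs accuracy on repeated-
structure datasets. The draw is made once and reused across epochs, so $T$
differs from $\mathrm{round}(E F M)$ by at most $E/2$ — the budget
identity is asserted exactly in the tests.

With class balancing on (default), innies and outies are drawn in equal
numbers (within one), sampling with replacement from the minority class
when it is exhausted; oversampling the minority rather than shrinking the
draw keeps $T$ under the user's control. With balancing off the native
class ratio is kept, and $F = 1$ visits every eligible pixel exactly once.

Each presentation optionally applies one of the eight dihedral symmetries
of the square (uniformly drawn per sample per epoch) to the patch stack.
Both labels are rotation/flip invariant, so augmentation acts on extracted
stacks — equivalent to transforming whole images but far cheaper.

Optimization is Adam at learning rate 0.001 with batch size
`batch_size` (default 64). The published workflow's only training knob is
the budget $T$; there is no early stopping and no schedule here either. A
batch of 64 was chosen because at desk-scale budgets
($T \sim 2.6\times10^4$ presentations for the bundled end-to-end check) a
much larger batch would leave Adam only ~100 updates — too few to train
from scratch — while 64 gives ~400 updates at identical cost per epoch.
"Training step" in all reporting means one sample presentation, so the
$T = EFM$ algebra holds regardless of batch size.

## Assembly choices

* **Markers.** `marker_level` defaults to $d_{\max} - 2$: the plateau of
  the distance map, well above the regression noise concentrated near
  edges. Every 8-connected component of
  $\{d \ge \texttt{marker\_level}\}$ inside the foreground seeds one
  basin. A region can only be found if its predicted distance reaches the
  marker level, so for scenes whose smallest regions have radii below
  $d_{\max} - 2$ the level should be lowered (it is an ordinary
  parameter).
* **Flooding.** Highest predicted distance floods first; ties go to the
  basin queued earlier (markers are queued in label order), which makes
  the assignment deterministic. Foreground connectivity is 8-connected.
* **Cleanup.** Basins smaller than `min_region_px` (default 10) are
  deleted — the network's probability map occasionally passes speckle at
  the threshold. Surviving labels are renumbered 1..K in raster-scan order
  of their first pixel, so output label maps are reproducible rasters.

## Evaluation

`seg_score()` implements the SEG measure: each true region is matched to
the predicted region of largest intersection (ties by Jaccard, then lower
ID) and scores their Jaccard index, zeroed when the intersection covers
less than half the true region; SEG is the mean over true regions, pooled
across images for a dataset. The half-overlap rule here uses *at least*
half; the strictly-greater convention used by the cell-tracking community
is available as `seg_strict_half`. Pooling over regions (rather than
averaging per-image SEGs) weights every region equally, which matches a
"score for a given dataset" reading; per-image scores are reported
alongside.

## What the synthetic fixtures emulate — and what they do not

`make_disks()` generates packings of textured disks with contacts allowed:
per-disk four-lobed angular patterns plus a radial ramp (a stand-in for
stress-fringe-like texture that forces the network to use shape rather
than brightness), an illumination gradient, Gaussian blur and noise.
Labels stay clean; contested pixels in slight overlaps go to the disk
whose rim is farthest, so touching disks meet along a line with distinct
IDs — exactly the case the watershed must solve. `make_lattice()` builds
thin bright struts with random deletions for the structure-finding use
case. The generators are deterministic given a seed.

These fixtures do **not** model real photoelastic fringes, defocus that
varies across the field, perspective tilt, or annotation noise in human
masks. A passing end-to-end check on fixtures therefore demonstrates that
the learning, assembly and scoring machinery is correct and that the
method separates touching textured regions — not that any particular real
dataset will reach a given SEG.

## Problem sizes used by the bundled checks

The end-to-end check trains on one 256×256 scene of ~30 touching disks at
scales {1, 3, 9}, $F = 0.2$, $E = 2$ (so $T = 26{,}214$ presentations from
$M = 65{,}536$ eligible pixels) and requires pooled SEG ≥ 0.8 on a
held-out scene from the same distribution; the determinism check repeats a
smaller 128×128 run twice and requires bit-identical output rasters. These
sizes exercise every stage at laptop scale; larger images and more epochs
only increase $T$ and wall time, not code paths.

## Numerical and degenerate-input conventions

* Distances are exact Euclidean (per-region Felzenszwalb transform); a
  region with no differently-labeled pixel anywhere gets the cap
  everywhere.
* A constant image normalizes to all zeros rather than NaN.
* Probability clamping to $[10^{-7}, 1-10^{-7}]$ is applied inside the
  BCE only; reported probabilities are the raw sigmoid outputs.
* The distance head is unconstrained during training and clipped to
  $[0, d_{\max}]$ at inference.
* Label rasters are written as 16-bit TIFF (exact up to 65,535 regions);
  probability and distance maps as true 32-bit IEEE-float TIFF, written by
  a minimal single-strip emitter because the available TIFF writer only
  stores quantized integers at 32 bits.

## Known limitations

Per-pixel patch inference costs one forward pass per pixel; a 256×256
image takes a few minutes on one CPU core. The architecture requires
`patch_side` values whose pooling plan reaches a consistent bottleneck
(25 works; `network_spec()` errors otherwise, naming the offending block).
Regions whose interiors never reach `marker_level` in the predicted
distance map are not seeded and vanish from the segmentation — lower the
level for scenes of small regions. No tracking across frames, no
morphological post-smoothing, and no photometric augmentation are
provided.
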