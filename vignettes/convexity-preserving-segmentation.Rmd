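---
title: "Convexity-preserving level-set segmentation of tumor organoids: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convexity-preserving level-set segmentation of tumor organoids: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, the numerical choices, what
the synthetic phantoms emulate, and the design decisions taken where the
design was genuinely open.

## 1. Problem and model

Bright-field images of cultured tumor organoids have a characteristic
structure: a bright, intensity-homogeneous background (culture medium), and
organoids that appear as roughly round or oval objects with a dark boundary
rim and a strongly inhomogeneous interior. The practical task is to
delineate *one chosen organoid*, including where it overlaps a neighbour —
in the overlap region the shared boundary dissolves optically, so no local
evidence marks the target's edge there.

The contour is a zero level set under the **inside-negative** convention
(`phi < 0` inside). We evolve

$$\phi_t = s(\kappa)\,[\lambda_1 (I-c_1)^2 - \lambda_2 (I-c_2)^2]\,
\delta_\epsilon(\phi) + \alpha\,\kappa\,\delta_\epsilon(\phi) +
\mu\,g\,\delta_\epsilon(\phi) + \beta\,(1-s(\kappa))\,\kappa\,\delta_\epsilon(\phi)$$

with $\kappa = \mathrm{div}(\nabla\phi/|\nabla\phi|)$,
$c_1, c_2$ the smoothed-indicator mean intensities inside and outside the
contour, $g$ the edge indicator, and $s(\kappa)$ the binary
curvature-sign indicator (CSI), 1 where $\kappa \ge 0$. Under
inside-negative, a convex inside region has $\kappa > 0$ along its
boundary, so the CSI flags locally convex contour segments. The division
of labour:

* **data term** (gated by $s$): pulls the contour toward the intensity
  boundary while the contour is convex;
* **length term**: curve-shortening regularization, always on;
* **area (balloon) term**: $\mu > 0$ drives the contour inward, modulated
  by $g$ so it stalls at strong edges;
* **curvature term** (gated by $1-s$): wherever the contour is dragged
  concave — by an overlapping neighbour, an impurity, or local leakage —
  the data term switches off and $\beta\,\kappa\,\delta_\epsilon$ (with
  $\kappa < 0$ there) grows the region locally, repairing the concavity.

The smoothed Heaviside/Dirac pair is the compactly supported cosine form
on a band of half-width $\epsilon$; all forces act only within that band.

### Why inside-negative

The level-set literature uses both orientations, and the two printed
conventions in this model's source material disagree with each other: the
set definition is inside-positive while the dynamics (a positive balloon
weight moving the contour inward, convexity at $\kappa \ge 0$ for a round
object) require inside-negative. We adopt inside-negative throughout —
the printed evolution equation is then *exactly* the gradient-descent
direction of the orientation-free two-phase energy, with no sign surgery.

## 2. Parameters

| parameter | default | units | role |
|---|---|---|---|
| `lambda1` | 3.5 | — | inside data weight; 1–5 useful. Larger pulls harder through overlapping interiors; too large leaks weak boundaries |
| `lambda2` | 1 | — | outside data weight (fixed) |
| `alpha` | 1 | — | length term; insensitive |
| `mu` | 10 | — | balloon; positive = inward |
| `beta` | 1 | — | concavity-repair strength; raise for very unclear boundaries |
| `eps` | 1.5 | px | Dirac/Heaviside band half-width (common practice at unit spacing) |
| `sigma` | 1.5 | px | Gaussian for the edge indicator |
| `edge_scale` | 255 | — | gradient scale inside `g` (below) |
| `csi_sigma` | 1 | px | smoothing of `kappa` before taking its sign |
| `dt` | auto | — | from the CFL bound (below) |
| `max_iterations` | 1500 | — | budget; convergence usually earlier |
| `reinit_every` | 5 | iter | periodic redistancing (below) |

### The `edge_scale` decision

Intensities are normalized to $[0,1]$ on load so that `lambda1` guidance
transfers across bit depths. But the published working regime
($\mu = 10$, $\lambda_1 \in [1,5]$) was developed on native 0–255
intensities, where the $g$-gradient at a real edge is tens of units and
$g$ drops to $10^{-3}$. On $[0,1]$ intensities the same gradient is 255×
smaller, $g \approx 1$ even at strong edges, and the $\mu = 10$ balloon
(an order of magnitude above the $O(0.1)$ data forces) crushes every
boundary. We therefore compute the gradient inside $g$ on the native
8-bit scale: $g = 1/(1 + (255\,|\nabla(G_\sigma * I)|)^2)$, keeping the
data terms on the $[0,1]$ scale. This reproduces the intended force
balance: in flat background $g \approx 1$ and the balloon sweeps the
contour inward quickly; at edges and inside grainy organoid interiors
$g \approx 0$ and the $O(0.1)$ data/curvature forces take over. Setting
`edge_scale = 1` recovers the plain printed formula.

### Time step and stability

`suggest_time_step()` evaluates the right-hand side once on the initial
field and returns
$\Delta t = \min(0.5/\max|R|,\; 0.25/\alpha)$ — the advective CFL bound
(≤ 0.5 px of level motion per step) and the parabolic bound for the
length term at unit spacing. With the defaults on phantom scenes
$\Delta t \approx 0.07$.

### Redistancing

The cosine Dirac is *compactly supported*: pixels with $|\phi| > \epsilon$
feel no force, so as band values saturate the profile steepens into a
cliff and the zero level set stalls after roughly $\epsilon$ px of travel.
CPLSE avoids this through its double-well distance regularizer; the
proposed and Chan-Vese evolutions have no such term, so they redistance
`phi` every 5 iterations with 5 Godunov-upwind sweeps of the
sign-preserving redistancing equation
$\phi_\tau = \mathrm{sign}(\phi)(1 - |\nabla\phi|)$. This is a deviation
from an initially contemplated "no reinitialization" design: without it
the contour cannot travel the tens of pixels the initialization requires,
a fact easily reproduced on a noiseless two-phase disk.

### Other numerical choices

* Central differences with replicated-edge (Neumann) boundaries
  throughout; $|\nabla\phi|$ floored at $10^{-8}$ in the curvature.
* The CSI is evaluated on `kappa` smoothed with a 1 px Gaussian
  (`csi_sigma`); raw discrete curvature flips sign on single-pixel noise,
  which would chatter the gate. The returned `kappa` itself is raw.
* Stopping: budget, or mean absolute per-iteration change of `phi` within
  the band below `tolerance` ($10^{-4}$), checked every 20 iterations; a
  field of uniform sign terminates with reason `contour_vanished` (a
  result, not an error).
* Region means with total smoothed weight below $10^{-12}$ on either side
  raise a degenerate-region error.
* `drlse_dp(1)` uses the upper branch so the value is exactly 0;
  `drlse_dp(0)` returns the limit 1.

## 3. Automatic initialization

One click at the organoid's inner center. The whole image is segmented
with Chan-Vese (length weight 0.05, 300 iterations) started from a tiled
sine pattern of period 40 px so every object is near an initial contour.
Because organoid interiors are inhomogeneous, the image is pre-blurred
(σ = 3 px) for this step only and remaining interior holes are filled;
the foreground is the minority-area phase (organoids occupy a minority of
a dish image). A featureless image (no contrast between the phases) is
rejected with an initialization error. The Canny operator then outlines
the foreground mask; the nearest outline pixels on the seed's row and
column (both directions searched, ties toward the smaller coordinate) set
the half-sizes, both expanded by 20 %, and the rectangle — clipped to the
image with a 1 px margin, so border-adjacent organoids stay segmentable —
becomes a signed-distance initial field. The expansion exists to make the
rectangle *strictly contain* the target, since the model's contour moves
inward only.

## 4. The synthetic phantom world

No public organoid dataset accompanies the source study, so evaluation
uses a seeded generator whose scenes emulate the qualitative properties
the algorithm exploits, not photorealism:

* background 0.85 with Gaussian noise sd 0.01 (homogeneous medium);
* organoids as disks/ellipses (radii ~40–55 px at 256²) with a dark
  boundary ring (level 0.25, width 2.5 px) and an interior of mean 0.55
  carrying correlated texture of sd 0.2 at correlation length 1 px —
  "extremely inhomogeneous" at the cell scale, which is what keeps
  $g \approx 0$ inside organoids and the balloon force inert there;
* overlapping pairs at center distance ≈ 0.85 of the radius sum, with the
  shared boundary dissolved inside the overlap;
* dish impurities (dark blobs, r 2–4 px, level 0.6) in the background;
* out-of-focus distractors (disks blurred at σ = 6 px, contrast −0.08 to
  −0.1); global optics blur σ = 0.8 px; pixel noise last; clipped to [0,1].

Two early generator guesses had to be corrected against these stated
properties: smoother texture (correlation 1.5 px, sd 0.17) left smooth
interior patches with $g$ up to 0.5 through which the balloon leaks
regardless of the data weight, and a "weak" ring at level 0.5 on a 0.55
interior was, after optics blur, not a boundary at all. The corrected
world (grainier interiors; weak ring = 0.4, still a visible dark rim) is
what the difficulty archetypes describe.

The default suite has ten fixed-seed scenes, two per archetype: overlap,
out-of-focus shadow, impurities, adjacent boundaries, weak boundary. Each
documents its target organoid, seed point, and data weight — 3.5 in
general, 2.5 where the distractor is intensity-close to the background,
3.0 where the main influence is a neighbouring boundary — mirroring how
the weight is tuned per image in practice.

**What a green phantom test does and does not establish.** It establishes
that the implementation realizes the intended mechanics: the balloon
sweeps homogeneous background, the data term pins intensity boundaries,
the CSI gate cuts through dissolved overlaps and yields convex masks, the
initialization contains the target. It does not establish performance on
real bright-field images: phantoms have no uneven illumination, no
optical halo around rims, ideal ellipse geometry, and stationary texture.
Real-data Dice can only be measured on real annotated data.

## 5. Baselines

`cv_evolve` is the two-phase Chan-Vese gradient flow (length weight 0.02
on the $[0,1]$ scale, `lambda1 = lambda2 = 1`), with the same band Dirac
and redistancing. `cplse_evolve` is the distance-regularized
convexity-preserving evolution: double-well regularizer, edge-weighted
length and area forces gated by the CSI, and the concavity-repair term.
Its front speed is limited by how fast the regularizer rebuilds the
distance profile ahead of the front — proportional to
$\mu_{reg}\,\Delta t$, which stability caps at 1/4 — so we use the
canonical far-initialization regime $\Delta t = 5$, $\mu_{reg} = 0.04$,
$\lambda = 5$, $\alpha = 3$. With pinned $s \equiv 1$ the implementation
reduces exactly to the three-term DRLSE update (tested to $10^{-12}$),
and with $s$ pinned the proposed model reduces exactly to Chan-Vese plus
a $g$-weighted area force (tested to $10^{-10}$) — each model's gated
structure is verified against its ungated ancestor.

## 6. Known limitations

* Inward-only evolution: the initial rectangle must contain the target;
  a click near the organoid edge can produce a rectangle that clips it.
* The CSI gate assumes a convex target; lobed or budding organoids will
  be convexified.
* Full-grid explicit updates; no narrow band or semi-implicit solver.
  Adequate at dish-image scale (≈ 5 ms per iteration at 256²).
* The pre-segmentation inherits Chan-Vese's two-phase assumption; scenes
  whose background is darker than the organoids would need the foreground
  convention flipped.
* 2-D only; anisotropic pixel spacing is not supported.
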