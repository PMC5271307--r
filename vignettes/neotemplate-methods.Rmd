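---
title: "Building a bimodal MR-CT neonatal head template: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a bimodal MR-CT neonatal head template: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neotemplate)
```

## The problem

MR templates of the neonatal head describe soft tissue well but carry almost
no signal from bone, so they cannot represent the cranial plates or the
fontanels and sutures — the membranous gaps between the unfused bones that
matter for skull modeling and for EEG/NIRS source localization in infants.
CT is the reference modality for bone, but clinical neonatal CT comes with
its own obstacles: intensities in Hounsfield units spanning -1000 (air) to
+1000 (bone) and beyond, reconstruction artifacts (a rim of about -3000 HU
around the air), pillows, pacifiers and feeding tubes near the head, and
poor soft-tissue contrast. `neotemplate` implements a pipeline that takes a
set of neonatal head CT scans and an MR reference template and produces an
unbiased CT template fully aligned with the MR one — a bimodal MR-CT
template in a single stereotaxic space.

Because clinical images cannot ship with a package, every stage is exercised
on synthetic head phantoms with known ground truth. The phantom generator is
first-class, tested code, and the validation battery
(`tests/testthat/test-acceptance.R`) runs the whole pipeline on phantom
populations.

## Pipeline overview

1. **Preprocessing** — head-mask extraction (Otsu threshold + morphology),
   assignment of exactly -1000 HU to everything outside the head (which also
   removes the sub-air rim), an invertible three-segment intensity
   transform, and optional isotropic re-slicing (default 0.47 mm).
2. **Intracranial extraction** — a coupled pair of level-set surfaces
   locates the inner surface of the cranial bones and closes smoothly across
   fontanel/suture gaps, yielding the intracranial mask.
3. **Two-step registration** — the intracranial CT is registered to an MR
   intracranial template (12-parameter affine, then symmetric diffeomorphic,
   both under mutual information), the resulting deformation is applied to
   the whole preprocessed CT (CT'), and CT' is affinely registered to the
   full MR template under MI (CT'').
4. **Groupwise template building** — all CT'' images are registered to an
   evolving template initialized with the MR reference; each iteration
   updates the template appearance (voxelwise mean of warped subjects) and
   shape (a small diffeomorphism toward the population average). Two
   iterations suffice once inputs are pre-aligned.
5. **Validation** — mutual information of normalized images against the
   template (smoothed with a 2 mm FWHM Gaussian), leave-one-out and held-out
   scenarios, and cross-correlation over all image pairs after
   normalization (n images give n(n-1)/2 pairs).

## The CT intensity transform

CT and MR intensity ranges are incompatible (roughly -1024..2048 HU versus
0..1023), and the soft-tissue contrast inside the skull occupies a tiny HU
interval. The transform maps

* -1000..-100 HU linearly to 0..900,
* -99..100 HU linearly to 901..3100 (a ~11x expansion of the soft-tissue
  window),
* I > 100 HU to I + 3000.

The printed anchor points leave segment 1 with slope exactly 1, and the gap
between -100 and -99 is filled at the same slope, so the map is strictly
increasing and exactly invertible (`inverse_ct_intensity()`); round trips
are exact to 1e-9 over the whole domain. Inputs below -1000 HU can only be
artifacts (the rim); they are clamped to -1000 with a message.

## Head-mask extraction and the Otsu threshold

`otsu_threshold()` maximizes between-class variance with ties broken toward
the smaller threshold; the tests check it against an exhaustive search.
Before thresholding, `extract_head_mask()` clamps values below the physical
CT floor (-1024 HU) to -1000: the artificial rim otherwise contributes a
third, far-out histogram mode that can capture the Otsu split. The
morphology recipe is opening (1 voxel), largest connected component, closing
(2 voxels), hole filling; radii are exposed in mm and realized as Euclidean
balls via exact distance transforms, so anisotropic grids behave correctly.

## Coupled level sets for the intracranial cavity

The skull reads as a bright shell interrupted at fontanels and sutures.
A single inward-moving surface would leak through those gaps. We evolve two
surfaces as geodesic active regions:

* the **exterior** surface starts at the head boundary and propagates
  inward;
* the **interior** surface starts from the head eroded by
  `inner_erosion_mm` (default 12 mm, placing the seed strictly inside the
  cavity) and propagates outward.

Both are signed-distance functions (negative inside), advanced with a
Godunov upwind scheme. The balloon speed is gated by three factors:

* a **bone-region gate** `1 - smoothed bone indicator`, where bone is
  `intensity > bone_threshold` (default 300 HU) on the *unsmoothed* image —
  thresholding a smoothed image lets bone intensity bleed into neighboring
  CSF voxels and stalls the interior front one voxel short of the true
  boundary;
* the classic **edge-stopping function**
  `g = 1 / (1 + |grad(G_sigma * I)|^2 / lambda^2)` (a configurable fraction
  `edge_balloon_mix` of the balloon, plus an edge-attraction advection
  term), with `lambda` picked from the gradient-magnitude distribution when
  not given;
* a **mutual soft gate** that vanishes as the two surfaces come within the
  touch distance (default 1 voxel), so that where bone is absent the fronts
  meet and stall instead of crossing.

Non-crossing is additionally enforced by projection (`phi_in >= phi_out`
after every step), so the invariant holds exactly at every iteration, not
just in expectation. Level sets are reinitialized every 10 iterations by
exact Euclidean distance transforms; the evolution stops when no voxel
changes region for several consecutive iterations (or when the mean band
change drops below `tol`). The returned `touched` map is computed after a
final reinitialization — touch distances measured on drifted level-set
values are not geometrically meaningful. On desk-scale phantoms the
intracranial Dice is about 0.99 without gaps and 0.987 with two gaps, and
the touched map coincides with the gap sectors.

## Registration

**Affine (12 parameters: translation, rotation, log-scale, shear).**
Multi-resolution (factors 4/2/1) deterministic search: Nelder-Mead followed
by a BFGS polish per level, starting from a center-of-mass translation. The
MI objective uses partial-volume interpolation of the joint histogram —
each mapped sample distributes its trilinear weights over the bins of the
pre-binned moving image — which makes the objective smooth in the transform
parameters; intensity-interpolated MI is jagged and stalls simplex search
about half a voxel from the optimum. The returned transform never scores
below its initialization. On phantoms, an 8 mm shift is recovered to well
under 0.1 voxel and a 10 % scale to within 1 %.

**Symmetric diffeomorphic.** Two half displacement fields deform the fixed
and the moving image toward a common midpoint under a shared symmetric
demons-style force (the force uses both warped images' gradients and is
exactly antisymmetric under swapping the inputs); each update is smoothed
(`sigma_update`, default 2 voxels), capped (0.6 voxel per iteration), and
the accumulated half-fields are smoothed every iteration (`sigma_total`,
default 1 voxel). The returned forward map composes the numerically
inverted fixed half-field with the moving half-field, and the inverse map
the other way around, so swapping the input images yields the inverse
transform by construction; forward-inverse residuals are ~0.01 voxel and
Jacobians stay positive with the default caps and smoothing. Multimodal
pairs are handled before the force computation: for the MI metric the
moving image is re-expressed on the fixed image's intensity scale through a
conditional remap (the per-bin *median* of the fixed intensities given the
moving bin — the median is robust to mixed bins, where a mean would lift a
compact-support image's background and create a constant mismatch); for CC
both images are z-scored. Forces act only on the union of the two images'
foreground supports (deviation from the modal background intensity, dilated):
over a shared background, residual remap offsets against the decaying tails
of smoothed compact-support images otherwise drive a small but systematic
drift that accumulates over the iterations into a large spurious far-field
deformation.

## What the phantoms emulate — and what they do not

`phantom_spec()` describes a nested-ellipsoid head: scalp, cranial bone
shell with fontanel gaps cut as angular sectors, CSF rim, gray-matter shell,
white-matter core, at the usual HU calibration (air -1000, CSF ~15, WM ~25,
GM ~40, bone +1000) with Gaussian noise (10 HU), extracranial nuisance
blobs, and a -3000 rim; the MR-like rendering inverts the bone/soft-tissue
contrast as in T1-weighted images, on a 0..1023 scale. Populations are
random rigid motions (sd 2 mm, 2 degrees) composed with smooth random
diffeomorphic warps (RMS 2 mm, correlation length 12 mm, Jacobian checked
positive, amplitude damped and logged otherwise); every subject carries its
generating transform as ground truth. Random warp fields are smoothed with
zero padding: replicate padding concentrates the variance of smoothed noise
at the grid corners (~40x), and a synthetic subject warp should be the
identity at the grid boundary anyway.

Two deliberate departures from realism:

* **Skull thickness defaults to 5 mm** (a neonatal calvarium is nearer
  2-3 mm): a 3 mm shell voxelized on the 2 mm desk-scale grid has diagonal
  discretization holes, and the coupled surfaces meet through them exactly
  as they do at true fontanels. What the pipeline exploits is the
  watertight-shell-with-gaps topology, so the default preserves that
  topology at the test resolution. At finer grids a thinner shell works.
* Tissue interiors are **piecewise constant plus noise** — there is no
  parenchymal texture, no cortical folding, no beam hardening. One direct
  consequence: warp components *tangential* to the tissue boundaries are
  invisible to any intensity metric (we measured a 0.3 mm normal-component
  recovery error against a 1.2 mm tangential one on a generic random warp).
  The warp-recovery validation therefore uses a smooth random *radial*
  deformation on a spherical phantom — a growth/compression pattern that is
  everywhere normal to the nested shells, hence observable; it is recovered
  from a mean landmark displacement of ~3.5 voxels down to ~0.8 voxels.
  Passing these tests shows the machinery recovers what is observable; it
  does not bound the error on tangential anatomy variation in real images,
  where texture provides the missing constraint.

## The two-step registration and boundary-profile matching

The intracranial CT entering step 1 is smoothed with the same 2 mm FWHM
kernel used to build the MR intracranial template. The two inputs then
present matching boundary profiles: registering a crisp binary-masked image
against a smoothed template otherwise generates strong spurious forces along
the entire cavity boundary, which the whole-image warp (CT') inherits as an
extracranial distortion.

## Groupwise template: appearance and shape updates

Each iteration registers every subject to the current template (affine
under MI — a global CC affine can anti-align on the first iteration, when
the template is still the MR image with inverted bone contrast — then
diffeomorphic under the chosen metric, CC by default), averages the warped
subjects voxelwise, and warps that mean by
`shape_update() = -step x smoothed mean forward field`. With the default
two iterations, a damping step of 0.25 leaves a mean residual field of
about one voxel; `build_template()` uses `step = 0.5`, which reaches a
~0.35 voxel residual (the unbiasedness proxy) with identical template
quality (CC against the true mean anatomy 0.975 either way) while each
update remains a small, smoothed diffeomorphism. On an 8-subject phantom
population the template is closer to the true mean anatomy than any single
subject, stays anchored in the initial MR space (its affine back to the
reference is within a voxel of identity), and building with 2 versus 4
iterations changes the per-subject MI by less than 5 %.

## Numerical choices

* FWHM-to-sigma: `sigma = FWHM / (2 sqrt(2 ln 2))`; replicate-edge padding
  for image smoothing (no darkening at the head boundary); zero padding for
  synthetic warp generation (see above).
* World convention: RAS, 0-based voxel indices, voxel centers at
  `origin + direction %*% (spacing * index)`; all transforms are pull-backs
  (fixed-space points to moving-space points), the resampling convention.
* Interpolation: trilinear for intensities, nearest for masks; out-of-field
  fills are -1000 HU (raw CT), 0 (transformed CT and MR).
* MI: equal-width histograms, zero cells skipped (0 log 0 := 0), base-2
  logs by default (the log base is configurable; reported MI values scale
  accordingly).
* Otsu ties: smallest maximizing threshold. Empty-vs-empty Dice: 1, with a
  message.
* Level-set CFL: `dt = 0.45 x voxel / speed`; curvature realized as
  `g x Laplacian(phi)`, exact for signed-distance functions and cheap.
* Determinism: there is no stochastic sampling anywhere in the optimizers;
  phantom generation is a pure function of its spec (seed included), and
  population generation restores the caller's RNG state.

## Problem sizes used in the validation battery

Level-set criteria run on 64^3 phantoms at 2 mm; the registration battery
uses a 72^3 spherical phantom at 1 mm for warp recovery and 64^3 phantoms
for affine recovery; the groupwise criteria use 8 subjects at 48^3
(2.5 mm), built with both 2 and 4 iterations; the pairwise-normalization
harness uses ten 32^3 subjects. These sizes keep the whole suite within
ordinary desk runtimes while leaving every structure (shell, gaps, CSF rim,
cortex-like layering) resolved by at least two voxels.

## Interfaces

All pipeline stages are exported R functions returning their intermediates
(head mask, intracranial mask and surfaces, CT', CT'', transforms, traces),
so every arrow of the flow diagram is individually inspectable; a thin
command-line wrapper (`inst/cli/neotemplate.R`) exposes
`phantom | preprocess | intracranial | register | build-template | evaluate
| run-all` over NIfTI files, plain-text manifests, a YAML configuration
(`pipeline_config()`, exact round trip via `write_config()`/
`read_config()`), CSV traces and JSON/text transform serializations. We
deliberately did not add content-hash stage caching: in an R API the
returned intermediates serve that purpose.

## Known limitations

* The phantom is stylized (see above); no claim is made about cortical
  folding, beam hardening, or scanner-specific artifacts.
* The demons-style registrar is greedy: it honors the symmetric,
  invertible, midpoint-parameterized contract but does not minimize a
  geodesic path-length functional.
* MI values depend on bin count and log base; cross-study comparisons of
  absolute MI numbers require matching both.
* The evaluation scenarios use whole-volume MI by default (a mask argument
  exists); masked and unmasked values differ systematically.
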