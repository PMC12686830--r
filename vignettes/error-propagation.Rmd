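---
title: "How surface-completion error propagates into liver registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How surface-completion error propagates into liver registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverreg)
library(dplyr)
library(ggplot2)
```

## The question

In laparoscopic liver surgery only a fraction of the organ's anterior
surface — typically around 30% — is visible to the intra-operative camera.
A popular strategy is to *complete* the partial surface with a learned
shape model and then register the pre-operative model to the completed
surface, rigidly or non-rigidly. Completion, however, is only accurate
where the surface was actually observed. `liverreg` implements a fully
synthetic, fully deterministic pipeline for quantifying how that spatially
structured completion error propagates into registration accuracy, with
every stage replaced by an analytically controllable counterpart:

1. a watertight two-lobed liver phantom with interior fiducial markers,
2. an analytic wedge deformation standing in for intra-operative
   deformation,
3. a partial-visibility simulator (posterior slicing, farthest-point
   downsampling to 1000 points, selection of the 300 camera-nearest),
4. pluggable surface completion, including a distance-dependent error
   model that blends ground truth into a rigid prior with distance from
   the visible patch,
5. progressive-coverage patches grown by breadth-first search from the
   visible region,
6. multi-start ICP (rigid) and coherent point drift (non-rigid)
   registration at every coverage level, and
7. metrics: per-vertex distance maps, fiducial target registration error
   (TRE), a visible/invisible split at 30 mm from the visible-patch
   centroid, TRE-versus-coverage curves, and threshold sensitivity sweeps.

## The phantom

`make_liver_mesh()` builds the phantom from a smooth two-lobed occupancy
field thresholded at 0.4 and extracted on a dense grid:

```{r phantom}
liver <- make_liver_mesh(seed = 1, resolution = 48)
liver
is_watertight(liver)
mesh_signed_volume(liver) / 1000  # mL
```

Interior fiducials play the role of the implanted markers used by
physical phantom studies; TRE is evaluated at them, never at surface
points used for fitting:

```{r fiducials}
fids <- sample_fiducials(liver, n = 53, seed = 2)
head(fids, 3)
```

A wedge deformation lifts one lobe by a smooth, compactly supported bump
— a deformation whose ground-truth displacement is known at every
fiducial:

```{r wedge}
wedge <- wedge_deformation(center = c(52, 20), radius = 45, height = 15,
                           lobe = "left")
deformed <- apply_wedge(liver, fids, wedge)
```

## Partial views and completion

Five camera viewpoints over the anterior surface produce partial targets:

```{r views}
vps <- make_viewpoints(liver)
partial <- simulate_partial_target(deformed$mesh, vps$vp1,
                                   n_anterior = 1000, k = 300, seed = 3)
nrow(partial)
```

The error-model completion interpolates between the deformed truth and a
rigidly aligned pre-operative prior with weight `exp(-d / lambda)`, `d`
the geodesic distance to the visible patch, plus Gaussian surface noise
of scale `sigma` — completion is near-perfect where the camera looked
and prior-like far from it:

```{r completion}
gen <- complete_with_error_model(
  partial, deformed$mesh, liver,
  error_model_params(length_scale = 40, noise_scale = 4, seed = 4))
dm <- nearest_vertex_distance(gen$mesh, deformed$mesh)
summary(dm$distance)
```

## Registration and error stratification

`run_experiment()` ties the stages together; everything is derived from
one root seed. The configuration below is reduced for a quick run —
defaults reproduce the full study (5 viewpoints, 10 coverage levels):

```{r experiment}
cfg <- experiment_config(seed = 1, resolution = 32, n_fiducials = 20,
                         n_viewpoints = 1, n_anterior = 400,
                         k_visible = 120, n_levels = 3, n_restarts = 2,
                         rigid_points = 400, nonrigid_points = 150)
report <- run_experiment(cfg)
report$summary
```

The headline stratification: TRE is computed separately for fiducials
within 30 mm of the visible-patch centroid ("visible") and beyond it
("invisible"). With the default error-model completion the invisible
region carries both larger surface error (Eq. 1 distance maps) and larger
TRE, and for non-rigid registration stopping at the *best* intermediate
coverage is never worse than using the full completed surface — the
far-field of the completion is exactly where it is least trustworthy.

```{r curves, fig.width = 6, fig.height = 3.5}
autoplot(coverage_curve(report$curves$coverage[report$curves$mode == "nonrigid"],
                        report$curves$tre[report$curves$mode == "nonrigid"]))
```

## Notes on the registration engines

Rigid registration is multi-start point-to-point ICP (10 restarts over
rotations in ±π/2). Non-rigid registration is coherent point drift with
a Gaussian-kernel displacement field plus an explicit, unpenalized
translation; the motion-coherence penalty regularizes only the
genuinely non-rigid part, so pure shifts are recovered exactly. The
kernel displacement field extends naturally off the surface, which is
how interior fiducials are mapped (`apply_displacement_to_fiducials()`).
The experiment's kernel width (`nonrigid_beta`, 25 mm) is matched to the
radius scale of the wedge deformations under study, and its coherence
weight (`nonrigid_lambda`, 5) is stiffer than the engine default because
sparse samples of the smooth, self-similar liver surface can otherwise
slide tangentially onto wrong neighborhoods while the mixture variance
anneals.

## Reproducibility

Two runs with the same configuration produce byte-identical reports:

```{r determinism}
r2 <- run_experiment(cfg)
identical(report$summary, r2$summary)
```
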