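---
title: "Quantifying leaf shape along heteroblastic series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf shape along heteroblastic series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafmorph)
```

## The problem

Many vines change leaf shape from node to node as the shoot apical
meristem matures — heteroblasty. A vine's first (basal) leaves are
juvenile; later leaves progressively express the species' adult form.
`leafmorph` quantifies this with two complementary shape representations
and asks three questions of a multi-species leaf collection:

1. **Allometry.** How do the areas of leaf subregions (blade vs vein)
   scale with overall leaf area across the series?
2. **Effect decomposition.** For each shape trait, how much variation is
   species-specific (regardless of node), node-specific (regardless of
   species), and species-by-node interaction?
3. **Juvenile convergence.** Are basal leaves more alike across species —
   harder to discriminate, less variable, and tightly clustered at the
   base of per-vine trajectory vectors in a 2-D embedding?

## Shape representations

**Landmarks.** Each leaf is 15 homologous (x, y) points: the petiolar
junction and the bases of the major veins (landmarks 1–6), plus lobe
tips, sinuses and vein tips (7–15). The precise biological identity of
landmarks 7–15 is metadata, not code: every function that needs the
margin takes a `boundary` ordering argument
(`leaf_boundary_order()` is the default for this scheme).
Configurations are aligned by generalized Procrustes analysis (`gpa()`,
`align_leaves()`): translation removed, every configuration fixed to unit
centroid size, and rotation (optionally reflection, the default) chosen
to minimize summed squared distance to the evolving mean shape.
Numerical choices: convergence when the mean shape moves less than
`1e-8` (root summed squares) between iterations, at most 100 iterations;
because the solution is only defined up to a global rotation, the final
mean is anchored to the first input configuration, making output
deterministic.

**Elliptical Fourier descriptors.** A leaf outline — a traced binary
mask (`trace_contour()`, Moore boundary following to a Freeman chain
code) or any closed polyline — is decomposed into per-harmonic
quadruples $(a_n, b_n, c_n, d_n)$ of its arc-length parameterization
(`chain_to_efd()`, `outline_efd()`). Normalization
(`normalize_efd()`) uses the first-harmonic ellipse: the parameter
origin moves to the semi-major axis, the shape is rotated so that axis
lies along x, and all coefficients are divided by the semi-major length,
leaving $a_1 = 1$, $b_1 = c_1 = 0$ and $|d_1| \le 1$. Two numerical
conventions matter:

* the half-period ambiguity of the axis direction is resolved by taking
  the candidate whose reconstructed point at parameter 0 has the larger
  x coordinate (a deterministic tie-break; coefficient-level
  compatibility with other programs' tie-breaks is not promised, only
  invariance to rotation, scale and starting point);
* contours are forced counter-clockwise before the transform, since
  coefficient signs depend on orientation.

A caution about analytic expectations: because the parameterization is
arc length, the normalized $d_1$ of a 2:1 ellipse is about 0.587, not
the axis ratio 0.5 (which presumes uniform-angle parameterization). The
test suite checks this against dense quadrature of the exact contour.

The harmonic count defaults to `H = 20`, enough that reconstruction
error of digitized outlines is sub-pixel; it is a plain argument
everywhere.

## Subarea allometry

Aligned leaves are subdivided into distal blade, proximal blade, midvein
and proximal-vein polygons (`default_polygon_spec()`,
`leaf_subareas()`). The subdivision is configuration: a named list of
landmark-index rings. A subregion may consist of more than one simple
part — the midvein strip necessarily splits each blade into left and
right parts — and parts share internal chords exactly, so the four
subareas sum to the whole-leaf area identically (shoelace additivity) on
any configuration where each part keeps its orientation; folded parts
are flagged rather than silently summed. `fit_allometry()` regresses
`sqrt(subarea)` on `sqrt(total area)` — the square-root transform puts
both axes on a length scale — overall or per species, with pointwise 95%
confidence bands from the OLS covariance (simultaneous bands are not
claimed). Zero-area subregions enter as `sqrt(0) = 0`.

A caveat worth stating: per-subregion slopes pooled across species mix
within-species allometry with between-species differences in how blade
area is partitioned, and can be individually erratic even when every
within-species fit is clean. Per-species fits are the interpretable
ones.

## Effect decomposition

`effect_matrices()` fits `trait ~ species * node` per trait with
treatment coding: the reference species is absorbed into the intercept,
node enters as a numeric covariate (a single slope per term — matching
one "heteroblasty" row and one interaction row per species in the
effect heatmaps), and estimation is ordinary least squares. The
reference defaults to the alphabetically first species and is
overridable. Note a consequence of treatment coding: the "heteroblasty"
coefficient is the reference species' own node slope, so the choice of a
species with little heteroblastic change as reference is what makes that
row small relative to interactions. Constant traits (including the
normalization-fixed $a_1, b_1, c_1$ columns) get zero effects and a
flag; `drop_constant_traits()` removes them before clustering or
discrimination. Trait ordering for heatmaps is complete-linkage
hierarchical clustering on Euclidean distances (`cluster_traits()`);
the linkage is declared and configurable, and leaf order is hclust's
deterministic order.

## Discrimination and variability

`loo_species_assignment()` performs leave-one-out linear discriminant
analysis per node: for each leaf, the discriminant rule (pooled
within-class covariance, priors proportional to training counts,
configurable to uniform) is estimated without that leaf, which is then
assigned to the highest-scoring species. Species with fewer than two
leaves at a node are excluded with a warning — a declared rule, since
deposited analyses rarely state theirs. A singular pooled covariance
(more traits than leaves at one node) is ridge-regularized with
$\epsilon = 10^{-8}\,\mathrm{tr}(S)/p$, warned once; near-constant
features are dropped first. `trait_sd_by_node()` is the sample standard
deviation (n − 1) of each trait over all leaves at a node, pooled across
species.

## Trajectories

`embed_2d()` reduces the joint trait space (30 aligned coordinates plus
4H EFD coefficients by default; the trait set fed to the embedding is
whatever columns you pass) to two dimensions, by exact t-SNE at
perplexity 40. The implementation is O(n²) — appropriate for hundreds to
a few thousand leaves — with standard early exaggeration (factor 12 for
120 iterations), 600 gradient iterations, and deterministic
initialization on the leading principal plane, so a given input
reproduces exactly and duplicated rows stay exactly co-located (they are
collapsed to one embedded point). Perplexity is auto-reduced to
`floor((n - 1)/3)` with a warning on small collections, and
`method = "pca"` is a fast deterministic alternative.

`vine_vectors()` draws one vector per vine from its *first sampled* to
its *furthest sampled* node (not nominal node 1/10 — vines differ in
sampled nodes), `center_vectors()` translates bases to the origin, and
`convergence_stat()` summarizes juvenile convergence as the ratio of
mean pairwise distance among bases to that among tips. Mean pairwise
distance is used rather than variance for robustness to embedding scale;
the ratio is invariant to rotation and translation of the embedding.

## The synthetic generator

`simulate_leaves()` produces collections with known ground truth. Every
leaf is
$$ X_{s,v,k} = J + w_s(k)\,(M_s - J) + \varepsilon, $$
rescaled to centroid size `size_base + size_gain * k`: a shared juvenile
shape $J$, species-specific adult shapes $M_s$, and a logistic-in-node
trajectory weight $w_s(k)$ with species-specific rate and a shared early
inflection (default node 1.5), so most shape change happens within the
first two or three nodes. Choices and why:

* **Dimensions** default to 8 species × 5 vines × 10 nodes — a
  desk-scale stand-in for a 40-species glasshouse collection.
* **Noise** (`shape_noise_sd = 0.005`) is isotropic per-landmark
  Gaussian error of half a percent of leaf height, i.e. a few pixels of
  digitizing error on a ~1000-pixel scan.
* **Adult divergence** is built from interpretable components: lobing
  (sinuses cut toward the midvein while lobe tips extend), apex
  elongation, proximal "wing" spread, and breadth (a proportional width
  change, the allometrically clean axis: a pure x-scaling multiplies all
  subareas equally). Breadth takes a balanced sign across species with
  bounded magnitude, so every species has a resolvable within-series
  area trend — in a real genus, adults are distinctly broader or
  narrower than the juvenile form.
* **Trajectory directions are centered** to zero mean across species, so
  the node main effect is negligible by construction and species
  diverge in genuinely different directions.
* **The first species changes little** along its series (its raw
  trajectory is the across-species mean, hence nearly null after
  centering), like the lance-leaved members of such genera. Since the
  fitted "heteroblasty" row is the reference species' slope, a
  low-change reference is what the model's intercept choice presumes.
* **Vein landmarks** are placed in closed form so the midvein and
  proximal-vein polygons take exact area fractions (the squared
  generating slopes) of the total at both trajectory endpoints; they
  interpolate linearly with the margin in between, keeping the leaf
  model exactly linear in $w$.
* `simulate_subareas()` draws subarea records directly from the exact
  sqrt-linear model (constant fractions equal to normalized squared
  slopes), for slope-recovery validation with closure exact by
  construction.

What the generator does **not** emulate: venation networks, petioles,
asymmetry and erratic lobing reversals, bimodal leaf-type transitions,
multi-leaf scan sheets, and any imaging texture. Passing tests therefore
validate the estimators under a clean forward model of the hypothesized
structure — shared juvenile, divergent saturating trajectories,
allometric scaling — not the segmentation of real scans.

## Problem sizes in the test suite

The suite validates GPA against an independent alternating-minimization
oracle on 10 random 15-landmark configurations; EFDs against dense
quadrature on digitized circles, ellipses and squares; subarea closure
on a 1,040-leaf collection; effect recovery on 400-leaf collections at
noise 0 and 0.01; discrimination and variability orderings across 10
generator seeds; and trajectory convergence with full t-SNE embeddings
across 10 seeds plus 10 no-heteroblasty (w0 = 1) controls. These sizes
were chosen as the smallest at which the contrasts of interest are
unambiguous.

## Interfaces and limitations

The package's interface is its functions — tibbles in, tibbles out,
composable with the pipe — plus `run_pipeline()`, which drives
ingest-or-simulate through every stage from one (YAML-able)
configuration with a seed-substreamed reproducibility manifest; a shell
wrapper would add nothing over `Rscript -e`.

Known limitations: 2-D configurations only; no semilandmarks or sliding;
no mixed models (vine is never a random effect); no
standardized-major-axis allometry; LDA only (no quadratic or tuned
regularized discriminants); exact t-SNE does not scale past a few
thousand leaves. The NEF reader/writer follows the SHAPE layout (name
line, harmonic count, H rows of four coefficients) and tolerates
Windows line endings and repeated whitespace, but no other dialects.
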