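---
title: "Methods: quantifying pancreatic endocrine objects in 2D sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pancreatic endocrine objects in 2D sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoquant)
```

## The problem

In bright-field immunohistochemistry of human pancreas, endocrine tissue is
visualized by chromogens deposited where anti-insulin (DAB, brown) and
anti-glucagon (red AP chromogen) antibodies bind, over a hematoxylin
counterstain. An *endocrine object* (EO) is any contiguous structure of one
or more hormone-positive endocrine cells — from a single extraislet β cell to
a whole islet of Langerhans. Quantifying the full EO size spectrum, rather
than only classical islets, is what reveals the early loss of small
insulin-only objects in type 1 diabetes (T1D). This package implements that
quantification end to end and ships a synthetic-data generator so every stage
is verifiable against pixel-exact ground truth.

## Stain deconvolution

Chromogen amounts mix additively in optical-density space (Beer–Lambert), so
each pixel's RGB intensity is converted to OD as
$\mathrm{OD}_c = -\log_{10}\!\big((I_c + \varepsilon)/I_{0,c}\big)$ with
background intensity $I_0$ (default 255 per channel) and stabilizer
$\varepsilon = 1$ intensity unit, which avoids $\log 0$ while shifting OD by
less than 0.003 at 8-bit depth. Each stained pixel (OD magnitude above a
floor, default 0.05) is assigned winner-take-all to the stain whose unit OD
vector has the maximal projection onto the pixel's OD vector; a pixel counts
hormone-positive only when that projection also exceeds the stain's OD
threshold (default 0.15). Exact ties go to hematoxylin, the conservative
choice. Where both chromogens are strong, only the stronger is counted, so
dual hormone-positive pixels are systematically under-counted — a known
limitation of winner-take-all chromogen deconvolution that we document rather
than hide.

The default stain vectors are the Ruifrok–Johnston hematoxylin and DAB
vectors, plus the Fiji "Fast Red" vector standing in for Warp Red (no
standardized published vector exists for it). All vectors and thresholds are
configuration-overridable (`stain_model()`, `read_run_config()`), because
archival slides vary in staining intensity and real deployments re-tune the
OD threshold per section. The override is explicit and logged, never an
automatic optimizer.

## EO detection, filtering, classification, binning

Candidate objects are 8-connected components of the union of the two
hormone masks; 8-connectivity treats diagonally touching pixels as
contiguous, matching the visual contiguity of compact chromogen blobs.
Components below **170 µm²** — the approximate area of a single endocrine
cell — are discarded. Objects touching the image border are retained but
flagged, preserving auditability where the convention is otherwise arbitrary.

Retained candidates pass the staining-artifact filter: an object survives iff
its insulin- or glucagon-labeled area is **strictly greater than 40 µm²**;
the same threshold defines each hormone-positivity flag, yielding the
exhaustive three-class partition Ins⁺Gluc⁻, Ins⁺Gluc⁺, Ins⁻Gluc⁺.

The size bin is
$\mathrm{bin} = \big\lfloor \log_2(\mathrm{area}/170\,\mu m^2) \big\rfloor$ —
i.e. the area expressed in approximate cell equivalents, log2-transformed and
rounded down. Bin boundaries are exactly $170 \cdot 2^k$: bin 0 covers
170–340 µm², bin 6 starts at 10,880 µm² (about one islet equivalent). Bins
0–3 are *small*, 4–6 *medium*, 7–9 *large*; bins above 9 are clamped to 9
with a warning, matching the 0–9 reporting range. Note that some published
bin tables print slightly different upper bounds (e.g. 399 µm² for bin 0);
this package follows the formula, whose boundaries are 340 and
21,760 µm² — the discrepancy is in the printed table, not the rule, and the
bin-6 *lower* bound 10,880 µm² is formula-exact either way.

## Morphology

Shape descriptors operate on closed polygons: circularity $4\pi A/P^2$,
solidity $A/A_{\mathrm{hull}}$, maximum/minimum Feret (caliper) diameters
computed on the convex hull (the minimum width is attained perpendicular to a
hull edge — the rotating-calipers result), and circle-equivalent diameter
$2\sqrt{A/\pi}$. For detected raster objects the boundary polygon is traced
along pixel edges (directed edges around each pixel cancel where shared;
the remainder chain into loops, taking the most-clockwise turn at diagonal
pinch vertices). The traced polygon's area equals the pixel count exactly.
Raster perimeters of smooth shapes are overestimates, so circularity of
rasterized objects is biased low relative to the continuous shape; the
closed-form checks (unit square → circularity π/4, solidity 1; regular
64-gon → circularity > 0.99) therefore use polygon inputs directly, and
cross-object morphology comparisons should be made at a common resolution.

## Cross-platform annotation matching

When two platforms annotate the same section, objects are paired by the sum
distance of their centroids and four bounding-box corner coordinates (equal
weights), matched greedily in ascending score order under a gate (twice the
95th percentile of nearest-neighbor centroid distances). Greedy matching is
deterministic and auditable; the underlying platforms do not publish their
assignment algorithm, so this is the package's documented choice. Matched
pairs whose EO bins differ by more than 1 are rejected, and the coefficient
of determination of the two platforms' areas is reported before and after
that filter. R² is computed on areas, not bins, because area agreement is
what the QC is about.

## Aggregation and statistics

All metrics are computed per section, then averaged in two stages: sections →
pancreas region (head/body/tail/other), then regions → donor, so regions
contribute equally regardless of section counts. The donor-level metric
family covers total and per-bin×class EO density (count/mm²), % endocrine
area of tissue, per-bin×class % of total EO count and of endocrine area
(each summing to 100% per donor), hormone⁺ area as % of tissue per bin, and
small/medium/large density sums.

The test plan mirrors standard practice for unbalanced population cohorts:
Mann–Whitney U between two groups with Benjamini–Hochberg adjustment across
the metric family; Kruskal–Wallis plus Tukey post hoc contrasts on estimated
marginal means for ≥3 groups on one variable; and type II two-factor ANOVA
(group × bin or class) with Tukey (all pairs) or Dunnett (versus control)
post hoc contrasts — the Tukey/Dunnett choice is always an explicit argument,
never inferred. Groups with fewer than 3 donors cause a skip with a flag;
all-tied comparisons are reported as degenerate with p = 1. Group summaries
use a t-interval 95% CI on donor-level values; the CI method is a documented
package choice. Clinical rules: T1D endotype T1DE1 is diagnosis age < 13
years, T1DE2 is ≥ 13 (13.0 exactly → T1DE2); an autoantibody-positive donor
is high progression-risk iff at least three of {GRS ≥ 50th percentile,
reported insulitis, HLA-I hyperexpression, IA2A⁺} hold, with missing flags
conservatively treated as false (logged). Pancreas-weight fold changes are
ratios of bracket medians against the previous non-empty bracket (default
brackets 0–1, 2–6, 7–12, 13–17, ≥18 years), with gaps flagged rather than
interpolated.

## The synthetic-data generator

`render_section()` draws each specified EO as a superellipse perturbed by
low-frequency radial noise (`shape_irregularity` controls exponent, aspect,
and noise amplitude — larger objects can be made less circular and solid,
as real islets are), rasterizes it by the pixel-center rule, lays insulin
pixels in the core and glucagon pixels in the mantle, and composes the 8-bit
RGB image by Beer–Lambert mixing over a near-white background with a light
hematoxylin tissue tint. The ground-truth table reports *pixel-exact* areas,
so the deconvolution → detection → classification chain can be checked for
exact recovery. The core/mantle layout is a documented stand-in — real
α/β-cell topography varies — and is immaterial downstream because
classification depends only on areas. Touching blobs merge into one
ground-truth object (with a warning), exactly as a connected-component
detector would see them. Ground-truth total area counts all EO pixels,
including any hormone-unlabeled remainder when the hormone fractions sum to
less than 1; the cohort sampler always uses fractions summing to 1, so
detection recovers its ground truth exactly.

`sample_cohort()` draws donor cohorts from per-group profiles: a 10 × 3
matrix of EO density (count/mm²) by bin and content class. Counts are
Poisson with mean density × tissue area, modulated by a mean-one lognormal
donor effect (sdlog 0.25, a realistic inter-donor variability that leaves
group densities unbiased); areas are uniform within bin boundaries
$[170\cdot2^k, 170\cdot2^{k+1})$ — the simplest distributions consistent
with per-bin summaries. The default scale is 0.5 µm/px (a ×20 scan).

The shipped profiles encode the contrast the analysis is designed to
detect. ND (non-diabetic adult): total density 8 EO/mm², class count shares
54.5% Ins⁺Gluc⁻ / 36.8% Ins⁺Gluc⁺ / 8.7% Ins⁻Gluc⁺, with 96% of Ins⁺Gluc⁻
and 99.1% of Ins⁻Gluc⁺ objects in the small bins and Ins⁺Gluc⁺ objects
concentrated in medium/large bins. T1D: total density 4 EO/mm², shares
5.8% / 12.3% / 81.9%, with *zero* small-bin Ins⁺Gluc⁻ density — the virtual
absence of extraislet β cells — and residual Ins⁺Gluc⁺ objects confined to
medium/large bins. The class shares and small-fraction figures are the
published cohort values; the total densities are the package's own
realistic choice, fixed once. AAb⁺ profiles are ND-like (single AAb) or
intermediate (multiple AAb: small Ins⁺Gluc⁻ density halved).

What the generator does *not* emulate: histological texture, nuclei, blood
vessels and ducts, immune infiltrate, staining gradients and artifacts on
archival slides, or the topographic lobularity of T1D. Passing the recovery
tests therefore demonstrates the correctness of the measurement chain on
clean, known inputs — not classifier robustness on real whole-slide images,
which the package does not claim (neural-network tissue classification is
out of scope; segmentation here is deconvolution-plus-thresholding).

## Problem sizes and numerical choices

Validation runs use deliberately desk-scale problems: 50 rendered sections
of 300 × 300 px with 2–4 blobs each for exact ground-truth recovery; a
two-group cohort of 20 donors per group, 3 sections of 25 mm² each, for
density recovery (within 3 Monte-Carlo SEs per bin × class cell) and for the
ND ≫ T1D / T1D ≫ ND orderings (adjusted p < 0.001 at n = 20/group); and 200
re-simulations of two identical groups (n = 10 + 10) for family-level type-I
control of the BH-adjusted Mann–Whitney plan. All randomness flows from
explicit integer seeds (`with_seed` restores the caller's RNG state);
rendering is noiseless by default so boundary pixels are never flipped by
quantization. Floating-point binning uses plain `floor(log2(area/170))`
with no epsilon: generated areas never sit exactly on a boundary, and exact
powers of two (340, 680, 10,880…) divide exactly in binary so the anchors
are reproduced without fuzz.

## Known limitations

Dual hormone-positive pixels are under-counted by design (winner-take-all);
circularity of rasterized objects is resolution-dependent; the acinar
compartment is reported only as tissue-minus-endocrine; the matcher is
greedy, not globally optimal (adequate when annotation sets differ by small
perturbations, which is the QC use case); and cohort profiles are stylized
summaries, not a reproduction of any real donor cohort.
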