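---
title: "Methods behind neutrokit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind neutrokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrokit)
```

neutrokit implements the computational side of a common experimental
program in neutrophil biology: differentiate HL-60 or PLB-985 myeloid
cells into a neutrophil-like state, quantify how far they got
(cytometry, chemotaxis, nuclear morphology), and place their
transcriptomes next to primary human and mouse neutrophils. This
vignette explains each statistical procedure, its assumptions, the
tunable parameters, and the choices made where the design was open.

## Uniform-gene expression normalization

RNA-seq datasets produced by different labs on different platforms
cannot be compared on raw FPKM. The normalization used here anchors
every dataset on its "uniform genes": the genes whose expression lies
between the 50th and 90th percentile *in every sample* of the
collation. Genes in this band are expressed at unexceptional,
broadly stable levels, so their geometric mean is a robust per-sample
size factor:

$$f_j = \Big(\prod_{g \in U} x_{gj}\Big)^{1/|U|},
\qquad x'_{gj} = \frac{x_{gj}}{f_j}\,\bar f_{\mathrm{ref}},$$

where $\bar f_{\mathrm{ref}}$ is the mean factor over a designated
reference group of samples (in a cross-species collation, the human
datasets), so every dataset lands on the reference scale. After
normalization the geometric mean of the uniform genes equals
$\bar f_{\mathrm{ref}}$ in every sample — an invariant the test suite
checks to 1e-9 — and multiplying any sample by a constant beforehand
changes nothing (scale invariance).

Decisions the definition leaves open, and the defaults taken:

* **Percentile convention.** Linear interpolation between order
  statistics (`stats::quantile` type 7), membership inclusive at both
  bounds. Configurable via `lower`/`upper`; the bounds used are
  recorded in the returned `uniform_gene_set`.
* **Degenerate samples.** Percentiles are computed over all genes,
  zeros included. If a sample's median is 0, membership in that sample
  additionally requires a positive value, otherwise geometric means
  are undefined. An all-zero sample therefore yields an empty set and
  a warning rather than NaNs.
* **Reference averaging.** "Mean scaling factor" is read as the
  arithmetic mean of the reference factors; a geometric option exists
  (`reference_average = "geometric"`).

Log transformation maps zero-count genes to −4 (log10 scale) to avoid
infinities, and floors positive values at the same −4; values in
(0, 10⁻⁴) would otherwise escape below the floor that zeros receive.
For PCA a separate, higher floor of −2 is applied before the
decomposition so that noise among lowly expressed genes does not
dominate the components.

Replicate averaging is a two-stage arithmetic mean on the log scale
(equivalently a geometric mean of raw values): replicates are averaged
within each laboratory first, then lab-level profiles are averaged
with equal weight. This stops a lab that contributed many replicates
from dominating a "primary neutrophil" consensus profile.

Cross-species comparison is restricted to homolog pairs supplied as a
two-column table. One-to-many mappings are dropped by default
(`policy = "one_to_one"`) to avoid double-counting a gene; a
"first listed" policy exists for users who prefer coverage over
strictness. Protein-coding restriction is a plain annotation filter.

## Similarity, clustering, PCA

Sample similarity is Spearman rank correlation (average ranks on
ties), which is invariant under any monotone transform of a sample and
therefore insensitive to residual scale differences normalization did
not remove. Constant columns have undefined rank correlation and are
reported as `NA` with a warning, never silently imputed. Hierarchical
clustering uses one minus Spearman correlation as the distance with
average (UPGMA) linkage; distances live in [0, 2]. Neither the tie
break nor leaf ordering is prescribed by the method, so samples are
processed in lexicographic label order, which makes equal-distance
merges resolve deterministically to the earliest pair.

The fold-change reproducibility analysis computes per-gene log10 fold
changes (treated minus control) within each of two replicate
experiments and correlates them across genes, after excluding genes
whose mean log10 expression over the four samples is below −1; below
that level fold changes are mostly noise. The upregulated-gene filter
retains a gene only if its mean log10 expression across the
differentiation samples is at least −1 *and* it is at least 3-fold up
in every matched (treated, control) pair. Both bounds are inclusive,
and fold changes are compared on the log scale with a 1e-9 tolerance
so an exactly 3-fold gene is not lost to floating-point rounding.
Because inputs are floored log values, a zero-expression gene enters
as −4 and can never produce an infinite ratio.

## Cytometry gating statistics

All gating is threshold-based and control-derived: the gate is an
upper quantile (default 0.995) of the matched negative control —
isotype antibody for CD11b-style stains, unstained cells for
ligand stains such as FLPEP. No automatic mixture modelling is
attempted; the quantile is configurable and recorded in the `gate`
object. Because the gate is a quantile, percent positive is invariant
under any strictly increasing transform applied jointly to sample and
control — the statistic depends only on ranks.

Percent positive optionally restricts first to the live
(viability-stain-negative) population, matching how results are
reported "in the NucRed-negative population". MFI is the arithmetic
mean over that same live population by default (a `positive_gate`
restriction is available), and normalized MFI rescales all samples so
the designated reference (cells differentiated with DMSO only) is
exactly 100. Autofluorescence correction subtracts the mean unstained
signal and deliberately keeps negative corrected intensities: clipping
at zero would bias every downstream mean upward. Death fraction is
the percentage of events above the viability gate and complements the
live fraction to 100 exactly. Growth curves are normalized to their
first observation.

## Chemotaxis directionality

For each step of each tracked cell, the step angle is the absolute
angle between the displacement vector and the vector from the step's
*start position* to the gradient source (recomputed every step, since
cells move relative to a fixed uncaging spot): 0° is straight at the
source, 180° straight away. Zero-length displacements carry no
direction and are excluded from angle statistics, though they still
contribute elapsed time (and zero length) to speed.

The angular-bias statistic scores each step as $90° - \text{angle}$,
averages within cells, then averages over cells. This is the simplest
statistic satisfying both anchors: movement straight at the source
scores exactly 90°, and uniformly random directions have expectation
0° (the Monte-Carlo check at 10⁵ steps stays within ±1°). Per-cell
weighting is the default because the quantity is a *cell*
directionality parameter; `per = "step"` pools steps instead. Windows
are half-open on the right and assigned by step start time, with the
pre-stimulus window ending at, and the post-stimulus window starting
at, the uncaging time — so the uncaging frame itself belongs to
"after". Mean speed is per-cell path length over elapsed time,
reported in μm/min.

The mixed-population simulation formalizes the observation that only
~70% of Nutridoma-differentiated cells express the FPR1 receptor:
each simulated cell is a responder with probability `f_responder`
(estimated independently as the cytometry percent-positive),
responder step angles are resampled with replacement from an
empirical responder angle sample (primary neutrophil steps), and
non-responders draw uniform angles. The closed-form expected
histogram, $f\,\hat p_{\mathrm{emp}} + (1-f)\,\mathrm{Unif}$, is
returned alongside the simulated draw. When comparing a simulated
mixture against an observed mixed population by chi-square, the test
is calibrated only if pooled steps are independent; with many steps
per cell the shared responder status inflates the statistic, so the
package's own validation uses one post-stimulus step per cell.

## Genotype concordance

Cell-line identity is established from RNA-seq-derived genotype
calls: loci are kept only when read depth is ≥ 10 in *every* sample
and site quality is strictly greater than 100 (the strict inequality
is deliberate and boundary-tested), then every sample pair is scored
by the fraction of loci with identical unphased genotypes. Genotypes
are compared as allele multisets, so `0/1` and `1/0` match — phase
from RNA-seq calls is noise. "Quality" means site QUAL, not
per-genotype GQ; both the thresholds and the field choice are
arguments. Fractions near 1 indicate a shared genetic origin (a line
and its sub-line), while unrelated donors fall clearly below.

## Nuclear morphometry

Nuclei are segmented by a global intensity threshold; connected
foreground components below 100 px are discarded as debris (bound
inclusive: a 100-px object survives, a 99-px object does not).
Components are 8-connected by default — the common choice for blob
segmentation — with 4-connectivity available. Dead cells are removed
by a co-registered viability channel: any object whose mean viability
intensity exceeds the threshold is excluded. Areas convert to μm² by
the square of the pixel size, default 0.4389 μm/px (100 px ≈ 19.26
μm²). The intensity threshold is a required input; an Otsu-style
automatic threshold is provided as a convenience extension, not a
default.

## The expression catalog

`build_catalog()` outer-joins per-group averaged log10 profiles on
gene id, attaches optional symbols, homolog links and user-supplied
protein-domain annotations, and `query_catalog()` supports exact-match
search by symbol, id or domain with a stable sort by any expression
column (ties keep catalog order) and top-k truncation. Missing values
stay `NA` in memory and an explicit `NA` token in CSV — never a
numeric floor, which would be indistinguishable from "measured but
low". Domain annotations are a user-supplied two-column table; the
package does not fetch PFAM.

## What the synthetic generators emulate

Every generator is seeded, deterministic, and returns hidden truth
labels so estimators can be validated by parameter recovery:

* **Expression** (`gen_expression`): per-gene baseline log10 levels
  drawn Normal(0.5, 1) by default, lab offsets, Normal(0, 0.15)
  measurement noise, and a designated signature gene subset (20% of
  genes) shifted per condition by `differentiation_shift`. Zeros are
  injected by masking each sample's lowest-expressed genes, mimicking
  dropout of lowly expressed genes and matching the heavy left tail
  the −4 floor exists for. A condition with a large shift serves as
  the "primary neutrophil" template; conditions with intermediate
  shifts correlate with it in shift order, which is how the
  qualitative differentiation result is reproduced in silico.
* **Cytometry** (`gen_cytometry`): two-component log10-normal marker
  mixture (defaults: negative at 1.0, positive at 2.5, SD 0.3 — a
  5-SD separation typical of a clean stain), a viability channel with
  live/dead components at 1.0/3.0 (SD 0.25), and a dye-free unstained
  control drawn entirely from the negative/live components. Percent
  positive and death fraction recover `f_positive` and `f_dead`
  within ±3 percentage points at 10⁴ events under these defaults,
  which were configured once from the marker-positive and death
  percentages printed for the DMSO and DMSO + Nutridoma protocols.
* **Tracks** (`gen_tracks`): cells start in an annulus (100–300 μm)
  around the source, step lengths Normal(5, 1.5) μm per 30-s frame
  (~10 μm/min, a realistic neutrophil speed), uniform directions
  before the stimulus; afterwards responder cells draw step angles
  from a von Mises distribution centred on the instantaneous source
  direction. Von Mises is the standard circular-noise model and its
  concentration is the single directionality dial. Per-step draws are
  the default; `angle_mode = "cell"` gives each responder a persistent
  heading instead, for users who prefer ballistic responders.
* **Genotypes** (`gen_genotypes`): identity groups share genotypes at
  every locus exactly; each non-reference group differs from the first
  group at a Bernoulli(`discordance_between_groups`) subset of loci,
  so between-group identity concentrates at 1 − discordance. Depth is
  Poisson(30), site quality Uniform(150, 3000) by default.
* **Nuclei images** (`gen_nuclei_image`): non-overlapping ellipses
  (log10 area Normal(log10 300, 0.12) px², axis ratio 0.6–1) on a
  16-bit intensity scale, with a 1-px separation margin so objects
  are never 8-connected to each other; dead nuclei are painted on the
  viability channel. Placement is rejection sampling with a bounded
  retry budget; an impossible packing raises a generation error.

What the generators do **not** emulate: library-size and
gene-length biases (values are already FPKM-scale), spillover between
cytometry channels, cell collisions or confinement in chemotaxis,
linkage between genotype loci, textured nuclei or uneven
illumination. Passing tests therefore demonstrate correctness of the
statistics under clean assumptions, not robustness to every artefact
of real data.

## Problem sizes and numerical choices

The validation suite uses 5,000-gene matrices for normalization
properties, 10⁴ events × 20 seeds for gating recovery, 10⁵ steps for
the angular-bias Monte-Carlo anchor, 10³ loci for concordance and
~300² px images — sizes at which binomial/sampling error is far
smaller than the tolerances being checked, while the whole suite runs
in seconds. Noteworthy numerical choices: near-(anti)parallel steps
snap to exactly 0°/180° (1e-12 cosine tolerance) so the perfect-track
anchor is exact; fold-change bounds compare with 1e-9 log-scale
tolerance; Spearman ties use average ranks; quantiles are type 7
everywhere; equal-linkage merges resolve lexicographically.

## Known limitations

* Gating is a single global threshold; samples with drifting
  autofluorescence between control and stain need the explicit
  autofluorescence correction first, and bimodal viability stains
  with overlapping components will bias the death fraction.
* The uniform-gene set can be empty for strongly discordant
  collations; the package warns and stops rather than inventing a
  factor.
* UPGMA leaf order is deterministic but arbitrary beyond the
  documented tie-break; do not read meaning into left/right order.
* The catalog is a static table; it does not attempt the web
  database's live search, only its query semantics.
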