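---
title: "Methods: models, parameters and design choices in loopstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in loopstack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopstack)
```

`loopstack` compares the three-dimensional chromatin organization of two
cell states from loop-level data. This vignette records the models the
package implements, the parameters that matter, and the design decisions
taken where the methodology was genuinely open — in enough detail that a
maintainer can tell deliberate choices from accidents.

## The binned-genome model

All cross-assay comparisons happen on a uniform tiling of the genome into
fixed-width bins (default 1 kb), the last bin of each chromosome truncated
at its end. Two overlay semantics exist and the distinction is load-bearing:

* **Score overlays** (`overlay_score()`, `anchor_strength()`) add the
  *full* score of a feature to every bin it overlaps. There is no
  length-proration: a loop anchor is either present at a bin or it is not,
  and its evidence (the loop score) is not diluted by how the anchor
  happens to straddle bin boundaries. `prorate = TRUE` is available for
  sensitivity checks.
* **Span overlays** (`overlay_span()`) add overlap base pairs, capped at
  the bin width (default cap = 1000 bp per 1 kb bin). The cap prevents
  features annotated once per gene — promoters and enhancers shared by
  several transcripts — from counting multiple times at one location.

Anchor strength deliberately counts a loop once per overlapping anchor, so
a self-looping record whose two anchors hit the same bin contributes twice
there; `dedupe_anchors = TRUE` switches to once-per-loop counting. The
double-count default reflects the definition of the statistic as a sum
over anchors, not over loops.

Between-condition comparability is achieved by linear scaling of the
larger library to the smaller one (`normalize_conditions()`), not by
subsampling: scaling is deterministic, preserves within-set ratios
exactly, and makes reruns reproducible without a seed. A seeded binomial
subsampler (`subsample_loops()`) exists for sensitivity analyses.

Coordinates are 0-based half-open everywhere — in memory and in every
file written — matching BED/BEDPE conventions; nothing in the package
emits 1-based closed coordinates.

## Directionality index and TAD calling

The directionality index at 40 kb bins contrasts each bin's upstream
contact sum $A$ and downstream sum $B$ inside a 2 Mb one-sided window:
$E = (A+B)/2$ and
$DI = \mathrm{sign}(B-A)\,\big[(A-E)^2/E + (B-E)^2/E\big]$, with $DI = 0$
when $A = B$ or $E = 0$. Bins whose window is truncated by a chromosome
end keep their DI by default — masking them would silently drop telomeric
domains — with `mask_edges = TRUE` available.

Domain boundaries are called by deterministic run-segmentation of the DI
sign rather than the original three-state hidden Markov model: a domain
opens at the first bin of a sustained positive run and closes at the last
bin of the sustained negative run(s) preceding the next positive run.
Two parameters govern robustness:

* `sustain` (default 2 bins = 80 kb): minimum run length for a sign run to
  count, suppressing single-bin sign flips;
* `noise_floor` (default $0.2 \times \mathrm{median}|DI|$ over non-zero
  bins): absolute-DI values below it are treated as zero and bridge
  same-sign runs.

The run-based caller is exactly reproducible, has two interpretable
parameters, and on simulated matrices with planted domains (enrichment 5,
depth $10^6$ per chromosome) recovers over 90% of borders within one bin —
the property the test suite enforces. An HMM backend could be added behind
the same interface without disturbing callers.

Border comparison is directional (each border of set A to the nearest
border of set B), matching how border reorganization between two specific
conditions is quoted; ties break toward the lower coordinate, and a border
counts as "changed" at a shift of at least one bin (40 kb). Statistics
(mean/min/max) summarize the changed borders only, so the minimum equals
the threshold by construction whenever any border changed exactly one bin.

## Hierarchical paired-t differential grid

Loops are assigned to fine-bin pairs by their two anchor midpoints — a
single, unambiguous assignment per loop — then fine pairs are grouped into
coarse cells (default geometry: 100 kb fine within 1 Mb coarse
genome-wide, i.e. 100 values per full cell; 1 kb within 10 kb at loci).
Diagonal coarse cells keep only upper-triangle fine pairs so no value is
tested twice; their $n$ is therefore 55 rather than 100, and the t-test
uses the cell's own $n$.

Paired t-tests run per cell on the condition-2 minus condition-1
differences. Degenerate cells are handled explicitly: all-zero differences
give $p = 1$ (no evidence of change, not missing evidence), while
constant non-zero differences are flagged `degenerate` with $p = 0$.
Multiplicity handling differs by scale, and both modes are first-class:
genome-wide grids default to *no* Bonferroni correction (at millions of
cells the correction is uninformative; glyph scaling by $p$ is the
intended rendering), while locus-scale and border-aligned analyses default
to Bonferroni, which is what the differential-loop renderer and the
acceptance checks use. Under a shared Poisson background with dense cells
the per-cell test is calibrated: 3–7% of cells reach $p<0.05$, a property
the suite asserts on 2080 cells of 100 pairs.

Differential loops keep only positive-delta cells per condition, annotate
the statistic on the strongest delta per midpoint, and — when an aligned
TAD context is supplied — drop loops reaching past the midpoint of a TAD
containing one of their ends, so left- and right-border features never
average together.

The top-N network ranks favored cells by mean fine-pair strength in the
favored condition (ties by coordinates), with two optional retention
filters (a 95th-percentile floor and the "omit average strength > 1"
display exclusion — implemented with exactly that semantics but off by
default, since it is a display-scale rule, not a statistical one). Degree
and local clustering coefficients are computed from the adjacency matrix
in-package; igraph serves only as an independent oracle in the tests.

## Pile-ups, orientation and masking

All aligned analyses share one container: a loci × offset-bin matrix with
an explicit logical mask. The invariant the whole module is built around
is that *masked cells never enter any summary* — column means, row means,
correlations — which the tests enforce with sentinel values. Masks arise
from chromosome edges and from the TAD-midpoint truncation rule: at a
border-aligned view, positions past a TAD's own midpoint belong to the
other border's neighborhood and are excluded.

DiffTAD orientation uses the length-normalized sum of strand-directional
spans (plus-strand genes contribute $+\mathrm{length}$, minus-strand
$-\mathrm{length}$) of the significantly regulated, direction-consistent
genes ($q < 0.05$) in each TAD; reverse-oriented TADs are coordinate-
flipped before alignment. A TAD with no qualifying gene keeps the forward
orientation and is flagged (`default_orientation`), so downstream code can
drop or inspect those rows; silently guessing an orientation seemed worse
than an explicit flag.

Same-size stacking (default 200 TADs of 480 kb ± one bin) sorts rows by
mean anchor strength and correlates the 5-TAD-binned sort attribute with
each other attribute's binned means — Pearson's $R$ and $R^2$. The
five-per-point binning for row and column means matches the reporting
granularity used throughout (5 × 1 kb = 5 kb column points, 5-TAD row
points).

Z-score enrichment uses the sample (n−1) standard deviation over all bins
of the profile, two-tailed normal $p$, and tiers at 0.05/0.01/0.005; a
constant profile returns $p = 1$ everywhere rather than NaN. Positional GO
profiles compute per-bin category ratios with a *per-bin* denominator
(category genes / all genes in the bin), gene-free bins contributing 0
before zero-centering — this keeps profiles summable and exactly
zero-mean; a per-span denominator is available since the ratio's intended
denominator is ambiguous.

The motif resampling scanner samples fixed-width subsequences uniformly
within each 10 kb offset bin (pooled over borders), counts PWM hits at a
log-odds threshold of 80% of the maximum score (or exact k-mer matches),
averages per-bin counts over iterations, drops motifs counted ≤ 10 times
in total, and Bonferroni-adjusts the per-motif z-derived $p$ by the number
of motifs retained. De novo discovery is out of scope: the scanner is
pluggable over supplied matrices. The protocol-scale sampling effort
(50 iterations × 10 repeats × 1000 samples) is configurable; tests and the
acceptance script run 4 × 2 × 400, which is ample at the planted effect
sizes.

## Two-window features and class prediction

For each center bin, an attribute's mass is summed over the bins fully
inside an inner and an outer window (windows are whole numbers of bins;
for even bin counts the center bin sits at position $\lceil k/2 \rceil$)
and divided by the window width, giving concentrations in $[0,1]$ for
span attributes. Centers whose outer window leaves the chromosome are
dropped rather than padded.

FPKM class boundaries are $[0,1)$, $[1,30]$, $(30,\infty)$ — the verbal
"<1, 1–30, >30" scheme leaves both endpoints of the middle class open, and
closing them on the middle class keeps the three classes a partition.
Interaction classes split at the mean score with ties to the lower class.

Two classifiers sit behind one interface: the default is a feed-forward
network with seven ReLU hidden layers (64, 24, 24, 12, 12, 10, 8 nodes)
and a softmax output, trained with Adam at a fixed seed (optimizer, epochs
and batch size are exposed configuration, since only the architecture is
fixed by the method); `method = "multinom"` selects a
multinomial-logistic model whose fit is deterministic given the split, and
is the surface used by acceptance checks, since even seeded network
training is fragile to floating-point reordering. PCA of the binned genome
is a thin `prcomp` wrapper — correlations are read from loadings, and only
orthonormality of the rotation is asserted.

## qPCR quantification

The three formulas are implemented exactly as defined on the CT scale,
including the double multiplication in the 3C percent-input form
(`[100 · 2^(ΔCT)] · 100`) — altering the constant would silently rescale
every downstream number. No normalization beyond the stated reference CT
is applied. Technical replicates are averaged within biological replicate
first, then biological replicates are summarized; the order is stated
nowhere, so the package fixes the conventional one and documents it.
Fisher's LSD uses the pooled residual mean square of the condition ×
treatment ANOVA; in a single-factor two-group design it reduces exactly to
the pooled-variance t-test, which the tests verify. Fold-change SEMs use
the delta method on the ratio of means.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` plants, per condition: TAD partitions drawn from a
size range (default 240–960 kb, inside the 120 kb–4 Mb range typical of
mammalian domains, rounded to 40 kb); a fraction of interior borders
(default 0.38, a realistic share of reorganized borders for a
differentiation transition) shifted by 1–5 bins in the
second condition; loop scores as Poisson counts around a truncated
power-law distance decay ($\alpha = 1$ by default) multiplied by
within-TAD (×3), border-proximity (×3) and planted differential (×4)
enrichments, with the total expected mass equal to `read_depth`
(default $10^6$); FDR q values as Benjamini–Hochberg over Poisson
upper-tail p-values against the decay-only background; border-enriched
binding peaks (×5 density within ±20 kb of borders); genes whose log2 fold
change adopts their TAD's latent sign with probability 0.8; GO labels with
a per-TAD dominant category; and simple structural annotations (promoters,
exons, UTRs, CpG features, enhancers, intergenic complement). Every output
file draws from its own RNG stream derived from the master seed, so a
fixed seed reproduces every file byte-identically and adding an output
never perturbs the others.

Defaults were chosen once as plausible study conditions at desk scale
(2 chromosomes × 20 Mb, 20 000 loops, 2 000 genes) and are not tuned to
test outcomes. What the generator does **not** emulate: restriction-
fragment structure, read-level noise, copy-number and mappability
artifacts, inter-chromosomal truth structure beyond uniform background,
distance-dependent loop-size distributions, or realistic gene models.
Passing tests therefore demonstrate that the implementations compute their
statistics correctly and recover planted structure of the stated effect
sizes — not that the pipeline is robust to every artifact of real
sequencing data. Loop scores are treated as count-like (valid-pair
semantics) throughout; the upstream loop caller's score definition is not
restated by its documentation, and this assumption is the single place it
enters.

## Problem sizes and numerical conventions

The test suite and acceptance script use: one 12 Mb chromosome at 40 kb
bins (≈ 20 planted TADs, depth $10^6$) for TAD recovery; a 65 Mb
chromosome at 100 kb/1 Mb geometry (2 080 off-diagonal cells × 100 pairs)
for null calibration and planted-cell recovery; 200 stacked TADs of
480 kb over 20 (tests) or 10 (script) seeds for the correlation-recovery
check; 600 kb of synthetic sequence over 5 seeds for motif detection; and
6 000 bins for the prediction check. These sizes were chosen so every
statistical property is measured with comfortable margins while the whole
suite runs in a couple of minutes on one core.

Ties and degenerate inputs are resolved deterministically everywhere:
nearest-border ties toward the lower coordinate, ranking ties by
coordinates, class-boundary ties to the lower class, zero-variance cells
and constant profiles to $p = 1$. All randomness flows through explicit
seeds; no function consults the global RNG state without restoring it.

## Known limitations

* The run-segmentation TAD caller has no notion of nested or overlapping
  domains and no compartment (A/B eigenvector) analysis.
* Matrix balancing (ICE/KR) is not implemented; inputs are assumed to be
  comparably processed before binning.
* The paired-t grid tests cells independently; spatial correlation between
  neighboring cells is not modeled.
* The network module computes degree and local clustering only — not the
  full report of a general graph-analysis tool.
* Interaction-directionality profiles at loop midpoints reuse the Dixon
  DI computed from binned loop scores; a formally distinct per-midpoint
  directionality statistic is not defined.
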