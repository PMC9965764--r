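---
title: "Methods: untargeted chemotaxonomy with chemophen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted chemotaxonomy with chemophen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Chemotaxonomy classifies organisms by their metabolite profiles. The
pipeline implemented here takes an untargeted LC-MS/MS study — a few taxa,
a few biological replicates each — and asks two questions: (1) which
variables (molecules, compound classes, superclasses, molecular
descriptors) distinguish the taxa, and (2) how congruent is a tree built
from chemical distances with a reference DNA phylogeny. The stages are
conditioning, ontology projection, chemodiversity, supervised marker
selection, tree building and congruence testing, plus an optional linkage
of phenotype-image spectra to compound-class composition.

## Conditioning choices

**Log transform.** Intensities are transformed with `ln(1 + x)`. The
field's convention is "log-transform and impute missing values with
zeros"; `ln(1 + x)` makes imputed zeros and true zeros coincide at exactly
0 and avoids `-Inf`. The choice of logarithm base cannot change any
topology-level result: switching to base *b* rescales every Euclidean
distance by `1/ln(b)`, and complete-linkage topology and the Mantel
statistic are invariant under positive rescaling of a distance matrix (a
property the test suite asserts).

**Presence calls.** A value is absent when it is below 10⁻⁸ % of the
median of all non-zero raw abundances. The median is global rather than
per-feature: it is the simpler reading, and it makes the call invariant to
rescaling the whole table. "Below" is strict; a value exactly at the
threshold is present.

**Retention-time filter.** Strictly earlier than 1020 s, applied before
anything else; late-eluting signals are column-wash artefacts.

**Ion-mode joining.** Positive- and negative-mode tables are joined after
prefixing feature ids (`pos_`/`neg_`). The compatibility check compares
the medians and variances of the non-zero entries of the two tables via
the relative deviation `|a − b| / ((a + b)/2)` on whatever scale the
supplied tables are on (recorded in the result); if either exceeds 10% the
join proceeds with a prominent warning rather than aborting — the check is
a gate that is expected to pass on comparable acquisitions, and aborting
would hide the diagnostic from the user.

## Ontology projection

Each annotated feature carries one root-to-class path through the
single-parent ontology. "Aggregating classes and multiplying by
precursor abundances" is implemented as: a feature contributes its
abundance once to every term on its path restricted to the requested level
(`most_specific`, `superclass`, or `all`). This single definition yields
both the subclass- and superclass-level analyses, and at `level = "all"`
it conserves the hierarchy: a parent's column equals the sum of its
children plus the contributions of features whose most specific class is
the parent itself. Whether raw or log abundances enter the projection is
recorded in the result; the default follows the processing order (log).
The descriptor table is the plain matrix product `D = A · X` with no
normalization — no weighting is defined for it, so none is invented.

## Chemodiversity

Shannon `H'` uses the natural logarithm (the sources cite standard
ecology texts without fixing a base; Pielou's `J = H'/ln(richness)` is
base-invariant anyway). `J` is undefined below richness 2 and returned as
`NA` with a note. A variable is "unique" to a taxon when it is present in
at least one replicate of that taxon and in no replicate of any other; the
stricter all-replicates rule is available (`rule = "all"`). Group
comparisons use `stats::aov` + `TukeyHSD`.

## PLS-DA marker selection

The model is PLS2 fitted by the NIPALS recurrence on autoscaled variables
(centered, unit variance; constant columns are centered only and receive
zero weight automatically) against the centered one-hot class matrix. The
component count is chosen in `1..max_components` by stratified
cross-validated accuracy with ties resolved toward fewer components.

Importance is VIP: `VIP_j = sqrt(p Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a)`,
where `SSY_a` is the response variance captured by component *a*. The
per-class columns reweight by each class's own `SSY_{a,k} = (tᵀt) q_{a,k}²`.
Every column obeys `Σ_j VIP_j² = p`, which the tests use as an anchor. The
library routine the field commonly wraps does not document its importance
formula; VIP is closed-form, standard, and testable, so it is the
implementation here.

Selection takes, per class, the variables **strictly above** the 0.995
empirical quantile (type-7 linear interpolation) of that class's
importances, then unions the classes; a pooled-quantile variant is a flag.
Two consequences deserve emphasis:

* The selection fraction is 0.5% per class by construction. On a table of
  1000 variables that is exactly 5 per class; on 300 variables it is at
  most 2 per class. When more markers are truly present than the quantile
  admits, recall against that ground truth is bounded accordingly — a
  property of the quantile rule, not of the data.
* Autoscaling caps a marker's scaled class contrast near `1/sqrt(p(1−p))`
  (~2.3 for one taxon in four) regardless of its fold change, while the
  chance contrasts of noise variables shrink only with replication. With
  3 replicates per taxon the two are comparable and selected sets mix
  markers with lucky noise variables; with ~6 replicates the planted
  markers dominate cleanly. The test suite exercises both regimes.

Evaluation clamps the requested 10 folds to
`min(k, smallest class size × #classes, n)` — 10-fold requests on 12
samples are honoured only as far as the design allows, and the k actually
used is returned. Accuracy pools held-out predictions; R² is `1 −
SSE/SST` of one-hot responses against the full model's fitted values;
ROC-AUC uses the rank (Mann-Whitney) identity with average ranks on ties,
and PR-AUC is average precision; multiclass summaries are one-vs-rest
macro averages.

## Trees and congruence

Tips are taxa: replicate rows are averaged (mean by default, median
optionally) before Euclidean distances, matching species-level trees.
Complete-linkage agglomeration is implemented directly so its tie-break is
specified: among equal-distance merges the lexicographically smallest
label pair merges first (clusters are named by their smallest member).
Merge heights become node heights, so the result is exactly ultrametric.

Cophenetic conventions differ by tree kind and each tree uses its own:
merge height of the lowest common ancestor for dendrograms, tip-to-tip
path length for phylograms. Both are valid dissimilarities, and the
Pearson correlations used downstream absorb the factor-of-two difference
for ultrametric trees. A consequence worth knowing: for 3-tip ultrametric
dendrograms the lower-triangle Pearson correlation can only be 1 (same
topology) or −0.5 (different topology); intermediate values such as 0.5
require other conventions (diagonal inclusion, full-matrix correlation)
that are deliberately not adopted here.

The Mantel statistic is the Pearson correlation of lower-triangle vectors
after aligning labels. For significance, rows/columns of the second
matrix are permuted jointly; when `n! ≤ n_perm + 1` the permutation
distribution is enumerated **exhaustively** and `p = #{M* ≥ M}/n!`
(identity included), which makes p-values at 3-6 taxa exact and
deterministic; otherwise `n_perm` random permutations give the usual
`(1 + hits)/(n_perm + 1)` estimate.

## Image spectra and dbRDA

Images are quantized to 8 bits; pixels exactly (0,0,0) or (255,255,255)
are segmentation background ("pure white" is read on the normalized scale,
i.e. 255 per channel) and are dropped before the three 256-bin channel
histograms are computed and normalized. The concatenated 768 frequencies
are the spectral trait vector.

dbRDA computes PCoA on the Gower-double-centered `−D²/2`, drops negative
eigenvalues (recording their relative mass; Euclidean input produces
none), and regresses the coordinates on centered constraints. With
Euclidean distances the constrained-inertia fraction equals the classical
RDA multivariate R² — the identity serving as the module's primary test
oracle, with vegan as an independent cross-check. Forward selection adds,
at each step, the candidate with the largest inertia gain if its
permutation p (response rows permuted) is at most `alpha`; an adjusted-R²
stopping rule was considered and not adopted, to keep a single documented
inclusion criterion. Envfit-style goodness of fit is the R² of the
least-squares regression of a variable on the first two constrained axes,
with a permutation p.

## The synthetic-data generator

`synth_generate()` draws, per feature, a baseline `u_f ~ N(0,1)` around a
grand mean `ln(1e5)`; species effects evolve by Brownian motion along a
species tree (variance `σ_b² ×` branch length; default tree: random
labelled topology with unit branches); planted markers add `ln 4` to one
taxon; replicate noise is `N(0, σ_e²)`; intensities are exponentiated.
Defaults mirror a small-clade-plus-outgroup design: 4 taxa × 3
replicates, 300 features, 60% annotated, 10 markers per taxon, `σ_b =
0.5`, `σ_e = 0.3`, 30% negative-mode features.

Missingness is modelled as missing-completely-at-random zeroing of
intensities, **off by default**. The reason is quantitative: a zero at a
log-baseline of ~11.5 contributes noise of magnitude ~11.5 to that cell
after the log transform, so even a 5% rate injects per-feature noise an
order of magnitude above `σ_e = 0.3` and swamps the structure the
configured noise knobs are supposed to govern. Keeping dropout opt-in
makes `σ_b` and `σ_e` the actual noise parameters of generated data;
analyses that want missingness (e.g. the presence/absence and sunburst
demonstrations in `analysis/`) enable a low rate explicitly. No
intensity-dependent dropout model is provided.

What the generator does **not** emulate: adduct/isotope redundancy among
features, retention-time structure, batch and injection-order effects,
intensity-dependent censoring, correlated annotation errors, or realistic
descriptor covariance (descriptors are class means plus unit noise).
Passing tests therefore demonstrate correctness of the computations and
recoverability under the stated statistical structure — not performance
on real acquisitions.

Reference images are synthetic by construction: per sample, the mean of
each colour channel over retained pixels is `min(1, 0.04 · log2(1 + Ā_c))`
with `Ā_c` the sample's mean abundance in one of three designated leaf
classes, plus a black and a white border row. Doubling a class abundance
shifts its channel by 0.04, which gives the image→dbRDA chain a known
planted signal.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; the pipeline
  orchestrator derives per-stage substreams so toggling one stage does not
  change another's results, and two runs with the same seed are
  byte-identical.
* NIPALS converges at a relative score change of 1e-12 (cap 500
  iterations); component extraction stops early when residual variance
  vanishes (perfect fits).
* Symmetry of distance matrices is required at 1e-12; ultrametricity is
  checked at 1e-9 relative; negative PCoA eigenvalues below 1e-10 of the
  spectrum maximum are treated as zero.
* Degenerate inputs fail loudly and early: all-zero tables (undefined
  median), single-sample classes (unstratifiable), star trees
  (zero-variance cophenetics return `NA`), empty selections (error with
  advice), images that are entirely background.
* Test and script problem sizes are desk-scale by design: 4-8 taxa, tens
  to hundreds of features, 10-20 generator seeds per stochastic property.
  These sizes keep every property check exact or well-powered while the
  whole suite runs in seconds.

## Known limitations

* The 0.995-quantile rule is a fixed-fraction selector; it does not adapt
  to the true number of markers (see above) and provides no error control.
* With 3 replicates per class, CV-based component selection and the
  VIP ranking are noisy; results on such designs should be read as
  exploratory, exactly as small-n metabolomics warrants.
* Aggregating to classes/superclasses averages away much of the
  tree-structured signal at desk scale; congruence statistics at
  aggregated levels are correspondingly weaker than at the molecule
  level.
* The Mantel permutation test at 4 taxa has only 24 distinct relabelings;
  the smallest achievable p is 1/24, and exact ties at M are counted
  conservatively.
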