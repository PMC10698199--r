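---
title: "Metabolic covariance parcellation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance parcellation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covparc)
```

## The problem

Fluorodeoxyglucose PET measures regional glucose metabolism. Across a
cohort of subjects, two brain locations whose uptake values rise and
fall together are said to *co-metabolize*; this across-subject
covariance is treated as evidence of network-level coupling. covparc
parcellates a seed structure — the hippocampus in the motivating
application — into subregions with distinct co-metabolism profiles, and
then carries those subregions through the downstream analyses a study
of this kind needs: group statistics on subregional uptake, seed-based
whole-brain network maps, spatial association of those maps with
external reference maps, and regional gene expression matrices built
from donor microarray tables.

Because the real inputs (a large multi-site PET cohort, donor
microarray data, meta-analytic term maps, receptor maps) cannot be
redistributed, the package ships a synthetic-data module that emulates
the statistical structure every stage consumes. All tests and the
reproduction script run offline on those synthetic inputs.

## Preprocessing model

Volumes are assumed registered to a common space. The package applies
only the steps downstream of registration:

* **Reference (pons) normalization.** Every voxel is divided by the
  mean uptake in a reference mask, making uptake a dimensionless ratio
  with mean 1 inside the reference. The operation is idempotent and
  scale-invariant, which the tests assert.
* **Resolution quality control.** A subject passes when the *largest*
  native voxel dimension is at most `max_mm` (default 2 mm). Applying
  the cut per axis is our reading of an "image resolution ≤ 2 mm"
  criterion; it is the strictest monotone interpretation.
* **Atlas combination.** A 400-region cortical scheme and a 54-region
  subcortical scheme are merged by shifting subcortical labels by an
  offset (default 400). Where both atlases claim a voxel the
  subcortical label wins — equivalent to zeroing the cortical label
  there — to avoid artificial correlation between overlapping parcels.
* **Biomarker classification.** CSF cut-offs: amyloid-beta(1–42)
  977 pg/mL (positive below), p-tau 24 pg/mL and t-tau 266 pg/mL
  (positive above). How the three cut-offs combine into one status is
  genuinely open; our default calls a subject positive when amyloid is
  positive AND at least one tau marker is positive, which matches the
  usual A/T biomarker semantics. The rule is configurable and recorded
  in the output's attributes, so analyses can state exactly which rule
  produced their grouping.

## Covariance profiles and clustering

For seed voxel $v$ and parcel $p$, the profile entry is the Fisher
transform of the Pearson correlation across subjects:

$$z_{vp} = \operatorname{artanh}\big(\operatorname{clip}(r_{vp},\ \pm(1 - 10^{-7}))\big).$$

Clipping keeps perfect correlations finite; unbounded entries would
break the Euclidean distances k-means relies on. Zero-variance voxels
or parcels are an error by design — silent `NaN`s propagate too far —
so degenerate columns must be masked explicitly upstream. Inside
bootstrap replicates, where resampling can manufacture degeneracy, the
offending columns are dropped from that replicate with a warning
instead.

Stability comes from a subject-level bootstrap (500 replicates in the
original analysis). Each replicate's profile matrix is clustered with
Euclidean k-means (best of many random initializations by
within-cluster sum of squares; the reference configuration uses 500
restarts and an iteration cap of 255). The clustering kernel is a
compiled Lloyd iteration with random-row initialization; restarts that
converge to an empty cluster are re-initialized. It draws its
initializations from R's RNG, so every run is reproducible under
`set.seed()`.

Bootstrap labelings are only defined up to label permutation, so before
any voting each replicate is aligned to the clustering of the
non-resampled sample by solving the assignment problem on the k×k
contingency table. The consensus assigns each voxel its most frequent
aligned label; ties break to the smallest label id so the pipeline is
deterministic.

## Choosing k by split-half stability

For each candidate k, subjects are repeatedly split into random halves;
the full covariance → k-means → bootstrap-consensus chain runs
independently in each half, and the adjusted Rand index (ARI) between
the two half parcellations is recorded. The stability of k is the mean
ARI across splits, and the selected k maximizes it (exact ties go to
the smaller k).

One subtlety surfaced while validating this curve. When k exceeds the
number of genuinely distinct profiles, the mode consensus tends to
empty the surplus cluster: the weakly supported split flickers across
bootstrap replicates and the vote collapses both halves onto the same
lower-order partition, which then agree almost perfectly. Left
unhandled, the stability curve is flat above the true k and the
selection is decided by noise. Since a parcellation is only a valid
k-level solution when all k clusters are nonempty, a split in which
either half's consensus collapses is scored at chance level (ARI 0)
for that k. With this rule the curve drops sharply above the supported
k, which is the behavior a stability criterion should have.

Defaults: the reference number of splits is 10,000, as in the
motivating study; desk-scale analyses and the package's own tests use
100, which the planted-structure experiments below show is ample to
separate the candidate levels. Within splits each clustering uses 5
random restarts and each half 50 bootstrap replicates — enough to make
the consensus stable at the within-half sample size while keeping a
100-split run around half a minute on one CPU.

## The synthetic cohort generator

The generator plants the structure the analysis assumes rather than
simulating scanner physics. With `k_true` clusters, each cluster $c$
carries a latent factor $f_{sc} \sim N(0,1)$ per subject $s$. A seed
voxel in cluster $c$ has uptake

$$x = \mu + \delta_{g(s)} + \lambda f_{sc} + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

with baseline $\mu = 1.2$ (a typical pons-normalized grey-matter
level), additive diagnosis-group shifts $\delta_g$ (defaults 0, −0.02,
−0.06, −0.12 for the control, early, late and dementia groups — small
monotone decreases of a few percent, qualitatively matching the
group-by-region findings such data show), loading $\lambda = 1$ and
noise $\sigma = 0.5$. Each cluster also owns a disjoint set of parcels
(6 of 60 by default) sharing the same factor; remaining parcels are
independent noise. CSF biomarker values are drawn per group around the
published cut-offs so that the classification step produces realistic
mixtures. Every generator is a pure function of its configuration and
seed.

What this emulates well: the across-subject covariance structure, its
sampling noise at realistic cohort sizes, group shifts, and the
probe/sample bookkeeping of donor expression tables (probe-to-gene
multiplicity, missing annotations, background flags, spatial
gradients). What it does not emulate: spatial point-spread and
partial-volume effects, site heterogeneity, registration error, or
anatomically shaped clusters (planted clusters are index blocks with no
spatial contiguity). Passing tests therefore certify the statistical
machinery, not robustness to those acquisition artifacts.

At the reference conditions (100 subjects, 200 seed voxels, 60
parcels, planted k = 5, loading 1, noise 0.5) the full chain recovers
the planted labels with ARI ≥ 0.95 and the split-half curve selects
k = 5; both are asserted in the acceptance tests, and
`scripts/acceptance.R` recomputes them from scratch.

## Group statistics

Subregional uptake tables are long tibbles (subject × subregion). The
two-way model is the crossed fixed-effects ANOVA
`uptake ~ subregion * group` — the degrees of freedom reported for
designs like 846 subjects × 5 subregions × 4 groups (corrected total
4229, interaction 12) imply exactly this model, with subregion treated
as a crossed factor rather than a repeated measure; we reproduce that
and note it as a modeling simplification. Unbalanced designs use
partial (Type II) sums of squares by default, Type III by option. Post
hoc pairwise group comparisons run within each subregion under
Tukey–Kramer familywise error control (the standard post-ANOVA choice
for pairwise means; Bonferroni available). The anterior–posterior
delta is the per-subject difference between the mean uptake of a
configurable anterior subregion set and a posterior set; which
subregions count as anterior or posterior is an anatomical labeling
decision made after inspecting a parcellation, so the sets are
explicit arguments, not defaults.

## Network maps and spatial association

For each subregion, the network map regresses every parcel's uptake on
the subregion's per-subject mean (ordinary least squares, optional
covariates). Without covariates the reported T equals the correlation
t, $T = r\sqrt{(n-2)/(1-r^2)}$, a closed form the tests check to
1e-10. Benjamini–Hochberg FDR at q < 0.05 flags the map's significant
parcels, assuming independence/PRDS across parcels; the unthresholded
T map is always retained because the spatial association stage
consumes it whole.

Association with reference maps (term maps, receptor maps, gene-set
expression maps) happens at the region level: maps are reduced to one
value per atlas region, correlated by Pearson (optionally partialling
out a shared spatial covariate such as a grey-matter probability
profile), Fisher-transformed, and compared against a permutation null.
The null construction was left open by the source description; the
default surrogate draws candidate permutations of the region values
and keeps, per null map, the candidate whose empirical variogram along
the region ordering best matches the observed map's — preserving
spatial autocorrelation approximately, in the spirit of
variogram-matched surrogates. A plain shuffle mode exists for
comparison and for calibration tests. Significance uses a one-sample t
test of the observed Fisher-z values against the null mean, BH
corrected across reference maps; a permutation-tail p is reported
alongside and stands in whenever only a single observed z exists. Term
decoding retains reference maps with r strictly above 0.1, sorted by
correlation; it operates on region-aggregated values because the
package carries no voxelwise meta-analytic store.

## Donor expression matrices

The transcriptomic chain follows the standard donor-microarray
workflow: drop probes without a valid Entrez id; discard probes below
background in ≥ 50% of pooled samples (discard at exactly half); pick
one probe per gene by differential stability

$$\Delta S(p) = \binom{N}{2}^{-1}
  \sum_{i<j} \rho\big(B_i(p), B_j(p)\big),$$

the mean Spearman correlation of the probe's regional pattern over all
donor pairs (ties in ΔS break to the lexicographically smallest probe
id). Samples are assigned to the nearest region representative under
hemisphere and gross-division constraints, with assignments beyond the
donor mean + 2 SD removed; distances are to region centroids — the
volume-native analogue of surface-vertex matching, which would need
meshes the package does not carry. Regions no donor sampled are filled
from each donor's nearest sample, averaged across donors with
inverse-distance weights, and flagged imputed.

Normalization is the robust sigmoid
$x_{norm} = \big(1 + \exp(-(x - \langle x\rangle)/\mathrm{IQR}_x)\big)^{-1}$
with $\mathrm{IQR}_x$ the interquartile range divided by 1.349 (the
normal-consistent scale; the divisor is configurable), followed by
rescaling to the unit interval — applied across genes within each
sample, then across samples within each gene, in that order. A zero
IQR yields the constant 0.5 with a degeneracy flag rather than an
error, since constant rows occur legitimately in small or noiseless
inputs. Finally, samples are averaged within regions per donor and
then across donors; an optional hemisphere restriction supports the
common case where one hemisphere is too sparsely sampled to keep.
Gene-set maps average the normalized expression of the set's genes
(case-insensitive symbol matching) per region and feed straight into
the spatial association stage.

## Numerical choices, degenerate inputs, limitations

* Correlation clipping at $1 - 10^{-7}$; GLM T clipped at $10^8$ for
  exact fits (p underflows to 0 there anyway).
* All ties break deterministically: consensus votes to the smallest
  label, k selection to the smallest k, probe selection to the
  smallest id.
* Empty design cells, rank-deficient GLM designs, zero-variance
  columns and empty reference masks are errors that name the offender;
  missing parcels and unassignable samples are flagged and propagated,
  never imputed silently.
* Problem sizes in the tests and the reproduction script: cohorts of
  40–100 subjects, 60–200 seed voxels, 24–60 parcels, 100 stability
  splits, 25–100 bootstrap replicates, 1000 calibration replicates.
  These sizes separate all the planted effects cleanly at desk scale.
* Not implemented by design: registration/segmentation/smoothing and
  partial-volume correction (inputs are assumed preprocessed),
  voxel-to-voxel covariance, spatial contiguity constraints in the
  clustering, mixed-effects alternatives to the crossed ANOVA, live
  access to meta-analytic or donor-atlas services, and enrichment
  statistics for gene sets.

## A small worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_subjects = 60, n_parcels = 30,
                        n_seed_voxels = 80, k_true = 3)
cohort <- generate_cohort(cfg, seed = 7)

stab <- split_half_stability(cohort$seed_uptake, cohort$parcel_uptake,
                             ks = 2:5, n_splits = 50,
                             n_boot_per_half = 25, seed = 8)
stab$selected_k
autoplot(stab)

parc <- consensus_parcellation(cohort$seed_uptake, cohort$parcel_uptake,
                               k = stab$selected_k, n_boot = 100, seed = 9)
adjusted_rand_index(parc$labels, cohort$truth$voxel_labels)

uptake <- subregion_means(cohort$seed_uptake, parc,
                          subjects = cohort$subjects)
two_way_anova(uptake)
```
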