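---
title: "Methods: an untargeted LC-Q/TOF polyphenol profiling workflow"
author: "rubusmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an untargeted LC-Q/TOF polyphenol profiling workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`rubusmet` re-implements, as tested and reusable R code, the data-processing
workflow of an untargeted UHPLC-Q/TOF metabolomics study of raspberry
(*Rubus idaeus* cultivars Glen Ample, Tulameen, Fall Gold; *R. occidentalis*
cultivar Jewel) fruit (poly)phenols: ion-mass arithmetic and isotope
modelling, replicate feature alignment, nonparametric feature selection,
rule-based MS$^2$ annotation against a built-in 68-compound knowledge base,
and genotype chemometrics. Raw instrument data for the original study are
not deposited anywhere, so the package ships a synthetic-cohort generator
with known ground truth; every pipeline stage is validated against that
ground truth and against the printed reference tables.

## Ion-mass arithmetic

All exact masses are sums of IUPAC lightest-isotope masses (`mass_constants()`),
with the proton mass 1.0072765 Da (H-atom mass minus the electron mass).
Three ion conventions cover the data:

* deprotonated ions $[M-n\mathrm{H}]^{n-}$ (negative ESI, $n \le 3$ for the
  large ellagitannins): $m/z = (M - n\,m_p)/n$;
* protonated ions $[M+\mathrm{H}]^+$: $m/z = M + m_p$;
* intact flavylium cations $[M]^+$ (anthocyanins): the plain atomic sum of
  the cation composition, with **no** electron correction. This is the
  convention under which the tabulated anthocyanin exact masses (e.g.
  611.16121 for C$_{27}$H$_{31}$O$_{16}^+$) reproduce exactly; the electron
  mass (0.00055 Da) is below the 5-decimal print precision but applying it
  would shift every cation mass visibly at the ppm level.

"MW" statements for large ellagitannins (1569 Da, 1721.2 Da) are *average*
masses over conventional standard atomic weights, not monoisotopic masses;
`average_mass()` exists for exactly this distinction, and charge
deconvolution (`neutral_mass_from_mz()`) returns the monoisotopic
reconstruction (e.g. $2 \times 551.0433 + 2 m_p = 1104.10$).

Isotope patterns are aggregated (nominal-resolution) distributions from
iterative per-element convolution, pruned at $10^{-5}$ relative abundance;
peak $k$ sits at $(m + k\,\Delta_{13C})/z$ with $\Delta_{13C} = 1.0033548$ Da.
Fine isotopologue structure is deliberately not resolved — the alignment
criterion consumes only the $(A{+}1)/A$ ratio, which is also the only ratio
reliable at realistic TOF intensities. Charge inference accepts the nearest
integer $z$ of $\Delta_{13C}/\mathrm{spacing}$ when within 0.1, up to $z = 3$.

## The knowledge base and its discrepancy flags

`load_knowledge_base()` returns the 68 annotated compounds (49 negative-mode,
19 positive-mode) with class, composition, ion species, retention time,
observed $m/z$, fragment lists (base peak flagged), MSI-style level, standard
availability and per-cultivar presence. On load every record is revalidated:
the theoretical $m/z$ is recomputed from the formula and must lie within
5 ppm of the observed value.

Thirteen records carry a frozen `discrepancy` flag because their printed
values are internally inconsistent (a formula that does not reproduce the
printed exact mass, digit transpositions, or a $\Delta$ ppm that matches
neither the rounded nor the unrounded reference). For these
"mass"-discrepant records the *tabulated exact mass* is kept as the matching
reference (`reference_mz`), on the grounds that the formula transcription,
not the measured ion, is the corrupted field. One record (peak 68) also has
typo-level fragment values; it is flagged `"fragments"` and excluded from
the golden level-flag check. The flag set itself is part of the package's
golden fixtures and is asserted by the test suite, so any edit to the
knowledge base that changes which rows reproduce is caught.

The neutral-loss dictionary (hexose 162.0528, deoxyhexose 146.0579,
aldopentose 132.0423, deoxyhexose-hexoside 308.1107, sophorose 324.1056,
galloyl-hexose 332.0743, HHDP 302.0063, CO$_2$, H$_2$O, methyl, methoxy,
acetyl, retro-cyclization) is defined by molecular formula, not by nominal
integer, so exact and nominal matching modes stay consistent. Diagnostic
ions cover the aglycone chemistry of every class: ellagic acid 300.9990 for
ellagitannins, $[Y_0]^-$/$[Y_0-H]^{\bullet-}$ pairs for quercetin and
kaempferol glycosides, (epi)catechin and quinone-methide ions for flavanols,
and the flavylium aglycones (cyanidin 287.0556, pelargonidin 271.0606,
delphinidin 303.0505, peonidin 301.0712) for anthocyanins.

## Alignment

`align_features()` pools per-run centroided feature lists, sorts by
retention time and $m/z$ (making the result independent of run order), and
greedily assigns each feature to the nearest existing cluster centroid that
keeps the cluster within both tolerances, ties broken by smallest ppm
distance. Joining requires the cluster's *total* tR spread to stay within
`rt_tol`, so the 0.05 min criterion holds by construction rather than only
pairwise. Centroids are intensity-weighted means — the original software's
choice is not documented, and weighting by intensity is the conservative
option because high-intensity measurements carry the smaller relative mass
error. The four acceptance criteria are: accuracy < 5 ppm, isotope-ratio
deviation < 20% (applied only when both an observed and a theoretical
$(A{+}1)/A$ are available), MS$^2$ purity >= 80% (applied only when spectra
exist in at least two runs), and tR tolerance <= 0.05 min. Purity is the
cosine similarity of tolerance-matched, intensity-normalized peaks, the
field-standard definition; the vendor score it stands in for is not
published. Failing or singleton clusters are emitted flagged, not silently
dropped.

## Feature selection

The cascade follows the three stages of the original workflow:

1. **CV filter** — keep features whose CV across the pooled biological
   samples strictly exceeds the CV across QC injections. "Among cultivars"
   is read as the pooled non-QC samples, matching the filter's purpose of
   removing features whose variation is instrumental.
2. **Kruskal–Wallis** at $p < 0.02$, midrank tie correction, chi-square
   reference with $k-1$ df. An exact enumeration mode exists for validation;
   at the study's $4 \times 3$ design the chi-square approximation agrees
   with enumeration to better than 0.02 wherever $p < 0.1$ (it can deviate
   by ~0.1-0.2 in the middle of the distribution, where no decision is made).
3. **DSCF post hoc** at $p < 0.2$: pairwise two-sample rank sums on each
   pair alone, standardized with the tie-corrected variance, referred to the
   studentized-range distribution with $k$ means. A feature passes when
   *any* cultivar pair is significant (the source states no quantifier;
   `pass_rule = "all"` is available).

A small-sample subtlety matters here: at $n = 3$ per group, even complete
separation gives an asymptotic studentized-range $p = 0.2017$ — above the
0.2 cutoff — while exact enumeration of the 20 rank allocations gives 0.10.
A workflow that selected features at these sample sizes can therefore only
have used a small-sample reference, so `dscf()` defaults to exact
enumeration whenever the largest group has <= 5 observations (the same
switch the standard R implementations of this test make) and to the
asymptotic reference above that.

Because the cascade only ever *removes* features after the Kruskal–Wallis
screen, its family-wise false-positive rate per feature is bounded by the
KW alpha; the test suite verifies this by Monte-Carlo over null cohorts.
"Manual revision" of spectra — a human step in the original workflow — is
replaced by an automatable proxy: a selected feature must carry an MS$^2$
spectrum with at least 2 peaks. This is documented as a proxy, not a
reproduction of expert judgement.

## Annotation

`match_precursor()` finds knowledge-base records of the right polarity and
charge state within 5 ppm (a 2$-$ feature can only match records whose ion
arithmetic reproduces the observed $m/z$ at $z = 2$). `explain_fragments()`
works in singly-charged fragment space (multiply charged precursors and
flagged 2$-$ fragments are deconvoluted first) and explains each fragment as
a diagnostic ion, the precursor itself, or a previously explained ion minus
a breadth-first chain of at most 3 neutral-loss rules at 0.05 Da; the
longest chains in the reference chemistry are length 2 glycosidic chains
plus small-molecule losses, so depth 3 is a safe cap. Fragment $m/z$
tolerance is 0.01 Da: Q/TOF fragment readings in the reference tables
deviate from theory by a few mDa, an order of magnitude more than the TOF
survey masses.

Levels follow the MSI tiers: I requires an available standard, retention
agreement within 0.05 min and purity >= 80% against the standard's
spectrum; II requires a formula match plus at least one explained fragment;
III is a class call from diagnostic ions alone; IV is an unknown. Two
deliberate refinements: the assigned level is capped at the matched record's
own tabulated level (matching a library entry that is itself only a
class-level call cannot produce a compound-level identification; the cap
also preserves monotonicity — adding a standard to a record raises the
cap), and records sharing a composition and ion species (anthocyanin
positional isomers, sanguiin isomers, procyanidins B1/B2) are disambiguated
purely by retention-time proximity within a +-0.3 min window, since their
spectra are genuinely identical. Level II here means "level II against the
internal knowledge base": external spectral libraries are out of scope.

## Chemometrics

PCA is the SVD of the autoscaled (mean 0, variance 1 per feature) intensity
matrix of the annotated compounds, run separately per ionization mode in the
original design; explained variance is reported as percent of total and the
number of eigenvalues > 1 is the retention heuristic. Autoscaled *raw*
intensities are the default (the source states only "autoscaled"); a log
mode exists. Sign convention: each loading's largest-magnitude element is
forced positive. The pooled-QC diagnostic is the ratio of mean QC
distance-to-origin to mean sample distance-to-origin in the PC1-PC2 plane,
passing below 0.3 — QCs are pooled aliquots of all extracts, so they should
sit at the grand mean, which autoscaling maps to the origin.

Pearson correlations against the pomology table use cultivar-level traits
repeated per replicate (QCs excluded), with two-sided $t$ p-values and flags
at $p < 0.05$. The pomology group test is Kruskal–Wallis per parameter with
DSCF letters built by greedy merging of non-significant pairs; at $n = 3$
per cultivar the exact DSCF cannot separate pairs at $\alpha = 0.05$
(minimum achievable $p = 0.1$), so distinct letters require more replication
— the letter algorithm of the source is not documented.

## The synthetic-data generator

`simulate_cohort()` emulates the study design: four cultivar groups times
three biological replicates plus three pooled-QC injections. Defaults are
the stated study conditions — mass error Normal with 2 ppm scale, tR jitter
0.01 min, log-normal intensities with 20% biological and 5% QC CV — and QC
means are the arithmetic mean of the group means, mirroring the
equal-aliquot pooling. MS$^2$ spectra contain the library fragment list with
10% dropout (base peak always kept) plus a Poisson(3) number of uniform
decoy peaks; decoy features draw $m/z$ from a grid kept >= 20 ppm away from
every library ion, so decoys can never precursor-match and ground truth
stays unambiguous. The pomology table is drawn from the built-in cultivar
means and relative SDs.

The canonical planted *effect* pattern is a 4-fold step between successive
cultivars in the ordering $G < GA < T < J$ (folds 1, 4, 16, 64): the source
reports exactly this qualitative ordering for anthocyanins, with black-vs-red
differences of 3-10x and near-absence in the yellow cultivar, and at
$n = 3$ the Kruskal–Wallis screen at $p < 0.02$ mathematically requires
near-complete separation of all four groups, which a single elevated group
cannot produce. A 4-fold *total* span spread over four groups yields only
~60% cascade power — below what any usable positive control should have —
so the per-step reading is the generator's definition of an effect feature.

What the generator does *not* emulate: chromatographic peak shapes and
co-elution, detector saturation, inter-batch drift, correlated (compound-
family) intensity structure, and real MS$^2$ chimericity under DIA. Passing
tests on this generator therefore demonstrate correctness of the *data
processing* under the stated statistical model, not robustness to every
artifact of real acquisitions.

## Problem sizes and numerical choices

The test suite and the acceptance script use deliberately modest problem
sizes chosen to estimate each quantity to well within its decision margin:
100-200 null cohorts of 100 features for the type-I error (Monte-Carlo SE
~0.001 on an alpha of 0.02), 20 planted effect features for power, the full
68-record base for golden checks. Isotope convolution prunes at $10^{-5}$;
exact DSCF enumerates up to $\binom{10}{5} = 252$ allocations per pair;
ties everywhere use midranks. Degenerate inputs fail loudly (empty spectra,
groups below two observations) or are flagged rather than dropped silently
(undefined CVs, zero-variance features, unaligned singletons).

## Known limitations

* The printed reference tables themselves contain 13 internally
  inconsistent rows; the package freezes them as documented fixtures rather
  than silently "correcting" either side. Counting those rows, 55 of 68
  rows reproduce at printed precision.
* Real-data feature counts of the original study (13,211 / 44,251 aligned;
  49 / 19 final) are not reproducible without the undeposited raw data and
  are not targeted.
* Level I assignment assumes the standard's reference spectrum is the
  library fragment list with nominal intensities; the source prints no
  fragment intensities.
* The compact-letter display gives each group a single letter (greedy
  merging), which cannot express overlapping letter classes.
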