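---
title: "Methods: structure-corrected GWAS and QTL delineation for soybean IDC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-corrected GWAS and QTL delineation for soybean IDC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idcqtl)
```

## The problem

Iron deficiency chlorosis (IDC) limits soybean yield on calcareous,
high-pH soils. In the field it is scored visually on a 1–5 scale (1 green,
5 severely chlorotic/necrotic). The trait is polygenic and the material of
interest — advanced breeding lines from two trial populations — is highly
related and structured, so naive single-marker association is confounded
both by subpopulation membership and by kinship. `idcqtl` implements the
complete analysis chain from a filtered biallelic SNP panel and 1–5 scores
to QTL intervals, epistatic pairs, variant effects, and marker-assisted-
selection allele combinations.

## Phenotype handling

Two populations (n = 132 and n = 138 by default in the simulator) are
analysed combined. `adjust_phenotype()` re-expresses each score as its
within-population deviation plus the grand mean
(`adjusted = raw − population mean + grand mean`), removing the
population/trial main effect while preserving within-population deviations
and the overall mean. Allelic means, combination statistics and tolerance
classes are always computed on the raw 1–5 scale; association tests use the
adjusted scores.

## Structure and kinship

`geno_pca()` decomposes the column-centered dosage matrix without variance
scaling (the covariance form; the alternative correlation form would
up-weight rare alleles, and the covariance form is the common choice for
dosage PCA). Two covariate sets are derived: the components reaching 25%
(`PC25`) and 50% (`PC50`) cumulative variance. `kinship_centered()` builds
K = XcXc′/m, the "centered" kinship of mixed-model GWAS tools, whose rows
sum to zero; identical samples therefore give K = 0 rather than an error.
`gower_similarity()` reports interval-scaled Gower coefficients with a
fixed dosage range of 2 so that values do not depend on panel composition.

## The six association models and the exact mixed-model test

Markers are tested under six models: naive OLS, OLS + PC25, OLS + PC50,
and the three kinship mixed models (kinship alone, PC25 + kinship,
PC50 + kinship). The mixed model is

y = Wα + xβ + u + ε,  u ~ N(0, σg²K), ε ~ N(0, σe²I).

`fit_marker_lmm()` re-optimizes the variance ratio λ = σg²/σe² by REML for
**each marker's alternative model** (the exact-test convention, as opposed
to approximate methods that fix λ under the null once), using a one-time
eigendecomposition of K and a 1-D search: an 11-point grid on log λ over
[1e−5, 1e5] followed by local refinement (`optimize`, tolerance 1e−4 on
log λ). The marker is then assessed by a Wald test β̂²/Var(β̂) against
F(1, n − c − 1). When λ → 0 is optimal the test reduces to OLS; with
K = I the two agree to machine precision (a unit test asserts 1e−6
relative agreement). An optimizer solution at the λ-range boundary is
flagged, not fatal; a marker collinear with the covariates is flagged
degenerate with p = 1. Reported p-values are floored at 1e−300 so
−log10(p) stays finite in Manhattan output.

Model choice uses the rank-based mean squared difference (MSD): sorted
p-values are compared with the uniform order-statistic means i/(m+1) and
the model with the smallest mean squared difference is selected — the
model whose genome-wide p-value distribution is best calibrated. The
expectation i/(m+1) (rather than i/m) is the mean of the i-th uniform
order statistic.

## Bootstrap percentile thresholds

Rather than a fixed α, significance cutoffs are extreme quantiles of the
empirical p-value distribution: the p-vector is resampled with replacement
10,000 times, the 1e−4 and 1e−3 quantiles (the "0.01-percentile" and
"0.1-percentile" tails) are taken per resample with type-7 interpolation,
and the cutoff is the mean of the 10,000 resampled quantiles (the median
is available via `aggregate = "median"`; the procedure's aggregator is not
otherwise pinned down, and the mean is the natural bootstrap point
estimate). Resampling p-values — not re-running the association on
resampled genotypes — is the only reading that is computable at the scale
of ~35,000 markers, and is what `bootstrap_thresholds()` implements. With
fewer markers than 1/level the extreme quantile interpolates near the
minimum p-value; the function warns in that case.

## Per-marker allelic statistics

For inbred material the two homozygote classes carry the information:
allelic means are computed over dosage-0 and dosage-2 carriers only
(heterozygotes excluded from means but retained in regression p-values),
the mean difference is their absolute difference, and the additive effect
of the variant allele is **half** the signed difference — so
|additive effect| = mean difference / 2 holds exactly, an identity the
test suite asserts across whole simulated tables. R² (%) comes from the
simple one-marker regression over all called samples.

## LD, decay fitting, and QTL regions

`partial_r2()` is the squared Pearson correlation of two dosage vectors
after both are residualized on the structure covariates (PC25 throughout
the QTL machinery) — unlinked loci can be in LD purely through structure,
and partialling removes that component. `fit_decay()` fits the
drift–recombination–sample-size expectation

E(r²) = [(10+C)/((2+C)(11+C))]·[1 + ((3+C)(12+12C+C²))/(n(2+C)(11+C))],

with C = ρ·distance and ρ the single free parameter, by multi-start least
squares over a log-spaced ρ grid (10⁻¹² to 10⁻² per bp, half-decade steps)
with local refinement; crossing distances of query r² levels (0.7, 0.2,
0.1 by default) are solved by root finding. At C = 0 and n = 100 the
closed form evaluates to 0.4620; as C grows the curve falls toward the
1/n sampling floor, so a query level below 1/n has no crossing (reported
NA). Crossing distances are report outputs, not targets — they depend on
the data.

A QTL region grows outward from a stepwise lead marker while the partial
r² between the current block **edge** and the next adjacent marker exceeds
0.6 (lead-anchored chaining is available via `anchor = "lead"`; the edge
rule follows the "adjacent marker" phrasing of the procedure). A lead in
LD with neither neighbour yields a single-marker region. Adjacent blocks
merge when the end-to-start gap is under 10 kb AND at most 4 intervening
markers are in LD with neither block (the conjunction is one reading of an
ambiguous rule; both knobs are exposed). Region boundaries are the
outermost member positions, and gene overlap is any-intersection of closed
1-based intervals — for the cases of interest a candidate gene interval
lies fully inside its region, so containment and intersection agree.

## Stepwise selection, epistasis, allele combinations

`stepwise_select()` is forward selection with elimination over the markers
significant at the 0.1-percentile cutoff: a candidate enters when its
partial p and the overall model F-test p are both ≤ 0.05; after each entry
any included marker whose partial p has drifted above 0.05 is dropped
(elimination enabled by default; disabling it is a one-line change). The
selection uses markers only — no PC covariates — matching common stepwise
regression practice on adjusted phenotypes; covariates can be supplied.
The final multiple R² (%) is reported. Note that with a 0.05 entry gate
and k null candidates, about 1 − 0.95ᵏ of runs will admit one spurious
marker; the tests assert recovery of true predictors and a sub-one mean
false-entry count rather than exact support recovery.

`epistasis_scan()` fits y ~ PC25 + m1 + m2 + m1·m2 for every unordered
pair of significant markers (k(k−1)/2 pairs; 33 markers give 528) and
flags interactions at p ≤ 1e−3. `allele_combos()` builds one allele letter
per stepwise marker, in fixed marker order, for every sample homozygous at
all of them (heterozygous/missing samples are excluded and counted), then
reports group size, min, max, mean, and sample SD (n−1; absent for
singletons). Classification is inclusive — tolerant when mean ≤ 2.5,
susceptible when mean ≥ 3.5 — because the boundary case (a combination
mean of exactly 2.50) is classified tolerant in the reference usage and
the inclusive rule reproduces the published 14/6 split.

## The synthetic breeding panel

`simulate_population()` emulates the study material rather than soybean
demography:

* **Founder pools and LD.** Each subpopulation has a small disjoint pool
  of founder haplotypes (8 by default). Founder alleles and local allele
  frequencies both derive from AR(1) Gaussian-copula latents along each
  chromosome, so the pools carry block LD; each inbred line is then a
  mosaic that copies from one founder at a time, switching template with
  per-bp probability `copy_switch_rate_per_bp`. The default 1e−7 was
  chosen once at design time to place mean partial r² near 0.5–0.6 around
  300–500 kb — the strong local LD of a narrow breeding panel — and to
  decay monotonically beyond (the test suite asserts the shape, not the
  level). A coalescent simulator would be more realistic but is
  unnecessary for calibrating the analysis; the mosaic is O(n·m).
* **Structure and relatedness.** Subpopulation allele frequencies diverge
  by an independent AR(1) perturbation scaled by `fst` (default 0.15,
  enough for PC separation while keeping Gower similarity concentrated in
  a narrow band, IQR < 0.15). Lines are fully inbred — dosages 0/2 before
  missingness — though the pipeline accepts dosage 1 from real VCFs.
* **Phenotype.** baseline 2.76 + subpopulation shift (0.15 by default) +
  Σ effectᵢ·(dosageᵢ − 1) + N(0, 0.30), clipped (not resampled) to [1, 5];
  the clip count is recorded. The default planted profile
  (`idc_qtl_profile()`) is eight markers on eight chromosomes with signed
  per-allele effects of 0.08–0.19 and allele frequencies 0.07–0.46.
  Planted positions are added to the marker map if absent; invalid
  chromosome or out-of-range/duplicate positions are rejected.
* **What it does not model.** Genotyping error, a real recombination map,
  multi-allelic sites, heterozygosity, linkage between the planted profile
  and any real gene. Passing tests therefore demonstrate that the
  statistics behave as designed under the assumed generating process, not
  that any specific soybean locus would be found in new data.

`simulate_annotation()` builds a compact random reference plus clean gene
models (5′UTR, 2–3 CDS exons with introns, 3′UTR, alternating strands;
CDS length divisible by 3, ATG start, single terminal stop) for exercising
the annotator; CDS bases are written into the reference so every transcript
translates. Use compact chromosomes for annotation fixtures — the
annotator only needs local codon context.

## Variant annotation

`classify_site()` assigns intergenic / intron / UTR5 / UTR3 / coding with
precedence coding > UTR > intron when transcripts overlap; among coding
transcripts the most severe consequence wins (nonsynonymous over
synonymous), ties broken by first transcript id. The codon is assembled
from the CDS in transcript orientation (reverse-complemented on the minus
strand; a mirrored-fixture test asserts strand consistency), the variant
base substituted, and both codons translated; start/stop gains and losses
are folded into nonsynonymous. A CDS whose length is not divisible by 3 is
skipped with a warning. Transitions are substitutions within {A,G} or
{C,T}; `ts_tv()` reports category counts and the Ts/Tv ratio (flagged
infinite when no transversions exist).

## Numerical and scale choices

* REML search range λ ∈ [1e−5, 1e5]; boundary solutions flagged.
* Bootstrap quantile: type 7; aggregator mean; B = 10,000 in the pipeline
  and the acceptance script.
* Decay fit: ρ grid 10⁻¹²…10⁻², `optimize` refinement.
* Mode imputation ties break toward the lower dosage.
* MAF cutoff is strict (> 0.05), computed on non-missing calls; the
  haplotype-model imputation used upstream in practice is out of scope, so
  filtering precedes mode imputation here.
* Test-suite problem sizes (package choices): MSD model ranking at
  n = 270, m = 2000 over 20 seeds; planted-profile recovery at m = 5000
  over 20 seeds with B = 1000 bootstrap; type-I-error calibration pooled
  over 10 seeds × 2000 null markers. The acceptance script runs a single
  m = 5000 study with the full B = 10,000 bootstrap.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  simulate = sim_config(seed = 1, n_markers = 5000),
  model = "auto", boot_B = 10000, seed = 1)
res <- run_pipeline(cfg, "idc_run")
res$results$stepwise
```

Every stage writes a TSV with a provenance header (package version, seed,
config hash) into the run directory, plus `results.json` with the headline
numbers; a rerun with the same config and seed is byte-identical.

## Known limitations

* The LMM Wald test assumes a Gaussian phenotype; a 1–5 visual score is
  bounded and coarsely observed. The combined-population grand mean sits
  near mid-scale, where clipping is rare, but heavy planted effects can
  clip.
* Mode imputation is deliberately naive; with high missingness it deflates
  heterozygosity-free panels toward the major allele and will bias MAF.
* p-value resampling treats markers as exchangeable; LD makes the
  effective number of independent tests smaller than m, which the
  percentile-threshold approach absorbs only partially.
* The stepwise 0.05 gates admit occasional null markers by construction
  (see above); downstream region/combination reports inherit them.
* Percentile thresholds cap the number of significant markers at about
  m × level: the 0.1-percentile tail of a 5,000-marker panel can admit
  only ~5 markers no matter how strong the signal, and when more loci
  (plus their LD partners) carry real effects the cutoff moves inside the
  signal cluster. The method is well matched to panels where the expected
  signal fraction is near the chosen percentile (~0.1% of markers, as in
  a ~34,000-marker panel with ~33 true associations); on small panels
  prefer the 1-percentile level or a fixed α.
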