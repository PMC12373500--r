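# pdxmet

Metabolic fidelity analysis of patient-derived xenografts (PDXs).

## The problem

PDXs — patient tumour tissue engrafted and serially passaged in
immunodeficient mice — are the standard pre-clinical model in melanoma,
but the mouse host changes the tumour's environment (diet, microbiota,
immunity, physiology). `pdxmet` is for researchers who need to know, from
bulk metabolomics, *which* metabolic features of a PDX are artifacts of
the host and *which* faithfully carry the patient tumour's identity
across passages P1–P6 (P0 denotes the patient tumour itself).

The pipeline answers three questions:

1. **What does xenografting change?** Per-metabolite moderated linear
   models (limma-style empirical Bayes) and variance partitioning across
   host species, pigmentation and other clinical factors.
2. **Can a PDX be traced to its patient?** A linear mixed model (host as
   fixed effect, random intercept per origin, profiled REML) screens for
   *species-agnostic* metabolites (host P > 0.1); on the z-transformed
   panel, each PDX is matched to the patient tumour at minimal Euclidean
   distance
   D<sub>total</sub> = sqrt(Σ<sub>k</sub> (x<sub>k</sub> − y<sub>k</sub>)²),
   and the per-metabolite decomposition
   Δd<sub>k</sub> = d<sub>k</sub><sup>match</sup> − d̄<sub>k</sub><sup>non-match</sup>
   (with d<sub>k</sub> = (x<sub>k</sub> − y<sub>k</sub>)²) shows which
   metabolites drive the match (Δd<sub>k</sub> < 0 pulls matched pairs
   together).
3. **Is the fingerprint stable?** Per-line passage slopes, P0–P6 Pearson
   correlation, and classification of *characteristic* metabolites
   (> 30% of variance explained by origin AND r > 0.3).

A ¹³C isotope-tracing module handles natural-abundance correction of
mass isotopomer distributions (convolution-matrix construction +
nonnegative least squares), total labelling (1 − M+0), normalization to
glucose M+6, and the CitM2/PyrM3 pyruvate-dehydrogenase surrogate.
Hypergeometric metabolite-set enrichment (GMT collections, detected
metabolome as background) rounds out the pipeline. A synthetic cohort
generator with recorded ground truth makes every stage testable without
patient data — see the methods vignette
(`vignettes/pdx-metabolic-fidelity.Rmd`) for the models, assumptions and
design decisions.

## Worked example

```r
library(pdxmet)

# a synthetic cohort: 10 origins, 1 patient + 2 PDXs per passage P1-P6
sim <- simulate_cohort(sim_config(n_origins = 10, seed = 42))
#> Synthetic patient/PDX cohort: 305 metabolites x 130 samples (10 origins, passages 0,1,2,3,4,5,6)
#>   missing entries: 2241 (5.7%)

norm <- preprocess(sim$intensity)        # filter, normalize, log10, impute
#> Normalized table: 298 metabolites x 130 samples, 1343 imputed cells (3.5%)

# species-agnostic screen: metabolites with no host evidence (mixed-model P > 0.1)
flags <- select_species_agnostic(norm, sim$annotation)
sum(flags$species_agnostic)              # 134 of 298

# fingerprint matching on the species-agnostic panel
std   <- zscore_metabolites(norm)
ann   <- sim$annotation
pat   <- ann$sample_id[ann$host == "human"]
pdx   <- ann$sample_id[ann$host == "mouse"]
panel <- flags$metabolite_id[flags$species_agnostic]
mr <- match_pdx_to_patient(pairwise_distances(std, pdx, pat, panel), ann)
#> PDX-to-patient matching: 120/120 correct (accuracy 1.000)

dec <- decompose_distance(std, ann, pdx, pat, panel)
mean(dec$per_pair$frac_negative)         # 0.93: fraction of panel with delta_d < 0

rec <- fidelity_records(norm, ann)       # origin variance, P0-P6 r, classification
attr(rec, "n_characteristic")            # 294 of 298
head(rec[order(-rec$origin_variance_fraction),
         c("metabolite_id", "origin_variance_fraction",
           "p0_p6_pearson_r", "characteristic")], 3)
#>     metabolite_id origin_variance_fraction p0_p6_pearson_r characteristic
#> 123        met127                0.9394374       0.9243493           TRUE
#> 23         met025                0.9277601       0.9480105           TRUE
#> 204        met210                0.9217453       0.9219937           TRUE
```

Reading the numbers: 164 of 298 metabolites show host dependence and are
excluded from matching; on the remaining panel every synthetic PDX traces
back to its patient of origin, with ~93% of panel metabolites
contributing to (rather than working against) each match. The planted
origin fingerprint (origin SD = 2× residual SD) is deliberately strong;
real cohorts match at lower rates. Characteristic metabolites are those
whose levels are both patient-specific and stable from P0 to P6.

The same pipeline is scriptable from the shell via the installed
`exec/pdxmet` entry point
(`pdxmet simulate | preprocess | diff | match | fidelity | isotope | enrich`).

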