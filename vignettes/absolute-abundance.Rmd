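---
title: "Absolute amplicon abundances with internal genomic standards: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute amplicon abundances with internal genomic standards: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Amplicon read counts are compositional: sample *j*'s reads are, to a good
approximation, a multinomial draw whose probabilities are proportional to the
16S gene-copy loads that reached the PCR, times taxon-specific amplification
efficiencies. Spiking a known copy quantity of foreign genomic DNA into each
sample turns this into an absolute measurement. If standard *s* contributes
`C_s` copies to sample *j* and receives `R_sj` reads, then for a community
ASV *i* with `R_ij` reads the volumetric gene-copy abundance is

    ASV_ij = (R_ij * C_s) / (R_sj * V_j)     [copies / L]

with `V_j` the filtered volume in liters. The derivation assumes only that
ASV *i* and standard *s* amplify with equal efficiency — the unknown
amplification factor and the library size cancel in the read ratio. This is
why `spikequant`'s estimates are invariant to sequencing depth and library
scaling (a tested property), and why primer/pipeline combinations validated
for accurate *relative* abundances are a prerequisite rather than an output.

`C_s` is derived from the spiked DNA mass by standard molar arithmetic:

    C_s = mass_g / (genome_size_bp * m_bp / N_A) * copies_per_genome

with `m_bp = 650 g/mol` per double-stranded base pair (configurable; the
conventional dsDNA average) and the exact SI Avogadro constant. One spiked
genome's rRNA operons can denoise into several ASVs, so a standard's read
count is the sum over all ASV ids assigned to it; `C_s` is per organism, not
per ASV.

### The nine-estimate design

With three technical replicates (independently filtered subsamples) and
three standards, every (site, ASV) gets up to nine independent estimates.
The reported abundance is their arithmetic mean (a median aggregator is
available but the mean is the default and the tested path); the min–max range
and the pooled percent-error distribution |estimate − set mean| / set mean
quantify end-to-end technical error. The upper percentile of that pool is
computed with linear interpolation between order statistics (R quantile
type 7) — the convention matters for reproducing any specific percentile
value, so it is fixed and documented here.

**Standard dropout.** A (replicate, standard) slot with zero standard reads
makes that single estimate undefined (division by zero). The package drops
exactly that estimate — for all ASVs of the sample, since the dropout is a
property of the sample × standard pair — records it, and reports `n < 9` for
the site. Failing the whole site would discard the remaining independent
estimates for no reason; winsorizing would bias the mean. A site that loses
*all* slots is excluded with a warning record. Whether any real pipeline run
drops or winsorizes estimates before averaging is not observable from
published summaries; plain dropping is the conservative reading.

### Cells from copies

Dividing a gene-copy abundance by the genomic 16S copy number yields cells
per liter. Defaults cover only the two validated picocyanobacteria
(*Prochlorococcus* 1, *Synechococcus* 2 copies per cell); every other taxon
stays in copies/L unless the user supplies a copy number, because copy
numbers for most uncultivated taxa are unknown and silently assuming 1 would
masquerade as a cell count. Aggregation order is: sum member-ASV copy
estimates within each retained (replicate, standard) slot, convert to cells,
then average slots. Summing first keeps the conversion exact and applies the
"mean of nine" at the level at which abundances are reported; slot alignment
by (replicate, standard) key ensures sums combine like with like even under
dropout.

## Matchup validation

Amplicon sites and FCM events are paired under a great-circle distance bound
(haversine, sphere radius 6371 km; default 20 km) and an absolute time
offset bound (default 6 h). A site's position/time is the mean over its
replicates, which are drawn from the same underway stream minutes apart.

The pairing policy is greedy nearest one-to-one: candidates sorted by
(distance, |Δt|, site id, event id) and accepted so that each site and each
event is used at most once. One-to-one prevents pseudo-replication in the
regression (one FCM event serving many sites); the lexicographic tie-break
makes the pairing deterministic under input permutation (tested); an
`all_pairs` policy is available for exploration. Relaxing the distance bound
only adds candidates, so the pair count is non-decreasing in the bound under
either policy — asserted inside `sensitivity_analysis()`.

Validation regressions are ordinary least squares with a free intercept,
with FCM means on *x* and amplicon means on *y*. Which instrument sat on
which axis in any given published figure is rarely stated; since a slope
near 1 makes the choice nearly moot, both the through-origin slope and the
reversed-orientation slope are reported alongside so the choice is
auditable. Both populations' points are pooled for the headline cell-count
regression; per-population regressions are also emitted. The ratio
regression (*Prochlorococcus*:*Synechococcus*) uses only pairs where both
taxa are positive in both instruments.

## The synthetic world

The generator states one fixed study design and never adapts to test
outcomes: 65 sites at 46-km spacing along a northward meridional track,
triplicate 2-L samples (±10% volume jitter), three genomic standards at 4 ng
each, ~1e5 reads per sample (lognormal, sdlog 0.1 ≈ ±20% at two sigma), and
FCM three times daily in triplicate along the same track, over a transect
lasting ~9 days at 13.7 km/h.

* **Profiles.** True cell abundances are parametric logistic functions of
  latitude: a *Prochlorococcus*-like taxon (2e8 → 1e6 cells/L) declining
  northward out of the subtropical gyre, a *Synechococcus*-like taxon
  (5e5 → 8e7 cells/L) rising into the transition zone, crossing at 32.5°N
  over a ~1.2° width, plus two flat background heterotrophs. Closed-form
  truth enables exact recovery assertions; resampled real data would not.
* **Spike fraction.** The background taxa's baseline is calibrated once,
  deterministically from the configuration, so that the three standards'
  summed copy load is the target fraction (default 1%) of all 16S copies at
  the transect-mean sample. The fraction is defined in copy terms rather
  than DNA-mass terms because read counts constrain the copy fraction
  directly; the two differ only by genome-size weighting.
* **Error structure.** Community taxa receive one lognormal
  capture-efficiency draw per replicate (σ = 0.1, median 1) — filtration
  efficiency varies per filter. Standards are exempt: they are added to the
  lysis buffer *after* filtration, which is exactly the error structure the
  nine-estimate design averages over. FCM replicates get lognormal noise
  with σ = 0.05. Reads are multinomial over community ASVs plus standard
  ASVs with probabilities ∝ load × amplification bias (default unbiased).
* **Determinism.** The three stages draw from `seed`, `seed+1`, `seed+2`;
  identical configuration and seed give byte-identical output files
  (tested).

What the generator does **not** emulate: sequencing error and chimeras
(simulation is at the count level; ASV calling is out of scope), primer
bias beyond the per-taxon efficiency knob, real cruise-track curvature,
diel vertical structure, and any spike-load deviation from the nominal
mass-derived `C_s` (pipetting error, DNA integrity). A green end-to-end test
therefore establishes that the *estimator* is correct under its stated
assumptions — not that any particular wet-lab protocol satisfies them.

## Numerical and interface conventions

* Canonical units: liters, copies/L, cells/L; FCM sources in cells/µL or
  cells/mL are converted at ingest via a declared unit column. One unit
  system prevents silent factor-of-1000 errors (mL vs L metadata is tested
  to give identical results).
* Timestamps are ISO 8601 UTC; zone-less timestamps are rejected unless a
  default zone is configured, because a 6-h matchup window is meaningless
  across unlabeled zones.
* Abundance tables are written with 12 significant digits; read → re-write
  is byte-identical (tested).
* Structured configs (standards, copy map, run config) are JSON: the
  installed R stack has no YAML parser, and JSON round-trips numbers
  losslessly via `jsonlite`.
* Estimates are computed in the exact association order
  `(R_ij * C_s) / (R_sj * V_j)` so that an independent nested-loop
  recomputation agrees bit-for-bit.

## Limitations

* Equal amplification efficiency between standards and targets is assumed,
  not checked; a mis-calibrated efficiency shifts all abundances by a
  constant factor that the FCM matchup — not the internal consistency of the
  nine estimates — would reveal.
* Cell-abundance output is only as good as the copy-number map; taxa with
  unknown copy number are deliberately left in copies/L.
* The realized spike copy load is taken at its nominal mass-derived value;
  systematic spike bias is representable in the generator but no published
  value constrains it.
* The matchup policy is a modeling choice where real studies rarely state
  one; both policies are exposed and the pair count / regression sensitivity
  to the distance bound is part of the standard output.
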