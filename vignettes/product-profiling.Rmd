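---
title: "Product-profile fingerprinting of pectin lyases: models and methods"
author: "pelprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Product-profile fingerprinting of pectin lyases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelprofiler)
```

## The problem

Fungal genomes carry several gene copies encoding pectin lyase
(EC 4.2.2.10), an enzyme that depolymerizes the homogalacturonan backbone
of pectin by beta-elimination, preferring linkages between
methyl-esterified galacturonate (GalA) residues. Copies differ subtly in
how they attack substrates that vary in degree of methoxylation (DM),
degree of acetylation (DAc) and substituent placement. Bulk activity
assays hide these differences; what discriminates the copies is *which*
oligomeric products each one makes — its product profile, read out by
LC-ESI-MS of the released oligogalacturonides.

`pelprofiler` implements that profiling workflow end to end, together
with a mechanistic digestion simulator so every stage can be exercised
and tested on synthetic data with known ground truth.

## The mass model

Products are Delta-4,5-unsaturated oligogalacturonides described by a
composition `(dp, n_methyl, n_acetyl)`. At unit (iontrap) resolution each
anhydro-GalA residue contributes 176 Da, a methyl ester +14, an acetyl
+42; the water gained at the reducing end cancels against the water lost
to the 4,5-unsaturation, so

$$ M = 176\,dp + 14\,m + 42\,a $$

and saturated species add 18. Nominal integer masses are primary because
they reproduce the curated compound table exactly; monoisotopic
counterparts (residue 176.03209, CH~2~ 14.01565, C~2~H~2~O 42.01057) are
provided for ppm matching. Ions follow the eluent chemistry: `[M-H]`^-^
and formate `[M+FA]`^-^ in negative mode, ammonium `[M+NH4]`^+^ and
`[1/2M+NH4]`^2+^ in positive mode, i.e. `m/z = (M + 18z)/z` for ammonium
at nominal resolution. The curated table of 48 identified compounds ships
verbatim; its three internally inconsistent rows are flagged
(`known_compound_exceptions()`), never silently corrected.

```{r}
nominal_mass(oligo_composition(3, 3))                    # gA_3_m_3
adduct_mz(936, adduct_spec("ammonium", 2))               # gA_5_m_4, z = 2
```

## Fragment prediction and acetyl localization

MS^2^ ions use the Domon–Costello nomenclature for 1,4-linked uronides.
With per-residue contributions $r_k$, the non-reducing-side ladder is
$C_i = \sum_{k \le i} r_k$ and $B_i = C_i - 18$; the reducing-side
$Z_j$ equals the anhydro sum of the last $j$ residues and is therefore
isomeric with a C ion of the complementary composition — matched
fragments keep both annotations rather than being forced to one series.
The only cross-ring series emitted is ^0,2^A (`C_i - 60`), the standard
0,2 cleavage for 1,4-linked sugars. A 32 Da methanol loss is offered only
when the reducing-end residue is methylated.

Positive-mode spectra of fully methoxylated species show a reproducible
anomaly: all B/C fragments sit 7 Da below expectation. The package treats
this as an opaque, series-wide empirical offset — configurable, applied to
fragment ions only, and flagged in every output row — because no chemical
mechanism for it is established; folding it into the mass model would
contaminate intact-mass arithmetic.

Acetyl placement is inferred set-theoretically: a B/C fragment of index
`i` that retained the acetyl puts at least one acetyl at positions
$\le i$; one that lost it excludes those positions. `localize_acetyl()`
enumerates all placements consistent with every observation, so evidence
can only shrink the feasible set, and a contradiction returns the empty
set instead of an error. MS^2^ cannot distinguish O-2 from O-3
acetylation; compositions carry counts only.

## Identification and profiling

Peaks (already-integrated XIC areas; the package does no peak picking)
are matched against library expectations within ±0.5 Da by default —
appropriate for unit-resolution data — choosing the smallest absolute
error, then the lower charge. Compositions observed at retention times
separated by at least `rt_gap` (default 0.5 min, motivated by baseline
separation of known isomer pairs on porous graphite) become `#1`, `#2`
isomers in elution order; co-eluting duplicates merge with summed
intensity. Profiles assign every library compound an intensity (zeros,
not missing values, for undetected compounds) and sum adducts, so no
intensity is created or lost.

One identification limit is structural, not instrumental: three methyl
esters and one acetyl group both add exactly 42 Da, so compositions
`(dp, m, a+1)` and `(dp, m+3, a)` are isobaric at unit resolution (and
differ by only 0.036 Da monoisotopically). `match_peaks()` therefore
reports every within-tolerance candidate and an `ambiguous` flag, and
breaks exact ties toward the higher methyl count — the lyase-product
prior: products of a methyl-requiring enzyme on high-DM pectin are
predominantly methylated, and the curated compound set is consistent
with that prior. MS² evidence, where available, overrules it. A second
coincidence, `[M+NH₄]⁺` of mass M versus `[½(2M)+NH₄]²⁺` of mass 2M, is
resolved by supplying the peak's charge state, which iontrap software
reads from isotope spacing.

Fingerprinting then normalizes each (enzyme, substrate, time) sample to
its most abundant compound. This is the crux of the method: it removes
per-sample global scale (dosage, injection, overall activity), leaving
only the *shape* of the product spectrum, and makes the downstream
clustering invariant to multiplying any sample by a positive scalar — a
property the test suite checks directly. Samples are clustered within
each (substrate, time) stratum by complete linkage on Euclidean
distances; rows are sorted lexicographically before clustering so leaf
order is reproducible, and column order is fixed. DP aggregation sums
normalized intensities per degree of polymerization, optionally split by
acetylation, and conserves the profile total.

## The digestion simulator

The simulator is the synthetic-data backbone and a mechanistic model in
its own right. Substrate chains carry per-residue methyl and O-2/O-3
acetyl marks. The generator draws methylation either i.i.d. (random) or
in contiguous runs (blockwise) to a target DM; acetylation marks a
`DAc`-fraction of residues with one acetyl at O-2 or O-3 (doubly
acetylated residues can be built manually but are rare enough in real
pectins that the generator omits them). RG-I and other non-GalA backbone
content is modeled only as an inert residue fraction.

Cleavage follows a subsite rule spanning −4..+4 across the scissile
bond: a methylated +1 is required; a methylated +3 gives the full
relative rate 1, otherwise the bond proceeds at `rho` (default 0.25 — the
literature established direction, "lower specific activity", but no
magnitude, so this is a configurable knob, as is the per-acetyl rate
penalty, default 0.5 per acetyl in the occupied window). Strict mode
(`rho = 0`) makes fully methylated DP3 inert (+3 cannot exist) and gives
fully methylated DP10 exactly 7 cleavable bonds — both consequences are
frozen in tests. Whether an acetyl at +1 blocks the elimination chemistry
outright is unknown; a hard-block flag exists and defaults to off.

Digestion is an exact Gillespie simulation: waiting times are
exponential in the total rate, one bond is cleaved per event with
probability proportional to its rate, and the fragment on the
reducing-end side gains the unsaturated non-reducing end. Exactness is
affordable at desk scale (a 10^4^-residue digest to completion runs in
about a second) and makes conservation laws — residues, methyls, acetyls,
chains = initial + cleavages, unsaturated ends = cleavages — testable to
the integer. Peak synthesis maps unsaturated products inside the library
range to intensities proportional to molar counts under multiplicative
lognormal noise (CV 9% by default, matching the technical variability of
normalized intensities reported for replicate injections on this
instrument class), with m/z jitter; out-of-range and saturated products
are reported separately rather than dropped.

What the generator does *not* emulate: retention-time physics (rt is a
deterministic function of composition), isotope patterns, in-source
fragmentation, ion suppression, chromatographic overlap between
different compositions, and enzyme processivity. Passing round-trip tests
therefore demonstrates the internal consistency of the pipeline and the
identifiability of count-proportional profiles under realistic intensity
noise — not instrument-level realism.

## Enzymology helpers

DM and DAc are percentages of GalA moieties carrying the substituent, so
saponification data invert as `DM = 100·methanol/GalA`. Substrate mass
loadings convert to mM GalA-bond via the GalA content; the (n−1)/n end
correction is dropped as negligible for polymeric pectin. A235 slopes
convert to specific activity through Beer–Lambert with the
4,5-unsaturated galacturonide extinction coefficient 5500 M^−1^cm^−1^
(path length and volume are configuration, not constants — plate-reader
geometries vary). Michaelis–Menten parameters come from the Hanes–Woolf
linearization (regress S/v on S; slope 1/V~max~, intercept K~m~/V~max~),
the classical treatment for these assays; `michaelis_menten_nls()` is a
diagnostic cross-check only. kcat is derived from V~max~ in U/mg and the
enzyme molar mass.

## Numerical choices and problem sizes

* Matching ties: smallest |error|, then lower z, then name order — the
  result is invariant under library permutation.
* Clustering ties: rows sorted lexicographically before `hclust`.
* All-zero profiles: returned unchanged with an `all_zero` flag.
* Empty evidence, empty ranges, dp = 1 fragmentation: empty results, not
  errors; contradictory acetyl evidence: empty set, logged by the caller.
* Every stochastic step takes a single integer seed; fixed seeds make
  trajectories, peak tables and analysis outputs byte-reproducible.
* Simulation scales used by the tests and the analysis scripts — 10^4^
  residues per trajectory, 50 seeds for stochastic properties, 100 seeds
  for kinetic recovery — were chosen as the smallest sizes at which the
  binomial/Monte-Carlo concentration bounds in the tests are comfortably
  sharp.

## Known limitations

* The 3×CH₂ = acetyl mass degeneracy means m/z-only assignment of
  acetylated compositions on low-DM substrates leans on the
  methylation prior; peaks flagged `ambiguous` need MS² confirmation.
* The −7 Da positive-mode offset is reproduced, not explained.
* The subsite model is a two-parameter caricature (rho, acetyl penalty)
  of a real enzyme's subsite energetics; it reproduces directionally
  correct behaviour (blockwise > random at equal DM, rate non-increasing
  in DAc, DP3 inertness) but is not calibrated to any specific enzyme's
  kinetics.
* Technical-replicate CV is modeled as compound-independent lognormal
  noise, whereas real variability has structure across the run.
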