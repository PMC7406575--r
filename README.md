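# pelprofiler

Discriminative substrate degradation profiling of pectin lyases
(EC 4.2.2.10) from LC-ESI-MS oligogalacturonide data.

Fungal genomes carry several near-identical pectin lyase genes. Bulk
activity assays rank the copies but do not explain why the copies exist;
what discriminates them is the *product profile* — which methyl- and
acetyl-substituted unsaturated oligogalacturonides each enzyme releases
from pectins of differing degree of methoxylation (DM) and acetylation
(DAc). `pelprofiler` implements that profiling workflow for anyone
comparing pectin-active enzymes:

* **Mass model** — an unsaturated oligogalacturonide `(dp, m, a)` has
  nominal mass `M = 176·dp + 14·m + 42·a` (anhydro-GalA 176, methyl +14,
  acetyl +42; saturated species +18), with monoisotopic counterparts for
  ppm matching and adduct rules `[M−H]⁻`, `[M+FA]⁻`, `[M+NH₄]⁺`,
  `[½M+NH₄]²⁺`. A curated 48-compound library ships as a fixture (three
  internally inconsistent printed rows are flagged, not corrected).
* **MS² fragments** — Domon–Costello B/C/Z and ⁰,²A series for 1,4-linked
  uronides, methanol (−32 Da) losses for methylated reducing ends, the
  empirical −7 Da positive-mode fragment offset (flagged, configurable),
  and set-based acetyl localization from retained/lost fragment evidence.
* **Identification & fingerprinting** — peak matching at ±0.5 Da with
  explicit ambiguity reporting (3×CH₂ and one acetyl are exactly
  isobaric), retention-time isomer grouping, per-sample max-normalized
  profiles, DP aggregation, and complete-linkage/Euclidean clustering of
  enzymes within each (substrate, time) stratum.
* **Digestion simulator** — homogalacturonan chains with random or
  blockwise methylation and O-2/O-3 acetylation, β-elimination under a
  −4..+4 subsite rule (methylated +1 required; methylated +3 for full
  rate, partial rate ρ otherwise; per-acetyl rate penalty), exact
  Gillespie dynamics, Beer–Lambert A235 traces, and synthetic peak tables
  with lognormal intensity noise (CV 9 % by default) — so the whole
  pipeline is testable with known ground truth.
* **Enzymology helpers** — DM/DAc from saponification data, GalA-bond
  concentrations, A235 → specific activity (ε = 5500 M⁻¹cm⁻¹), and
  Michaelis–Menten fitting via the Hanes–Woolf linearization.

## Worked example

Simulate a digest of an apple-pectin-like substrate (DM 69 %, DAc 2 %),
synthesize an LC-MS peak table, identify, and fingerprint:

```r
library(pelprofiler)

apple  <- pectin_presets("apple")
chains <- generate_chains(substrate_spec(200, 50, dm = apple$dm,
                                         dac = apple$dac), seed = 501)
dig  <- simulate_digest(chains, strict_rule(),
                        time_points = c(0, Inf), seed = 502)
lib  <- enumerate_library()
pk   <- synthesize_peak_table(dig$snapshots[[2]], lib,
                              noise_cv = 0.09, seed = 550)
res  <- match_peaks(pk$peaks, library_mz_table(lib), tol_da = 0.5)
prof <- normalize_profile(build_profile(group_isomers(res$matched), lib))
round(sort(prof$intensities, decreasing = TRUE)[1:5], 3)
#> gA_3_m_3 gA_2_m_2 gA_3_m_2 gA_2_m_1 gA_4_m_3
#>    1.000    0.634    0.508    0.465    0.463
```

The fully methylated trimer gA_3_m_3 dominates — the expected signature
of a lyase that requires methylated GalA in subsites +1 and +3 acting on
a high-DM pectin (DP3 cannot be cleaved further, so it accumulates), with
shorter and slightly demethylated products following. Normalizing each
sample to its most abundant compound removes overall activity from the
fingerprint, so clustering compares *what* enzymes make, not how much:

```r
m <- rbind(enzA = prof$intensities, enzB = prof$intensities * 0.1)
cluster_samples(t(apply(m, 1, normalize_profile)))$heights
#> [1] 7.860578e-17    # zero to machine precision
```

The numbered scripts under `analysis/` run the full study workflow on a
synthetic enzyme panel: `01_build_library.R` (library construction and
verification against the curated table), `02_simulate_digests.R` (panel ×
three pectins × four time points), `03_identify_profile.R` (peak tables →
normalized profiles), `04_cluster_profiles.R` (per-stratum clustering),
`05_kinetics.R` (Hanes–Woolf recovery). Each writes its tables under
`results/`.

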