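# mocrlink

Statistical characterisation of the inter-domain **linker peptides** of
MocR-family bacterial transcriptional regulators.

MocR regulators (a subfamily of the GntR family, including GabR and PdxR)
pair an N-terminal winged helix-turn-helix (wHTH) DNA-binding domain of
about 60 residues with a large C-terminal effector domain (~350 residues)
folded like a fold-type-I PLP-dependent aminotransferase (AAT). The peptide
connecting the two domains varies enormously in length and composition
across bacterial phyla, and its flexibility and residue make-up bear
directly on how the two domains communicate — and on how one might engineer
linkers with desired properties. `mocrlink` provides the complete analysis
toolkit for such linker sets:

- **Extraction** of linker peptides from domain-annotated sequences, either
  from a per-sequence boundary table or from a multiple sequence alignment
  via a reference row's column window. Coordinates are 1-based half-open
  `[start, end)`, so `length = end - start`.
- **Residue propensities** `p_i = f_linker(i) / f_ref(i)` with the
  conventional grey-shading categories (light: `1.01 <= p <= 1.19`, dark:
  `p >= 1.20`), stratified by phylum and length bin
  (0–20, 21–40, 41–60, 61–200 residues).
- **Dyad (dipeptide) propensities** from overlapping two-residue windows
  counted within each linker (compseq-style), compared against either a
  marginal-product or a uniform (1/400) expectation, with the dyad-matrix
  shading classes (very light: 1.10–1.99, light: 2.00–3.99, dark: >= 4.00),
  plus mean±sd pair-count summaries per phylum × bin.
- **Physicochemical profiling**: the Average Index (AI — the mean of an
  AAindex scale over a region) of wHTH domains, AAT domains and linkers,
  summarised as box-plot statistics. Seven scales ship as fixtures
  (flexibility VINM940101, hydrophobicity CIDH920105, linker propensity
  GEOR030101, Chou–Fasman turn/coil/helix/sheet CHOP780101, CHAM830101,
  CHOP780201, CHOP780202).
- **Secondary-structure fractions** (helix/strand/coil) pooled per group
  from externally predicted three-state strings.
- **Length histograms** on a finer bin scheme (0–20, 21–30, 31–40, 41–50,
  51–60, >60) for subgroup comparisons such as GabR vs PdxR.
- A fully seeded **synthetic generator** of MocR-like annotated sequence
  sets with controllable linker-length mixtures and per-residue enrichment
  factors, so every statistic above can be validated against known ground
  truth.

Everything is tidyverse-native: functions take data frames and return
tibbles, results have `tidy()`/`glance()` methods and `autoplot()` ggplot2
graphics, and `run_linker_report()` orchestrates the whole pipeline into a
TSV artifact set.

## Worked example

A bundled boundary table lists 72 MocR regulators with linkers of at least
60 residues:

```r
library(mocrlink)

b <- read_boundary_table(system.file("extdata", "mocr_long_linkers.tsv",
                                     package = "mocrlink"))
head(b, 3)
#>   id               start   end length
#> 1 A0A023C4T7_9PSED    88   148     60
#> 2 A0A0B2AVS1_9ACTN    85   145     60
#> 3 A0NP21_LABAI        80   140     60
```

Run the core statistics on a synthetic two-phylum set whose linkers are
enriched 1.8-fold in proline and 1.4-fold in glycine:

```r
cfg <- generator_config(seed = 42, n_sequences = 60,
                        phyla = c("Firmicutes", "Gammaproteobacteria"),
                        linker_enrichment = c(P = 1.8, G = 1.4))
sim <- generate_set(cfg)

linkers <- sim$sequences |>
  extract_by_coordinates(sim$boundaries) |>
  assign_length_bins("analysis")

pt <- residue_frequencies(linkers) |>
  residue_propensities(pooled_reference(sim$sequences), group = "all linkers")
dplyr::arrange(tidy(pt), dplyr::desc(propensity)) |> head(4)
#>   residue frequency ref_frequency propensity shade
#> 1 P          0.0758        0.0493       1.54 dark
#> 2 G          0.0982        0.0723       1.36 dark
#> 3 F          0.0396        0.0383       1.03 light
#> 4 D          0.0543        0.0531       1.02 light
```

The injected enrichments surface as the two dark-shaded residues. (The
estimates sit below the nominal 1.8/1.4 because the reference here is the
whole protein, one third of which is the enriched linker pool itself.)
Dyad statistics and per-cell sample sizes:

```r
glance(count_dyads(linkers) |> dyad_propensities())
#>   model            n_dyads n_verylight n_light n_dark max_propensity
#> 1 marginal_product    5408         139       5      0           3.22

pairs_summary(linkers, by = "phylum")
#>   phylum              n_linkers mean_pairs sd_pairs label
#> 1 Firmicutes                 60       45.2     37.8 45.2±37.8
#> 2 Gammaproteobacteria        60       44.9     41.6 44.9±41.6
```

Flexibility profile (AI under the VINM940101 scale) of domains versus
linkers, as box-plot statistics:

```r
prof <- profile_groups(sim$sequences, linkers, scales = mocr_scales("VINM940101"))
glance(prof)[, 1:8]
#>   scale_id   group      n   min    q1 median    q3   max
#> 1 VINM940101 wHTH     120 0.981 0.995  1.00   1.01  1.02
#> 2 VINM940101 AAT      120 0.991 0.998  1.00   1.00  1.01
#> 3 VINM940101 linker   119 0.947 0.995  1.00   1.01  1.03
#> ...
autoplot(prof)   # the corresponding box plots
```

`run_linker_report(run_config(outdir, simulate = TRUE))` writes the whole
artifact set (members table, propensity tables, dyad matrices, pair-count
summary, scale profiles, histograms) plus an `index.json`, and
`inst/scripts/linker_report.R` wraps the same pipeline for shell use.

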