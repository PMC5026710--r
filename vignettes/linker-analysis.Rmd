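---
title: "Methods: linker peptide statistics for MocR-family regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linker peptide statistics for MocR-family regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocrlink)
```

## The problem

MocR-family transcriptional regulators consist of an N-terminal winged
helix-turn-helix (wHTH) DNA-binding domain, roughly 60 residues, joined by
a peptide linker to a C-terminal aminotransferase-like (AAT) effector
domain of roughly 350 residues. The linker is the least conserved part of
the protein: its length ranges from essentially zero to well over a
hundred residues, and its composition is expected to be biased towards
flexible, disorder-promoting residues. `mocrlink` quantifies those biases
— per-residue and per-dyad propensities, physicochemical scale averages,
secondary-structure content, and length distributions — for linker sets
stratified by bacterial phylum and by linker length.

This vignette documents the statistical conventions, the tunable
parameters, and the design decisions behind the package, in the order a
user meets them.

## Coordinates and extraction

All region coordinates are **1-based half-open** `[start, end)`: `start`
is the first linker residue and `end` the first residue of the AAT domain,
hence `length = end - start`. This is the only convention under which a
boundary row such as `start = 88, end = 148` corresponds to a 60-residue
linker, as in the bundled table of long-linker MocR regulators
(`mocr_long_linkers.tsv`, 72 entries, all with `length = end - start`).
Zero-length linkers (`start == end`) are valid members — the 0–20 length
bin exists — and are retained by extraction, not rejected.

Two extraction paths exist and are tested against each other:

* `extract_by_coordinates()` slices each sequence at its own boundary row.
* `extract_from_alignment()` maps a *reference* row's residue interval to
  the minimal alignment-column window containing it
  (`map_reference_to_columns()`), slices every row at that window and
  degaps each slice. Non-reference rows inherit the reference window —
  per-row re-detection of domain boundaries is deliberately out of scope,
  matching how linkers are cut from alignment blocks in practice. Rows
  that are all-gap inside the window yield empty linkers and are kept.

For the reference row itself the two paths are provably identical, and the
property suite checks window mapping against a brute-force
slice-then-degap oracle on random gap patterns.

## Length bins

Two closed-integer bin schemes are used. The **analysis** scheme (0–20,
21–40, 41–60, 61–200) stratifies the propensity tables; lengths above 200
are folded into the top bin with a warning. The **histogram** scheme
(0–20, 21–30, 31–40, 41–50, 51–60, >60) is used for subgroup length
distributions; its top bin is unbounded because "longer than 60" has no
natural ceiling. Each length maps to exactly one bin in either scheme.

## Residue and dyad propensities

The propensity of residue $i$ in a linker pool is

$$p_i = \frac{f_{\text{linker}}(i)}{f_{\text{ref}}(i)},$$

where $f_{\text{ref}}$ is a reference composition. The **default
reference is the pooled composition of the full-length proteins of the
same input set** (`pooled_reference()`), so $p_i$ measures
linker-versus-protein enrichment; `aa_background()` (the Swiss-Prot
average composition) or any user-supplied frequency table can be used
instead, and the pipeline exposes the choice as the `reference` setting.
Which reference a published table used is often unstated, which is exactly
why the package makes it explicit rather than hard-wiring one. A letter
observed in the linker pool but absent from the reference raises an error
(an inadequate reference sample should not silently become $p = \infty$);
a letter absent from the linker pool gets $p = 0$.

Dyads are ordered adjacent residue pairs, counted in **overlapping
windows within each linker** and never across linker boundaries; a linker
of length $L$ contributes at most $L - 1$ dyads. Two expectation models
are provided: the default `marginal_product` expects
$f(i)\,f(j)$ — deviation from compositional independence, which is the
interpretable reading of shaded dyad matrices — and `uniform` expects
$1/400$ in every cell, emulating compseq's default. Cells with zero
expected frequency are reported as undefined (`NA`), never 0 or infinity.
Under the marginal-product model the identity
$\sum_{ij} p_{ij}\,E_{ij} = 1$ holds over defined cells, and
$\sum_i p_i f_{\text{ref}}(i) = 1$ for residues; both are enforced in the
test matrix at $10^{-9}$.

Ambiguity letters (B, Z, X, U, O) are tolerated in input sequences but
excluded from **both numerator and denominator** of every composition
statistic, and any dyad window touching one is skipped; exclusion counts
are reported. This one rule is applied identically across the residue,
dyad and scale-average paths.

### Shading

Shading categories are a pure function of the propensity value *as
printed*, i.e. after rounding to 2 decimals (the print precision of the
published-style tables): residues — light for $1.01 \le p \le 1.19$, dark
for $p \ge 1.20$; dyads — very light for $1.10 \le p \le 1.99$, light for
$2.00 \le p \le 3.99$, dark for $p \ge 4.00$. Rounding first closes the
nominal gaps between, e.g., 1.19 and 1.20, so every value gets exactly one
category and boundary values classify exactly as quoted.

### Pair-count summaries

`pairs_summary()` reports mean ± sample standard deviation (the $n-1$
denominator) of per-linker dyad counts within each phylum × bin cell,
formatted `m±s` at one decimal. Large means signal well-populated cells
whose dyad propensities deserve trust; empty cells are omitted rather
than reported as zero.

## Scale profiles

The Average Index (AI) of a region under an amino-acid scale is the
arithmetic mean of the scale's values over the region's standard-letter
residues — a composition statistic, invariant to residue order and
affinely equivariant in the scale (both properties are tested). Regions
left empty after ambiguity exclusion propagate `NA`; regions with more
than 20 % exclusions are flagged.

Seven AAindex scales ship as flat-file fixtures and load through
`mocr_scales()`: VINM940101 (flexibility), CIDH920105 (hydrophobicity),
GEOR030101 (linker propensity), CHOP780101 (β-turn), CHAM830101 (coil),
CHOP780201 (α-helix) and CHOP780202 (β-sheet). Figure legends in the
literature sometimes cite the helix/sheet scales as `CHOP780102` /
`CHOP780103` and truncate `GEOR030101` to `GEOR03010`; those codes do not
exist in the AAindex databank, so `mocr_scales()` accepts them as aliases
of the canonical accessions. The bundled values are cross-checked in the
test suite against an independent copy of the databank.

Group summaries follow standard box-plot conventions, chosen because the
published figures come from a standard statistical environment's defaults:
quartiles by linear interpolation (`quantile()` type 7), whiskers at the
most extreme data within 1.5 × IQR of the box (Tukey), outliers listed
individually. Group order on the axis is fixed: wHTH, AAT, all linkers,
then length bins ascending. Rendering (`autoplot()`) is a convenience; the
numeric tables are the canonical output.

## Secondary-structure fractions

Three-state strings (H/E/C) are consumed, not predicted; letters from
richer alphabets are reduced by a configurable map (default G,I→H; B→E;
T,S,gap→C). The canonical summary is **pooled** (residue-weighted):
fraction(H) = total H residues / total residues per group, which sums to
exactly 1 per group and is invariant to how the pooled content is split
into records. A `mean` mode (average of per-linker fractions, each linker
weighted equally) is provided because published tables rarely state which
was used; the two differ whenever linker lengths vary.

## The synthetic generator

`generate_set()` emulates the study conditions: per phylum,
`n_sequences` proteins, each a wHTH segment (length
$\mathcal{N}(60, 5^2)$, rounded), a linker, and an AAT segment
($\mathcal{N}(350, 20^2)$). Domain residues are i.i.d. from
`aa_background()` (Swiss-Prot average composition); linker residues from
the background multiplied by per-letter `linker_enrichment` factors and
renormalised. Note the renormalisation: a nominal factor of 2.0 on
proline yields a true frequency ratio of $2/Z$ with
$Z = 1 + f_{\text{bg}}(P) \approx 1.047$, i.e. ≈ 1.91 against the
unenriched background — parameter-recovery checks compare against this
exact truth, which still lies within 5 % of the nominal factor.

Linker lengths are drawn from a mixture over the analysis bins, uniform
within the chosen bin (published data report only bins, not within-bin
shapes), with the 61–200 bin uniform on [61, 200]. The default mixture
(0.15, 0.40, 0.30, 0.15 over the four bins) reflects that most MocR
linkers are short-to-medium, with a substantial 41–60 shoulder and a
minority of long linkers; subgroup-specific mixtures (e.g. a GabR-like
set peaked in 21–40 versus a PdxR-like set peaked in 41–60) can be
attached via `subgroup_labels`. One global random stream per run, keyed
by `seed`, makes whole sets byte-reproducible.

`generate_alignment()` builds a gapped alignment as three column blocks
(wHTH, linker, AAT); each row's residues are scattered over seeded random
columns within its blocks, and the reference row's linker is pinned to the
block edges so that its minimal column window covers every row's linker
residues. Degapping any row reproduces its source sequence exactly, which
makes the alignment a constructive ground truth for window-based
extraction: the recovery rate is checked at 100 % across seeded gap
patterns.

`inject_dyad_excess()` overwrites seeded random adjacent positions with a
chosen dyad until its expected frequency is `excess` ×
$f_{\text{bg}}(i)f_{\text{bg}}(j)$. The ground truth is deliberately
defined **against the background composition**: injection of a dyad of
abundant residues (like GS) inflates the pool's own marginals, which
caps the self-marginal propensity well below the injected excess (near
4.1 for a 5× GS injection), whereas against fixed background marginals
the excess is recovered exactly in expectation. Recovery tests therefore
pass `marginals = aa_background()` to `dyad_propensities()`.

What the generator does **not** emulate: evolutionary divergence and
phylogenetic correlation between sequences, indel processes, actual
wHTH/AAT sequence motifs, or position-dependent composition within a
region. Passing tests on synthetic data therefore demonstrate the
correctness of the statistical machinery and its inversions
(parameter recovery), not biological conclusions about real MocR sets.

## Numerical choices and degenerate inputs

* Frequencies and mixture weights must sum to 1 within $10^{-9}$;
  normalisation identities are asserted at the same tolerance.
* Empty residue pools, empty groups and empty histogram sets are errors
  or omissions (stated per function), never silent zeros.
* Rendered tables default to 2 decimals; `pairs_summary()` labels to 1
  decimal, matching the conventional table formats.
* Sample standard deviations use the $n-1$ denominator; a single
  observation reports sd 0 in `pairs_summary()` and a degenerate box in
  profiles.
* Test problem sizes were chosen for tight statistical bounds at small
  cost: ≥ 50,000 linker residues for enrichment recovery (multinomial
  SE ≈ 0.1 % per letter), 1,000 random peptide sets for the dyad-count
  oracle, 100 gap patterns × 24 rows for alignment recovery; the whole
  suite runs in well under a minute.

## Known limitations

* The alignment path assumes the reference window is trustworthy for all
  rows; genuinely mis-aligned rows will yield truncated or extended
  linkers with no warning beyond their anomalous lengths.
* Propensities come with no significance test; the shading thresholds are
  conventions, not inference. Cells should be read together with the
  pair-count summaries.
* The AAindex parser covers the single-entry flat-file layout (H/D/I
  lines) and two-column tables, not multi-entry databank dumps.
* `read_ss()` validates lengths only when a linker set is supplied;
  free-standing state files are taken at face value.
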