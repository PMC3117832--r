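---
title: "Measuring the evolutionary plasticity of gene families"
author: "evoplast authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the evolutionary plasticity of gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoplast)
```

## The model

An orthologous group (a KOG/COG-style cluster containing both orthologs
and paralogs) leaves a *phyletic pattern*: for each species `i` of an
`M`-species panel, a member count `s(i,α)`. The package reduces that
pattern to three numbers.

**Diversity** is the Shannon entropy of the count profile, normalized to
`[0, 1]` by `ln M`, with `p(i,α) = s(i,α)/N_α` and the usual convention
`0·ln 0 = 0`:

$$H_\alpha = -\frac{1}{\ln M}\sum_{i=1}^{M} p(i,\alpha)\,\ln p(i,\alpha).$$

The normalization deliberately uses the *full* panel size `M`, not the
number of occupied species: a family can only be maximally diverse if it
is evenly present in every species of the panel. Absent species
contribute zero terms to the sum but still shrink the attainable
maximum. Natural logarithms throughout.

**Abundance** is the mean copy number over occupied species,
`D_α = N_α / M_α ≥ 1`; species lacking the family do not affect it.

**EPI** combines the two as

$$EPI = 1 - \frac{H_\alpha}{\sqrt{D_\alpha}} \in [0, 1].$$

The index is zero exactly for the fully conserved case (`H = 1`,
`D = 1`: one copy in every species), strictly decreasing in diversity
and strictly increasing in abundance. The square root tempers the
abundance penalty: doubling copy number everywhere leaves `H` unchanged
and multiplies `D` by two, raising EPI, but sub-linearly — a deliberate
choice that keeps very large families (`D` in the hundreds) from
saturating the index immediately. This functional form is pinned by two
desk-checkable two-species cases that the test suite asserts to nine
decimals: counts `{99, 1}` give `H = 0.080793136`, `D = 50`,
`EPI = 0.988574125`; counts `{50, 50}` give `H = 1`, `D = 50`,
`EPI = 0.858578644`. Any change to the form must reproduce both.

No phylogeny enters the index: species are exchangeable, and taxonomic
relatedness among the panel is intentionally ignored. Two sister species
and two distant phyla contribute identically.

## Sequence divergence

For a family alignment the package scores every unordered pair: columns
where either sequence carries a gap (`-`) or missing data (`X`, `?`, `.`)
are removed *for that pair only* (pairwise deletion), `p` is the fraction
of differing residues among the remaining sites (case-insensitive,
literal comparison — `B`, `Z`, `J` compare as themselves), and the
Poisson-corrected distance is `d = −ln(1 − p)` substitutions per site.
No rate-heterogeneity (gamma) correction is applied, and alignment is
taken as given; the package never aligns.

Two degenerate pair types cannot be scored: pairs with no shared
ungapped column, and saturated pairs with `p = 1`, where the correction
diverges. Both are excluded from the family mean and surfaced in a
skipped-pair count (`nSkipped`) rather than clamped — clamping would bias
means invisibly, and an exclusion you can see is easier to reason about.
A family whose pairs are all skipped has no defined mean and errors.

## Statistical layer

* **Group sampling** takes the smallest integer not below
  `fraction × n` groups (minimum one), uniformly without replacement
  under a mandatory seed. With `n = 4850` and `fraction = 0.05` this is
  exactly 243 groups — the sample size at which sequence-level analysis
  of a genome-scale table stays tractable.
* **EPI–distance association** is a Pearson correlation with a
  two-tailed p from the t distribution on `n − 2` df. Groups lacking a
  distance are dropped and counted.
* **EPI distributions** use 100 equal-width bins on `[0, 1]`, half-open
  `[lo, hi)` with the last bin closed so `EPI = 1` is counted.
* **Gene-set comparison** defaults to a two-sided Mann–Whitney U with
  normal approximation and tie correction. The choice is the package's
  own: EPI is bounded and typically skewed, so a rank test is the safer
  default; a Welch t-test is available via `test = "t"` for users who
  want a mean-based contrast. P-values are floored at machine precision
  and never reported as zero. Quartiles, medians, means and standard
  deviations for both sides accompany the test, since a significant U
  says nothing about effect size.

## Network projection

Edges below the confidence threshold (default 0.700, the conventional
high-confidence cutoff for STRING-style weighted edge lists) are
dropped, as are self-loops and isolated nodes; duplicate edges collapse
to their maximum weight and direction is ignored. Each node inherits the
EPI of its group; a protein in several groups takes the *minimum* EPI by
default — a node is treated as being as conserved as its most conserved
family — with `combine = "mean"` as the alternative. Regional structure
is summarized two ways: `smoothEpi()` replaces each node's value by the
mean over its ≤ `radius`-hop annotated neighborhood (radius 0 is the
identity; on a connected graph the limit of large radius is the global
mean), and `moduleSummary()` reports per-pathway EPI statistics with
multi-label nodes counted under each label. Smoothing is a contraction —
smoothed values never leave the range of the node values — so it can
reveal, but never invent, a low-plasticity region. Grid-based landscape
rendering is out of scope; the testable claims are regional rankings,
which the summary table carries.

## The simulator

`simulateOrthoTable()` draws families under regimes defined by two
knobs: a per-species retention probability ρ (each of the `M` panel
species independently keeps the family) and a duplication rate λ
(retained species hold `1 + Poisson(λ)` copies). Families retained
nowhere are redrawn, so every emitted group is non-empty. The default
panel has 55 species, matching the eukaryote panel of the orthology
resource the method was designed around. The two named regimes bracket
the dichotomy the index is meant to capture: *conserved* (ρ = 1, λ = 0)
forces `H = 1`, `D = 1`, `EPI = 0` by construction; *plastic* (ρ = 0.3,
λ = 3) produces patchy, duplication-heavy profiles with strictly
positive EPI.

`evolvePair()` provides sequence-level ground truth: a uniform random
ancestor over the 20 amino acids, each lineage's sites hit by
`Poisson(d/2)` substitutions, each substitution to a uniformly chosen
*different* residue. Because 20 states can revert, the expected observed
difference at true distance `d` is not `1 − e^{−d}` but

$$\mathbb{E}[p] = \frac{19}{20}\left(1 - e^{-20d/19}\right),$$

exposed as `expectedPoissonP()`. Recovery tests compare the mean
estimated distance against `−ln(1 − E[p])` — the expectation matched to
the generating process — rather than against `d` itself; the product
code keeps the plain Poisson correction, which is the estimator under
study. Recovery runs use pairs of length 2000 with 200 replicates at
true distances 0.05, 0.2 and 0.5, asserting agreement within three
standard errors.

What the simulator does **not** emulate: a dated species tree (retention
is independent per species, with no phylogenetic covariance in losses),
realistic exchange matrices (no WAG/LG), indels (alignments are
ungapped), rate variation across sites, and correlated
duplication/retention between interacting families. Tests passing on
simulated data therefore validate the estimators and the pipeline
plumbing under the model's own assumptions — they do not show that real
orthology tables satisfy those assumptions.

## Numerical and interface choices

* Counts must be non-negative integers; empty groups and single-species
  panels (`ln M = 0`) are errors, not NaNs.
* The uniform fully-occupied profile returns `H = 1` exactly (a
  shortcut avoids summing `M` identical floating terms), so conserved
  families report `EPI = 0` exactly; all other values are stored
  unrounded and written at nine decimal places in the results TSV.
* Membership tables deduplicate on (protein, group); a protein in
  several groups counts once *per group*, including in per-protein EPI
  histograms — a documented choice where upstream conventions are
  silent.
* Groups and species are ordered lexicographically on construction, so
  reading a shuffled table yields a byte-identical object.
* All stochastic entry points (`sampleGroups`, the simulator, the CLI's
  `simulate`/`distance` subcommands) require an explicit seed and
  restore the caller's RNG state afterwards.
* Desk-scale defaults keep the full test suite and the end-to-end CLI
  smoke run in well under a minute: fixture bundles default to 25
  families per regime, 150-residue alignments, 200-protein gene sets.

## Limitations

The index treats the species panel as exchangeable and equally weighted;
taxonomic bias in the panel (e.g. many close relatives) inflates
apparent diversity for families shared among them. Abundance cannot
distinguish one species with 99 paralogs from an even 50/50 split —
diversity is what separates those two cases, which is precisely why the
index combines both. Saturated pairs are excluded from family means, so
means for extremely diverged families are conditional on the scorable
pairs. The Mann–Whitney normal approximation is poor below roughly ten
observations per side; for such sets, rely on the reported descriptive
statistics (or an exact test) rather than the p-value.
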