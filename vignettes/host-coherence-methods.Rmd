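---
title: "Host coherence scores for strain-level metagenomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host coherence scores for strain-level metagenomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainniche)
```

## The problem

When a gut microbial species is found in several host species — say a
species-level genome bin (SGB) detected in cats, dogs and humans — its
strains may either form host-specific lineages (evidence of host
adaptation and infrequent cross-host transmission) or be genetically
interchangeable across hosts (evidence of frequent transmission).
`strainniche` quantifies this with a coherence (niche-association)
score computed from pairwise genetic distances between per-sample
consensus strains, and packages the surrounding community-level and
screening analyses such surveys rely on.

## Distance model

Strain relatedness is measured by Kimura's two-parameter (K2P/K80)
distance, which separates transitions (A↔G, C↔T; rate α) from
transversions (rate β for each of the two alternatives). With `P` and
`Q` the observed transition and transversion proportions over compared
sites,

$$d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big].$$

Two practical choices matter here:

* **Pairwise deletion.** Consensus-strain alignments are gappy, and a
  site is only informative for a pair if both sequences carry a real
  base there. For every pair we drop sites where either sequence has
  `N` or `-`; both symbols are treated identically as "no information".
  IUPAC ambiguity codes other than `N` are rejected at read time rather
  than resolved — consensus strains rarely contain them and any silent
  resolution rule would bias `P` and `Q`.
* **Saturation and short overlap.** When `1 − 2P − Q ≤ 0` or
  `1 − 2Q ≤ 0` the model cannot invert the observed divergence; the
  pair is flagged *saturated* and carried as `NA`, a value, not an
  error. Pairs with fewer than `min_sites` comparable sites (default
  100) are treated the same way: distances feed medians downstream, and
  estimates from very short overlaps are noisy enough to distort them.
  The default is a deliberate package choice; it is configurable per
  call.

`k2p_distance_matrix()` agrees with `ape::dist.dna(model = "K80",
pairwise.deletion = TRUE)` to 1e-10 on simulated alignments (this is an
independent cross-check in the test suite, not the implementation).
Distance matrices can be written/read as labelled square TSVs, with a
`scale = 100` option matching the per-100-sites convention of EMBOSS
`distmat` output; triangular (one-sided) files are mirrored into the
canonical square form on read.

## The coherence score

For an SGB with host-labelled strains, each host *h* with at least
`min_strains = 5` strains receives

$$\mathrm{score}_h = \max\!\left(0,\;
  \frac{\mathrm{median}(B) - \mathrm{median}(W)}{\mathrm{median}(B)}\right),$$

where `W` are the finite distances among *h*'s strains and `B` the
finite distances from *h*'s strains to all other strains. The SGB score
`C` is the unweighted mean of the defined host scores.

Design choices, made where the design was genuinely open:

* **Median contrast, clipped at zero, normalised by the between-host
  median.** The score is then scale-invariant (multiplying all
  distances by `k > 0` changes nothing), lives in `[0, 1]`, equals 0
  for fully mixed clades, and approaches 1 for tight host-exclusive
  clades. Medians rather than means keep single saturated or outlying
  pairs from dominating, which is also why saturated pairs can simply
  be dropped from `W` and `B`. Plausible alternatives exist (e.g. a
  nearest-neighbour label fraction); the median contrast was chosen for
  its closed-form behaviour under the simulation model below, which
  makes the estimator testable.
* **Undefined rather than wrong.** If more than half of the pairs
  relevant to a host are saturated, that host's score is `NA`; the SGB
  mean averages only defined scores. This prevents a handful of
  invertible pairs from standing in for a mostly saturated clade.
* **Small hosts feed, but are not scored.** Hosts with fewer than 5
  strains contribute their strains to other hosts' `B` pools (all data
  are used) but receive no score of their own (no medians over a
  handful of pairs).
* **Unweighted mean across hosts**, so a host with 400 samples does not
  drown one with 20.

Eligibility for scoring an SGB at all follows the standard screening
rules: shared by ≥ 2 hosts, ≥ 20 samples in total, and ≥ 5 samples in
each of at least 2 hosts (`eligible_sgbs()`).

## Synthetic data and what it does (not) show

`simulate_strain_set()` draws a uniform random root sequence, one host
ancestor per host at branch length `t_b` (expected substitutions/site)
from the root, and each strain at branch length `t_w` from its host
ancestor, all under the K80 process with transition/transversion rate
ratio `kappa` (default 2, a typical bacterial value). The generator's
defaults — 3 hosts, 20 strains per host, `L = 5000` sites,
`t_w = 0.01`, `t_b = 0.09` — define the validation conditions used
throughout: within-host pairs then diverge by `2 t_w` and between-host
pairs by `2(t_w + t_b)` in expectation, so the expected coherence is

$$C \approx \frac{t_b}{t_w + t_b} = 0.9,$$

a closed form that the acceptance checks verify to ±0.05 over 20
simulation seeds. A `mixing` parameter relabels a fraction of strains
uniformly at random; `mixing = 1` (or `t_b = 0`) is the no-signal
control under which `C` stays below 0.05.

The star-within-star genealogy is intentional: no coalescent, no
recombination, no rate variation across sites or lineages. That is what
gives the closed-form expectation; it also means a passing test shows
the estimator recovers planted within/between divergence contrast, not
that real strain phylogenies (with nested subclades, uneven sampling
and homoplasy) will yield any particular score. Real-data scores also
depend on upstream profiler choices that are out of scope here.

`simulate_abundance_table()` generates log-normal relative abundances
with `n_signature` taxa per host multiplied by `1 + effect` in that
host, rows renormalised to 1 — enough structure to calibrate the
ordination and PERMANOVA machinery (null p-values uniform at
`effect = 0`, planted signal detected at moderate `effect`), while
making no claim to realistic taxon co-occurrence or compositional
correlation structure. `simulate_screening_fixtures()` plants records
on every branch and boundary of the MAG/ARG rules, including ties and
the exact threshold values.

## Ordination and PERMANOVA

Bray–Curtis dissimilarities (`vegan::vegdist` behind `bray_curtis()`)
feed a classical PCoA: Gower double-centering of `−d²/2`,
eigendecomposition, scores scaled by `sqrt(λ)`. Axes with non-positive
eigenvalues are dropped without Lingoes/Cailliez correction — the
ordination is used for display and for the score-based statistics
below, none of which need the negative part of the spectrum. For
Euclidean-embeddable input the scores reproduce the input distances to
1e-8 (a property test against `stats::cmdscale`).

Two survey-specific operations sit on top:

* `frequency_correct()` divides each sample's scores by its host's
  sample size, compensating for heavily unbalanced designs (hundreds of
  dogs vs tens of cats). The correction is guarded against double
  application and preserves within-group rank order. Taxon annotations
  via `feature_positions()` use the abundance-weighted average of the
  *same* scores as plotted — corrected if the ordination was corrected;
  whether to annotate raw or corrected ordinations is the caller's
  choice and the package simply follows the state of the ordination
  object.
* `permanova()` implements the one-factor permutational MANOVA directly
  from distance sums of squares (`R² = 1 − SS_w/SS_t`, Anderson's
  pseudo-F), with the permutation p-value `p = (#{F* ≥ F} + 1)/(B + 1)`
  and a mandatory seed. It matches `vegan::adonis2` and a brute-force
  double-loop oracle to 1e-10 in the tests. Multi-factor marginal
  models are out of scope; one factor covers every property validated
  here.

## Screening and ARG rules

All screening thresholds are strict inequalities exactly as
conventionally stated, with boundary behaviour unit-tested:

* MAG quality: `high` iff completeness > 90 and contamination < 5,
  else `medium` iff completeness > 50 and contamination < 10, else
  `low`. Note the common prose definition of "low" (< 50% completeness
  *and* > 10% contamination) does not partition the plane; `low` is
  therefore defined as "neither high nor medium", which matches its
  discard semantics and makes the grading total.
* Genome-bin assignment: nearest bin by Mash distance (ties broken to
  the lexicographically smallest bin id, for determinism), at SGB /
  genus / family level for distances below 0.05 / 0.15 / 0.30, else
  novel. Novel SGBs enter a marker database only with ≥ 5 supporting
  genomes.
* Presence: a taxon is present in a host when ≥ 3 of that host's
  samples carry it at relative abundance ≥ 1e-5 (the threshold is
  inclusive; both the floor and the count are configurable), and
  host-sharing categories are the exact set of hosts with presence.
* ARG hits: retained at ≥ 90% identity and ≥ 80% *mutual* coverage —
  both query and subject, the only reading under which "mutual" adds
  information. ARG presence needs abundance > 0 in ≥ 3 samples of at
  least one single host (not pooled). Drug-class aggregation sums
  member ARGs per class; an ARG mapped to several classes contributes
  its full abundance to each (resistance classes overlap and are not a
  partition), and unmapped ARGs land in an `unclassified` bucket so
  that mass is conserved relative to the class map's multiplicity.

## Numerical and reproducibility choices

* Saturated distances are `NA` throughout — a value with defined
  semantics at every consumer (dropped from medians; written as the
  literal `NA` on disk; rejected by PCoA/PERMANOVA, which require
  finite input).
* Every stochastic routine takes a mandatory seed and restores the
  caller's RNG state on exit; identical config + seed reproduces
  pipeline outputs byte-for-byte (checksummed in the run log).
* Distance files round-trip through disk at 6 decimals; all round-trip
  tests use absolute 1e-6 tolerances.
* Validation problem sizes were chosen as the smallest at which the
  statistical claims are sharp: 20 replicate simulations at `L = 5000`
  and 20 strains/host for coherence recovery (Monte Carlo error well
  under the ±0.05 band), 200 seeds × 199 permutations for the PERMANOVA
  null-uniformity check (the p-value grid of 1/200 is negligible at the
  KS α = 0.01 used), and `L = 100 000` for the transition:transversion
  ratio check.

## Known limitations

* The coherence score is a summary of medians; it does not localise
  *which* subclade is host-associated, detect nested structure, or date
  transmission events. Tree-based methods are needed for those.
* K2P assumes equal base frequencies and no rate variation across
  sites; for highly diverged or compositionally skewed clades the
  saturation marker will fire often and the score degrades to
  undefined rather than attempting a richer model.
* The PERMANOVA is one-factor; confounded designs (host vs study)
  need marginal multi-factor models outside this package's scope.
* The simulators are validation instruments, not realistic data
  emulators: no coalescent within hosts, no recombination, no
  compositional covariance between taxa.
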