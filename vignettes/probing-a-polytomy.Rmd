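---
title: "Probing a polytomy: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing a polytomy: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytomyprobe)
```

# The question

Three lineages — call them A, B and C, with the elephant/hyrax/sea-cow
triplet as the canonical instance — can be joined in exactly three ways.
When thousands of gene trees distribute almost evenly over the three
resolutions, the species-tree branch separating them is either very short
(deep coalescent variance), crossed by gene flow, or both; it may be
operationally indistinguishable from a hard polytomy. This package
assembles the evidence for one such branch from per-gene trees and
(optionally) codon alignments.

# The coalescent model underneath

All expectations come from the multispecies coalescent (MSC) on the
species tree ((A,B),C),O. Time is measured in coalescent units (2N
generations). On an internal branch of length T, the A and B lineages
coalesce before reaching the ancestral population with probability
1 − e^(−T); otherwise all three lineages enter it and pair uniformly, so

* P(gene tree matches the species tree) = 1 − (2/3)e^(−T),
* P(each discordant resolution) = (1/3)e^(−T).

Two consequences drive the tests:

* **Equal discordant frequencies.** Under ILS alone the two discordant
  topologies are equally probable. The discordant-count test (DCT) is the
  two-cell χ² (df = 1, no continuity correction; an exact binomial is
  available via `dct(..., exact = TRUE)`) against that 50:50 null.
* **Equal discordant coalescence depths.** Under ILS alone both discordant
  classes first coalesce *above* the branch, so their depth distributions
  coincide. Introgression at time t_m < t1 creates recent coalescences in
  the recipient-donor pair only. The branch-length test (BLT) compares
  depth distributions: Kruskal-Wallis for raw depths, Mann-Whitney for
  depths scaled by each gene's total tree length (the scaled variant
  cancels per-gene rate variation). Holm's step-down correction is applied
  within each three-comparison family.

Inverting the concordance probability gives the branch-length estimator
`msc_branch_length()`: T̂ = −ln((3/2)(1 − ĉ)) for majority fraction
ĉ > 1/3, 0 below it, capped (default 10) when ĉ = 1. Its delta-method
standard error, used by the recovery tests, is √(ĉ(1−ĉ)/n)/(1−ĉ).

The local posterior probability of each resolution integrates the MSC
concordance probability over an exponential (Yule, rate λ = 0.5 by
default) prior on the branch length and normalises across the three
resolutions given the multinomial gene counts. The integral is evaluated
by Laplace-windowed quadrature on the log scale with the tail terms
written analytically (log((1−θ)/2) = −d − log 3), which keeps counts in
the tens of thousands stable; the test suite checks it against an
independent quadrature in a different parameterisation.

# Classification choices

A gene tree is restricted to the focal taxa plus **one** outgroup
representative (chosen by a priority list) rather than requiring outgroup
monophyly: gene trees with scattered outgroups remain usable, which
matters when genes may lack up to a handful of species. A lineage with
several taxa must form a clade on that restricted unrooted tree; if not,
the gene is `NONMONOPHYLETIC` (the gDFP class). The focal stem is the
single internal edge subtending the sister pair after collapsing lineages
(`mode = "stem"`); `mode = "representative"` first prunes each lineage to
one taxon, mirroring analyses that test single species. Whole-group
monophyly is judged separately, against *all* sampled outgroup taxa.

Pairwise coalescence depth is half the patristic distance between lineage
anchors (the leaf for a singleton, the lineage-clade root otherwise). Note
a consequence: a multi-taxon lineage's anchor sits at its own crown
height, so its depths carry a constant offset relative to singleton
lineages. Cross-class BLT comparisons at lineage level are therefore most
cleanly interpreted in representative mode or through `run_trios()`, which
tests every species trio separately — the practice this mirrors also used
species trios.

Internode certainty uses counts of gene trees per split (not quartet
counts): IC = 1 + p₁log₂p₁ + p₂log₂p₂ over the two most frequent
conflicting splits, ICA = 1 + Σp̄ᵢlog_k(p̄ᵢ) over all k of them. The
"maximum IC" of a one-tree margin is modelled as a single reassignment
from a perfect tie of the same total (counts n/2+1 vs n/2−1) — an
interpretation, recorded here because the construction is not otherwise
determined.

Site concordance is the descriptive parsimony variant: a site is decisive
for a sampled quartet (one taxon per lineage plus an outgroup taxon) when
it shows two states, twice each, with no gap or N; the pairing picks the
resolution. Quartets are capped (default 100 per gene, seeded subsampling,
exhaustive below the cap). Likelihood-based sCF implementations weigh
sites differently, so per-gene values need not match theirs; the decisive
properties (symmetry near a collapsed branch at ≈33%, saturation to 100%
on long stems) are what the tests pin down.

# Topology tests

The likelihood engine is plain Felsenstein pruning over JC69/K80/HKY85
(spectral decomposition of the reversible rate matrix, branch lengths in
expected substitutions/site), with an optional discrete-gamma layer using
the mean rate per equal-probability category. Gaps and N are missing data;
multifurcations are native, so the polytomy tree needs no special casing.
The engine is validated against an independent implementation (phangorn)
to 10⁻⁶ on mixed-gap alignments.

Branch lengths are optimised coordinate-wise (bracketed scalar
optimisation per branch, cycling until the round improves the
log-likelihood by < 1e−4, at most 50 rounds, lengths clamped to
[1e−9, 10]). Each resolved quartet is seeded from the fitted polytomy with
the internal branch collapsed to the clamp floor, so
lnL(polytomy) ≤ lnL(resolution) + 1e−6 holds by construction — the
nesting the per-gene test logic depends on. The clamp floor sits at 1e−9
because the collapsed branch's residual likelihood cost is proportional to
floor × sites and must stay below that 1e−6 budget.

The RELL family resamples per-site log-likelihoods (multinomial site
weights, default 10,000 replicates): bootstrap proportions with ties split
equally (totals within 10⁻³ lnL count as tied — differences that small
are optimiser noise, not signal), KH as the centred two-sided test of the
pairwise ΔlnL, SH as the per-tree-centred max statistic over the
candidate set, weighted variants studentised by each replicate's own
resampled site variance, and expected likelihood weights as mean
exp-normalised weights. Pairings follow `comparison = "vs_polytomy"`
(each resolution against the collapsed tree — the reading of a test *for
improvement over the polytomy*) with `"vs_best"` available. Degenerate
pairs — |ΔlnL| and its site-variance both under 10⁻² — are reported as
p = 1: two fits that close are numerically the same model, and resampling
noise against noise would otherwise manufacture spurious zeros. The AU
test fits the signed-distance/curvature model z(r) = d√r + c/√r to
normal-quantile-transformed bootstrap proportions across resampling scales
0.5–1.4 by weighted least squares and returns 1 − Φ(d − c), falling back
(flagged) to the plain bootstrap proportion when fewer than two scales are
informative. A gene rejects the polytomy when its best resolution's
pairwise KH p ≤ α; `summarize_rejections()` also reports the weight-based
criteria (polytomy ELW or bp ≤ α) per test.

# Alignment hygiene

`drop_incomplete_codons()` gaps out, per species, any codon containing a
residual gap or N, then removes codon columns gapped in every species (in
triplets, preserving frame). `trim_indel_flanks()` implements the
indel-flank rule: at each side of every maximal gap run, over windows of
x = 1..20 codons, if more than x/2 of the window's codons translate to an
amino acid different from the column consensus, those x codons are gapped
out for that species. Several x can qualify; the **largest** is taken —
the conservative, most-removing reading, and the one consistent with a
worked 8-of-12 → remove-12 example (any smaller qualifying window is
subsumed). The strict inequality means 2-of-3 qualifies at x = 3 but
1-of-3 does not. The scan runs at most twice (removal can merge gap runs),
with the consensus recomputed for the second pass; a third pass is
guaranteed to remove nothing, and the log records every removal with its
mismatch count. Consensus ties break alphabetically (flagged) and stop
codons count as a 21st symbol. Codon indices are 1-based throughout, as is
natural in R.

# The simulator: what it emulates, and what it does not

`simulation_config()` fixes the study conditions; the defaults are the
conditions the analyses assume, not tuning knobs. One lineage is sampled
per focal lineage; the default taxon set mirrors the motivating clade
(elephant, two hyraxes, manatee, one outgroup), with a two-species lineage
drawn as a fixed cherry (split at 0.3 coalescent units) beneath its stem —
hyrax monophyly is treated as settled, so lineage polyphyly arises only
from the explicit `poly_noise` component (random-join genealogies resampled
until a lineage is interleaved). Introgression is a pulse: with
probability γ the recipient lineage sits in the donor population from t_m
until the populations merge, the minimal model that generates both the
count asymmetry (DCT) and the depth shift (BLT). Coalescent-unit branch
lengths become substitutions/site through μ times a per-gene lognormal
rate of mean 1.

`preset_paenungulata()` fixes T = 0.08 coalescent units, γ = 0.08 (C→A at
t_m = 0.1), μ = 0.005 substitutions/site per coalescent unit, lognormal
rate sd 0.3, 10% polyphyletic noise, 1% missing species and 13,388 genes:
chosen once so the census lands near the motivating dataset's signatures —
the concordant class leading with the two discordant classes close behind,
roughly a tenth of genes polyphyletic, ~97% of focal stems under 0.02
substitutions/site, and only ~2% of stem supports reaching 95. Branch
supports themselves are a stylised emulation (a saturating function of
edge length plus Gaussian noise, clamped to [0, 100]): they reproduce the
support-length correlation and the "mostly below 95" regime but are not a
likelihood-ratio computation.

Genealogies have binary roots; empirical gene trees are unrooted, so
rendered trees are spliced to a root trifurcation and the two root edges
merged — otherwise one unrooted edge would carry two conflicting support
labels. The recorded per-gene classification (category, stem, depths,
support) is computed directly from coalescence times and is tested to
agree exactly with `classify_gene_tree()` on the rendered newick.

Each gene draws from its own RNG stream derived from (dataset seed, gene
index) by two Lehmer rounds, making datasets reproducible bit-for-bit and
genes independent across both indices and nearby dataset seeds.

What the simulator does **not** emulate: sequence errors and alignment
artifacts, rate variation across sites within a gene beyond the optional
gamma layer, ancestral population structure, recombination within loci,
and more than four lineages. Passing tests therefore demonstrate the
statistical machinery under a clean MSC + pulse model — they do not show
that real alignments satisfy those assumptions.

# Problem sizes and numerical choices

The test-suite simulations use 800–10,000 genes per dataset (10,000 for
closed-form frequency checks, 200 replicates of 2,000 genes for the DCT
size check, 40 replicates of 1,000 genes per γ for power monotonicity,
5,000 genes for branch-length recovery) and 60–500-codon alignments for
the likelihood tests — sizes at which binomial standard errors make the
assertions sharp while the whole suite stays comfortably interactive.
Statistical assertions are framed at 3 standard errors or as interval
checks on rates, never as exact matches to stochastic output. Where exact
values are asserted (IC/ICA arithmetic, χ² statistics, Holm adjustments,
the trimming examples, two-taxon likelihoods) the expected numbers come
from closed forms or hand enumeration.

Known limitations, beyond the simulator scope above: the census is
triplet-only by design (no all-branch concordance over a full species
tree); site concordance is the parsimony variant; the likelihood engine
offers no codon, amino-acid or mixture models; and the local posterior
takes the ASTRAL-style default prior (λ = 0.5) as given rather than
estimating it.
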