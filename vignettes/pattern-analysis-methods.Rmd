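---
title: "Distributed sequence patterning of compositionally biased protein regions: models and methods"
author: "cbpatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed sequence patterning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbpatterns)
```

# Scope

Intrinsically disordered regions (IDRs) and low-complexity or
compositionally biased regions (LCRs/CBRs) encode function in a
*distributed* way: what matters is less a precise motif than how residues
of particular types are used and arranged along the tract. `cbpatterns`
scores five complementary aspects of that arrangement — compositional
modules, compositional banding, residue blockiness, homopeptide content,
and interval-entropy repetitiveness — each against an explicit null model,
so that every reported feature comes with a z-score, an empirical p-value,
and a direction call.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices made where the design was genuinely open,
and the limits of what the bundled toy-sequence generator can demonstrate.

# Null models

Two null models are used throughout.

**Scrambled-sequence nulls.** Blockiness, homopeptide content, and
interval entropy are compared against the same statistic computed on
composition-preserving random permutations of the input (default
`nSamples = 1000`). Because a scramble conserves composition exactly, any
signal is attributable to *arrangement*, never to amino-acid usage.

**Random-endpoint nulls.** Band evenness is compared against random band
layouts on the same span: the two outermost endpoints stay pinned at the
observed span ends and the `2k - 2` interior endpoints are redrawn
uniformly. Pinning is a deliberate choice — the comparison is "how evenly
are these bands arranged *over this span*", and free outer endpoints would
systematically shrink the span and bias the null.

Empirical p-values use the add-one convention,
`p_high = (1 + #{null >= obs}) / (n + 1)` and the `<=` analogue, so p is
never 0: `n` null samples cannot support p below `1/(n+1)`. Both one-sided
p-values are always computed; each analyzer interprets direction (for
blockiness, "high" means significantly blocky and "low" significantly
un-blocky, and so on). The significance level `alpha` defaults to 0.05 and
is configurable; every calibration statement in the tests refers to the
per-direction rate, which for an exchangeable statistic sits at `alpha` by
construction. A degenerate null (zero standard deviation, e.g. any
statistic of a homopolymer) flags the z-score undefined; the call is still
derived from the empirical p-values, so a constant null equal to the
observed value yields "none" rather than an error.

The pipeline derives one sub-seed per (sequence, analyzer) pair from the
global seed by hashing the sequence id, which makes batch output
independent of input order and byte-reproducible.

# The compositional-bias scanner

The scanner (`scanBias`) finds windows whose residue usage is improbable
under a background composition, scoring a window of width `w` containing
`k` residues of a candidate class with the exact binomial tail
`P(X >= k)`, `X ~ Binomial(w, p_class)`. Its three parameters are the
minimum window `m`, the maximum seed window `M`, and the p-value threshold
`t`. The search is a seeded hill-climb:

1. For each residue type, windows of increasing size (every size when the
   `m..M` range is short, else doubling from `m`) are slid along the
   sequence. A window becomes a seed when its count passes the pre-filter
   `k >= p_a * w + 2` — tails are never computed for windows that cannot
   be meaningfully enriched — and its tail p-value passes a relaxed
   threshold (`max(t, 0.1)`): a window can fail `t` on its own yet anchor
   a multiple-residue signature that passes it, so only final regions are
   filtered at `t`.
2. Each seed is refined by hill-climbing: the boundary move (±1 on either
   end) that most lowers p is accepted until no move lowers it. Every
   reported region is therefore locally p-minimal.
3. Multiple-residue signatures are grown greedily. A candidate residue
   must itself be enriched in the current window under the same count
   pre-filter; adding it treats the signature as a composite success
   class (`p_S` = summed background frequencies, `k` = total count),
   boundaries are re-minimized, and the extension is kept only if the
   p-value strictly decreases. The greedy chain is additionally evaluated
   at each raw seed window, because a composite optimum (for instance two
   adjacent different-residue runs) may not be reachable from any
   single-residue local optimum.
4. Overlapping hits with the same primary residue are merged: the union
   span is re-minimized under each parent's signature and under the
   primary alone, and the best of those candidates — or the better parent,
   if the union refuses to improve on it — replaces the pair. A merge can
   therefore never worsen the best hit, and merged runs longer than `M`
   survive as single regions.

Signatures are reported in order of bias precedence: the *primary*
residue is the most dominant signature member in the final window
(members are ordered by their final counts, ties keeping order of
addition). The enrichment requirement on extension candidates keeps
signatures interpretable: a residue that merely borders a biased run, at
background frequency, never joins its signature.

The background composition defaults to the frequencies of the input set
itself, add-one smoothed over the 20 standard residues so every frequency
is strictly positive and no external table is required; `uniform` (1/20)
and user tables are also supported. X (unknown) residues count toward
window length but can never be signature members.

Because hill-climbing and fixed-window greedy chains explore slightly
different spaces, exact equality with an exhaustive enumeration holds for
single-residue signatures (and is asserted in the tests for L ≤ 30);
for multiple-residue signatures the scanner is asserted to *dominate* the
fixed-window greedy-chain minimum — it never reports a weaker best region
than enumeration finds, and may report a stronger one, since it also
re-minimizes boundaries between additions.

# Compositional modules and boundary sets

`deriveModules` reduces hits pooled over twelve parameter triads to
*compositional modules*: regions sorted on increasing p-value are accepted
greedily, and each acceptance de-selects every remaining same-primary
region on the same sequence whose overlap covers at least half *of that
remaining region's own extent* — "its" is read as the candidate being
de-selected, which guarantees that an accepted strong region absorbs
nested weaker variants of any length. Ties on p are broken toward the
longer region, then the smaller start, making the outcome independent of
pool order. `deriveBoundarySets` runs the same loop with a different
de-selection criterion — both endpoints within a 5-residue margin — and
therefore retains at least as many entries, useful as alternative
boundary choices for constructs.

The default module grid is `m ∈ {15, 25, 50} × M = 500 ×
t ∈ {1e-3, 1e-5, 1e-7, 1e-9}`: three target length scales crossed with
four stringencies. It is a documented, configurable default (any
twelve-row `data.frame(m, M, t)` is accepted), chosen to span short
motif-scale and long domain-scale biases.

# Compositional banding

Banding is two or more patches of the same bias along one sequence.
Detection uses a small-window grid (`m ∈ {3, 5} × M ∈ {10, 20} ×
t ∈ {1e-2, 1e-3, 1e-4}`) so that short patches are visible; hits are
segregated by primary residue (or by the (primary, secondary) ordered
pair for multiple-residue hits), and within each group a maximal pairwise
non-overlapping band list is selected greedily by ascending p-value —
the strongest patches define the pattern.

Evenness is the *distance to perfect banding* (DPB): the `2k` sorted band
endpoints are compared with `2k` evenly spaced endpoints over the same
span (`perfect_j = s + (j-1)(e-s)/(2k-1)`) and the absolute deviations are
summed. DPB is 0 exactly on the even grid and is invariant under
translation and reflection. For sets of at least 4 bands, inter-band gaps
are screened with the modified z-score rule
(`0.6745 (g - median) / MAD >= 3.5`); an outlying gap splits the set and
every sub-set with at least two bands is assessed, the largest first.
When the MAD is zero (all other gaps equal), a longer gap maps to +Inf
and is still excised — the one-wild-gap case the rule exists for. Per
primary bias three (possibly coinciding) sets are reported: most bands
(ties to the smaller empirical p), lowest z, highest z. A "low" call
is significantly *even* banding; "high" is significantly uneven.

# Blockiness

For every position `i`, `dmin_same(i)` is the distance to the nearest
residue of the same type and `dmin_diff(i)` to the nearest residue of a
different type (one-sided at the termini);
`B = Σ dmin_diff / Σ dmin_same`. Segregated arrangements push different
types far apart (large numerator) and same types together (small
denominator), so high B means blocky; perfect alternation gives the
minimum. Numerical choices:

* a position whose residue type occurs once has no same-type partner and
  is dropped from **both** sums — asymmetric dropping would bias B;
* X positions are excluded from both sums but count as a (different)
  21st type for their neighbours' `dmin_diff` — unknown residues must not
  create spurious signals, yet they do interrupt runs;
* a homopolymer has no different-type residue anywhere: B is flagged
  undefined (`NA`), not an error;
* only the raw score is used, with the scrambled null providing the
  reference scale — no normalization by a "minimum possible blockiness".

Residue-specific scores `B_a` restrict both sums to positions holding
`a`; residues with `B_a > B` are reported as contributing to the
segregation tendency.

# Homopeptide content

Homopeptides are maximal runs of one residue type with length at least 3
(configurable). The tested statistic `hpep` is the *mass* — the total
number of residues inside runs — rather than the run count: "content"
reads naturally as mass, enrichment/lack calls then track the amount of
homopeptide sequence, and the run count plus per-residue totals are
emitted alongside for transparency. X runs are never reported.

# Interval-entropy repetitiveness

An *interval type* is an ordered residue pair `(x, z)` separated by
`delta` residues strictly in between (adjacent residues have
`delta = 0`; the off-by-one is easy to trip over). The census counts
**all** ordered position pairs with `delta <= 100`, restricted to residue
types occurring at least 3 times sequence-wide; X never participates but
does occupy positions between a pair. All-pairs counting (rather than
adjacent occurrences only) is deliberate: the delta cap keeps the cost
linear in `L × 101`, and only all-pairs censuses can register structure
between residues of different types at large separations.

Interval entropy is the Shannon entropy of the census in bits,
`IE = Σ (-p_i log2 p_i)`. A repetitive sequence concentrates its interval
mass on few types and scores *low*, so the repetitive direction is the
"low" call with a negative z. Entropies of the same-residue (`x == z`)
and different-residue subsets are renormalized within each subset and
assessed against the same scrambles, showing which component carries a
signal. Per-type one-sided enrichment p-values against the scrambles feed
two top-ten lists (by observed frequency; by p-value). The scramble loop
reuses one preallocated census buffer with sparse resets, which is what
keeps the dominant cost of a batch run tractable.

# The toy generator

`makeToySequence` builds the four canonical test articles: a tandem
repeat (`PAQGS` repeated, period 5), discrete residue blocks (five equal
blocks over A, G, P, Q, S), alternating bands (pure patches of one
residue evenly interleaved with random diverse spacers drawn from the
other 19 residues), and a uniform-random sequence over five residue
types. Defaults are length 200 with six 8-residue bands. Each toy carries
its ground truth (period, block or band coordinates) so tests compare
detected features against construction, and calibration properties
(false-call rates at `alpha`) are measured on the random kind.

What the toys do **not** emulate: real IDR composition (they use small
alphabets and hard transitions), length heterogeneity, mixtures of weak
overlapping biases, and evolutionary correlation between sequences.
Passing the toy matrix shows the analyzers respond to the arrangement
features they were built for, and that their nulls are calibrated — not
that any particular biological prevalence will be reproduced.

One interaction deserves a note. A banded toy with *pure* patches of one
residue necessarily has that residue's positions arranged regularly, so
its same-residue intervals are themselves strongly non-random: in such
constructions the same-residue entropy component carries a repetitiveness
signal at least as strong as the different-residue component. A
different-residue-only signal requires cross-type structure without
single-type regularity, which pure evenly spaced patches cannot provide
by construction.

# Problem sizes used by the tests and the acceptance script

Monte-Carlo checks use 1000 scrambles or endpoint sets per null
throughout (the default). Rate calibrations use 500 generator seeds for
the random-toy false-call matrix and 400–800 scrambled inputs for the
exchangeability check; the stability check re-runs a fixed batch of 100
default-length toys (25 per kind) 10–12 times with fresh null seeds and
summarizes each category percentage's standard deviation. With 100
sequences one call flip moves a percentage by a full point, so this is a
coarse-grained mirror of stability at proteome scale. Exhaustive oracle comparisons run at
L ≤ 30 for the scanner, 1000 random pools for module de-selection, and
L ≤ 300 for the interval census. These sizes are the package's own
choices for a reproducible desk-scale validation.

# Known limitations

* The scanner is a heuristic minimizer: only single-residue optima are
  provably exact; composite signatures are guaranteed to dominate
  fixed-window greedy enumeration, not to be globally optimal.
* Significance is per-sequence and per-analyzer; no multiple-testing
  correction across a proteome is applied or implied.
* Band grouping treats the (primary, secondary) pair as ordered;
  multi-residue band sets with swapped precedence form separate groups.
* Modules shorter than 10 residues are re-analyzed but flagged
  `low_power`: scrambled nulls on very short tracts have few
  distinguishable arrangements.
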