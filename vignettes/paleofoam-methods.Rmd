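---
title: "Dating and codivergence analysis of endogenous foamy-like viral elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and codivergence analysis of endogenous foamy-like viral elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleofoam)
```

## The problem

Retroviruses occasionally integrate into their host's germline and are then
inherited vertically as endogenous retroviral elements (ERVs) — molecular
fossils of past infections. Foamy viruses (spumaretroviruses) rarely
endogenize, so the few known endogenous foamy-like elements, including the
one in the coelacanth genome, carry outsized information about the deep
history of the family. Three questions recur in analysing such an element,
and `paleofoam` implements the computations for each:

1. **What did the element look like?** The genome assembly contains multiple
   decayed, fragmented copies; a consensus reconstruction recovers an
   approximation of the integrated provirus, and defect annotation
   (premature stop codons, frameshift indels) documents that the copies are
   no longer functional.
2. **When did it invade the germline?** Copies arising from post-insertion
   segmental duplication — recognisable because they share nearly identical
   flanking host sequence — diverge neutrally from the moment of
   duplication, so their divergence divided by twice the neutral rate dates
   the duplication, and the invasion must be at least that old.
3. **Did the virus family codiverge with its hosts?** When the virus
   phylogeny is topologically identical to the host phylogeny, each virus
   branch maps to a host branch; regressing virus branch lengths
   (substitutions/site) on host branch durations (millions of years) tests
   whether viral divergence accumulated in proportion to host divergence
   time.

A seeded simulator (`simulate_endogenization()`,
`simulate_codivergence()`) generates data with exactly the generative
structure these analyses assume, with truth records, so every stage is
validated by parameter recovery rather than by fiat.

## Consensus reconstruction and defect annotation

`build_consensus()` works per alignment column. The plurality non-gap base
is called when its support — the fraction of non-gap characters in the
column carrying it — reaches `min_support` (default 0.5). Ties, and columns
where no base reaches the threshold, are encoded as the IUPAC ambiguity
code of the observed bases rather than by an arbitrary choice, so the
consensus is deterministic and invariant under record reordering. Columns
that are gaps in a majority of records represent insertions in a minority
of copies, not the element, and are dropped. There is no published
consensus-calling rule for this kind of reconstruction; plurality with
ambiguity fallback is the transparent default, and the support vector is
returned so a user can mask low-support columns downstream.

`annotate_defects()` scans a declared reading frame (0-based half-open
span, frame 0 of the given strand) for TAA/TAG/TGA codons, excluding the
terminal codon, and — given a pairwise alignment to an intact homolog —
reports indels whose length is not a multiple of 3 as frameshifts. Both
checks are pure bookkeeping, but they are the evidence that an element is a
fossil rather than an active provirus.

`identify_duplicate_sets()` single-linkage clusters contigs whose flanking
sequences align with identity at least `min_flank_identity` (default 0.90)
over at least `flank_window` bp (default 100). Flank comparison is ungapped
sliding identity: deterministic, adequate for the < 10% divergence expected
of flanks a few tens of My old, and cheap. The defaults are our choice —
no threshold is standard in the literature — and both are exposed.
Unannotated contigs are excluded with a warning rather than silently
clustered, and singletons are legitimate sets (independent integrations).

## Distances and the neutral clock

`count_substitutions()` compares aligned pairs with *pairwise deletion*:
columns with a gap, `N`, or any other ambiguity code in either sequence are
excluded. Ambiguity codes are treated as missing rather than resolved
probabilistically, keeping every downstream number deterministic.

`k2p_distance()` implements the Kimura two-parameter distance

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q),$$

with $P$ and $Q$ the transition and transversion proportions, and the
standard delta-method sampling variance. Saturation ($1-2P-Q \le 0$ or
$1-2Q \le 0$) raises an error instead of returning `Inf`/`NaN`, so a
saturated pair can never silently produce an "age".

Under a strict neutral clock two copies that split $t$ years ago
accumulate $2rt$ expected substitutions/site, hence `date_pair()` computes
$t = d/2r$. The default rate prior is the mammalian neutral rate,
$r = 2.2\times10^{-9}$ substitutions/site/year (SD $0.1\times10^{-9}$),
used as a proxy when the host's own rate is unknown — for the coelacanth
this is conservative, since its lineage is thought to evolve slowly, so
true ages are likely older than the estimates. The interval propagates
both sources of uncertainty by the delta method,
$\mathrm{var}(t) = t^2\,(\mathrm{var}(d)/d^2 + \sigma_r^2/r^2)$, as a 95%
normal interval truncated at zero.

## Multi-copy duplication-set dating

For a set of three or more copies, `date_duplication_set()` builds the K2P
distance matrix, clusters it with UPGMA into an ultrametric tree, and
divides the root height (per-lineage substitutions/site back to the common
ancestor) by the rate. A full Bayesian strict-clock analysis of such a set
would normally be run in an MCMC sampler with an explicit tree prior; this
estimator is a deliberate methodological substitution at desk scale. It
shares the strict-clock assumption and the rate prior, and its intervals —
alignment-column bootstrap replicates combined with rate draws from a
truncated normal — are expected to approximate, not match, posterior HPD
intervals. In seeded recovery experiments (five 5-kb copies duplicated
19.3 My ago, the configuration of the largest known duplication set of the
coelacanth element) the 95% intervals cover the true age in well over 90%
of runs and the median relative error of the point estimate is under 5%.

`upgma_tree()` is written in-package because its tie-break rule is part of
the contract: tied merges resolve towards the cluster pair whose
lexicographically smallest leaf labels sort first, making the whole dating
pipeline reproducible to the byte. It is cross-checked in the tests
against an independent implementation on random matrices. K2P rather than
a richer model feeds the matrix: at the divergences involved
($d \lesssim 0.1$) the difference between K2P and HKY-type distances is
second order, and K2P keeps the whole estimator in closed form.

## Cophylogeny

Virus trees without a usable outgroup are rooted by the midpoint method
(`midpoint_root()`, delegating to the standard implementation and verified
against an all-pairs brute-force oracle); with an outgroup, root the tree
upstream and pass it in rooted.

`map_congruent_branches()` demands *exact* topological congruence: after
translating virus tips to host names through the tip map (a bijection),
the set of clades of one tree must equal that of the other. Polytomies are
congruent only when both trees share the identical polytomy — "same
topology" is the precondition of the branch-pairing step, not a nuisance
to be smoothed over. On failure the offending clades are reported; on
success every branch of one tree pairs with exactly one branch of the
other ($2n-2$ branches for rooted binary trees).

`codivergence_test()` regresses virus branch length on host branch
duration by ordinary least squares *with* an intercept (forcing through
the origin is available behind a flag but is the stronger assumption),
reporting $R^2$, the slope in substitutions/site per My, the analytic
F-test p-value, and optionally a seeded permutation p-value obtained by
shuffling virus lengths across branches and counting permutations with
$R^2$ at least the observed one.

The packaged host fixture `host_tree_foamy()` is the six-host tree of the
known foamy and foamy-like virus hosts (coelacanth, sloth, aye-aye, horse,
cow, cat) with branch lengths in My. The coelacanth–tetrapod split is set
to 407 My (the minimum age of the earliest coelacanth fossils); the
placental radiation (100 My) and the splits among laurasiatherian hosts
(96, 84, 78 My) follow commonly cited molecular timetables. These times
are approximations and the root age is exposed as a parameter, because the
duration assigned to the two basal branches is a genuine modelling choice:
we measure both basal branches from the root node at the
coelacanth–tetrapod split, which is the weakest-assumption reading of a
rooted dated tree. The published regressions on the real (amino-acid,
Bayesian) virus trees are not reproducible without those posterior branch
lengths; the packaged analysis validates the machinery on simulated
codiverging trees instead.

## The simulator: what it emulates, and what it does not

`evolve_sequence()` applies the continuous-time K2P substitution process
site-independently using the closed-form change probabilities for an
expected $r\,t$ substitutions/site, with transition/transversion rate
ratio $\kappa$ (default 2.0, a typical nuclear value; the data it
emulates state none). `simulate_codivergence()` mirrors a dated host tree
exactly; at zero rate noise virus branch lengths are deterministically
$\text{rate}\times\text{duration}$, so a perfect codivergence signal gives
$R^2 = 1$ to numerical tolerance, and per-branch lognormal rate
multipliers (mean 1) degrade the signal the way relaxed-clock variation
would.

`simulate_endogenization()` encodes the dating design directly: an
ancestral provirus (a single long ORF with no internal stops) flanked by
random host sequence integrates `endogenization_time` My ago; segmental
duplications copy one extant lineage each (copies inherit identical
flanks, the signature the duplicate-set detector keys on); all lineages
decay at the host neutral rate; indel events (Poisson, geometric lengths
capped at 10, rate default $10^{-11}$ per site·year — a round value chosen
to yield roughly one indel per copy over ~20 My, not calibrated to any
measurement) are applied while the true multiple alignment is maintained,
so downstream distance computation can be tested with and without its
pairwise-deletion machinery engaged. Defaults — 5-kb element, five copies
duplicated 19.3 My ago, rate $2.2\times10^{-9}$ (SD $0.1\times10^{-9}$) —
are the study conditions of the motivating system.

What the simulator does *not* emulate: recombination and gene conversion
between copies (which homogenize real ERV sets and bias LTR-style dating
young), selection on any viral ORF, CpG rate heterogeneity, sequencing or
assembly error, and realistic WGS fragmentation (fragmentation here is a
simple overlapping-window cut with a 300-bp minimum). Passing recovery
tests therefore demonstrates that the estimators are correct *under the
neutral strict-clock model they assume*, not that real data satisfy that
model.

## Numerical choices and degenerate inputs

* Saturated distances, invalid rates, empty alignments, non-bijective tip
  maps and stale branch mappings raise errors naming the problem; nothing
  returns `NaN`.
* Age intervals are truncated at 0 (ages are non-negative); identical
  copies date to exactly 0 with a degenerate interval.
* UPGMA is ultrametric to $10^{-10}$ by construction and asserted in tests.
* All stochastic entry points (`evolve_sequence()`, the simulators,
  bootstrap and permutation loops) take explicit seeds and restore the
  caller's RNG state; identical config + seed reproduces outputs
  byte-identically, which the pipeline tests assert.
* Problem sizes in the test suite — 200 replicate 10-kb pairs for clock
  calibration, 100 seeded runs with 300 bootstrap replicates for interval
  coverage, 40 replicates per noise level for the $R^2$ sweep — were chosen
  so each stochastic property is resolved to well within its assertion
  margin (3 Monte-Carlo standard errors for means, ±5 percentage points
  for coverage).

## Orchestration

`run_pipeline()` runs any subset of the stages (simulate → consensus →
defects → dupsets → dating → codivergence) from one YAML/JSON config,
validates all referenced inputs before the first stage runs, writes every
numeric result to JSON/TSV (never only to logs), and emits a manifest with
the tool version, config hash, seeds and input digests so a run can be
reproduced exactly. Each stage is equally callable as a plain function,
which is how the examples in this vignette and the README use them.

## Worked example

```{r example}
cfg <- sim_config(genome_length = 3000, seed = 42)
sim <- simulate_endogenization(cfg)
identify_duplicate_sets(sim$contigs, sim$truth$coords)
date_duplication_set(sim$element_alignment, n_bootstrap = 300, seed = 42)

# pairwise worked example: the printed 4.1% divergence at the mammalian rate
date_pair(0.041, rate_mean = 2.2e-9, rate_sd = 0.1e-9)
```

## Known limitations

The clock estimator substitutes a distance-based procedure for full
Bayesian inference, and its bootstrap intervals are not HPDs. Dating
inherits every caveat of the neutral-rate proxy: if the host's neutral
rate is lower than the prior (as suspected for the coelacanth), ages are
underestimates. Congruence testing is all-or-nothing by design and offers
no reconciliation of near-congruent trees. The regression treats branch
pairs as independent observations, as is conventional for this analysis,
although phylogenetic structure makes them only approximately so.
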