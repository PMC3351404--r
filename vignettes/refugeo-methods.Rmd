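---
title: "Methods: models, estimators and design choices in refugeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in refugeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`refugeo` implements the genetic half of a comparative phylogeographic
study: given aligned mtDNA fragments (typically ~590 bp of COI) sampled
from many localities for one or more sympatric species, it asks whether
lineages show the signature of postglacial expansion and, for those that
do, where the expansion started. This vignette records the models, the
estimators, the tunable parameters and the places where the design was
genuinely open — and what the synthetic data generator does and does not
emulate.

## Sequence handling

An alignment is a set of equal-length sequences over the IUPAC alphabet;
uppercase normalization maps U to T. Two deletion conventions coexist
deliberately:

* **Pairwise deletion** for diversity reporting: each pair of sequences is
  compared at the sites where *both* carry an unambiguous base. π is the
  mean over pairs of the per-site difference proportion `d_ij / v_ij`.
  This matches the convention of the common distance software and keeps a
  locality with one gappy sequence comparable.
* **Complete deletion** for the neutrality statistics (D, F_S, mismatch):
  only columns unambiguous in every sequence are used, because the
  coalescent simulation null is gap-free and the observed statistic must
  be measured on the same footing as its null.

Whether ambiguous bases should count as differences is not standardized;
they are excluded here (conservative). Haplotype identity is exact string
equality after normalization — sequences containing N are never merged
into compatible haplotypes, because any merging rule is arbitrary and the
cost of keeping them distinct is a conservative haplotype count.

Sample sizes of one yield not-calculable markers (`NA`, printed `n/a`),
never zero: a diversity of zero is an observation, not a default.

## Diversity

Haplotype diversity uses the unbiased estimator
`H = n/(n-1) (1 − Σ p_i²)`. The `n/(n-1)` correction matters at the small
per-locality sample sizes (1–15) typical of such surveys; the worked
examples in the test suite (compositions 8+1, 3+2+2, 6+2, 1+1+1)
reproduce the published four-decimal values exactly.

## Neutrality statistics and their null

Tajima's D is the standard normalized difference between the mean
pairwise difference count `k̄` and the segregating-sites estimate `S/a₁`,
with the usual `a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂` constants. Fu's F_S uses
the Ewens sampling distribution of the number of alleles: with
`θ̂ = k̄`, `S' = Pr(K ≥ k_obs)` and `F_S = ln(S'/(1−S'))`. The Ewens
probabilities are computed from unsigned Stirling numbers of the first
kind evaluated in log space (stable to at least n = 270, the largest unit
such surveys produce). Monomorphic samples (S = 0, or a single haplotype
for F_S) are not calculable.

**Simulation null.** p-values come from neutral constant-size coalescent
genealogies: exponential waiting times, mutations placed on branches with
probability proportional to branch length. The null is conditioned on the
*observed number of segregating sites* by default (each simulation drops
exactly S mutations), with conditioning on θ̂ (Poisson mutations) behind a
flag; the conditioning choice of the legacy software is undocumented, and
S-conditioning removes one nuisance parameter. `p = Pr(sim ≤ obs)` for
the usual one-sided (negative-deviation) test, with a two-sided option
`2·min(p_lo, p_hi)`; both use the `(1+b)/(1+reps)` finite-sample
correction. Significance conventions: 0.05 for D, 0.02 for F_S. The test
suite verifies the nominal type-I error of the two-sided D test at 0.05
within its binomial 95% envelope over 500 null datasets (199 null
replicates per p-value; sizes chosen to make the check sharp at desk
scale).

## Mismatch distributions and raggedness

Observed mismatch distributions are relative frequencies of pairwise
difference counts (complete deletion). Two expectations are available:

* constant size: geometric, `F_j = θ^j/(θ+1)^(j+1)`;
* sudden expansion with the post-expansion size taken to infinity: the
  pair separation is τ mutational units of deterministic drift plus a
  stationary geometric component, i.e. `F = Poisson(τ) ⊛ Geom(θ₀)`.
  At τ = 0 this reduces exactly to the constant model — a useful identity
  test.

The expansion parameters are fitted by least squares on the relative
frequencies (coarse 21×21 grid, then Nelder–Mead refinement); the
original software's estimator is undocumented, and least squares is the
simplest defensible choice for a curve-fitting diagnostic. Harpending's
raggedness `r = Σ_{i=1}^{d+1} (x_i − x_{i−1})²` includes the terminal
class `x_{d+1} = 0`, so a degenerate single-class distribution has
r = 1; the terminal-class convention is not standardized and is stated
here so results are reproducible. Its p-value is `Pr(r_sim ≥ r_obs)`
under coalescent simulations from the *fitted* expansion model (no
coalescence more recently than τ, rate `k(k−1)/θ₀` beyond, branches
mutating at unit rate in mutational time) — a parametric bootstrap of the
goodness of fit; high observed raggedness rejects the expansion model.

## McDonald–Kreitman counts

Codons are read under the invertebrate mitochondrial code (AGA = Ser;
frame auto-detected by minimizing internal stop codons, with a warning if
the best frame still leaves stops in more than half the codons). Per
codon position:

* variation *within* a species contributes polymorphic changes, summed
  over a minimum spanning tree of the observed codon variants;
* a position whose allele sets are *disjoint* between the species
  contributes a fixed change between the species' majority codons. The
  disjointness rule (rather than "no variation within") is what makes the
  textbook example — species A = {TTT, TTC}, species B = {TTA} — yield
  one synonymous polymorphism *and* one non-synonymous fixed difference.

Synonymous/non-synonymous assignment averages over all minimal mutational
pathways between two codons, discarding pathways through stop codons when
an alternative exists; multi-hit codons can therefore contribute
fractional counts, which is stated rather than hidden by rounding.
Positive selection is indicated only when `Mn/Pn >> Ms/Ps`; with Mn = 0
the ratio test is reported as not indicated.

## Statistical-parsimony networks and nesting

The connection limit is the largest step count j whose probability of a
fully parsimonious connection still exceeds the confidence level
(default 0.95). That probability is modelled as the chance that j
mutational events over L sites all strike distinct sites,
`P_j = Π_{i=1}^{j-1} (1 − i/L)` — no superimposed change, so every event
is visible. For L = 590 this gives an 8-step limit at 95%, slightly
conservative relative to the classic coalescent-based software (9–10 for
COI-length fragments); the limit is a user-overridable parameter, and
every downstream result records it.

Construction adds haplotype pairs in increasing distance order; at each
distance, an edge is added for every pair not already connected through
strictly shorter edges. This retains *all* equally parsimonious
alternatives (the union of all minimum spanning trees — verified against
a brute-force enumeration over Prüfer sequences in the tests) and defers
ambiguity to an explicit resolution step. Multi-step edges are expanded
with inferred zero-frequency intermediates so every displayed edge is one
mutational step.

Loop resolution removes one edge per cycle by an ordered cascade:
longest edges first (keeping the resolved network a minimum spanning
tree), then retain connections to higher-frequency haplotypes, then to
interior haplotypes, then between geographically closer locality sets
(minimum great-circle distance), then a lexicographic tie-break. The
cited resolution criteria come without a total order; this order is fixed
as the package default, every removal is logged with the deciding
criterion, and the operation is idempotent.

Nesting unites nodes (haplotypes *and* intermediates) within one
mutational step working inward from the tips of the resolved network,
iterating within a level until every node is assigned; interior nodes
left isolated stay singleton clades in that level and are absorbed by the
same rule at the next level (so a five-node chain nests as
{A,B}, {C}, {D,E} and then merges completely). Higher levels apply the
same rule to the clade graph. The MOTU level is deliberately a user
parameter: the published analyses chose different levels for different
species on resolution grounds, and that judgment is not automated here.
MOTUs are numbered by decreasing total haplotype frequency; disconnected
subnetworks are distinct MOTUs at every level.

## Refugium localization reconstruction

Tips of each rooted genealogy carry the (pooled) locality set of their
haplotype; a haplotype observed at several pooled localities gets a
multi-state tip, which set-valued parsimony handles natively. Root states
are computed by the Hartigan generalization of Fitch parsimony: a node's
set is the states attaining the maximum count across its children's sets
(intersection-if-nonempty-else-union for binary nodes). The root V-set
equals the set of most parsimonious root states, which the tests verify
against exhaustive minimal-labeling enumeration on *all* rooted binary
topologies with up to six tips and four states. Each of the n equivalent
root states gets weight `w = 1/n`; the relative probability score of a
locality is `100 · Σ_trees w / N_trees`, reported on the 0–100 scale on
which such scores are conventionally quoted (the per-tree weights sum to
one, so scores sum to 100).

Bayes factors between demographic models use the harmonic-mean marginal
likelihood `−(logsumexp(−ℓ) − log N)` (stable in log space) and are
reported as log₁₀, because the conventional qualitative grades
(substantial ½–1, strong 1–2, decisive > 2) are decimal. The harmonic
mean estimator is known to be high-variance; it is provided because it is
the comparison such studies report, not because it is the best available
marginal-likelihood estimator.

## The synthetic generator

The structured coalescent runs backward in time on a haploid-copy
timescale (mtDNA-like: a deme of effective size N has pairwise
E[TMRCA] = N generations and θ = 2Nμ). Within-deme coalescence at rate
`k_d(k_d−1)/2/N_d`, per-lineage migration from a backward rate matrix,
and a schedule of events: `expansion-from-source` (daughter demes'
lineages drop into the source; looking further back the daughters did not
exist) and `size-change`. Mutations are Poisson on branches —
infinite-sites by default (each mutation a fresh site), finite-sites
Jukes–Cantor as an option. Calibration tests pin the simulator to closed
forms: pairwise TMRCA against E[T₂] = N (2000 replicates) and segregating
sites against Watterson's `E[S] = θ a₁` (1000 replicates, n = 10).

The **refugial-expansion** preset emulates the study design the analysis
targets: a refugium (`RFG`) that persisted at small size through the
glacial maximum (N = 200 before the expansion time), then grew (N = 5000)
and founded four daughter demes. Sizes and times are coalescent-rescaled
— only ratios matter — with the per-site rate raised to 2.5×10⁻⁶ so that
a 590-bp fragment accumulates realistic variation (S ≈ 15–25 in a sample
of 44). The strong variant (expansion 400 generations ago, daughters
N = 1500, no post-expansion migration) is designed for clear
identifiability: genealogies are star-like (mean D ≈ −2), and the deep
coalescent structure sits in the source, which is also sampled most
densely (16 of 44 tips) as a refugium would be. The weak variant uses an
older expansion (1500 generations), a milder bottleneck and low
post-expansion migration. **island-constant** (four equal demes,
symmetric migration) and **single-panmictic** (the null used for type-I
calibration) complete the presets.

"Posterior-like" tree samples are independent draws from the scenario,
not MCMC output: they exercise the RLR contract (many rooted genealogies
with shared tips) without implementing phylogenetic MCMC, but they lack
the autocorrelation and the topology uncertainty *given one dataset* that
a real posterior sample has. Likewise the generator omits recombination
(appropriate for mtDNA), selection, sequencing error and ambiguity codes;
passing tests therefore demonstrate correctness of the estimators under
the stated models, not robustness to artifacts real COI data may carry.
Recovery experiments (20 replicate scenarios, 60 genealogies each at
desk scale) top-rank the true source deme by RPS in well over 80% of
replicates under the strong preset.

## Numerical conventions

* Not-calculable values are `NA` internally, `n/a` (diversity tables) or
  `n. c.` (neutrality tables) when formatted; diversity values print to
  four decimals.
* All stochastic routines take explicit integer seeds; scenario objects
  carry their seed, and passing `seed = NULL` explicitly draws from the
  current RNG state for replicate studies.
* Empirical p-values always use the `(1+b)/(1+reps)` correction, so a
  reported p is never exactly zero.
* Ties in loop resolution, nesting and MOTU numbering are broken
  lexicographically so reruns are byte-identical.

## Known limitations

* The connection-limit probability model ignores the coalescent depth of
  the sample; it is a few steps conservative relative to the classic
  implementation for long fragments.
* MK counts assume one reading frame across the whole alignment and skip
  codons containing gaps or ambiguities.
* The mismatch fit is a diagnostic, not an estimator with standard
  errors; τ and θ₀ should not be over-interpreted.
* The harmonic-mean marginal likelihood has infinite variance in theory;
  decisive calls on small |log BF| differences should be distrusted.
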