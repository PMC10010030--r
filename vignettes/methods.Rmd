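---
title: "Models and methods behind hostflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hostflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hostflux` reconstructs the host-association history of a bacterial gut
symbiont from comparative-genomic inputs. This vignette documents the
models, the tunable parameters and their defaults, the synthetic-data
generator and what a green test on it does and does not establish, and the
numerical and design choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The synthetic world

All tests run against `simulate_dataset()`, which produces every pipeline
input from one seed and logs every event (the *truth log*), so estimators
can be checked by parameter recovery rather than against fixtures.

**Tree.** A rooted ultrametric tree of unit height with an explicit
two-level structure: between-lineage splits (the backbone) above
`backbone_min` (default 0.6), within-lineage splits (the crowns) below
`crown_height` (default 0.35), topologies drawn by random coalescence. A
single-level pure-birth tree was rejected because the depth gap between
backbone and crowns — which the lineage concept presupposes, and which the
pairwise SNP-distance bimodality exploits — would then hold only for lucky
draws; here it is part of the stated world. Tip counts are split as evenly
as possible across `n_lineages`.

**Hosts.** A continuous-time Markov switch process runs along branches from
`root_host` (default `"rodent"`) at `host_switch_rate` per unit height.
The default 0.15 gives a handful of switch events per tree, matching a
world with a few milestone host transitions rather than rampant switching;
at high rates the root state is genuinely unidentifiable and no
reconstruction method recovers it.

**Gene content.** The root carries `root_family_count` families (default
600). Along each branch, present families are lost at `loss_rate` (0.15 per
unit height), absent root families are re-gained at `gain_rate` (0.1), and
new families originate at `innovation_rate` (150 per unit branch length),
existing only within the subtree of their origin (Dollo-like innovation).
These defaults make extant genomes about 10% larger than the root genome —
innovation-driven genome expansion. A block of `host_linked_families`
(default 120) flips deterministically with the host state at the logged
switch times: this is the generator's device for *convergent gene content*,
the central empirical structure in this problem domain (distant clades that
share a host share a gene repertoire). Without it, independent gain/loss
cannot produce content groups that unite phylogenetically distant lineages,
and the ordination stage would have nothing to detect. The truth log
records every flip, and a replay test reconstructs each tip's gene set from
the root set plus the logged events exactly.

**Core genes.** Each of `n_core_genes` genes evolves site-independently
under a one-parameter (Jukes–Cantor-type) substitution process at
`clock_rate` substitutions/site/year (default 3e-6), with branch durations
`edge.length * tree_age` (default 9100 years). Richer substitution models
would not change what the downstream contracts test. A
`recombination_fraction` of genes (default 0.2) is made mosaic: a
contiguous half-gene segment from a donor genome in one lineage replaces
the homologous segment in a *single recipient genome* of another lineage.
The strain-level (rather than whole-lineage) transplant is deliberate: a
whole-lineage replacement produces site pairs that remain pairwise
compatible, whereas a single-strain mosaic creates the crossing
bipartitions that a homoplasy test can detect.

**Prophages.** Genomes carry Poisson(`prophage_mean_per_genome`) resident
prophages of 6–40 kb with per-gene viral/bacterial labels, plus decoys
(< 5 kb, or bacterial-genes-only) that the retention filter must discard.
Transfers copy a full sequence between genomes — within lineages at
`prophage_within_rate` (2) and across at `prophage_between_rate` (0.1) per
unit total branch length, a 20:1 ratio — so donor and recipient share an
exact fragment ≥ 5 kb by construction. Random backbone sequence makes
spurious ≥ 5 kb matches impossible in practice.

**Adhesion.** Strains in the designated rodent-type content group draw
log₁₀ CFU/g from Normal(7.6, 0.3), others from Normal(6.0, 0.3); the
reference strain is fixed at 7.6, the value jointly implied by the two
published threshold equivalences (10% ↔ 6.6 and 20% ↔ 6.9).

What a green test establishes: that each estimator recovers the generating
process of *this* world at desk scale. What it does not: robustness to
annotation error, paralogy, alignment error, rate heterogeneity across
sites or lineages, or non-exact (diverged) prophage homology — none of
which the generator emulates.

**Determinism.** Every operation derives an independent substream from the
master seed by hashing the operation name (`op_seed`), so adding draws in
one stage never perturbs another, and identical configurations give
byte-identical outputs.

## Pan-genome

Core families are those with prevalence *strictly above* `core_threshold`
(default 0.95), matching the usual "more than 95%" phrasing; accessory
families are at or below the threshold but in more than one genome;
singletons are excluded from the Jaccard basis. Openness is a Heaps-law fit
`n(N) = κN^γ` by least squares on the log of the permutation-mean
accumulation curve (100 seeded permutations), open iff γ > 0.

`jaccard_distances()` has two modes. `standard` is the usual
`1 − |A∩B|/|A∪B|` and is what every downstream stage consumes.
`paper_literal` preserves a published variant that denominates by the
symmetric difference, `1 − |A∩B|/|AΔB|`, guarded to return 0 when the
symmetric difference is empty: that formula is not a metric, is undefined
for identical sets, and is almost certainly a typographical slip for
standard Jaccard, but the package can reproduce either reading. Neither is
asserted to be the published computation.

## Core-genome structure

SNP distances count columns where both sequences carry an unambiguous
A/C/G/T and differ; the ANI proxy is 100 × matches / comparable columns on
the same rule, so `ani = 100·(1 − snp/comparable)` holds identically.

**PHI.** The recombination screen computes, over pairs of
parsimony-informative sites within a `window` of 100 alignment positions,
the mean *incompatibility excess*: the number of observed joint states
beyond `k₁ + k₂ − 1`, the maximum a homoplasy-free pair can show (0 for a
compatible pair). Significance comes from permuting the order of the
informative sites (default 100 permutations,
`p = (1 + #{perm ≤ obs})/(n+1)`); clonally evolved columns are i.i.d.
across positions, so site order is exchangeable under the null and the
p-value is calibrated. Genes with fewer than two informative sites (or no
in-window pair) are non-testable and return p = 1. The pair statistic runs
in C++; a pure-R reference implementation stays in the package and the
suite asserts their equality. Genes with p below `alpha` (0.05) are
excluded; surviving genes are trimmed (columns ≥ 50% gap/N removed — the
trim rule is this package's choice, as the original only names a tool) and
concatenated with partition bookkeeping.

**Trees.** UPGMA is average-linkage agglomeration (`hclust`), exactly
reproducing ultrametric inputs; NJ comes from `ape`, rooted at a named
outgroup. Bootstrap support is the percentage of alignment-column-resampled
replicates containing each internal bipartition. Maximum-likelihood tree
search is intentionally out of scope — externally computed trees can be
imported as Newick.

**Lineage delineation.** The pairwise SNP distances of a clade-structured
population are bimodal: an intra-lineage mode and one or more inter-lineage
modes. The threshold is found on a kernel-density estimate as the *deepest
relative valley* — among valleys between adjacent substantial modes
(density ≥ 2% of the maximum), the one with the smallest density relative
to its smaller flanking mode. Two simpler rules were tried and rejected:
the valley between the two *largest* modes fails when two inter-lineage
modes (shallow vs deep backbone splits) dominate, and the valley after the
*first* mode fails when crown substructure splits the intra mode. Genomes
are then linked single-linkage below the threshold; components smaller than
`min_size` (4) are flagged `unassigned` rather than given a lineage label.
A unimodal distribution (no valley deeper than 0.95 relative) is an error
advising an explicit threshold. The package reports its threshold and
cluster count; it does not assert any particular lineage number.

## Ordination and tree comparison

NMDS minimizes Kruskal stress-1 by alternating isotonic regression of
configuration distances on the rank order of the input dissimilarities
(primary tie treatment via pooled-adjacent-violators) with Guttman-transform
updates. The first restart starts from classical metric scaling — on
distances that are exactly Euclidean in k dimensions this converges to
stress ≈ 0 immediately — the rest from random configurations; the best of
`n_restarts` (20) is returned with its per-iteration stress trace, which is
non-increasing by construction (iteration stops on any increase).

ANOSIM uses midpoint-tied ranks and the divisor M/2 with M = n(n−1)/2,
fixed by the binding contract that perfectly separated groups give exactly
R = 1 (verified against a hand-ranked 4-point example and `vegan`). The
permutation p is `(1 + #{R_perm ≥ R})/(n+1)`.

Tree comparison reports Robinson–Foulds distance over canonical unrooted
bipartitions, its normalization by 2(n−3), cophenetic correlation, and the
bipartitions unique to each tree. Gene-content groups are obtained by
cutting the UPGMA content clustering into `k` groups (default 4), the
operational version of "clearly separated" groups, validated downstream
with ANOSIM.

## Pan-GWAS

For each family and binary trait: sensitivity = 100·TP/(TP+FN),
specificity = 100·TN/(TN+FP); the naive p is the two-sided Fisher exact
probability computed by hypergeometric enumeration (sum of table
probabilities ≤ the observed one, with a 1e−7 relative tolerance for
floating ties), asserted equal to `stats::fisher.test` on random tables.
BH and Bonferroni corrections are applied across the families tested for
that one trait (the per-trait output table is the correction universe).
A family is *specific* iff sensitivity > 70, specificity > 70, and the
naive, selected adjusted (BH by default, Bonferroni selectable — published
accounts differ on which was used, so both are available and neither
asserted), and empirical p are all strictly < 0.05.

The empirical p permutes trait labels: the phylogeny-aware pairwise test of
the original tool is deliberately not reproduced, as plain label
permutation is the only scheme the available description specifies. The
prescribed inclusive-ties estimator `(1 + #{p_perm ≤ p_obs})/(n+1)` is
valid but cannot be distribution-uniform: the Fisher p is discrete with a
large atom at 1 (the observed table is the modal one with probability
≈ 0.2 at 20 genomes). `ties = "randomized"` gives the observed statistic a
uniform rank among its permutation ties, the canonical construction that is
exactly uniform under exchangeability; the calibration tests check KS
uniformity on that variant and validity (P(p ≤ 0.05) ≤ 0.05 + noise) plus
the conservative ordering for the default. For throughput,
`select_specific_genes()` computes the expensive empirical p only for
families that already pass the sensitivity/specificity and naive/adjusted
gates — the decision for the others cannot change.

## Ancestral gene content

Parsimony: Fitch with downpass ties resolved toward *absence* (conservative
against inflating the ancestral genome; configurable), and Dollo (single
gain at the carriers' MRCA, minimal losses below it).

The main reconstruction is a two-state (absent/present) continuous-time
Markov chain with one gain and one loss rate per branch class (default one
class; per-lineage-stem classes can be supplied). Branch lengths are
height-normalized before fitting, so rates are per unit tree height
regardless of input units. The likelihood uses the pruning recursion
vectorized over families and is conditioned on each family being observed
in ≥ 1 tip, since all-absent families cannot appear in a pan-genome table.
The root prior is *estimated* as a free parameter by default rather than
fixed at the stationary distribution: the generator (like real pan-genomes)
starts far from stationarity, and with a stationary prior the rate
estimates absorb the mismatch (gain inflated ~70% in recovery experiments);
with the free prior both rates recover within a few percent at 100 tips ×
2000 families. `root_prior = "stationary"` remains available. Optimization
is multi-start Nelder–Mead with a BFGS polish; the conditional likelihood
is nearly flat in the root prior near the Dollo (loss-only) boundary, a
genuine ridge the polish step is there to navigate. Marginal ancestral
presence probabilities come from the standard up-down pass; per-branch
expected gains/losses are posterior probabilities of differing endpoint
states (a lower bound on expected transition counts, adequate for
event-level summaries); node contents threshold the marginals at 0.5.

Origin classification of a lineage-specific family: *gained-on-lineage* iff
absent from the reconstructed root; otherwise *LCA-inherited*, subdivided
into *retained* (every tip of the target lineage carries it) or *partially
retained*. The retained/partial split is relative to the lineage under
test, the one unambiguous reading at the level of a single trait.

## Dating and ancestral hosts

Strict-clock dating minimizes Σ(bᵢ − r·Δtᵢ)² over node ages with tips fixed
at 0 (contemporaneous), by solving the normal equations exactly; with a
root-age calibration the rate is estimated by alternation (rate update in
closed form), which converges in a few iterations. Violations of
parent ≥ child ≥ 0 are projected out and flagged. Exactly clock-like inputs
are reproduced with zero residual, and times are invariant to joint
rescaling of branch lengths and rate. Bayesian machinery (MCMC, HPD
intervals) is out of scope by design; uncertainty can be bootstrapped by
resampling genes and re-dating.

Ancestral hosts: Fitch parsimony with ambiguity retained, or a k-state CTMC
with independent off-diagonal rates (asymmetric) fitted by maximum
likelihood via pruning, root prior = stationary distribution of the fitted
matrix, marginals by the up-down pass. Modal-state ties are broken by host
label order and flagged. Host switches are the branches whose endpoint
modal states differ, reported with the `[parent age, child age]` interval,
oldest first. How host species are collapsed into discrete states is a
caller decision (the metadata column), not hard-coded.

## Prophage exchange

Retention: length ≥ 5000 bp AND (≥ 1 viral gene OR no bacterial genes);
"shorter than 5 kb" is read strictly, and discards are logged with reasons.
A query prophage counts as shared iff it has an exact common substring
*strictly longer than* `min_fragment` (5000 bp) with any subject sequence;
the directed percentage is 100 × counted/submitted, computed for every
ordered lineage pair (self-comparisons excluded). Intra-lineage sharing is
each genome's prophages searched against its lineage mates; the summary
ratio is mean intra / mean inter, reported as infinite when no
inter-lineage sharing exists.

Matching replaces an external aligner with exact maximal-substring
detection: 16-mer seeds (exact 2-bit integer codes; query probed at a
stride that guarantees any > 5 kb common substring contains a seed) are
extended to maximal matches; chance 16-mer collisions are eliminated by the
extension itself. The synthetic prophages are exact copies, so exact
matching suffices; diverged homology detection is explicitly not attempted.
An O(nm) dynamic-programming longest-common-substring in C++ serves as the
independent oracle in the tests.

## Adhesion

`relative_adherence` is `100·10^(strain − reference)`. Classification:
effective iff log₁₀ CFU/g ≥ 6.9 (≥ 20% of the reference), ineffective iff
≤ 6.6 (≤ 10%); the published thresholds leave (6.6, 6.9) unassigned, so a
third class *intermediate* covers the gap rather than forcing a binary
call, and boundary equality goes to the adjacent definitive class. The two
printed equivalences independently imply a reference of 7.6 log₁₀ CFU/g,
a consistency the acceptance script recomputes.

## Pipeline

`run_pipeline()` executes the stages in dependency order on a simulated
dataset, writes per-stage outputs (Newick, FASTA, TSV, CSV, JSON) that all
round-trip through the package's own readers, and emits a summary JSON with
no timestamps, so identical configurations produce byte-identical
summaries (timestamps live in a separate run log). Unknown configuration
keys are rejected by name. Analysis defaults are the published values
(core threshold 0.95; PHI window 100, 100 permutations, α 0.05;
sensitivity/specificity 70; 1000 GWAS permutations; 5000-bp fragment). The
CLI stages (`inst/cli/hostflux.R <stage>`) always run with their upstream
dependencies, which keeps per-stage invocation simple and reproducible.

## Known limitations

- The gain/loss chain is a two-state presence model: copy number,
  birth–death innovation, and per-family rate variation are out of scope.
- Expected per-branch events count endpoint-state changes, not multiple
  hits within a branch.
- The PHI screen tests *exchangeability of site order*; it has power only
  against mosaics that create crossing site patterns, and (like the
  original) limited power at low diversity.
- Exact-substring prophage matching cannot see diverged homology; the hook
  is the `longest_common_substring` interface, behind which an external
  aligner could be substituted.
- Least-squares dating gives point estimates; no credible intervals.
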