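---
title: "Methods: venom evolution and transposon dynamics in parasitoid wasps"
author: "parawasp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: venom evolution and transposon dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`parawasp` re-implements, as tested and reusable functions, the
computational analyses behind a two-genome study of the egg parasitoids
*Anastatus japonicus* and *A. fulloi*: transposon-rich ~950 Mb genomes in
which recent LTR retrotransposon bursts, an expanded piRNA defence, rapid
venom gene turnover and a venom-gland coexpression module interact. This
vignette documents each model, its parameters and the design decisions
taken where the original procedures were manual or under-specified.
Every stage runs on synthetic data with known ground truth; the final
section states what that does and does not establish about real data.

## LTR insertion dating

At insertion the two LTRs of an element are identical; divergence since
is measured by the Kimura two-parameter distance over the aligned pair,

$$K = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q),$$

with $P$ and $Q$ the transition and transversion proportions over
comparable columns. Columns with a gap or `N` in either sequence are
excluded (pairwise deletion — the standard K2P convention). The insertion
time is $T = K/2r$: the factor 2 accounts for both LTRs accumulating
substitutions independently. When $1-2P-Q \le 0$ or $1-2Q \le 0$ the
distance is undefined (saturation); such elements are flagged and
excluded from age histograms rather than clamped, to avoid fabricating
old ages.

The lineage rate $r$ (subs/site/My) is a **required input**: rates differ
between insect lineages and must come from an external dated phylogeny.
`date_ltr_pairs()` carries a placeholder default (0.0029) purely so the
function is runnable, and warns whenever the default is used.

`gen_ltr_pairs()` simulates pairs under the K80 process — the exact
generating model of the K2P estimator — using closed-form substitution
probabilities at branch length `rate * age_my` per LTR, with transition:
transversion rate ratio `kappa` (default 2, i.e. equal expected transition
and transversion *rates* per target). Because simulator and estimator
match exactly, the only estimator error is sampling noise, which shrinks
as `ltr_len` grows; at the study scale used in the tests (500 elements,
age 2 My, rate 0.005, 400 bp) the mean estimated age sits within 10% of
truth.

## Small RNAs and the Ping-Pong signature

Candidate piRNAs are reads of 24–35 nt not matching structural ncRNAs.
Two hallmarks are profiled: uridine at position 1 (1U, primary piRNAs)
and adenine at position 10 (10A, Ping-Pong responders). For TE silencing,
reads mapped to TE consensus sequences are paired across strands and the
5′-to-5′ overlap tabulated for $o = 0..30$.

**Overlap convention.** For a plus-strand 5′ end at $p$ and a
minus-strand 5′ end at $q$ (plus-strand coordinates), the overlap is
$o = q - p + 1$, so the canonical Ping-Pong pair scores exactly $o = 10$.
The alternative convention $o = q - p$ (which shifts the signature to 9)
is rejected; the synthetic generator plants pairs under the same
convention, so planted signal lands in the 10-nt bin by construction,
and a mismatch between analyzer and generator conventions would be
caught immediately by the dose–response tests.

**Scoring.** $Z = (N_{10} - \bar B)/\mathrm{sd}(B)$ where the background
$B$ is every bin except 10 and sd is the sample (n−1) standard deviation.
A flat spectrum has no defined score and returns `NA` with a diagnostic.
Pair counting uses the minimum of the two 5′-position multiplicities
(avoiding quadratic double-counting); a `unique` mode collapsing
multiplicities is provided since either weighting is defensible, with
min-multiplicity the default.

**Generator choices.** `gen_small_rna()` applies the 1U bias to *every*
read, so the measured first-nucleotide U frequency estimates `u1_bias`
directly; the 10A bias applies to the planted minus-strand responders,
matching the biology of the amplification loop. Read placement is
uniform for background reads. Sequencing errors, quality values and the
mapping step itself are not simulated — hits are emitted directly — so
null calibration (|Z| < 3 in ≥ 95% of seeds at fraction 0) tests the
statistic, not a read mapper.

## Venom gene calling

The venom gland is extremely skewed: a small fraction of genes carries
90% of transcription. The N90 threshold is the TPM of the first gene at
which cumulative expression (sorted descending) reaches 90% of the
total; replicate samples are arithmetically averaged per label before
thresholding. A venom gene must exceed N90 **strictly** (a gene exactly
at the threshold is not called — the literal reading of "higher than")
and carry at least three completely matching proteomic peptides. Since
N90 scales with the data, the called set is invariant under any global
rescaling of TPMs.

The "specialized expression" score shown on venom identification plots
has no published formula; `vg_specificity()` reports
`TPM_VG / (max non-VG TPM + 0.01)` as a clearly labelled descriptive
stand-in that never influences calls.

## Venom origins on trees

**Orthogroup ages.** Presence/absence of an orthogroup across the 19
reference taxa is reconstructed by Wagner parsimony (equal gain and loss
costs) via Sankoff inside–outside dynamic programming; the OG's age node
is the most ancient node reconstructed as present in *some*
minimum-cost labeling (gain-early preference, matching the parsimony
reading of shared presence as ancestral). The implementation is tested
against exhaustive enumeration of all internal labelings on trees of up
to 10 leaves. Recovery from noisy presence data depends on tree shape:
losing the single basal taxon of a clade (e.g. the one-tip sister inside
the Chalcidoidea crown of the bundled tree) legitimately shifts the
minimal reconstruction one node younger, so recovery experiments plant
gains at nodes whose children both contain ≥ 2 taxa (e.g. `"EPA"`).

The bundled `default_species_tree()` is ultrametric with round-number
node ages consistent with published calibration windows; it
parameterizes simulations and examples, and is not a new dating result.

**Duplication annotation.** Gene-tree nodes are annotated by the
species-overlap rule: a node is a duplication iff the species sets of
its child clades intersect. This mechanizes what was originally manual
tree inspection. It is deliberately *not* full LCA reconciliation: the
two coincide when sibling species spans are complementary in the
species tree (the regime covered by the oracle tests), but strict LCA
reconciliation additionally infers duplications at nodes whose sibling
spans are nested, at the cost of positing extra losses. Support values
are ignored by default.

**The four origin models.** For each venom leaf, the most recent
duplication node on its root path decides the call: none (and a
single-copy OG) → co-option of a universal single-copy gene; a
duplication spanning non-Chalcidoidea species → co-option after an
ancient duplication; within Chalcidoidea but spanning non-*Anastatus*
chalcids → co-option after a chalcid duplication; confined to
*Anastatus* with at least one non-venom paralog → recent duplication
with neofunctionalization. Genes fitting no predicate stay
`unclassified` rather than being forced — consistent with reported model
shares not summing to 100%. OGs that are *Anastatus*-specific or have
fewer than five members are filtered out beforehand as uninformative.
`gen_gene_trees()` builds noiseless trees realizing each scenario from
pruned copies of the species tree, randomizing taxon sampling; the
classifier is exact on all four (50 trees each in the tests).

## Regulatory divergence and NRERs

Ortholog expression divergence uses Spearman rank correlation over
matched stage profiles (ties mid-ranked; constant profiles return `NA`).
Group comparisons (e.g. pairs with vs without a recent TE insertion in
their regulatory regions) use the two-sided Wilcoxon rank-sum test:
exact when `min(n, m) ≤ 8` and tie-free, otherwise the normal
approximation with tie correction and no continuity correction (the
plain "rank-sum test" reading; exactness is verified against full
enumeration for all small group sizes).

**NRER detection.** Regulatory regions are the strand-aware 1 Kb
upstream/downstream flanks and introns from the gene models. Against the
pairwise alignment, each reference position is aligned-identical,
aligned-mismatch, or unaligned (no block, or query gap). Positions whose
centered 20 bp windowed identity is ≤ 0.5 (unaligned = non-identical)
form candidate runs; runs are trimmed to their outermost truly
non-identical columns — making planted boundaries exact — merged when
separated by < 10 bp, and reported at ≥ 60 bp. Only the 60 bp minimum is
from the original analysis; the identity threshold, window and merge gap
are invented defaults exposed as arguments (the original screen was by
eye, so these are calibration knobs, not claims). A region with no
alignment coverage at all is returned whole and flagged `no_coverage`
instead of being silently treated as one giant divergent run. Detection
is invariant to how the MAF is split into blocks at non-divergent
positions.

TE attribution requires ≥ 50% of an NRER's length to overlap a recent TE
insertion (supplied as BED — deriving "recent, non-orthologous" TE calls
is upstream of this package). Fold-change classes for the enrichment
test use `FC = (max + 0.1)/(min + 0.1)` over the two venom-gland TPMs —
the pseudocount guards near-zero denominators — with > 6 large-shift and
< 1.25 stable. The χ² test is Pearson without continuity correction
(Yates available via flag), counting *genes* with ≥ 1 NRER, not NRERs.

## The venom coexpression module

Networks are unsigned with soft power 4: $a_{ij} = |cor(x_i,x_j)|^4$,
zero diagonal, and the topological overlap matrix
$TOM_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$.
All-zero and constant genes are dropped first. Coexpression runs on
`log2(TPM + 1)` in the analysis scripts: on raw TPM the venom-gland
spike dominates the variance and correlation saturates, erasing the
hub/periphery gradient that kME is meant to measure.

**Tree cut.** Modules come from average-linkage clustering on
`1 − TOM`. The dynamic hybrid tree cut of the reference implementation
is under-specified for reimplementation; the package instead uses a
static cut at the midpoint of the *largest gap between consecutive merge
heights whose induced cut yields at least one cluster of minimum size*.
The validity condition matters: the raw largest gap can sit among
near-duplicate leaf pairs at the bottom of the dendrogram, and a plain
upper-quantile rule undoes a fixed ~1% of merges and therefore returns
two or three clusters regardless of the true module count. The chosen
rule recovers planted partitions exactly (including five 40-gene blocks
from only 12 samples), sends unstructured genes to `"grey"`, and is
overridable via `cut_height`. Clusters below 30 genes are unassigned;
modules whose eigengenes correlate at ≥ 0.75 (the "merge threshold
0.25" convention) merge iteratively.

Module eigengenes are the first principal component of the standardized
module submatrix, oriented to correlate non-negatively with the mean
module profile (PC sign is otherwise arbitrary; the rule makes runs
deterministic). kME is the signed Pearson correlation with the ME;
module-shift and connectivity analyses use |kME|. The VRM is simply the
module holding the most venom genes (ties to the lexicographically
smaller label, logged). The venom-gland dependence check re-runs the
pipeline without venom-gland samples and reports the maximum venom-gene
fraction of any module against a 0.5 dispersal threshold — a transparent
descriptive substitute for model-based module-preservation statistics.
Cross-species conservation uses one-to-one orthologs only; grey genes
are excluded from shift statistics, shifts are tested against venom
status by χ², and |kME| ranks of conserved vs shifted genes expose the
core-stays / periphery-shifts pattern.

## What the synthetic data emulates — and what it does not

The generators plant exactly the structures the analyses look for:
K80-diverged LTR pairs of known age; read pairs at exactly 10 nt
5′-overlap with 1U/10A biases; a two-species factor-model expression
data set sharing latent stage factors, with a venom-gland-specific
module whose periphery (largest residual noise, hence lowest |kME|)
shifts to a background module in species B — one coherent mechanism that
simultaneously realizes expression shifts (FC > 6 in the venom gland),
module shifts, their concentration in non-venom genes, and the
periphery pattern; alignments whose divergent segments have exact
planted boundaries; binary characters gained at a known node with
independent tip losses; and noiseless gene trees per origin scenario.
Block factors in the planted-partition generator are orthogonalized so
"between-block correlation 0" holds exactly even with few samples.

None of this emulates sequencing error, mapping ambiguity, assembly
artefacts, compositional biases, phylogenetic uncertainty or correlated
gene loss. Passing tests therefore establish that the *estimators and
rules are implemented correctly and recover planted truth under their
own assumptions* — not that those assumptions hold in any particular
wasp genome. Headline numbers from the original study (venom gene
counts, TE-mapping percentages, specific p-values) derive from the full
datasets and are not reproducible at this scale; the acceptance script
instead reports oracle agreement and planted-truth recovery.

## Problem sizes and runtime

The bundled experiments are sized for a laptop: 500 LTR pairs of 400 bp;
3,000-read ping-pong populations (100 null seeds, 20 seeds per planted
fraction); 200-gene × 27-sample expression pairs; 200 presence/absence
characters on the 19-taxon tree with exhaustive ≤ 10-leaf oracles; 50
gene trees per origin scenario; ~40 kb synthetic chromosomes. The whole
test suite runs in well under five minutes on one CPU.

## Known limitations

* The static gap cut is a deliberate simplification of dynamic tree
  cutting; extremely unbalanced or nested module structures may be split
  or merged differently from the reference implementation.
* A network of pure noise (no coherent module anywhere) can still yield
  one large weak cluster; the dispersal check is meaningful because real
  stage-driven modules remain after removing venom-gland samples.
* Wagner-parsimony ages inherit the tree-shape caveat above: gains at
  nodes with single-taxon basal children are under-recovered at high
  loss rates, which is a property of parsimony, not a bug.
* The venom-gland "specialized expression" axis is a stand-in; only the
  N90-and-peptides rule determines calls.
* MAF support covers the two-row pairwise dialect emitted by common
  pairwise aligners; multi-species MAF is out of scope.
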