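---
title: "Likelihood-based analysis of B cell repertoire evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based analysis of B cell repertoire evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrlik)
```

## The quantities

A masked protein language model, asked about position $i$ of an
amino-acid sequence, returns a probability distribution over the 20
canonical residues. Stacking these gives the per-residue likelihood
(RL) matrix $P \in [0,1]^{L\times 20}$, row-stochastic, aligned to the
sequence. Two summaries drive everything in this package:

* the **sequence pseudolikelihood**
  $\mathrm{SP} = \frac{1}{|S|}\sum_{i \in S} \ln P[i, a_i]$, the mean
  log-probability of the observed residues $a_i$ over a scored position
  set $S$; and
* the **substitution rank**: at a position where a lineage parent and
  child differ, the descending rank of the child's residue within the
  *parent's* probability column (1 = the model's top choice).

SP is computed with natural log by default. The magnitudes this
produces (0 for a perfectly predicted sequence, $\ln(1/20)\approx-3.0$
at the uniform baseline) are the scale on which antibody models are
usually reported; a `log_base` argument switches to log2 for readers
who prefer bits. Observed probabilities of exactly zero are clamped to
a floor of $10^{-10}$ before the log — scores stay finite, and the
number of clamped positions is carried on the result so the
intervention is auditable.

Four input sources control $S$ and the matrix context: `full_vdj`
(full sequence in, all positions scored), `cdr3_from_vdj` (full
sequence in, only CDR3 positions scored — full context, local score),
`cdr3_only` (bare CDR3 in and scored), and `paired` (heavy and light
positions pooled into one mean; the two chains are scored with their
own matrices and the log-probabilities concatenated, heavy first).

## The likelihood provider contract

Scoring is separated from probability generation by a minimal
contract: a provider is a named function from a sequence to a validated
probability matrix, deterministic for fixed input, plus a
`paired_scoring` capability flag. Real language models can be wrapped
behind this surface without touching any analysis code. The package
ships three synthetic providers:

* `germline_anchored_provider(q)` puts mass `q` on the germline
  residue at every position and spreads the remainder uniformly over
  the 19 alternatives. This caricatures the well-documented germline
  bias of antibody models, and makes SP an exact linear function of the
  germline mismatch count:
  $\mathrm{SP} = \frac{(L-k)\ln q + k \ln\frac{1-q}{19}}{L}$ for $k$
  mismatches. The default $q = 0.7$ gives a germline SP of
  $\ln 0.7 \approx -0.36$, inside the range antibody-specific models
  produce on near-germline sequences. `q` must lie strictly between
  $1/20$ (where the provider degenerates to uniform and the germline
  anchor disappears) and 1.
* `uniform_provider()` is the null model, SP $\equiv \ln(1/20)$.
* `positional_profile_provider(concentration, seed)` draws each column
  from a symmetric Dirichlet seeded by a hash of the sequence —
  deterministic per input, but with non-trivial structure over the 19
  alternative residues. It exists because the germline-anchored
  provider is *exchangeable* over alternatives: substitution-rank
  analyses that must distinguish "model-preferred" from "arbitrary"
  mutations need a provider whose alternatives differ.

## Repertoire ingestion and filtering

Readers accept AIRR-Rearrangement-style TSV (amino-acid CDR3
coordinates, 0-based half-open) and CellRanger-style contig CSV
(1-based inclusive, converted on read). Rows with non-canonical
letters (`X`, `*`, gaps) are dropped and counted at read time, because
providers emit 20-letter distributions and every downstream statistic
assumes the canonical alphabet.

Filtering applies five rules in a fixed order, counting each cell
against the first rule it violates: (1) more than one transcript for a
locus, (2) incomplete cells, (3) missing heavy germline, (4) missing
heavy C-gene, (5) duplicated barcode. A barcode is "duplicated" when it
occurs in more than one sample — within a sample, one heavy plus one
light contig per barcode is simply a cell — and all copies are removed,
since there is no principled way to decide which is real. The counts
always reconcile: removed plus retained equals input.

SHM is the Hamming distance between a sequence and its germline,
defined only for equal lengths. Cells whose germline length differs
(indels) return `NA` and drop out of SHM and edge-substitution
analyses rather than being force-aligned; trees still accept them
because Levenshtein distance handles indels.

Clonotyping is configurable. The default groups cells by heavy and
light V-gene family plus identical heavy and light CDR3 amino-acid
sequences. This is a standard single-cell heuristic, but it has a
consequence worth knowing: the moment hypermutation touches the CDR3,
the descendant is split into its own clonotype, so clone size becomes
mechanically entangled with mutation load (on synthetic data this
inflates the SP–expansion correlation from $\approx 0$ to
$\approx +0.6$). `filter_cells(..., clonotype = "input_clone_id")`
instead trusts a `clone_id` column provided upstream — simulation
truth here, or a dedicated clonal-inference tool on real data — and is
what the package's own expansion analyses use.

## Lineage forests

Each clone's unique sequences are arranged into a tree rooted at the
germline by iterative minimum-distance attachment: repeatedly attach
the unattached sequence whose minimum Levenshtein distance to any
attached node is smallest, as a child of that nearest node. This
Prim-style growth provably yields a minimum spanning tree of the
complete distance graph over germline plus sequences, which the test
suite checks against an independent Kruskal implementation. Ties are
broken deterministically: prefer the candidate parent with the larger
cell count (expanded intermediates are the more plausible ancestors),
then the lexicographically smaller child sequence, then the earlier
attached parent. Other tools may break ties differently, so exact
topologies can differ on tied inputs; edge-aggregated statistics are
robust to this.

Trees are built on heavy chains by default, or on concatenated
heavy+light sequences (`chains = "paired"`) for intraclonal analyses
of paired data. Export is Newick with node identifiers as labels and
edge weights as branch lengths; the serializer is written directly on
the tree structure because these trees contain labelled internal nodes
and unary chains that a tip/internal phylogeny representation cannot
hold.

## Edge-substitution statistics

For every edge with equal-length endpoints, the probability matrix is
computed for the *parent* (the sequence before the edge). At each
differing position the child residue's descending rank is recorded;
an edge with several differing positions is summarized by the
arithmetic mean of its per-position ranks. Rank ties use competition
ranking (1 plus the number of strictly greater probabilities): exact
ties are vanishingly rare for real models but common for synthetic
providers, and this rule keeps "most likely residue has rank 1" exact.
Germline-to-child edges are scored by default — the germline is a
perfectly valid parent sequence and root edges carry much of a small
clone's signal — with a flag to exclude them for sensitivity analyses.

The predictability of *where* SHM strikes is measured by comparing the
parent-residue likelihood at mutating versus conserved positions of
each edge, paired per edge and tested with a paired t-test. Note the
power asymmetry: an edge contributes a conserved mean over $\sim L$
positions but a mutating mean over only one or two, so per-edge noise
is dominated by the mutating side; detecting the targeting signal on
simulated data needs pooled means and many edges, and the unit tests
therefore assert direction on simulations and significance on a
constructed scenario where mutations deterministically hit the
lowest-likelihood positions.

Per-position uncertainty is summarized by Shannon evenness
$H/\ln 20$, 1 for a uniform column and 0 for one-hot, with
$0\ln 0 = 0$. Sample-level substitution ranks are aggregated as
unweighted means of per-sample means, so large repertoires do not
dominate cross-sample averages.

## Association analyses

Correlations are plain Pearson or Spearman with two-sided p-values;
zero-variance inputs are returned flagged rather than as errors so
that batch analyses can proceed. Group contrasts use Welch's
(unequal-variance) t-test — isotype groups differ in both size and
spread — with Holm adjustment over each family of pairs by default
(Bonferroni and BH available). Cross-sample summaries are unweighted
means of per-sample statistics, without Fisher transformation;
per-sample estimates are reported alongside so readers can transform
if desired.

## The synthetic generator

`simulate_repertoire()` produces the study conditions the analyses
assume: paired heavy/light repertoires of a configurable size (default
1000 cells) descending from 8 independent germlines of 110 residues
with the CDR3 at positions 95–107 near the 3' end; clone sizes from a
discrete power law $P(s)\propto s^{-2.5}$ truncated at the cell count,
giving a few expanded clones and a heavy singleton tail; lineages in
which each cell derives from an earlier member by whole rounds of
point substitutions (2 per round, up to 8 rounds, no indels); isotype
switching with per-round probability 0.3, inherited once it happens;
and light chains mutating at half the heavy rounds (rounded down).
Every substitution is recorded, and replaying a cell's log against its
germline reproduces its sequence exactly — the generator's audit
trail, enforced by tests.

Two design points deserve emphasis. First, each cell's *total* round
count is drawn uniformly on $\{0,\dots,\text{max}\}$ independently of
clone size, and its parent is any earlier member with at most that
many rounds. This keeps mutation load statistically independent of
clonal expansion, which is the null the expansion analyses are
calibrated against; a scheme where depth accumulates freely down the
lineage would couple the two by construction. Second, the mutation
strategy is a flag: `uniform` replaces a residue with one of the 19
alternatives uniformly (the simplest null), while `provider` draws the
replacement from a provider's column and prefers positions where the
provider finds the current residue unlikely (weight $1 - \mathrm{RL}$).
The guided mode exists to give the rank and targeting analyses a
positive control with a known direction.

What the generator does *not* emulate: AID/polymerase hotspot motifs
and 5-mer context models of SHM targeting, germinal-center population
dynamics, indels, nucleotide-level processes, allelic diversity within
a V family, and realistic germline sequence composition (germlines are
i.i.d. uniform residues). Passing tests on this generator therefore
demonstrate that the machinery measures what it claims under known
truth — not that real repertoires will show the same effect sizes.
Real-model SPs are noisy in ways the germline-anchored provider is
not; its SP–SHM correlation of exactly $-1$ is the designed limiting
case, and real analyses should expect substantially weaker values.

## Numerical choices and degenerate inputs

* Probability rows must sum to 1 within $10^{-6}$ (provider output is
  validated, not trusted); evenness validates non-negativity and the
  sum before computing entropy.
* Zero observed probabilities: clamped at $10^{-10}$, counted.
* Identical sequences in one clone are merged into one node (cell
  counts add); duplicate sequences passed explicitly to `build_tree()`
  are an error rather than silently merged.
* A sequence identical to its germline forms a node at edge weight 0;
  weights between distinct sequences are always $\geq 1$.
* Empty repertoires are valid results of filtering; statistics that
  need data (expansion, correlations with $n < 3$) fail loudly instead
  of returning fragile numbers.
* Memoization keys probability matrices by input string within a
  scoring run, so repeated sequences cost one provider call.

## Problem sizes

The bundled analyses and tests run at sizes chosen to make every
statistic stable while keeping a full run interactive on a laptop:
1000 cells for the repertoire-level directional analyses, 350 cells
(about 280 scoreable edges) for the mutation-strategy contrast, 200
cells for the affinity association, 200 random clones for the
tree-weight oracle, and $10^4$ random columns for the rank oracle.
The pipeline scales linearly in cells for scoring and roughly
quadratically in unique sequences per clone for tree construction.

## Known limitations

Levenshtein trees are one reconstruction heuristic; maximum-parsimony
and other phylogenetic methods can disagree on topology, and no
bootstrap support is computed. Clonal undersampling means "conserved"
positions are only conserved among observed cells. Epistasis is
invisible to per-position ranks: the likelihood of a residue depends on
the rest of the sequence, so multi-mutation edges conflate contexts.
The provider contract deliberately leaves open whether a wrapped model
uses masked or unmasked passes and how paired chains are concatenated —
both vary across published models and belong to the adapter, not the
analysis.
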