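# bcrlik

Masked protein language models assign every residue of an antibody
sequence a probability, and the length-normalized sum of the log
probabilities of the observed residues — the sequence pseudolikelihood
(SP) — summarizes how "likely" the model finds the whole sequence.
`bcrlik` is an R package for relating these likelihoods to signatures of
in vivo B cell selection and evolution in single-cell BCR repertoires:
isotype usage, V-gene family composition, clonal expansion, somatic
hypermutation (SHM), lineage-tree structure, and binding affinity.

It is aimed at computational immunologists who have single-cell V(D)J
annotations (AIRR Rearrangement TSV or CellRanger-style contig CSV) and
per-residue probability matrices from any likelihood provider — a real
protein language model behind the package's provider contract, or the
synthetic providers bundled here.

## What it computes

For a sequence of length `L` with per-residue probability matrix
`P` (`L x 20`, rows indexed by position, columns by amino acid), the
pseudolikelihood is

    SP = (1/|S|) * sum_{i in S} ln P[i, aa_i]

where `S` is the scored position set: the full V(D)J sequence
(`full_vdj`), the CDR3 positions inside the full-context matrix
(`cdr3_from_vdj`), the bare CDR3 string (`cdr3_only`), or all heavy plus
light positions jointly (`paired`).

On top of scoring, the package provides:

* **Repertoire ingestion** — AIRR/contig readers, the standard
  five-rule cell filter (multi-transcript, incomplete, missing germline,
  missing heavy C-gene, duplicated barcode) with an auditable
  `filter_log`, clonotype assignment, Hamming SHM.
* **Lineage forests** — one germline-rooted tree per clone over unique
  sequences, grown by iterative minimum-Levenshtein attachment
  (Prim-style, so total edge weight equals the minimum-spanning-tree
  weight of the complete distance graph), with Newick export.
* **Edge-substitution statistics** — at every mutated position along a
  tree edge, the rank of the child's residue in the parent-sequence
  probability column (descending, competition ranking; 1 = most likely),
  plus conserved-vs-mutating residue likelihoods and per-position
  Shannon evenness `H/ln 20`.
* **Association analyses** — Pearson/Spearman correlations of SP with
  SHM, expansion, root-path length and Kd; Welch pairwise isotype
  contrasts with Holm adjustment; cross-provider SP correlations;
  group-frequency associations.
* **A synthetic generator** — power-law clone sizes, germline-anchored
  lineages with recorded substitution truth, SHM-coupled isotype
  switching and affinity tables, so the whole pipeline runs and is
  tested without model weights or sequencing data.

## Worked example

```r
library(bcrlik)

sim    <- simulate_repertoire(sim_config(n_cells = 300, seed = 42))
rep    <- filter_cells(sim$chains, clonotype = "input_clone_id")
prov   <- germline_anchored_provider(q = 0.7)
scored <- score_repertoire(rep, prov, sources = c("full_vdj", "paired"))
forest <- build_forest(rep)
feat   <- sp_feature_table(scored, rep, forest = forest)

hf <- subset(feat, locus == "heavy" & source == "full_vdj")
correlate(hf$sp, hf$hamming_shm, "pearson")
#>   analysis statistic estimate p_value   n degenerate
#> 1     <NA> pearson_r       -1       0 300      FALSE

group_compare(hf, group = "isotype")
#>   group1 group2  mean1  mean2 estimate       t  p_value  n1  n2 adjusted_p
#> 1    IgA    IgG -0.706 -0.704  -0.0026  -0.137 8.91e-01 101  95   8.91e-01
#> 2    IgA    IgM -0.706 -0.505  -0.2010 -10.318 2.74e-20 101 104   8.23e-20
#> 3    IgG    IgM -0.704 -0.505  -0.1984  -9.769 1.24e-18  95 104   2.48e-18

recs <- forest_edge_substitutions(forest, prov)
mean_substitution_rank(recs)$grand_mean
#> [1] 2
```

Reading the output: SP falls exactly one germline-anchored step per
hypermutation (Pearson r = −1 under this provider — real models are
noisier but show the same negative trend), unswitched IgM cells score
about 0.2 natural-log units higher than class-switched IgA/IgG cells,
and along lineage edges the observed substitution is on average the
model's 2nd-ranked residue (rank 1 is the unmutated germline residue
under this provider).

The one-command demonstration runs every stage and writes all artifacts
(scores, trees, edge records, statistics, manifest with hashes):

```r
run_pipeline(demo_config(), "demo_run")
```

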