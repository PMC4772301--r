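---
title: "Methods: comparative hologenome analysis with holocompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative hologenome analysis with holocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocompare)
```

# The analytical problem

Sponges with dense microbial consortia (HMA) and sponges with sparse
ones (LMA) offer a natural contrast for asking how a host genome and a
symbiont community are shaped by their partnership. `holocompare`
implements the two halves of that comparison:

* **host side** — compare protein-domain repertoires across sponge
  genomes, with emphasis on innate-immune and symbiosis-related
  domains, their co-occurrence architecture within proteins, and the
  internal structure of the highly duplicated SRCR-like
  (scavenger receptor cysteine-rich) family;
* **symbiont side** — compare the expressed functions of the two
  microbial communities through homology-group read counts,
  differential expression, and domain enrichment.

Every stage accepts real inputs (InterProScan-style domain tables,
FASTA, read-assignment tables) or synthetic ones from the generator
module, which plants known truth so recovery can be measured.

# Host-side models

## Gene-origin tagging

Assembled sponge gene models can be contaminated by symbiont DNA.
`tag_gene_origin()` assigns each gene `E` (eukaryotic) when any
eukaryotic hit has e-value below the threshold (default `1e-4`), `P`
when only prokaryotic hits do, and `X` otherwise. The eukaryotic tag
dominates: a gene with both kinds of significant hit is `E`. Hits to
taxa outside the binary split (viruses, unplaced sequences) carry no
information under this rule and are dropped with a warning — a policy
choice, since the rule is defined only for the eukaryote/prokaryote
contrast.

## Repertoire statistics

The unit of comparison is the *occurrence count*: how many times a
domain appears in a genome, with the number of distinct
domain-bearing genes carried as a secondary statistic. Expansion
calls between species use the inequality form
`count_a >= t * count_b` (default `t = 1.5`), which needs no division
and therefore handles zeros cleanly: any positive count against zero
is an expansion; 0 against 0 is never reported.

Over/under-representation against a panel of background species is
ranked by `z_d = (x_d - mu_d) / sigma_d`, with the sample (n − 1)
standard deviation because the panel is a sample of eukaryote genomes,
not a population. Domains with a constant background (`sigma = 0`) or
missing from the panel are flagged unscorable rather than mapped to
infinite scores; Z-scores are computed on raw counts.

Keyword selection of immune/symbiosis domains is case-insensitive
substring matching of each keyword against the domain's concatenated
annotation strings. The default keywords are `"symbio"`,
`"innate immunity"`, `"antimicrobial peptides"` and
`"antibacterial"`. Strict substring semantics means
"innate immune response" does *not* match "innate immunity"; the rule
is simple and auditable, and the keyword list is a parameter.

## Co-occurrence networks

An edge between domains `d1` and `d2` has per-species weight equal to
the number of *proteins* of that species containing at least one copy
of each — presence-based counting, so a protein with three copies of A
and one of B contributes 1, not 3. Self-pairs are excluded. Edges are
retained when the weight reaches `min_count` (default 5) in at least
`min_species` (default 1) species; node size is the number of retained
incident edges. A conservation identity (total weight equals
`sum over proteins of C(k_p, 2)` with `k_p` distinct subset domains in
protein `p`) is used as a structural test.

## SRCR-like family analysis

The SRCR-like domain is a pattern-recognition module whose members
keep a scaffold of conserved cysteines over an otherwise fast-evolving
sequence. The family pipeline is:

1. **All-vs-all exact local alignment** (`local_align`):
   Smith–Waterman with BLOSUM62 and affine gaps, gap open 11 and
   extend 1 — the familiar protein-search defaults. Raw scores are
   rescaled to bit scores with the gapped Karlin–Altschul constants
   (lambda = 0.267, K = 0.041). `X` scores 0 against everything.
   Traceback prefers diagonal, then up, then left, so reported
   alignments are deterministic.
2. **Homology criterion** (`homology_graph`): an edge requires >= 90%
   positive-scoring aligned residue pairs. The denominator is the
   number of aligned residue–residue columns (the "Positives"
   convention; an alternative denominator, the shorter sequence
   length, is a switch). Because the *optimal* local alignment of two
   unrelated sequences is often just a handful of residues — which
   trivially reaches any positives fraction, and which a word-seeded
   heuristic search would never report — an edge additionally requires
   at least `min_aligned = 30` aligned columns. With ~100-residue
   domain instances this floor only excludes degenerate alignments.
3. **Markov clustering** on bit scores (below), retaining clusters
   with at least 5 members, ranked by size with deterministic
   tie-breaks; smaller clusters are reported separately rather than
   dropped.
4. **Centre-star multiple alignment** (`progressive_msa`): the centre
   is the member with the best summed pairwise global score; others
   are aligned to it and merged under "once a gap, always a gap".
   For short, high-identity family members this is adequate, and it
   keeps the whole pipeline exact and dependency-free; it does not
   perform the iterative refinement of a production multiple aligner,
   which is the main divergence to keep in mind for distant members.
5. **Conservation profiles** (`conservation_profile`): per-column
   frequencies over residues plus gap (summing to 1), with
   `conservation` = the largest amino-acid share and
   `cysteine_conservation` = the share of C. Lineage-specific
   expansion tables flag a dominant species when it holds a strict
   majority of a cluster.

# Markov clustering

`mcl_cluster()` is a from-scratch dense-matrix implementation of the
Markov Cluster algorithm, used both for SRCR families and for
metatranscriptome homology groups. Self-loops are added with weight
equal to each node's maximum incident weight (the standard loop
policy; 1 for isolated nodes); columns are normalised to a stochastic
flow matrix; and the iteration alternates expansion (matrix power
`e = 2`), inflation (elementwise power `r`, then column
renormalisation) and pruning of entries below `1e-5`, until the matrix
changes by less than `1e-8` or 200 iterations pass. Clusters are read
off the idempotent limit: attractors (positive diagonal) are grouped
into systems via their mutual support, and each node joins the system
of its largest-probability attractor, ties broken by smallest node id
— making the partition fully deterministic.

Inflation controls granularity: `r = 2` is the canonical default and
is used for SRCR families (where no published value exists, so it is
exposed as a parameter); `r = 3.6` is the documented setting for
homology-group construction and is the default of
`build_homology_groups()`. Two structural properties anchor the
implementation: MCL output refines connected components, and on graphs
whose components are cliques it equals `connected_components()` for
any `r > 1` — both are exercised in the test suite over random graphs.

The dense implementation targets desk-scale graphs (up to a few
thousand nodes); it makes no attempt at the sparse, out-of-core regime
of the reference network-clustering tools.

# Symbiont-side models

## From reads to group counts

Reads aligning to an rRNA reference at >= 90% identity *and* >= 90%
coverage are removed (`rrna_filter`; thresholds inclusive). Remaining
reads are assigned to the homology group of their best-hit reference
sequence and summed per sample (`aggregate_counts`); reads whose best
hit falls outside every group go to an explicit `unassigned` bucket so
totals are conserved.

## Quantile normalisation

`quantile_normalize()` replaces each sample's value at rank `i` with
the cross-sample mean of the rank-`i` values; tied entries within a
sample all receive the mean of the reference values across their tied
rank span. On tie-free data every sample's sorted vector is identical
afterwards and the transform is idempotent (both held to numerical
precision in the tests); with ties, the averaging necessarily perturbs
those identities slightly — an inherent property of rank-based
normalisation of discrete counts, shared with the standard
implementations.

## Differential expression

The DE caller is a fully specified substitute for an external tool,
so that its error rates can be measured on planted data. The default
method, `nb_exact`, uses the exact negative-binomial test conditioned
on group totals, with dispersions estimated from within-community
replicates (delegated to edgeR's `exactTest`). The rationale is
calibration: symbiont read counts are overdispersed, and a
Poisson-conditioned binomial test treats a group with biological
variance far above its mean as if sampling noise were the only source
of spread, which inflates significance badly (at mean 200 and
dispersion 0.1 the variance ratio is about 21). The Poisson-limit
test is still available as `method = "binomial"` — an exact two-sided
binomial test of the community split against the library-size ratio —
and is the automatic fallback when a community has no replicates.
P-values are Benjamini–Hochberg corrected and a group is DE at
`q <= 0.05`; reported fold changes and directions come from
quantile-normalised community means with pseudocount 1. DE calls made
by an external tool can be fed directly into the enrichment step,
which takes a plain vector of group ids.

## Domain enrichment

For each domain present in at least one DE group,
`domain_enrichment()` computes the upper-tail (cumulative)
hypergeometric probability of seeing `k` or more carriers among the
`n` DE groups, given `K` carriers in a universe of `N` groups, then
applies BH over the tested domains (`q <= 0.05`). The default
universe is the *annotated* groups — those carrying at least one
domain — because unannotated groups cannot inform a domain test
either way; `universe = "all"` switches to every group. The test is
at group-level presence, not domain-instance counts, since the
homology group is the unit of quantification. The same machinery
applies to any labelling of groups (e.g. GO terms) by relabelling the
mapping.

# The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed once and the tests are run against
them, not the other way around.

* `gen_panel()` — negative-binomial domain counts
  (`var = mu + phi * mu^2`) for three focal species (`SC`, `XT`, `AQ`)
  and a 30-species background panel. Defaults: baseline mean 200
  occurrences, dispersion 0.01, planted expansions of fold 3. The
  small dispersion models within-lineage stability of domain counts;
  cross-lineage differences are what the planted folds represent.
  `phi = 0` is the deterministic limit (counts equal the rounded
  mean), which gives exact expectations in degenerate tests.
* `gen_srcr_sequences()` — each cluster has a scaffold of length 100
  with 8 cysteine columns kept with probability 0.95 per member, and
  variable columns drawn from a per-cluster Dirichlet centred on a
  consensus residue. The concentration parameter is the Dirichlet
  weight on the consensus (default 60, giving ~90% expected
  within-cluster identity; infinite concentration makes members
  identical). Variable columns never use cysteine, so the cysteine
  profile is an unambiguous scaffold signature. Between-cluster
  identity is at the random-background level. The generator emulates
  substitution diversity only — real SRCR repertoires also contain
  indels, fragmentary domain calls and inter-family mosaicism, so
  exact recovery here demonstrates correctness of the machinery, not
  performance on hard real data.
* `gen_meta_counts()` — two communities with 3 replicate samples
  each, 500 homology groups, log-normally spread baseline means
  (expectation 200 reads) with NB dispersion 0.1; 50 planted DE groups
  at |log2 fold| = 3 split symmetrically between communities; a
  40-domain vocabulary in which 3 planted enriched domains attach to
  DE groups with probability 0.8 versus 0.1 background. Truth labels
  are returned alongside, never embedded in the data.

All generators are pure functions of their spec, including the seed.

# Numerical and design choices

* Coordinates are 0-based half-open internally; annotation files are
  read as 1-based inclusive (the InterProScan convention).
* Substitution scores come from Biostrings' BLOSUM62 with the `X`
  row/column zeroed.
* Smith–Waterman floors at zero; a best score of 0 means "no local
  alignment" (no homology edge, empty aligned strings).
* MCL: convergence tolerance `1e-8` on the max absolute change,
  pruning threshold `1e-5`, 200-iteration cap with a warning flag on
  non-convergence.
* Hypergeometric tails use `phyper` directly; the test suite checks
  them against full enumeration for every `N <= 12` configuration.
* BH correction is `p.adjust(method = "BH")` throughout; "FDR <= 0.05"
  always means the adjusted value.
* Degenerate inputs are explicit: empty domain tables produce all-zero
  count rows; all-zero count groups are excluded from DE testing;
  single-sample tables pass through quantile normalisation unchanged
  with a warning; singleton clusters are their own alignment.

# Problem sizes

The test and acceptance runs use desk-scale sizes chosen to exercise
every code path with comfortable statistical margins: 50 random
clique-union graphs of up to 60 nodes for the MCL/components
equivalence; 100 random pairs of up-to-8-mers against the exhaustive
alignment oracle; all hypergeometric configurations to `N = 12`;
20 replicate null and 5 replicate signal datasets of 500 groups for DE
calibration; 4 replicate five-cluster SRCR simulations (50 sequences,
~1.2k pairwise alignments each); and 20 replicate panels of 300
domains for expansion recovery.

# Known limitations

* The aligner and MCL are dense, exact implementations sized for
  thousands — not millions — of sequences or nodes.
* Centre-star alignment has no refinement pass; for clusters with
  long indels or very divergent members a production multiple aligner
  will do better.
* The homology criterion depends on local-alignment geometry; the
  `min_aligned` floor (30 columns) is appropriate for ~100-residue
  domain instances and should be revisited for much shorter inputs.
* The DE caller assumes exactly two communities and uses group totals;
  it does not model sample-level covariates.
* Keyword selection is deliberately literal; synonym or ontology
  expansion is out of scope (GO-style labellings can still be tested
  for enrichment by relabelling).
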