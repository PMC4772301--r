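# holocompare

Comparative analysis of sponge hologenomes: the protein-domain
repertoires of hosts that carry dense (HMA, high microbial abundance)
versus sparse (LMA, low microbial abundance) symbiont communities, and
the expression of the communities themselves.

Marine sponges filter enormous volumes of seawater yet maintain
species-specific microbial consortia, which makes the innate-immune
machinery of the host — and the expressed functions of its symbionts —
a natural place to look for the genomic basis of the partnership.
`holocompare` implements both sides of that comparison as a tested,
reusable R pipeline, driven either by real annotation tables or by a
built-in synthetic-data generator that plants known signal (domain
expansions, sequence families, differentially expressed groups) so
every stage can be benchmarked against truth.

## What it computes

**Host side.**

* Domain occurrence counts per genome and per gene
  (`count_domains`), keyword selection of immune/symbiosis domains
  (`select_keyword_domains`), and expansion calls between species `a`
  and `b` by the inequality `count_a >= t * count_b` (default
  `t = 1.5`; `fold_change_selection`).
* Over/under-representation against a multi-species background panel,
  ranked by `z_d = (x_d - mu_d) / sigma_d` with the sample standard
  deviation (`zscore_representation`), and inter-species Pearson
  correlation of repertoires (`correlate_species`).
* Domain co-occurrence networks: an edge's per-species weight is the
  number of proteins containing both domains, filtered by the
  "seen >= 5 times in >= 1 species" rule (`build_cooccurrence`,
  `filter_edges`).
* SRCR-like (scavenger receptor cysteine-rich) domain families: exact
  Smith–Waterman alignment with BLOSUM62 and affine gaps (open 11,
  extend 1; `local_align`), a homology graph over pairs with >= 90%
  positive-scoring aligned residues (`homology_graph`), Markov
  clustering on bit scores (`mcl_cluster`, written from scratch),
  centre-star multiple alignment (`progressive_msa`), per-column
  residue/cysteine conservation profiles (`conservation_profile`) and
  lineage-specific expansion tables (`lineage_expansion`).

**Symbiont side.**

* rRNA read filtering at 90% identity and 90% coverage
  (`rrna_filter`); homology groups by MCL at inflation 3.6
  (`build_homology_groups`); per-group read-count aggregation
  (`aggregate_counts`).
* Quantile normalisation across samples (`quantile_normalize`),
  differential-expression calling between the two host communities at
  FDR <= 0.05 (`call_differential`), and upper-tail hypergeometric
  domain enrichment among DE groups with Benjamini–Hochberg correction
  (`domain_enrichment`):
  `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.

## Worked example

Simulate five SRCR-like families (10 members each, cysteine scaffold
retained at 95%), cluster them blind, and profile the result:

```r
library(holocompare)

spec <- srcr_spec(n_clusters = 5, cysteine_retention = 0.95, seed = 11)
sim  <- gen_srcr_sequences(spec)
fam  <- cluster_srcr(sim$seqs)          # homology graph + MCL
fam
#> SRCR-like domain cluster set: 5 retained cluster(s) (sizes: 10, 10, 10, 10, 10), 0 below-threshold cluster(s)

prof <- conservation_profile(progressive_msa(sim$seqs[fam$clusters[[1]]]))
round(mean(prof$cysteine_conservation[spec$cysteine_positions]), 3)
#> [1] 0.95
head(lineage_expansion(fam), 2)
#>   cluster size AQ SC XT dominant
#> 1       1   10  3  4  3     <NA>
#> 2       2   10  3  4  3     <NA>
```

The clustering recovers the five planted families exactly (sizes
10×5), and the mean cysteine conservation at the scaffold positions
reproduces the generator's retention probability. On the symbiont
side:

```r
m  <- gen_meta_counts(meta_spec(seed = 42))      # 500 groups, 3+3 samples
de <- call_differential(m$counts, m$samples$community)
enr <- domain_enrichment(de$group[de$de], m$group_domains)
enr$domain[enr$enriched]
#> [1] "PF00001" "PF00002" "PF00003"
```

which are exactly the three planted enriched domains.

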