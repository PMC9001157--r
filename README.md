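# refkit

Build and evaluate multi-locus chloroplast reference databases for plant
DNA barcoding.

Plant metabarcoding has no single universal locus: *matK*, *rbcL*,
*trnH-psbA* and other chloroplast regions each resolve some plant groups
and fail on others. Targeted hybridization capture sidesteps the problem by
generating references for many gene regions (here, a 20-region panel) in
one assay. `refkit` implements the full desk-side workflow around such a
database, for researchers building or assessing multi-locus barcoding
references:

* **Probe panel design** — greedy clustering of candidate targets at 95%
  identity (longest sequence kept per cluster) and 120-mer probe tiling at
  2X (60 bp step, 3′ end anchored).
* **Consensus calling** — pileup observations filtered at base/mapping
  quality ≥ 30, haploid majority calls, positions with depth < 50 masked to
  `N`, gene regions annotated by local alignment.
* **Database accounting** — FASTA + taxonomy TSV I/O and gene-recovery
  matrices (which genes yielded usable sequence per sample).
* **Leave-one-out evaluation** — each record searched against the database
  minus itself by global-alignment identity, the top hit classified by the
  lowest shared taxonomic rank (species → genus → family → order → class).
* **Distance analyses** — Kimura two-parameter (K2P) distances under
  pairwise deletion, per gene and over gene concatenations: baseline
  profiles, an all-genes UPGMA dendrogram, and iterative gene-concatenation
  curves for comparison groups,
  with transition proportion *P* and transversion proportion *Q*:

  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)

* **Synthetic data** — a generator producing rank-structured taxonomies,
  sequences evolved under a continuous-time K2P model with per-gene rate
  variation, gene dropout, and quality-labelled pileups, with exact known
  truth for validating every stage.

The alignment substrate (Needleman–Wunsch/Gotoh and Smith–Waterman with
affine gaps, deterministic tie-breaking, `N` scored as mismatch) is
implemented in C++ and validated against exhaustive enumeration.

## Worked example

Simulate a small study (32 samples, 4 gene regions, 10% gene dropout) and
run every analysis stage:

```r
library(refkit)

cfg <- sim_config(seed = 42, n_classes = 1, orders_per_class = 2,
                  families_per_order = 2, genera_per_family = 2,
                  species_per_genus = 2, samples_per_species = 2,
                  gene_panel = c("matK", "rbcL", "trnH-psbA", "ndhC"),
                  dropout_rate = 0.1)
res <- run_study(cfg)
print(res)
#> synthetic study analysis
#> refdb: 32 samples, 4 gene panel, 116 sequences
#> ranks: 16 species, 8 genera, 4 families, 2 orders, 1 classes
#> recovery: min 2 / max 4 / mean 3.6 genes per sample
#> LOO family level or below (pooled): 100.0%
#> baseline: Sp01_01_01_01_01_s2_SiteB; 60 iterative-concat rows

round(res$loo$table, 1)
#>           species genus family order class none
#> matK         86.7  13.3      0     0     0    0
#> rbcL         93.3   6.7      0     0     0    0
#> trnH-psbA    85.7  14.3      0     0     0    0
#> ndhC         85.7  14.3      0     0     0    0
```

Reading the output: of the 32 samples, each recovered between 2 and 4 of
the 4 target genes (mean 3.6, matching the simulated 10% dropout); every
leave-one-out query matched a database record of its own family or below;
and per gene, 86–93% of queries matched a record of their own species,
the rest their genus — conspecific samples diverge by ~0.1% in the
generator while congeners sit at ~2%, so a sample whose conspecific
partner dropped a gene falls back to a congener hit.

The distance estimator against known truth:

```r
pair <- simulate_k2p_pair(d = 0.05, length = 10000, kappa = 3, seed = 7)
k2p(site_counts(pair$a, pair$b))
#> [1] 0.04866598
```

`run_study(cfg, out_dir = "out/")` additionally writes all tables (TSV),
the database FASTA, the dendrogram (newick) and summary figures (PNG). A
thin command-line wrapper over the same functions is installed at
`inst/exec/refkit.R` (subcommands `simulate`, `study`, `recovery`, `loo`,
`dist`, `iterate`, `consensus`).

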