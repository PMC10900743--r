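# satellitome

Comparative analysis of satellite DNA libraries from short reads.

Satellite DNAs (satDNAs) are tandemly repeated sequences that make up the
bulk of heterochromatin.  Under the **library hypothesis**, related
species inherit a shared ancestral set of satDNA families whose
per-species profiles diverge mainly by differential amplification, not de
novo origin.  Testing this requires comparing whole satellite catalogs
("satellitomes") across species.  `satellitome` implements that
comparative layer for anyone working with per-species monomer catalogs
(FASTA) and paired-end reads (FASTQ):

* **Monomer comparison** — rotation- and strand-aware similarity between
  circular monomers (`monomer_similarity()`), consensus building, and a
  statistical credibility gate that keeps chance alignments of short
  monomers out of the homology graph.
* **Similarity tiers** — same sequence variant (≥ 95%), variant (≥ 80%)
  and superfamily (≥ 50%) within species (`classify_intraspecific()`);
  cross-species groups at ≥ 50% with a main-group flag for groups
  spanning ≥ 4 species (`assign_groups()`).
* **Quantification** — cross_match-style exclusive read masking with a
  Kimura-divergence cutoff (`mask_reads()`), divergence landscapes in 1%
  bins over 0–20%, the paired-end **Tandem Structure Index**
  (`compute_tsi()`; the fraction of a family's mapped mates whose partner
  maps to the same family — near 1 for long arrays, near 0 for scattered
  copies), single-copy-gene normalization
  (`normalize_by_single_copy()`) and a UPGMA clustermap
  (`clustermap_matrix()`).
* **Substructure** — self-dotplots, periodicity detection, decomposition
  of monomers into duplicated subrepeats with intra- vs inter-repeat
  Kimura divergence (`decompose_subunits()`), and higher-order-repeat
  annotation (`annotate_hor()`).
* **Synthetic satellitomes** — a fully seeded generator that evolves a
  satellite library on a species tree (substitution, differential
  amplification, silencing and loss), assembles genomes with clustered
  arrays and scattered copies plus single-copy genes, and emits
  paired-end reads with complete ground truth
  (`simulate_library_evolution()`, `build_genome_and_reads()`).

The divergence model is Kimura 2-parameter,
`K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`, with transition/transversion
proportions `P`/`Q` measured over ungapped aligned columns and saturated
pairs reported as undefined.  See the methods vignette
(`vignettes/satellitome-methods.Rmd`) for the full model description,
parameter defaults and design rationale.

## Worked example

The package ships the published five-species Alligatoridae satellitome
summary (39 families) as a reference table:

```r
library(satellitome)
summarize_catalogs(alligatoridae_satellites())
#> sat_summary: 39 families in 5 species
#>   per species: Asi 3, Cla 13, Cya 6, Mni 6, Ptr 11
#>   RUL range: 23-6317  mean A+T: 47.0%
#>   groups: 4  sizes: 19/8/6/2  ungrouped: 4
```

Thirty-nine families, 3 (Alligator sinensis) to 13 (Caiman latirostris)
per species, repeat units of 23–6317 nt averaging ~47% A+T, and four
cross-species similarity groups of 19, 8, 6 and 2 families with 4
families ungrouped.

A synthetic five-species satellitome, evolved from 6 ancestral families
on a crocodylian-like tree, and its cross-species classification:

```r
sim <- simulate_library_evolution(sim_config(seed = 1))
sim$catalogs$Cya
#> sat_catalog of Cya: 6 families
#> CyaSat01-115  [Cya]  115 nt, A+T 40.0%
#> CyaSat02-224  [Cya]  224 nt, A+T 49.1%
#> ...

groups <- assign_groups(sim$catalogs)
attr(groups, "groups")
#>   group n_members species_span is_main
#> 1     1         5            5    TRUE
#> 2     2         5            5    TRUE
#> 3     3         5            5    TRUE
#> 4     4         5            5    TRUE
#> 5     5         3            3   FALSE
#> 6     6         3            3   FALSE
```

Each group collects the descendants of one ancestral family; groups
spanning at least four species are flagged as main groups (here four of
the six ancestral families survived in all five catalogs; two were lost
from distant lineages).  `run_full_pipeline()` chains simulation (or
user-supplied catalogs and reads), classification, quantification, TSI,
normalization, clustermap and substructure into a TSV report bundle with
a checksummed manifest.  A thin command-line wrapper with `simulate`,
`all` and `summarize` subcommands is installed at
`inst/cli/satpipe.R`.

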