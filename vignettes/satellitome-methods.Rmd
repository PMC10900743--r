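---
title: "Comparative satellitome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative satellitome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satellitome)
```

# The problem

Satellite DNAs (satDNAs) are tandemly repeated sequences organized in long
(peri)centromeric arrays and scattered short arrays.  Under the *library
hypothesis*, related species inherit a shared ancestral set of satDNA
families whose per-species profiles diverge mainly by differential
amplification rather than de novo origin.  Testing this requires comparing
whole satellite catalogs ("satellitomes") across species: classifying
monomers into similarity tiers, quantifying each family from short reads,
distinguishing clustered from scattered organization, and decomposing long
monomers into the shorter subrepeats they arose from.  This package
implements that comparative layer, together with a fully seeded generator
of synthetic satellitomes evolving on a species tree, so every analysis
can be validated against ground truth.

# Monomer comparison

Monomers are circular units of a tandem array deposited with arbitrary
phase and strand.  `monomer_similarity()` therefore doubles the shorter
monomer and locally aligns the other against it on both strands, which
captures every rotation in one linear alignment.  Scoring is the
repeat-permissive scheme match +1, mismatch -1, gap open -2, gap extend
-1; the mismatch penalty carries a 0.001 epsilon so that among equal-score
optimal alignments the match-maximal one is returned deterministically
(local alignment otherwise trims terminal mismatch/match pairs
arbitrarily).  Similarity is matched bases over alignment columns with the
denominator floored at the shorter monomer's length, so it reads as "the
fraction of the shorter monomer matched" and end-trimming cannot inflate
it; an alignment must span at least half the shorter monomer to count at
all.  For equal-length monomers differing only by substitutions this
reproduces exactly the best position-wise identity over all rotations and
strands.

## When is a similarity credible?

A permissive local aligner hands short monomers high "similarity" against
unrelated sequence: the best-scoring window of a 24-nt monomer against a
200-nt one reaches 50--65% identity by selection alone, and gap weaving
can push match counts far beyond the binomial level without raising the
score.  Classification edges are therefore gated
(`similarity_is_credible()`): a hit is accepted when its alignment score
clears the chance (Gumbel) regime outright (score >= 15; chance scores
stay near 8--10 under this scoring for any monomer lengths), or when the
alignment is essentially colinear (gap fraction <= 2%) and its match count
is unachievable by chance, measured as a binomial E-value over all
placements of the shorter monomer (threshold 5e-4).  The E-value draws as
many Bernoulli(0.25) trials as the alignment has columns -- the doubled
subject lets windows exceed the monomer length -- floored at the full
monomer so window trimming cannot help.  The practical effect matches what
alignment-based maskers achieve with score thresholds: long monomers may
link at 50--60% identity, very short monomers only at high identity.

# Similarity tiers and groups

Within a species, monomers at >= 95% similarity are the same sequence
variant, >= 80% variants of one satDNA, and >= 50% members of one
superfamily; across species, interspecific links at >= 50% define groups.
Components are single-linkage (connected components of the thresholded
homology graph), so the tiers nest by construction.  Superfamilies with a
single member are reported blank, following the field's tables.  Groups
are numbered by decreasing member count with deterministic tie-breaks
(wider species span, then smallest member name); group numbers are labels,
so analyses should compare memberships, not indices.  A group spanning at
least four species is flagged `is_main`; two-species components are still
reported as groups, with the flag distinguishing the two notions.

# Kimura 2-parameter divergence

`kimura2p()` implements `K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` with
`P`/`Q` the transition/transversion proportions per ungapped aligned
column (the calcDivergenceFromAlign convention: gap columns are excluded
from the denominators).  Saturated inputs (`1 - 2P - Q <= 0` or
`1 - 2Q <= 0`) are reported as undefined (`NA`), counted, and excluded
from means -- never coerced to a large number.  `N` bases are neutral
everywhere: no match, no mismatch, no P/Q event.

# Abundance from read masking

`mask_reads()` emulates a cross_match-style RepeatMasker run at desk
scale.  Each mate is aligned locally against every family consensus, on
both strands; the consensus is tandem-extended so that a full read plus
one unit fits (at least two copies).  Plain doubling, the usual
circularity device, fails for monomers shorter than half a read: a 30-nt
monomer doubled gives a 60-nt subject, below the 50%-of-read acceptance
span, which would make short-RUL families unquantifiable; tandem extension
generalizes the same idea.  The best-scoring family wins the read
exclusively, with ties resolved toward the more abundant-ranked family,
and a hit is accepted when it spans at least half the read and its K2P
divergence is at most 20% (both configurable).  An exact 11-mer prefilter
skips reads sharing no word with any family before alignment; within the
20% cutoff a read shares many exact 11-mers with its family, so the
prefilter is a pure optimization.

Genomic abundance is reported as masked nucleotides over analyzed
nucleotides (a dimensionless genome fraction); the literal
masked-reads-per-analyzed-nucleotide quotient is emitted alongside for
traceability with older reports.  Accepted hits are binned by K2P percent
into 1% bins over 0--20% to form the divergence landscape; binning
conserves masked nucleotides for retained hits.

# Tandem Structure Index

For paired-end data, the TSI of a family is the fraction of its mapped
mates whose partner maps to the same family.  Reads inside arrays much
longer than the insert size almost always have their mate in the same
array (TSI near 1, with edge pairs the only loss), while families present
as scattered short arrays leave the partner in unique sequence (TSI near
0).  The denominator is the family's own mapped mates, which keeps the
index in [0, 1] per family and independent of genome size; a family with
no mapped mates has an undefined TSI (`NA`), not 0.

# Single-copy-gene normalization and the clustermap

Sequencing depth differs between libraries, so masked counts are
normalized by a per-species factor: the mean over reference single-copy
genes of `mapped_reads x read_length / (gene_length x analyzed_reads)`,
i.e. the per-read single-copy depth.  The matrix entry for species `s`
and family `f` is `log10((masked_reads[s,f]/analyzed_reads[s])/factor[s]
+ 1)`: a family absent from a species is exactly 0, doubling a species'
depth leaves its row unchanged up to sampling error, and identical
species yield identical rows.  `clustermap_matrix()` clusters rows and
columns by UPGMA on Euclidean distances, with rows pre-sorted by label so
degenerate inputs order stably; dendrograms are emitted as Newick text.

# Monomer substructure

`self_dotplot()` scores every off-main diagonal by fuzzy k-word support
(default k = 8 with up to 2 mismatches, so words still match at ~25%
divergence where exact words vanish) and by position-wise identity along
the diagonal.  `detect_period()` ranks diagonals with at least 3
supporting words, identity >= 0.55 (random sequence sits near 0.25) and
overlap >= 10, preferring smaller offsets among ties so the fundamental
period outranks its harmonics.

`decompose_subunits()` treats an array-like monomer as circular: analysis
starts from the lexicographically minimal rotation, which makes the
output exactly invariant to the input's phase.  The monomer is tiled into
repeat units of the given period (boundaries refined by up to 3 nt
against the first repeat), and the subunit structure within the repeat is
inferred from the self-dotplot lags of the whole array -- lags are
phase-independent, unlike any fixed cutting frame.  A candidate lag
qualifies either by fuzzy-word support that recurs across repeats (well
above the chance level, scaling with the repeat count) or by diagonal
identity of at least 0.40 over at least 100 positions (an old duplication
whose fixed mismatch pattern happens to lack any dense word window still
elevates the whole diagonal far above the 0.25 random baseline).  A
qualifying lag is then validated by the duplication homology it implies:
over all rotations of the repeat consensus, consecutive subunit pieces
must reach 45% positional identity, with a small-window penalty so a
short chance window cannot outscore a long genuine duplication.  A lag that nearly divides the period yields a
uniform split (60 = 3 x 20); otherwise two unequal subunits (40 = 29 +
11).  Subunits are labeled alpha, beta, ... cyclically; intra-repeat
divergence is the all-pairs K2P between differently-labeled subunits
within a repeat, inter-repeat divergence the all-pairs K2P between
like-labeled subunits across repeats (the "aligned two by two" pairing of
the field's figures admits several readings; all-pairs means are used and
recorded in the output).  When no subunit structure is detectable each
repeat is its own subunit and the two means coincide.  Under duplication
divergence `d1` followed by amplification divergence `d2 < d1`, the
inter-repeat mean stays below the intra-repeat mean -- the signature that
the duplication predates array homogenization.

`annotate_hor()` segments long monomers into maximal tandem runs by a
greedy left-to-right scan: at each position the shortest unit length
whose next copy stays within 45% divergence (ties to the best identity
within 0.08, so a 2x or 3x multiple of the true unit never wins on noise)
starts a run, extended while consecutive units stay within the cutoff; a
run may only start where no position within the next unit offers a
strictly better first comparison, which stops a misphased start from
swallowing intervening sequence.  Runs are then extended unit-by-unit
against the run consensus -- a consensus comparison tolerates twice the
divergence a consecutive-unit comparison does -- recovering units eroded
by the seeding pass.  Two-unit runs in otherwise unstructured sequence
are accepted only at >= 75% identity.  Length bookkeeping is exact:
tandem segments plus intervening stretches tile the monomer.

# The synthetic satellitome generator

`simulate_library_evolution()` implements the library hypothesis at desk
scale.  Ancestral families are built by duplication-divergence cycles
(`evolve_duplication_divergence()`, which records every intermediate for
substructure validation) from random units of 20--60 nt; candidate
families too similar to an existing one are redrawn, since distinct
library members are by definition unrelated and a coincidental similarity
between two short random ancestors would propagate to every descendant
pair.  Along each branch of the species tree, sequences accumulate
substitutions at `subst_rate` per site per branch-length unit
(transitions twice as likely as transversions) with indels at one tenth
the substitution rate -- substitutions dominate so orthologs keep their
unit length, as real catalogs show; per-family abundances follow a
log-normal amplification walk with variance proportional to branch length
(differential amplification), and a family may be silenced to
scattered-only remnants.  At each leaf, families whose walked abundance
fell below the detectability floor (the low end of `abundance_range`) are
absent from the catalog -- tandem-repeat discovery only sees sufficiently
abundant families -- while remaining recorded in the truth; every catalog
keeps at least its three most abundant families, matching the 3--13
families per species seen in real crocodylian satellitomes.

`build_genome_and_reads()` assembles, per species, an i.i.d. random
background holding clustered tandem arrays (each copy independently
diverged at the family's array divergence), scattered short arrays, and
three planted single-copy genes; paired-end reads are drawn uniformly
with normal fragment lengths (default 350 +/- 30 nt, the typical
paired-end fragment range) and Bernoulli substitution errors.  The
realized composition is recorded exactly, so family fractions, gene and
background fractions sum to one.  Identical configurations (including the
seed) reproduce byte-identical genomes and read sets.

Defaults are sized for desk runs: five species on an ultrametric tree
with one long outgroup branch (tip depths 11--90 in Myr-like units), 6
ancestral families, genomic abundances drawn log-uniformly over
0.02--2.2%, 2 Mb genomes and 2 x 50,000 reads of 150 nt (a scaled-down
stand-in for the millions of reads of a real library).  The generator
emulates the statistical structure of real inputs -- family counts, unit
lengths, abundance ranges, clustered plus scattered organization -- but
not TE landscapes, GC heterogeneity, sequencing-quality profiles or
assembly artifacts; passing tests on simulated data therefore validate
the estimators' correctness and calibration, not robustness to every
artifact of real libraries.

# Numerical choices and degenerate inputs

* Ties everywhere are broken deterministically: base order A < C < G < T
  in consensus voting, abundance rank in read assignment, smaller offset
  among equal-support periods, label order in degenerate clustermaps.
* Saturated divergences are `NA` and excluded from means, with counts
  carried along.
* A read set with no hits yields zero abundances and an all-zero
  landscape; a family with no mapped mates has `NA` TSI; an empty summary
  table yields zero/undefined aggregates.
* All randomness flows through R's RNG; generator entry points take a
  seed and restore the caller's RNG state (`with_seed()`).

# Problem sizes used in the packaged checks

The packaged tests and the acceptance script run the full machinery at
reduced scale chosen to keep a complete run on one CPU within minutes
while leaving comfortable statistical margins: classification recovery
uses 20 replicate five-taxon simulations (6 ancestral families each);
abundance recovery uses one species, 2 Mb and 50,000 pairs; the TSI sweep
uses 150-nt monomers in 400 kb genomes so that pure arrays are much
longer than the insert; the duplication-divergence sign test uses 100
seeded monomers of 8 repeats.  The clustermap check uses 30 families and
5,000 pairs per species with consensus substitution slow relative to
within-array heterogeneity -- the regime of concerted evolution, where
reads of every species mask onto a shared column basis and family
presence/absence plus the amplification walk carry the phylogenetic
signal.

# Known limitations

* The alignment scoring is a declared default, not a reconstruction of
  any specific cross_match parameter set; similarity percentages are
  comparable within this package, not across tools.
* Low-identity (50--60%) superfamily links are statistically marginal for
  monomers under ~50 nt and are deliberately suppressed by the
  credibility gate unless colinear and substitution-only.
* The masking abundance estimator loses read ends at array boundaries
  (span rule); with arrays much longer than reads the bias is well under
  one percent of the estimate, but heavily fragmented short arrays are
  underestimated.
* TSI compares organization between families of similar monomer length;
  for monomers much longer than the insert size, concordant pairs arise
  within a single copy, so a scattered long monomer can still show a high
  TSI (the field reports the same caveat).
* UPGMA on the normalized abundance matrix recovers the species topology
  when enough families carry signal (the packaged scenario uses 30); with
  few families or extreme amplification noise the dendrogram is a
  description of abundance similarity, not a phylogeny estimate.
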