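---
title: "Methods: graph-based repeat landscapes from low-coverage reads"
author: "repeatscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based repeat landscapes from low-coverage reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`repeatscape` characterizes the repetitive fraction of a plant genome from
low-coverage (well below 1x) paired-end reads, without a reference assembly.
The guiding observation is that at, say, 0.5x coverage a single-copy locus is
sampled by at most a handful of overlapping reads, while a repeat family
occupying even 0.1% of the genome contributes hundreds of mutually similar
reads. Mutual read similarity therefore identifies repeat families directly,
and the share of reads in a family estimates the share of the genome the
family occupies (its *genome proportion*, GP).

The package covers the full analysis cycle: read preprocessing and combined
multi-species datasets, similarity-graph clustering with per-cluster contig
assembly, library-based annotation and superfamily summary tables, tandem
satellite monomer and deletion-variant detection, shared/species-specific
classification across genomes, CenH3 ChIP-seq enrichment over clusters, and
bootstrapped neighbor-joining trees of reverse-transcriptase (RT) domains.
A synthetic-data generator with complete ground truth closes the loop: every
stage is validated against planted structure.

# The similarity graph and its partition

Candidate read pairs are found by shared canonical k-mers (default k = 17,
both strands). Each candidate is verified by an ungapped comparison at the
seed offset; the verification is ungapped because the sources of variation
this pipeline models — divergence among copies of a family and sequencing
errors on short-read platforms at these settings — are substitution-dominated,
so the k-mer seed fixes the correct alignment frame. An edge requires

* identity of at least `min_identity` (default 90%) over the overlapping
  region, and
* an overlap covering at least `min_overlap_fraction` (default 0.55) of the
  shorter read.

These two thresholds are the canonical defaults of graph-based read
clustering for repeat discovery. Both are configuration knobs.

For efficiency, each read alignment-verifies only its `max_candidates_per_read`
(default 30) candidates with the most shared seeds. This sparsification
cannot split a genuine family — high-identity neighbors have the most shared
k-mers — and only prunes redundant edges inside dense clusters.

The default partition is connected components, which is exactly checkable
against a union-find oracle; Louvain community detection is available for
graphs in which distinct families share mobile domains. Clusters are ranked
by read count (ties: lexicographically smallest member id) and labeled
`CL1, CL2, ...`. GP of a cluster is `100 * n_reads / total reads analyzed`.
A cluster is *detailed* when it holds at least two reads and at least
`detail_threshold` of the analyzed reads; the default 0.00005 is the 0.005%
rule used at multi-million-read scale. At desk scale (thousands of reads)
an absolute analogue is more meaningful, and the comparative checks in this
package use 0.004 (0.4%, i.e. 20 of 5000 reads) for the same purpose: below
that size, chance co-placement of overlapping single-copy reads produces
legitimate but uninteresting mini-clusters.

Mate information is not used to merge clusters; mate rescue is off by
default and paired-end reads simply enter as two reads.

**A coverage caveat.** Chaining reads across a template requires consecutive
read starts within `read_length * (1 - min_overlap_fraction)` of each other.
At per-family depth below roughly 10x, coverage gaps split families into
several clusters. This is inherent to overlap thresholds, not a defect; the
validation designs in this package keep per-family depth at 15x or higher.

# Contig assembly

Within a cluster, reads are laid out greedily: the highest-degree read seeds
coordinate zero, neighbors are placed breadth-first by their verified seed
offsets (layout accepts overlaps down to 30% of the shorter read, since
membership is already decided), and a per-column majority vote yields the
consensus. Uncovered gaps split the consensus into multiple contigs; contig
strand follows the seed read. For tandem arrays, the layout can extend past
one monomer; the satellite detector recovers the true period downstream.

# Annotation

Contigs are compared to a user-supplied repeat library (FASTA; names follow
the RepeatMasker-style `id#Superfamily` convention) by gapped local
alignment (match 1, mismatch -1, gap open 5, extend 2, both strands). A hit
passes only with identity strictly above 70% and *query* coverage strictly
above 50%. Coverage is interpreted as query coverage — the fraction of the
contig (or read) aligned — because that is the reading under which short
queries against long references behave sensibly; the alternative (subject
coverage) would discard every short-read hit against a full-length element.
The cluster's superfamily is the plurality over contig-assigned reads, ties
conservatively `Unclassified`; clusters without a passing hit but with
detectable tandem structure are `Satellite`. Clusters hitting an organelle
reference under the same screen are eliminated before GP totals.

The superfamily summary derives a retroelement subtotal (Ty1/Copia +
Ty3/Gypsy + Unclassified LTR + LINE/SINE), a DNA-transposon subtotal (hAT,
Mutator, RC/Helitron, En-Spm, PIF-Harbinger, Tc1-Mariner, Other), and a
grand total additionally including rDNA, Satellite, and Unclassified, with
display rounding half away from zero to two decimals.

Per-read annotation against a reference library (used to compare two
reference genomes' annotations) uses the same screen with a 13-mer seed; the
shorter seed tolerates the up-to-30% divergence the 70% identity threshold
admits.

Protein-domain evidence (profile searches in the original workflow) is
approximated by six-frame translated comparison to user-supplied reference
peptides; no external profile databases are bundled or required.

# Satellite monomers and deletion variants

Candidate periods come from the recurrence-distance histogram of repeated
12-mers within a contig (distances between successive occurrences of the
same 12-mer), supplemented by a direct scan of all periods below 24 bp so
that short telomere-like units (7 bp) are never missed. Candidates are
evaluated in ascending order by chopping the contig into consecutive
windows of the candidate length and calling a majority consensus; a partial
final window of at least 20 bp counts toward coverage, so arrays of at
least 1.5 units are detectable — assembled satellite contigs are often only
slightly longer than one monomer. The smallest period whose consensus
explains at least 80% of the contig at window identity of at least 80%
wins. Testing candidates smallest-first
makes the reported period minimal (never a multiple of the true unit); the
80%/80% rule replaces the score-based heuristics of classical tandem
finders with an explicitly testable criterion. The consensus is reported in
canonical form — the lexicographically minimal rotation of the
lexicographically smaller strand — so that repeated runs, rotations, and
strand flips of the same array always produce the identical monomer string.

**Deletion variants.** Reads of a satellite family are anchored on the
circular consensus by exact 12-mers. A read wholly inside full-length
monomers shows one consistent offset `(consensus position - read position)
mod period`; a read spanning the junction of an internally deleted monomer
splits into two offset runs whose circular difference equals the deleted
length. A variant is reported when at least `min_support` (default 5,
excluding singleton artifacts) reads show the same deletion length with the
junction at least `flank` (default 20) bases from both read ends.

The *family fraction* converts the junction-read rate into a copy fraction.
A variant copy exposes `L - 2*flank + 1` read start positions that reveal
its junction (L = read length), while each monomer copy attracts reads in
proportion to the period P. With S supporting reads among R family reads,

```
family_fraction = 100 * (S / R) * P / (L - 2*flank + 1)
```

is an (asymptotically) unbiased estimator of the percentage of monomer
copies carrying the deletion. The raw percentage of supporting reads
(`read_share`) is also reported: that quantity, computed on the ChIP-side
reads of a centromeric satellite, is the "percentage of the family in the
ChIPed DNA" figure of merit, and `chip_satellite_variant_share()` reports
exactly that read-level share for ChIP versus genomic read sets.

# ChIP-seq enrichment without a reference genome

ChIP reads are matched against the genomic reads of the clusters under an
explicit contract: a hit is an edit alignment with at most 3 edited
positions, of which at most 2 are gaps — the matching rule of short-read
pattern matchers used for reference-free centromere-repeat identification. Each ChIP read is assigned to the
single cluster containing its best-matching genomic read; distance ties
across clusters go to the larger (lower-ranked) cluster. Candidates are
prefiltered by shared 17-mers with a minimum seed support of 20, which by
the pigeonhole principle cannot reject any 100 bp read within 3 edits
(such a pair shares at least 33 17-mers) while skipping the phase-shifted
pairings that dominate tandem repeats. The default assumes reads of
approximately 100 bp; for much shorter reads the support floor must be
lowered accordingly.

Enrichment per cluster is the ChIP read fraction over the input (mock) read
fraction, normalized by the pooled fold of the negative-control clusters
(their summed ChIP fraction over their summed input fraction). The pooled
control — an input-weighted mean of control folds — avoids the upward skew
of averaging per-cluster ratios at small counts. Binomial standard errors
of all four fractions are propagated by the delta method. Only a fraction
of family reads find a within-contract partner at low genomic depth
(phase-matched partners must exist); this thinning applies equally to ChIP
and input reads of a family and cancels in the fold's expectation, at the
price of wider confidence intervals, which the reported SE reflects.

# Comparative clustering

Combined datasets carry a species code as a `CODE|` read-id prefix.
Clustering runs on the pooled reads exactly as for one species; per-species
GP normalizes by that species' read total, so a species' GP is invariant to
the other species' sequencing depth. A species is called present in a
cluster with at least `max(5 reads, 0.0005% of its reads)` — a two-part
floor that suppresses cross-contamination and mis-assignment artifacts
(published comparative tables report clusters at proportions as low as
0.0001%, which is indistinguishable from noise without such a floor). The
presence pattern (e.g. `A+B`, `B`) keys the shared/specific summary.

Flow-cytometry genome sizes follow the fluorescence-ratio formula
`size_object = (meanG1_object / meanG1_standard) * size_standard`; the
genome-size ratio is rounded half-up to one decimal. Survey coverage is
`n_reads * read_length / (2 * genome_size)`: the factor 2 in the
denominator is the convention under which published low-coverage plant
surveys' printed read counts, genome sizes, and coverages (1.84x, 2.76x)
are mutually consistent, and it is documented here precisely because it is
not the textbook definition.

# RT-domain phylogeny

For each LTR family, contigs are translated in six frames and locally
aligned (BLOSUM62, gap open 10, extend 4) to user-supplied reference RT
peptides; the top-scoring contig represents the family and the aligned
peptide segment is its RT peptide. Families scoring below `min_score`
(default 50) carry no RT signal and are dropped. The multiple alignment is
center-star with BLOSUM62 global pairwise alignments — deterministic and
adequate for the conserved RT core; a profile aligner would be preferable
for deeply diverged sets and this is a stated approximation. Distances are
p-distances with pairwise gap deletion, matching the default peptide-NJ
behavior of standard tree software and keeping the estimator
oracle-checkable.

Neighbor joining is the classical Saitou–Nei algorithm with the standard
branch-length formulas, negative lengths clamped to zero, and a fixed tie
rule (smallest pair of subtree labels) so the tree is invariant to input
order. On additive matrices the generating topology and exact branch
lengths are recovered; the test suite verifies this for every 4- and
5-taxon topology and cross-checks against brute-force least squares over
all topologies. Bootstrap support resamples alignment columns (default 100
replicates, seeded) and labels each internal edge with the percentage of
replicates containing its bipartition. Clade assignment of a family is the
clade of its nearest reference leaf by patristic distance.

# The synthetic-data generator

Genomes are built from an i.i.d. uniform background (single-copy sequence
must not cluster) with planted families:

* dispersed families (LTR-like, DNA transposons, rDNA) as independently
  substituted copies of a random or supplied template;
* satellites as one contiguous head-to-tail array, with internally deleted
  variant monomers (one fixed contiguous deletion) interspersed at a
  controlled fraction of copies.

Copy counts are exact bookkeeping (`round(target_gp * genome_size /
unit_length)` copies), so realized GP is within rounding of target, and the
truth table (0-based, half-open coordinates) is exact. Copies carry
substitutions only — no indels — which keeps truth GP exact and leaves indel
handling to the ChIP matcher, where it is exercised deliberately. Reads are
uniform over both strands with Gaussian insert sizes, constant base quality,
and substitution-only errors; a read is truth-labeled to a family when at
least half of its bases overlap the family's coordinates. ChIP sets raise
the fragment start density over the target family's coordinates by the
enrichment fold; the matched input set is uniform.

Passing tests on this generator demonstrate correctness of the algorithms
under substitution-dominated divergence, uniform sampling, and clean
quality profiles. They do not demonstrate robustness to indel-rich
divergence, PCR duplicates, platform-specific error profiles, nested or
truncated insertions, or library-preparation biases — real-data behavior on
those axes is out of scope by design.

# Validation designs and problem sizes

The package's end-to-end checks use fixed study designs, chosen for
statistical power at desk scale:

* *Satellite detection*: random 153 bp monomer, 60 copies, 2% per-copy
  divergence, 20 seeds; the 102 bp deletion variant (51 bp removed) on its
  own array under the same conditions.
* *Cluster recovery*: 1 Mb genome, 8 dispersed families (random templates
  are pairwise ~25% identical) at GP 6–8%, 2% divergence, 5000 x 100 bp
  reads (0.5x); every family must land in one detailed cluster with GP
  within ±20% relative of truth.
* *Comparative classification*: two 120 kb genomes, two shared and one
  specific family each at GP 7–8%, 2 x 2500 pooled reads, detail threshold
  0.4%.
* *ChIP recovery*: 150 kb genome, a 4% centromeric satellite plus two
  neutral families (negative controls), folds {1, 2, 5, 10} x 5 seeds,
  1400 ChIP/input reads per run; the normalized fold must fall within 3
  standard errors of truth in at least 95% of runs.
* *Variant quantification*: 60 kb genome, half satellite, 1% variant copies
  (two copies of 196), 10000 reads, 20 seeds; the mean estimated family
  fraction must lie within 3 standard errors (across seeds) of the planted
  fraction.

These sizes are the package's chosen trade-off between statistical
resolution and a test suite that runs comfortably on a laptop; they are
stated here so that anyone re-deriving the numbers knows the design.

# Numerical conventions

* Table rounding is half away from zero (commercial rounding), matching how
  published tables print; R's default banker's rounding would differ at
  exact halves.
* All stochastic steps take explicit integer seeds and restore the caller's
  RNG state; fixed seed implies byte-identical FASTQ and table output.
* Cluster rank ties break on the lexicographically smallest member read id;
  NJ ties on the smallest label pair; ChIP assignment ties on the larger
  cluster.
* Negative NJ branch lengths are clamped to zero after each agglomeration.

# Pipeline configuration

`run_pipeline(config, out_dir)` orchestrates the stages from one
configuration (R list or YAML): `simulate` (species, families, reads, chip)
or `fastq` inputs; `preprocess` (mean-quality floor, default Phred 20 — a
conventional stand-in, since "low quality" is rarely defined precisely);
`cluster`, `annotate` (library and organelle FASTA), `compare`, `chip`,
`phylo` settings; a global `seed`; and a `stages` subset. Outputs are plain
TSV tables with a `#`-prefixed header line, FASTA contigs, Newick trees, a
run log, and a JSON manifest recording versions, seeds, thresholds, and
input checksums. A thin command-line wrapper is installed at
`inst/scripts/repeatscape.R`.

# Known limitations

* Edge verification is ungapped; families whose copies differ by frequent
  indels would need the gapped ChIP-style matcher at the graph stage.
* The center-star RT alignment and pairwise peptide similarity approximate
  profile-based domain searches; clade assignments for families far from
  every reference should be treated cautiously.
* Below ~10x per-family read depth, overlap chaining splits families
  (see the coverage caveat above); GP totals are unaffected, but
  per-cluster tables then list fragments of one family.
* The seeded ChIP candidate filter assumes reads of roughly 100 bp.
* `satellite_table` location columns require external (e.g. cytological)
  metadata; the package computes none.
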