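---
title: "Dissecting a tandem-duplicated CYP2D locus: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a tandem-duplicated CYP2D locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The equine CYP2D50 gene — the horse orthologue of human CYP2D6, the enzyme
behind a quarter of human drug metabolism — is annotated in the EquCab3.0
reference as a single 9-exon gene with an unusually long intron 7. Closer
inspection of that annotation reveals it to be a fusion: two highly similar
tandem genes (here CYP2D50-1 and CYP2D50-2, roughly 94% identical) separated
by an intergenic spacer, with the annotated exons 1–7 belonging to the first
copy and exons 8–9 to the second. The situation mirrors the human CYP2D6 /
CYP2D7 locus, including its pathology: gene conversion between the paralogs
produces hybrid alleles, and the near-identity of the copies confounds
PCR-based genotyping, variant interpretation and expression assays.

`paralocus` implements the complete computational workflow for this kind of
locus: detecting the internal duplication and proposing the two-gene
structure; identity accounting at exon and gene level; calling variants from
diploid Sanger-style consensus sequences (IUPAC ambiguity codes at
heterozygous positions) with codon-level effect annotation; assigning
sequenced transcripts to their source paralog by requiring exact replication
of the transcript's polymorphism pattern; detecting conversion tracts over
paralog-diagnostic sites and localizing the breakpoint interval; classifying
substitutions from externally supplied SIFT/PROVEAN scores; and quantifying
relative expression by the relative standard curve qPCR method. Because the
real cohort sequences are not distributable, a seeded synthetic-data
generator produces every input with known truth tables.

## Coordinate conventions

All coordinates are gene-local and 1-based: g.1 is the A of the ATG start
codon (the "from ATG" convention), and c. positions count along the spliced
CDS from 1. The two systems are connected by the splice map
(`splice_cds()`, `g_to_c()`, `c_to_g()`); the two paralogs' g. systems are
connected by a global alignment (`build_coordinate_map()`), never by raw
position equality — the donor paralog runs 59 bp ahead of the acceptor
downstream of its planted insertions, so e.g. donor g.3864 corresponds to
acceptor g.3805. All loci are modeled on the coding strand.

## Alignment scoring

Every inter-paralog comparison uses one fixed global scheme: match +1,
mismatch −1, gap open −4, gap extend −1 (a length-L gap costs 4 + L),
delegated to `Biostrings::pairwiseAlignment`. The scheme was chosen so that
the 3-nt length difference in exon 4 between the focal paralogs (161 vs
164 bp) aligns as one 3-bp indel — parsimony of indel events — and it is
validated in the test suite against an independent affine-gap
Needleman–Wunsch oracle. Two identity conventions coexist deliberately:
per-exon identities are *truncated* to integers (`floor(100·matches/columns)`;
one mismatch over 179 columns reads 99, two over 142 read 98), while
gene-level identities are rounded half-up to one decimal. Gap columns count
in the denominator.

## The synthetic family generator

`simulate_family()` emulates a nine-member paralogous family. The requested
pairwise identity matrix is converted to substitution-count targets, a
neighbor-joining guide tree is fitted to them (`ape::nj` +
`phangorn::nnls.tree`), branch lengths are rounded to integer substitution
counts, and sequences are evolved down the tree with every substituted
position used on at most one branch. That last constraint makes realized
pairwise divergence *exactly* equal to tree path length, so realized
identities track targets to well within ±1 percentage point; a matrix too
far from tree-additivity, or too close to 100% to carry the focal
landmarks, is rejected as infeasible. The default identity targets are
derived from a fixed guide tree whose cophenetic distances put every pair
in the 78–95% band typical of this gene cluster, with the focal pair at
93.7%.

Biological sanity constraints: the ancestor is uniform-random at 50% GC;
exonic substitutions never create stop codons; GT/AG splice dinucleotides,
the start and stop codons are immutable; wild-type CDSs therefore always
translate cleanly. Indels are planted as explicit events with recorded
coordinates rather than emergent mutations, which keeps truth tables
deterministic.

The focal pair carries fixed landmarks: the nine exon lengths
(189/172/153/161/177/142/188/142/179; CDS 1503 nt), 31 diagnostic
differences from g.3688 to g.4240 (two exonic in exon 8, one in exon 9),
one acceptor-retained diagnostic site at g.3625 bounding the conversion
tract from below, a 3-bp in-frame exon-4 insertion plus a 56-bp intron-1
insertion in the donor (the +59 offset), and a set of fixed codons that
make the canonical cohort substitutions produce their published amino-acid
changes (codon 31 = CGC so G>A at c.92 reads R31H; codon 491 = TCT so T>G
at c.1471 reads S491A; etc.). The retained site at g.3625 is a
*reconstruction*: its existence is implied by the published breakpoint
interval, not listed in any table. Intron lengths are free parameters of
the model — the real locus has multi-kilobase introns — and are chosen at
desk scale so that every cited g. position lands in its published exon or
intron; the vignette's scaled sizes (gene ≈ 4.3 kb, fused locus ≈ 21.6 kb
with a 13 kb spacer) keep the full pipeline in seconds while preserving
every coordinate relationship the analysis depends on.

What the generator does *not* emulate: chromatogram noise and base-calling
error (consensus sequences are exact), PCR allele dropout, copy-number
variation, and population structure. Passing tests therefore demonstrate
the correctness of the algorithms under clean diploid data, not robustness
to trace-quality artifacts.

## Cohort simulation and variant calling

`simulate_cohort()` plants substitutions at exact allele counts (default
cohort 72 diploid samples, 144 alleles — the denominator under which the
published frequencies are all integer allele counts: 0.69% = 1/144,
7.64% = 11/144, 42.36% = 61/144), or binomially if requested. Hybrid
haplotypes are tail conversions: every diagnostic site from g.3688 onward
takes the donor's *observed* base — which at the confounded site g.3805
equals the acceptor base, because the donor population is fixed for T>C at
its corresponding position g.3864. Variants that would fall within one
codon's reach of an already planted event go to different samples, since
co-located variants on opposite chromosomes are unphaseable in a diploid
consensus. Deletions are recorded as events rather than encoded in the
(equal-length) consensus string, mirroring how indel calls ride alongside a
Sanger consensus.

`call_variants()` decodes IUPAC codes (code containing the reference base →
HET; plain non-reference base → MUT), merges same-codon adjacent
substitutions of equal zygosity into one MNV — required to report a fully
substituted codon as a single event such as AAG>GGA (K248G) rather than
three SNVs — and annotates effects by mutating the codon in c. space
(missense as `<refAA><codon><altAA>` with codon = ⌈c/3⌉; deletions of
length ≢ 0 mod 3 as `<codon> fs`). Frequencies are
100·(HET + 2·MUT)/(2·genotyped), rounded half-up to two decimals; missing
genotypes shrink the denominator rather than being imputed.

## Transcript assignment

A transcript is assigned to a candidate gene only when its polymorphism
pattern is replicated *exactly* — genotype-level equality of unordered
allele pairs at every assayed position, not allele containment — because
the discriminating evidence against a fused annotation is typically a
HET-versus-HOM disagreement, not a missing allele. Candidates without a
call at an assayed position default to homozygous for their own reference
base (published patterns list only polymorphic positions). Exactly one
consistent candidate → assigned; several → ambiguous; none → unassigned.
Expressed-locus inference adds the indirect argument: a locus that a used
assay could have co-amplified, but to which no transcript was ever
assigned, is reported `not_detected`, distinct from `untested`.

## Hybrid detection

Diagnostic sites are the substitution columns of the paralog alignment. A
site whose donor position carries a known donor-population polymorphism is
masked as uninformative (the g.3805/g.3864 case) and never influences
tract boundaries. Per allele, a maximal run of ≥ `min_run` consecutive
donor-state sites is a conversion tract; `min_run = 2` because an isolated
converted site is indistinguishable from a point mutation (the S491A
allele is exactly that: a paralog-matching SNP treated as an ordinary
polymorphism). Only tail tracts (reaching the last informative site) are
labeled hybrid alleles; interior tracts are reported as conversion
segments. The switching interval is open: between the last acceptor-state
site and the first converted site, printed as "between g.X and
g.(first−1)" — on the synthetic replica, between g.3625 and g.3687 with
first converted site g.3688.

Diploid scoring makes one phasing assumption, stated in reports: an
uninterrupted run of heterozygous diagnostic sites is attributed to a
single hybrid haplotype rather than two reciprocal recombinants — the only
reading available to a Sanger-based study. A run mixing heterozygous and
homozygous-donor sites (e.g. a hybrid carrier whose other chromosome
carries the S491A point allele) is flagged complex and counted
conservatively as one hybrid allele. Cohort replicas default to
all-heterozygous carriers, since nothing in the published frequency forces
homozygous hybrids.

## Effect thresholds and expression

SIFT calls a substitution deleterious at scores ≤ 0.05. The boundary is
*inclusive* by design: the methods convention says "below 0.05", but the
published classification flags substitutions scoring exactly 0.05, and the
inclusive rule is the only one that reproduces the flag partition row for
row. PROVEAN is strict at < −2.5 (−2.428 and −2.281 are not flagged).
"Clearly deleterious" means deleterious under both tools. Scores are
always inputs; the prediction tools themselves are out of scope.

qPCR quantification follows the relative standard curve method: per-assay
least-squares line Ct = intercept + slope·log10(quantity), efficiency
10^(−1/slope) − 1, per-sample interpolation, actin normalization, and a
fold change defined as the ratio of group means of normalized quantities
(ratio of means, not mean of ratios — stable at n = 4). The simulator
constructs sample quantities so the planted ratio is recovered exactly at
zero noise, giving a machine-precision end-to-end check; with Ct noise of
sd 0.2 the recovered ratio is unbiased to within a few percent over
replicate simulations. Welch's t test is implemented from the closed form
(Welch–Satterthwaite degrees of freedom) and cross-checked against
`stats::t.test` to 1e-10 in the test suite; two zero-variance equal-mean
groups return p = 1 by convention.

## Problem sizes and determinism

Every generator is a pure function of (configuration, seed); the pipeline
re-run under the same seed produces byte-identical reports. The default
analysis scale — nine 4.3 kb genes, a 21.6 kb fused locus, 72 diploid
samples, 100-seed property sweeps — was chosen so the complete test suite
and the analysis scripts run in minutes on a single core while every
published coordinate relationship and count is preserved.

## Known limitations

* Only forward-orientation tandem duplications are sought; inverted
  repeats and genome-scale repeat masking are out of scope.
* No CNV calling: whole-gene deletion or multiplication alleles, the other
  classic CYP2D6-style structural events, are explicitly future work.
* Amplicon-mixture deconvolution (co-amplifying paralogs in one PCR and
  cloning to separate them) is not modeled; transcripts are assumed to be
  single-source consensus sequences.
* The one published frequency with an anomalous denominator (an MNV at
  0.72%, consistent with 1/139 rather than 1/144) is not modeled; the
  synthetic cohort plants it at 1/144.
* Real per-horse expression values are not published; the expression stage
  is validated by planted-ratio recovery, and the significance call only
  qualitatively.
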