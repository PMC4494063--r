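---
title: "Methods: comparative analysis of nucleomorph genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of nucleomorph genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

## The problem

Nucleomorphs are the relict nuclei of algal endosymbionts retained inside
the plastids of chlorarachniophytes and cryptophytes. Chlorarachniophyte
nucleomorph genomes are among the most reduced eukaryotic genomes known:
three chromosomes totalling roughly 370-610 kb, ~0.8-1.0 genes per kb,
AT-rich (~25-33% GC), with telomeric 7-mer tandem repeats, a near-identical
subtelomeric repeat (an rDNA operon plus *dnaK*) at all six chromosome
ends, and hundreds of *ultrasmall* spliceosomal introns of 18-23 nt with
canonical 5'-GT ... AG-3' boundaries. Comparative questions about such
genomes — which genes are shared, how gene order decays, whether intron
positions are conserved, and how exact segmental duplications inflate
genome size — require a reproducible pipeline rather than manual curation.
`nucmorph` implements that pipeline, together with a synthetic-genome
generator that plants a fully known ground truth so every stage can be
validated quantitatively.

## Gene calling with ultrasmall introns

A gene model is a chain of exons separated by intron candidates, where an
intron candidate is any 18-23 nt window reading `GT ... AG` in transcript
orientation. The caller performs dynamic programming over (position,
pending-partial-codon) states: from a start codon it reads codons, may
excise any candidate intron (including candidates that interrupt a codon —
stop codons may span splice junctions, so the 0-2 pending nucleotides of a
partially read codon are part of the DP state), and terminates at the first
in-frame stop. Among all parses from a given start the one maximizing the
spliced ORF length (in amino acids) is kept; exact ties are broken toward
fewer introns, making the caller fully deterministic. Overlapping candidate
models from both strands are resolved greedily by descending spliced
length, ties by leftmost position and then the plus strand.

Parameters (defaults in parentheses): minimum protein length (50 aa),
intron length bounds (18 and 23 nt), maximum introns per model (12;
nucleomorph genes average ~3), whether an ATG start is required (yes; a
stop-to-stop mode exists because reduced genomes are sometimes annotated
that way). The standard genetic code is used: chlorarachniophyte
nucleomorphs derive from a green alga, and nothing in the deposited
annotations suggests a deviant code.

This operationalizes what was originally expert curation in a genome
browser. Where a human would weigh homology evidence, the DP uses spliced
ORF length alone; the two agree whenever splicing is the only way to open a
long reading frame, which is exactly the situation the ultrasmall-intron
architecture creates.

## Repeat discovery

**Telomeres.** For each chromosome end the smallest period `p` (up to 10 bp)
is sought whose tandem occupies the terminus with at least 3 copies; among
qualifying periods the one whose tandem reaches deepest wins, with ties to
the smaller period, so a period-14 spelling of a 7-mer repeat is reported
as the 7-mer. Motifs are reported in the canonical (lexicographically
smallest) rotation of the G-rich-strand spelling, because the biological
convention (e.g. `[TCTAGGG]n`) is rotation-ambiguous. At the left end of
the forward strand the G-rich strand is the reverse strand, so the prefix
is reverse-complemented before canonicalization.

**Subtelomeric unit.** The longest sequence occurring exactly (allowing
reverse complement) within a search depth (50 kb, capped at half the
chromosome) of *every* chromosome end. Candidates are anchored by shared
100-mers in the first window, extended over runs, and verified by direct
substring search in every window — so a reported unit is always a true
common substring, while an adversarial interleaved arrangement could in
principle hide a longer one. Units shorter than 100 bp report length 0.

**Duplicated regions.** All maximal exactly identical pairs at or above a
minimum length (default 1,000 bp; the source genomes' duplicated regions
average ~2.9 kb but no threshold is stated anywhere, so this is exposed in
configuration). Discovery is by rolling-hash k-mer anchoring with maximal
extension, forward and reverse-complement, intra- and inter-chromosomal;
every reported pair is re-verified by character comparison during
extension, and anchor pairs lying on an already-extended diagonal are
skipped, making the scan near-linear. "Exactly identical" is taken
literally — no near-identity mode — matching how the duplications in these
genomes are described. A quadratic diagonal-scan oracle checks the
implementation on small genomes in the test suite.

## Homology and synteny

Protein similarity uses optimal local alignment (BLOSUM62, affine gaps
11/1, via `Biostrings::pairwiseAlignment`) with Karlin-Altschul e-values
`E = K m n e^{-lambda S}` (K = 0.041, lambda = 0.267, the gapped BLOSUM62
regime). All-vs-all search is seeded by shared amino-acid 5-mers; a pair is
aligned only when it shares at least 12 seeds. Besides speed, the seed
requirement guards against spurious matches between composition-biased
proteomes: AT-rich genomes encode amino-acid-biased proteins for which the
plain Karlin-Altschul e-value is optimistic, and genuine homologs at the
divergences relevant here share hundreds of exact 5-mers. Families are
single-linkage connected components over hits with e-value below 0.001
(the cutoff used for the original annotations), computed with `igraph`;
genes without qualifying edges become singletons.

Synteny blocks are chains of family-matched gene pairs, strictly monotonic
in both genomes — ascending in the first, ascending (same) or descending
(inverted) in the second — with at most 3 unmatched intervening genes on
either side, at least 4 homologous genes per block, and each gene in at
most one block per genome pair. Whole-block inversion is allowed because
documented inversions (e.g. of the rDNA operon) are part of these genomes'
history; a strict same-order mode is a flag away. Tandem same-family
neighbors are collapsed to a single anchor before chaining so duplicated
gene regions do not inflate blocks. Block *assignment* solves a packing
problem: greedy selection by descending chain size can strand genes on
adversarial orderings (take `1,5,2,6,3,7,4,8`, where one 5-chain blocks two
disjoint 4-chains), so chromosome-pair instances with few match points
(<= 20) are solved by exact chain-set packing (branch and bound over
enumerated chains) and larger instances greedily. One caveat observed with
any gap-tolerant chainer: a single gene of an inverted segment can be
absorbed into the surrounding collinear chain, so an inversion of k genes
may surface as an inverted block of k-1.

Syntenic ORFans — hypothetical proteins occupying the chromosomal slot of
an annotated gene in another genome — are detected by comparing each
ORFan's nearest family-matched flanks with the gene content between those
flanks' counterparts, including the split case of one gene corresponding
to two adjacent ORFans.

## Intron position conservation

Within each cross-genome family, member proteins are aligned by
deterministic center-star progressive alignment (center = maximal summed
pairwise score, ties by id; "once a gap, always a gap"). Each intron maps
to the alignment column of the protein residue containing (phase 1/2) or
following (phase 0) the splice, plus its phase; two introns are identical
in position iff both column and phase agree. A phase-insensitive mode is
available.

The conservation summary counts intron *sites* (distinct family/column/
phase triples) by default: a site is identical-in-all when every genome
carries it, shared when at least two do. An occurrence-weighted mode
reproduces the "x% of introns" convention, in which each intron record
contributes to the denominator. Site- and occurrence-based percentages
differ whenever deeply shared sites exist, and the package exposes both
because published statements use both framings. Conservation percentages
computed on real annotations depend on which genes are compared and on the
aligner, so they are treated as comparison diagnostics, not as fixed
targets.

Oversized introns (longer than 23 nt) are flagged and scanned for internal
AG dinucleotides whose donor-to-AG prefix has ultrasmall length (18-23 nt)
— the relict boundary expected if the intron arose by fusion of two
ultrasmall introns.

## Summary statistics

GC content excludes N from the denominator. Gene density is all annotated
genes per kb. Intergenic spacers are gaps between consecutive feature spans
per chromosome, excluding terminal flanks, with overlapping features
producing no gap; RNA genes can be excluded and intervals (e.g. collapsed
subtelomeric repeats) masked, since the published convention behind the
reported means is not fully specified. The one-way ANOVA and two-sample
pooled t-test wrap `stats::oneway.test` and `stats::t.test` with explicit
handling of degenerate zero-variance inputs (F = 0, p = 1 when means are
equal). Reported roundings follow the source tables: GC to 1 decimal,
density to 2, introns per gene to 1, with introns-per-gene using
protein-coding genes *including* duplicates as the denominator — the
convention that reproduces three of the four published columns; the fourth
is internally inconsistent in the source and is not forced.

## The synthetic-genome generator

The generator emulates the architecture the pipeline targets: by default
three 120-kb chromosomes at 28% GC, 80 protein-coding genes per chromosome
(mean protein 347 aa, sd 60), Poisson(3) ultrasmall introns per gene
drawn uniformly from 18-23 nt, intergenic spacers of mean 110 bp (sd 25),
`[TCTAGGG]` telomeres of 12 copies, one 3-kb subtelomeric unit (carrying
rRNA feature annotations) identical at every end, and a configurable
ORFan fraction of 0.4. These magnitudes mirror the published genome
feature tables; where no value is stated (spacer sd, subtelomeric unit
length at 3 kb standing in for the ~10 kb rDNA+dnaK cassette, telomere copy
number) a value of realistic order was chosen once and kept.

Two guard rails make planted structures *uniquely recoverable* by a
spliced-ORF-length-maximizing caller, and they are the key design decision:

1. Every gene is flanked by 26-nt G-free spacer zones containing stop
   codons in all reading frames (both strands). No reading frame can run
   across a gene boundary, and no GT donor or AG acceptor can exist in the
   zones, so no legal excision can bridge a boundary.
2. Intron interiors are G-free and carry stops in all frames. Retention
   always truncates a parse; alternative GT/AG boundaries cannot occur
   inside an intron; and the exon windows adjacent to each splice site are
   rejection-sampled free of competing GT/AG sites within excision reach.
   The last intron is kept at least 17 nt from the stop codon so a genuine
   short terminal exon never loses to retention into the interior stop
   guard.

Sequence divergence in `evolve_species` is codon-aware (random sense-codon
replacement inside exons, skipping start/stop and the splice-adjacent
codons that would erode guard rail 2) with 3:1 transition-biased per-site
mutation in spacer middles; introns, telomeres and subtelomeric units are
never mutated, and pieces participating in a recorded exact duplication are
frozen so the planted "exactly identical" truth survives later events.
Events apply in a fixed order — divergence, losses, duplications,
inversions, intron gain/loss — so duplications are copied *after*
divergence and remain exact.

What the generator does not emulate: real splice sites without stop-guard
interiors, nucleotide-level indels, intron-position clustering, overlapping
genes, GC heterogeneity along chromosomes, and pseudogene decay. Passing
the recovery tests therefore demonstrates algorithmic correctness on
genomes whose signal structure matches the model's assumptions, not
annotation accuracy on real nucleomorph data — on real sequence the caller
shares the usual limits of purely intrinsic gene finders.

All sampling runs under a caller-supplied integer seed through R's default
RNG with the RNG state restored afterwards; the same seed yields
byte-identical FASTA/GFF3 on any platform.

## Numerical and scale choices

Alignment determinism comes from `pairwiseAlignment`'s fixed traceback and
the id-ordered center choice. The duplication scanner uses a polynomial
rolling hash modulo 2^31 - 1 (exact in doubles) with verification on
extension, so hash collisions cannot produce false regions. The test suite
exercises chromosomes of 15-70 kb with 8-50 genes per chromosome — sizes at
which the quadratic oracles stay fast — while the acceptance checks run the
full default three-chromosome, 360-kb configuration; the pipeline itself is
near-linear in genome length and has no practical trouble at real
nucleomorph scale (a full default genome annotates in a few seconds).

## Known limitations

* The gene caller maximizes spliced ORF length only; on real genomes it
  will over-call random open reading frames in non-coding regions
  (precision on synthetic data is ~0.6-0.85 against planted truth for this
  reason — spurious ORFs in the random subtelomeric/filler sequence) and
  cannot distinguish overlapping genuine genes.
* The subtelomeric-unit finder is anchored and verified, not a full
  longest-common-substring algorithm across six windows.
* Karlin-Altschul e-values use fixed K and lambda without composition
  adjustment; the seed prefilter compensates within this package's use.
* Synteny on real genomes depends on curation choices (gap tolerance,
  tandem handling); published block statistics are approximate targets
  under any automated setting.
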