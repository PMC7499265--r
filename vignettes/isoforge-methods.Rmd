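---
title: "isoforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isoforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoforge)
```

`isoforge` re-implements, as a tested and reusable pipeline, the
computational stages of a combined single-molecule long-read (SMRT/Iso-Seq)
plus short-read transcriptome analysis of a plant genome: full-length
non-chimeric (FLNC) read classification, isoform collapse and completeness
statistics, long-read-driven annotation refinement, five-type
alternative-splicing (AS) analysis, NG86 Ks estimation with whole-genome
duplication (WGD) dating, and expression summaries. Because the scale of a
real sequencing study is not reproducible on a desk, every stage is
validated against a deterministic synthetic-data generator that plants
machine-readable truth.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## FLNC classification

A full-length cDNA read has the structure

```
5'-primer + insert + poly(A) tail + revcomp(3'-primer)
```

`classify_read()` searches the 5' primer within the leading `search_window`
(default 100 bp) and the reverse-complemented 3' primer within the trailing
window, both by Hamming distance with at most `max_mismatch` (default 2)
mismatches. Vendor pipelines do this with proprietary matchers; a windowed
Hamming scan is transparent and exactly testable. The poly(A) tail is a
backward scan from the 3'-primer match: a run of at least `min_polyA_run`
(default 20) adenines tolerating one non-A per 10 bases, but stopping at two
consecutive non-A bases. The consecutive-non-A stop is essential: without it
the scan creeps into transcript bodies that happen to end A-rich, and the
recovered insert is no longer exact.

Classification order mirrors the usual library-summary ordering: reads below
`min_length` (default 300 bp, configurable; the emulated study reports
"filtered short reads" without stating its cutoff) are `filtered_short`
before any structural test; reads with all three signals are full-length,
and among those an additional interior primer match (either primer, same
Hamming tolerance, non-overlapping count) marks `full_length_chimeric`; the
rest are `non_full_length`. Per-read records aggregate to the conventional
nine-field library summary (`summarize_library()`,
`aggregate_summaries()`), where full-length counts include chimeric reads
and the aggregate mean FLNC length is FLNC-count weighted.

One caveat carried over from the spec: published per-signal counts ("number
of 5' reads") come from vendor pipelines whose double-counting rules are not
public; `isoforge` counts signal presence per read, which is well-defined
but need not reproduce vendor numbers.

## Transcript models, collapse, N50/Ex90N50

Models are plain exon tables (one row per exon), 0-based half-open
internally; GFF3 (1-based inclusive) and BED12 (0-based half-open) are
converted at the I/O boundary only, with parsing delegated to `rtracklayer`.

`collapse_by_intron_chain()` replaces sequence-identity clustering (cd-hit
in the emulated study) with coordinate-space collapse: multi-exon models on
one chromosome/strand with identical intron chains merge when their 5' and
3' terminal ends each differ by at most `fuzz_end` (default 50 bp, the usual
allowance for degradation and RT variability in long-read collapse tools;
`Inf` merges all identical chains). Merging is single linkage, and the
representative spans the extremal ends, so the union of exonic bases is
invariant and the operation is idempotent. Mono-exon models merge at
reciprocal overlap `mono_overlap` >= 0.95, mirroring common long-read
practice. The switch from sequence space to coordinate space is deliberate:
downstream analyses consume models, not sequences, and the collapse becomes
deterministic and alignment-free to test.

N50 is the length-weighted median (largest L such that transcripts of
length >= L sum to at least half the total). Ex90N50 restricts the N50 to
the smallest expression-ranked set reaching 90% of total TPM. Ex90N50 is
*not* asserted to be <= N50 — dropping low-expression transcripts can raise
or lower it — only definitional correctness against a brute-force scan is
tested.

## Annotation refinement

**Split genes.** A transcript alignment supports merging annotated genes
when its exons overlap the exonic bases of two or more same-strand genes,
each by at least `min_exonic_overlap` (default 30 bp; the study states no
threshold for "covering" adjacent genes, and 30 bp is large enough to
ignore incidental 1-2 bp brushes while far below any real exon). Proposals
are connected components of the gene-gene support graph, so A-B and B-C
support merges transitively; one supporting transcript suffices by default
(`min_support = 1`), configurable because the study does not state its
requirement.

**Novel isoforms.** The trichotomy follows the three positional criteria:
`unmapped` (no alignment), `intronic`, `intergenic`. An aligned isoform
overlapping annotated exons on its own strand is not novel. `intronic`
requires strict containment within a single intron — the invariant form of
the definition — and is strand-agnostic, since "maps to introns of genes"
is positional; the host and an antisense flag are recorded. Everything else
is `intergenic`, with exonic overlap on the opposite strand retained as an
antisense flag rather than inventing a fourth category.

**lncRNA triage.** Two independent channels cross into a Venn partition:
a homology flag supplied as input (so a real protein-database search can be
slotted in without code change), and a coding-potential rule — coding iff
the longest AUG-initiated stop-free reading frame across both strands and
all three frames reaches `orf_min_codons` (default 100 codons, the common
lncRNA convention). The ORF rule is a transparent stand-in for trained
coding-potential classifiers, which are external models with their own
training data. The lncRNA set is the union of isoforms negative in either
channel; `homology_only + potential_only + both` recovers its size, and
adding `neither` recovers the input count.

## Alternative-splicing events

Events are local differences between two isoforms of one locus, enumerated
pairwise and deduplicated by coordinate signature (type, chromosome,
strand, anchors), so each event is counted once no matter how many isoform
pairs witness it — matching event-centric totals of SUPPA-style tools.

* **ES** — an internal exon of one isoform whose flanking splice sites are
  bridged by a single intron of the other.
* **IR** — an intron of one isoform strictly contained in an exonic block
  of the other.
* **A5/A3** — two introns sharing one boundary and differing at the other,
  labelled relative to transcription direction; the variable-side flanking
  exons must overlap, otherwise the difference is an alternative first/last
  exon, not a splice-site shift.
* **AE** — mutually exclusive exons: non-overlapping internal exons of the
  two isoforms between identical outer flanking sites, neither present in
  the other isoform. "Alternative exon" is implemented as the
  mutually-exclusive reading, the standard five-type nomenclature when
  listed beside exon skipping.

Alternative first/last exons (AF/AL) are detected and reported but excluded
from five-type totals, since the emulated study's percentages use five
types. Percentages are integer-rounded half-up (consistent with the
published values); tissue shares are rounded half-up to 2 decimals.

Mirroring a locus' coordinates while keeping the strand annotation swaps
A5 and A3 and fixes ES/IR/AE; mirroring *and* flipping the strand describes
the same molecules and leaves all labels invariant. Both properties are
tested, alongside equality with an independent base-mask brute-force
enumerator on random loci of up to 4 isoforms and 8 exons.

## NG86 Ks and WGD dating

`ng86()` implements Nei-Gojobori (1986) counting: per codon, the
synonymous-site fraction at each position is the share of the three
single-nucleotide changes preserving the amino acid (changes to stop codons
count as nonsynonymous); site totals are averaged between the two
sequences. Codon pairs differing at k > 1 positions average their
synonymous/nonsynonymous difference counts over all k! substitution orders,
excluding pathways through stop codons (the PAML/NG convention); if every
path is blocked the codon pair is dropped and counted. Proportions are
Jukes-Cantor corrected, d = -(3/4) ln(1 - 4p/3); ps >= 3/4 is flagged
saturated. Codons with gaps or ambiguity codes are removed pairwise
(complete deletion). The standard genetic code is assumed. The
implementation is checked field-by-field against an exhaustive recursive
path enumerator on 1,000 random 10-codon pairs.

`ks_distribution_peak()` locates the WGD peak as the mode of a Gaussian
kernel density estimate (Silverman's rule-of-thumb bandwidth, `stats::density`)
inside an analysis window, default (0.05, 2): the low cutoff excludes
recent tandem duplicates, the high cutoff saturated estimates. The study
does not state whether it used a histogram or KDE, so both the bandwidth
and window are arguments. `ks_to_time()` applies the molecular clock
T = Ks/(2r), default r = 6.5e-9 substitutions per site per year; the factor
2 accounts for both post-duplication lineages. A Ks peak of 0.34 dates to
26.15 million years.

The paralog-pair simulator (`evolve_paralog_pair()`) applies
Poisson-distributed uniform single-nucleotide substitutions independently
along two lineages; because substitutions are uniform over positions and
alternative bases, the expected synonymous substitutions per synonymous
site equal the expected substitutions per site, so each lineage draws
`Poisson(target_ks/2 * 3L)` events. Substitutions creating stops are
redrawn, which slightly enriches synonymous changes; the end-to-end
recovery requirement (median NG86 estimate within 15% of the target at 200
pairs x 300 codons) absorbs this small bias. Paralog-pair *identification*
(OrthoMCL in the study) is out of scope: pairs arrive as two-record FASTA
files.

## Expression

TPM is `rate_i / sum(rate) * 1e6` with `rate_i = counts_i / length_i`;
FPKM is `counts_i * 1e9 / (length_i * total_mapped)`. Effective length is
the plain transcript length — no fragment-length correction — because the
study mixes RSEM and Salmon conventions and the simpler definition is
exactly testable. Replicate concordance is Pearson correlation on
log2(TPM + 1); the study names the coefficient but not the transform, so
the transform is recorded in the result object. Zero-variance samples are
flagged rather than silently correlated.

The representative isoform per gene is the longest, with higher mean TPM
breaking length ties and the lexicographically smallest id breaking exact
ties. The study's phrase "longest transcripts with the highest levels of
gene expression" does not say which criterion wins a conflict;
`priority = "expression"` selects the other reading.

## The synthetic-data generator

`generate_dataset()` emulates the study's inputs at desk scale with a fixed
seed, byte-identically reproducible. It plants: split genes (one true
multi-exon gene emitted as two adjacent fragment annotations covering
disjoint exon subsets — the paper never states how the mis-annotation
arose, so the generator defines the positive control this way); one AS
locus per configured event with exactly two isoforms differing by that
event; novel intergenic/intronic isoforms painted into the genome and
unmapped isoforms kept out of it; non-coding novels built by rejection
sampling (no >= 100-codon ORF on either strand) and coding novels with an
embedded ORF; FLNC reads as primer-flanked, poly(A)-tailed inserts with
substitution-only errors (downstream stages consume alignments, so indel
realism buys nothing); chimeras joining two inserts with a full internal
primer copy; short and signal-deleted reads; negative-binomial count tables
(five tissues x three replicates by default, matching the emulated design)
with log-normal baseline abundances of sdlog = 2, i.e. spanning roughly
four orders of magnitude as real transcriptomes do — wide enough that
replicate Pearson correlations exceed 0.9 at NB dispersion 0.1; evolved
paralog pairs at target Ks 0.34 (the published peak, used as the planted
value); and a homology-flag table derived from coding truth with an
optional flip-noise channel (default 0).

What the generator does **not** emulate: realistic error profiles of any
sequencing chemistry (errors are uniform substitutions), polymerase
subreads/consensus passes, fragmentation or positional coverage bias,
alternative transcription starts/ends beyond the planted events, paralog
birth-death dynamics, and any metabolite data. Passing tests therefore show
the algorithms are correct on structurally faithful inputs, not that they
are robust to every artifact of real libraries. The published
dataset-scale numbers (hundreds of thousands of reads; 1,925 split genes;
Ex90N50 of a full assembly) depend on the deposited data and are treated as
method definitions and arithmetic anchors, not as reproduction targets.

## Problem sizes and runtime choices

Tests run desk-scale by design: most module tests use a 12-gene, 2-chromosome
configuration (~150 reads, 3 paralog pairs), the end-to-end acceptance run
uses the 30-gene default (~135 reads, 50 paralog pairs x 300 codons) and
finishes in seconds, and the heaviest property checks are the 1,000-pair
NG86-vs-enumerator comparison and a 200-pair x 300-codon Ks recovery,
each well under a minute. The KDE peak requires >= 30 in-window values by
default (`min_pairs`), relaxed explicitly in small-fixture tests.

## Known limitations

* Primer matching is Hamming (no indels); real adapter trimmers tolerate
  indels. At the simulated substitution-only error model this is exact.
* The ORF rule is a fixed-threshold stand-in for trained coding-potential
  classifiers; the homology channel is an input table, not a search.
* Gene-level AS roll-ups depend on the annotation's gene grouping; the
  study's exact gene-level de-duplication is unstated.
* `Ks` saturation (ps >= 3/4) is flagged, not extrapolated; deeply diverged
  pairs are excluded from peak detection by the window.
* The flower tissue share prints as 22.28% in the emulated study while the
  five published counts give 22.29% at 2 dp; `tissue_isoform_shares()`
  computes from counts and is tested against the four consistent values.
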