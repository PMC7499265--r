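# isoforge

Hybrid long-read/short-read transcriptome studies of non-model plants follow
a now-standard computational arc: classify single-molecule cDNA reads into
full-length non-chimeric (FLNC) and related classes from their primer and
poly(A) structure; collapse redundant isoform models and measure assembly
completeness (N50, Ex90N50); use full-length alignments to repair the genome
annotation — merge genes mis-annotated as adjacent fragments, triage novel
isoforms into unmapped/intronic/intergenic, and call lncRNAs from homology
and coding-potential evidence; enumerate alternative-splicing (AS) events of
the five classical types; date whole-genome duplications (WGD) from the
synonymous-divergence (Ks) distribution of paralog pairs; and summarize
tissue expression as TPM/FPKM with replicate concordance. Published studies
run this arc through a chain of external tools; `isoforge` implements the
analytical substance of each stage as tested, reusable R functions, and
ships a deterministic synthetic-data generator with machine-readable planted
truth so that every stage is verifiable end to end without any sequencing
download.

It is written for bioinformaticians who need the pipeline's logic —
auditable, parameterized, and testable at desk scale — rather than a rerun
of vendor software.

## Methods at the core

**FLNC classification.** A full-length read is
`primer5 + insert + poly(A) + revcomp(primer3)`; primers are matched by
windowed Hamming search (≤ 2 mismatches in 100-bp terminal windows), the
tail as a ≥ 20-nt A-run tolerating one non-A per 10 bases, and an interior
primer copy marks a chimera. Library summaries use the conventional
nine-field layout.

**NG86 Ks/Ka** (Nei & Gojobori 1986). Per codon, the synonymous-site
fraction at each position is the share of the three single-nucleotide
changes preserving the amino acid; sites are averaged between the two
sequences (S, N with S + N = 3·codons). Differences at codons differing at
k > 1 positions are averaged over all k! substitution orders, excluding
paths through stop codons (Sd, Nd). With p_s = Sd/S and p_n = Nd/N, the
Jukes–Cantor correction gives

    Ks = -(3/4) ln(1 - (4/3) p_s),   Ka = -(3/4) ln(1 - (4/3) p_n).

The WGD age is the molecular clock T = Ks_peak / (2r) with
r = 6.5 × 10⁻⁹ substitutions·site⁻¹·yr⁻¹; the Ks peak is the mode of a
Gaussian KDE over the paralog Ks distribution in a configurable window.

**AS events.** Pairwise isoform comparison per locus yields exon skipping
(ES), intron retention (IR), alternative 5'/3' splice sites (A5/A3,
strand-aware), and mutually exclusive exons (AE), deduplicated by coordinate
signature; alternative first/last exons are reported separately. TPM is
`(c_i/l_i) / Σ(c/l) × 10⁶`; FPKM is `c_i × 10⁹ / (l_i × total)`; replicate
concordance is Pearson r on log2(TPM+1).

See `vignettes/isoforge-methods.Rmd` for assumptions, parameter defaults,
and design notes.

## Worked example

Simulate a 30-gene dataset at zero read noise and run every stage:

```r
library(isoforge)
cfg <- simulation_config(seed = 42, read_error_rate = 0)
report <- run_pipeline(cfg, file.path(tempdir(), "demo"))
report
```

```
== isoforge pipeline report ==

Library summary: Total
  Number of reads of insert                  135
  Number of 5' reads                         132
  Number of 3' reads                         132
  Number of poly(A) reads                    129
  Number of filtered short reads             5
  Number of non-full-length reads            9
  Number of full-length reads                121
  Number of full-length non-chimeric reads   116
  Average FLNC insert length                 634

FLNC truth accuracy: 1.000
Assembly stats: 54 transcripts, max 1347 bp, N50 685 bp, Ex90N50 685 bp
Split genes: 8 mergeable into 4
Novel isoforms: unmapped=4, intronic=3, intergenic=6, novel_total=13
lncRNA Venn: homology_only=0, potential_only=0, both=6, neither=7, lncRNA_total=6

AS events: 15 total
  ES           3  (20%)
  IR           3  (20%)
  A5           3  (20%)
  A3           3  (20%)
  AE           3  (20%)

Ks peak: mode = 0.3539 (50 pairs used, 0 excluded, bw = 0.01431, window [0.05, 2])
WGD time: 27.22 MYA
Median replicate Pearson r: 0.877

Planted-truth recovery:
             task precision recall
       flnc_class         1      1
 split_components         1      1
 novel_categories         1      1
 lncrna_noncoding         1      1
        as_events         1      1
```

Reading the numbers: the 135 reads partition into the planted classes (116
FLNC = 2 reads for each of 58 transcripts; 5 chimeras are full-length but
not FLNC, hence 121 full-length); the 4 planted split-gene pairs are
recovered as 4 merge proposals covering 8 fragment genes; the 15 planted AS
events (3 per type) are enumerated exactly; the 50 paralog pairs evolved to
Ks = 0.34 peak at 0.354, dating the planted duplication to ~27 MYA (the
clock at exactly 0.34 gives 26.15 MY); and at zero noise every stage
recovers its planted truth with precision = recall = 1.

A single pair estimate, by hand-checkable example — two glycine codons with
one synonymous third-position change (S = 2, Sd = 1, p_s = 1/2):

```r
ng86("GGGGGG", "GGAGGG")
#> NG86 estimate: 2 codons (0 dropped)
#>   S = 2.00  N = 4.00  Sd = 1.00  Nd = 0.00
#>   Ks = 0.824  Ka = 0
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/isoforge.R run --config cfg.yaml --outdir out/
```

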