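#' Configuration for the synthetic-dataset generator
#'
#' Defaults emulate a desk-scale version of a combined long-read/short-read
#' plant transcriptome study: five tissues with three biological replicates,
#' a pooled long-read library with full-length reads carrying 5'/3' primers
#' and a 30-nt poly(A) tail, deliberately split gene models, planted novel
#' intergenic/intronic/unmapped isoforms (some non-coding), loci carrying one
#' alternative-splicing event of each of the five types, and paralog pairs
#' evolved to a synonymous divergence of 0.34 (the Ks value at which the
#' paralog distribution of the emulated study peaks).
#'
#' @param seed RNG seed; a fixed seed makes [generate_dataset()] output
#'   byte-identical.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of true gene loci (must cover the special roles:
#'   split genes, AS loci, intronic-novel hosts).
#' @param n_split_gene_pairs true genes annotated as two adjacent fragments.
#' @param n_novel_intergenic,n_novel_intronic,n_unmapped planted novel
#'   isoform counts per category.
#' @param as_events_per_type named counts of planted AS loci (names among
#'   ES, IR, A5, A3, AE), one event per locus.
#' @param n_noncoding how many planted novel isoforms are non-coding (must
#'   not exceed the total novel count).
#' @param read_error_rate per-base substitution probability on reads (in
#'   [0, 0.2)).
#' @param primer5,primer3 library primers; defaults are the standard
#'   template-switching cDNA primers.
#' @param polyA_length generated tail length (nt); kept above the detection
#'   threshold so error-trimmed tails still pass.
#' @param reads_per_isoform FLNC reads generated per transcript.
#' @param n_chimeric,n_non_full_length,n_filtered_short planted counts of the
#'   other read classes.
#' @param n_paralog_pairs,target_ks,paralog_codons paralog-pair simulation:
#'   number of pairs, target synonymous divergence(s) (recycled), codons per
#'   ancestral CDS.
#' @param counts_dispersion negative-binomial dispersion of the count tables
#'   (0 gives Poisson counts).
#' @param n_tissues,n_replicates count-table design.
#' @param homology_flip_rate probability that a homology flag contradicts the
#'   coding truth (label noise channel).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 300000L,
                              n_genes = 30L,
                              n_split_gene_pairs = 4L,
                              n_novel_intergenic = 6L,
                              n_novel_intronic = 3L,
                              n_unmapped = 4L,
                              as_events_per_type = c(ES = 3L, IR = 3L, A5 = 3L,
                                                     A3 = 3L, AE = 3L),
                              n_noncoding = 6L,
                              read_error_rate = 0.01,
                              primer5 = "AAGCAGTGGTATCAACGCAGAGTACATGGG",
                              primer3 = "AAGCAGTGGTATCAACGCAGAGTAC",
                              polyA_length = 30L,
                              reads_per_isoform = 2L,
                              n_chimeric = 5L,
                              n_non_full_length = 9L,
                              n_filtered_short = 5L,
                              n_paralog_pairs = 50L,
                              target_ks = 0.34,
                              paralog_codons = 300L,
                              counts_dispersion = 0.1,
                              n_tissues = 5L,
                              n_replicates = 3L,
                              homology_flip_rate = 0) {
  cfg <- list(seed = seed, n_chromosomes = n_chromosomes,
              chrom_length = chrom_length, n_genes = n_genes,
              n_split_gene_pairs = n_split_gene_pairs,
              n_novel_intergenic = n_novel_intergenic,
              n_novel_intronic = n_novel_intronic, n_unmapped = n_unmapped,
              as_events_per_type = as_events_per_type,
              n_noncoding = n_noncoding, read_error_rate = read_error_rate,
              primer5 = toupper(primer5), primer3 = toupper(primer3),
              polyA_length = polyA_length,
              reads_per_isoform = reads_per_isoform, n_chimeric = n_chimeric,
              n_non_full_length = n_non_full_length,
              n_filtered_short = n_filtered_short,
              n_paralog_pairs = n_paralog_pairs, target_ks = target_ks,
              paralog_codons = paralog_codons,
              counts_dispersion = counts_dispersion, n_tissues = n_tissues,
              n_replicates = n_replicates,
              homology_flip_rate = homology_flip_rate)
  for (f in c("n_chromosomes", "chrom_length", "n_genes", "n_split_gene_pairs",
              "n_novel_intergenic", "n_novel_intronic", "n_unmapped",
              "n_noncoding", "polyA_length", "reads_per_isoform", "n_chimeric",
              "n_non_full_length", "n_filtered_short", "n_paralog_pairs",
              "paralog_codons", "n_tissues", "n_replicates"))
    stopifnot_scalar_count(cfg[[f]], f)
  if (cfg$n_genes == 0L) stop("zero-gene config")
  if (read_error_rate < 0 || read_error_rate >= 0.2)
    stop("read_error_rate must be in [0, 0.2)")
  if (homology_flip_rate < 0 || homology_flip_rate > 1)
    stop("homology_flip_rate must be in [0, 1]")
  if (any(!names(as_events_per_type) %in% AS_TYPES))
    stop("as_events_per_type names must be among ", paste(AS_TYPES, collapse = ", "))
  if (any(as_events_per_type < 0)) stop("as_events_per_type must be >= 0")
  if (any(target_ks < 0)) stop("target_ks must be >= 0")
  needed <- n_split_gene_pairs + sum(as_events_per_type) + n_novel_intronic
  if (n_genes < needed)
    stop(sprintf("n_genes = %d cannot host %d split genes + %d AS loci + %d intronic-novel hosts (need >= %d)",
                 n_genes, n_split_gene_pairs, sum(as_events_per_type),
                 n_novel_intronic, needed))
  n_novel <- n_novel_intergenic + n_novel_intronic + n_unmapped
  if (n_noncoding > n_novel)
    stop("n_noncoding exceeds the number of planted novel isoforms")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config (seed", x$seed, ")\n")
  cat(sprintf("  genome: %d chromosome(s) x %d bp; %d genes (%d split pairs, %d AS loci, %d intronic hosts)\n",
              x$n_chromosomes, x$chrom_length, x$n_genes, x$n_split_gene_pairs,
              sum(x$as_events_per_type), x$n_novel_intronic))
  cat(sprintf("  novels: %d intergenic, %d intronic, %d unmapped (%d non-coding)\n",
              x$n_novel_intergenic, x$n_novel_intronic, x$n_unmapped, x$n_noncoding))
  cat(sprintf("  reads: %d per isoform + %d chimeric + %d non-full-length + %d short; error %.3f\n",
              x$reads_per_isoform, x$n_chimeric, x$n_non_full_length,
              x$n_filtered_short, x$read_error_rate))
  cat(sprintf("  paralogs: %d pairs x %d codons, target Ks %s; counts: %d tissues x %d reps, dispersion %.2f\n",
              x$n_paralog_pairs, x$paralog_codons,
              paste(x$target_ks, collapse = "/"), x$n_tissues, x$n_replicates,
              x$counts_dispersion))
  invisible(x)
}
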