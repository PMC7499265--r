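# Shared fixtures: toy primers, compact transcript-model builders, and a
# small simulation config reused across tests.

P5 <- "AAGCAGTGGTATCAACGCAGAGTACATGGG"
P3 <- "AAGCAGTGGTATCAACGCAGAGTAC"

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

flnc_read <- function(insert, polyA = 30) {
  paste0(P5, insert, strrep("A", polyA), isoforge::revcomp(P3))
}

## build a transcript_models table from a list: tx id -> matrix-like of
## (start, end) rows
make_models <- function(iso, chrom = "chr1", strand = "+", gene = "g1") {
  rows <- lapply(names(iso), function(tx) {
    m <- matrix(iso[[tx]], ncol = 2, byrow = TRUE)
    data.frame(transcript_id = tx, gene_id = gene, chrom = chrom,
               strand = strand, start = m[, 1], end = m[, 2])
  })
  isoforge::transcript_models(do.call(rbind, rows))
}

small_sim_config <- function(seed = 11, ...) {
  isoforge::simulation_config(
    seed = seed, n_chromosomes = 2, chrom_length = 120000, n_genes = 12,
    n_split_gene_pairs = 2,
    as_events_per_type = c(ES = 1, IR = 1, A5 = 1, A3 = 1, AE = 1),
    n_novel_intergenic = 3, n_novel_intronic = 2, n_unmapped = 2,
    n_noncoding = 3, n_paralog_pairs = 3, paralog_codons = 60,
    n_chimeric = 2, n_non_full_length = 3, n_filtered_short = 2,
    n_tissues = 2, n_replicates = 2, ...)
}
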