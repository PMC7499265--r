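ann_two_genes <- function() {
  transcript_models(rbind(
    data.frame(transcript_id = "A.t1", gene_id = "A", chrom = "chr1",
               strand = "+", start = c(1000, 1500), end = c(1200, 1700)),
    data.frame(transcript_id = "B.t1", gene_id = "B", chrom = "chr1",
               strand = "+", start = c(3000, 3500), end = c(3200, 3700))))
}

test_that("a read spanning two genes proposes one merge", {
  ann <- ann_two_genes()
  aln <- make_models(list(r1 = c(1000, 1200, 1500, 1700, 3000, 3200)),
                     gene = NA)
  res <- detect_split_genes(aln, ann)
  expect_equal(res$n_merged, 1)
  expect_equal(res$n_split_genes, 2)
  expect_equal(res$proposals$genes, "A,B")
  expect_equal(res$proposals$supporting_transcripts, "r1")
})

test_that("merge components are transitive and partition the genes", {
  ann <- transcript_models(do.call(rbind, lapply(1:3, function(i)
    data.frame(transcript_id = paste0(LETTERS[i], ".t1"), gene_id = LETTERS[i],
               chrom = "chr1", strand = "+",
               start = i * 10000, end = i * 10000 + 500))))
  aln <- make_models(list(rAB = c(10000, 10500, 20000, 20500),
                          rBC = c(20000, 20500, 30000, 30500)), gene = NA)
  res <- detect_split_genes(aln, ann)
  expect_equal(res$n_merged, 1)
  expect_equal(res$proposals$genes, "A,B,C")
  # genes appear in exactly one component
  all_genes <- unlist(strsplit(res$proposals$genes, ","))
  expect_false(any(duplicated(all_genes)))
  # opposite-strand reads never support a merge
  aln_anti <- make_models(list(r1 = c(10000, 10500, 20000, 20500)),
                          strand = "-", gene = NA)
  expect_equal(detect_split_genes(aln_anti, ann)$n_merged, 0)
  # sub-threshold exonic overlap is ignored
  aln_thin <- make_models(list(r1 = c(10490, 10500, 20000, 20500)), gene = NA)
  expect_equal(detect_split_genes(aln_thin, ann, min_exonic_overlap = 30)$n_merged, 0)
})

test_that("synthetic split genes are recovered exactly at zero noise", {
  cfg <- small_sim_config(seed = 41, read_error_rate = 0)
  out <- file.path(tempdir(), "split")
  truth <- generate_dataset(cfg, out, overwrite = TRUE)
  aln <- parse_models(file.path(out, "alignments.bed"))
  ann <- parse_models(file.path(out, "annotation.gff3"))
  res <- detect_split_genes(aln, ann)
  got <- lapply(res$proposals$genes, function(g) sort(strsplit(g, ",")[[1]]))
  expect_equal(res$n_merged, cfg$n_split_gene_pairs)
  expect_setequal(vapply(got, paste, "", collapse = "|"),
                  vapply(truth$split_components, paste, "", collapse = "|"))
})

test_that("novel isoforms are triaged by the three positional criteria", {
  ann <- transcript_models(data.frame(
    transcript_id = "G.t1", gene_id = "G", chrom = "chr1", strand = "+",
    start = c(1000, 3000, 5000), end = c(1500, 3500, 5400)))
  aln <- make_models(list(
    in_intron2 = c(3700, 4200),     # inside intron 2 of G
    on_exon = c(1400, 1600),        # overlaps exon -> not novel
    far_away = c(20000, 20600)),    # intergenic
    gene = NA)
  res <- classify_novel_isoforms(aln, unaligned_ids = c("lost1", "lost2"), ann)
  cal <- setNames(res$calls$category, res$calls$transcript_id)
  expect_equal(unname(cal["in_intron2"]), "intronic")
  expect_equal(unname(cal["far_away"]), "intergenic")
  expect_false("on_exon" %in% names(cal))
  expect_equal(unname(cal[c("lost1", "lost2")]), c("unmapped", "unmapped"))
  expect_equal(unname(res$totals[["novel_total"]]),
               sum(res$totals[c("unmapped", "intronic", "intergenic")]))
  # antisense exonic overlap: intergenic with the flag set
  anti <- make_models(list(as1 = c(1400, 1600)), strand = "-", gene = NA)
  res2 <- classify_novel_isoforms(anti, character(0), ann)
  expect_equal(res2$calls$category, "intergenic")
  expect_true(res2$calls$antisense_flag)
  expect_error(classify_novel_isoforms(aln, "in_intron2", ann), "disjoint")
})

test_that("synthetic novel categories are recovered exactly", {
  cfg <- small_sim_config(seed = 43, read_error_rate = 0)
  out <- file.path(tempdir(), "novel")
  truth <- generate_dataset(cfg, out, overwrite = TRUE)
  aln <- parse_models(file.path(out, "alignments.bed"))
  ann <- parse_models(file.path(out, "annotation.gff3"))
  iso <- Biostrings::readDNAStringSet(file.path(out, "isoforms.fa"))
  unaligned <- setdiff(names(iso), unique(aln$transcript_id))
  res <- classify_novel_isoforms(aln, unaligned, ann)
  pred <- setNames(res$calls$category, res$calls$transcript_id)
  expect_mapequal(as.list(pred), as.list(truth$novel_categories))
})

test_that("intron-count profiles normalize and order as planted", {
  mono3 <- make_models(list(a = c(0, 10), b = c(20, 35), c = c(50, 70)))
  pr <- intron_count_profile(mono3, mono3)
  expect_equal(unname(pr$freq_a[["0"]]), 1)
  mixed <- make_models(list(a = c(0, 10, 20, 30),
                            b = c(100, 110, 120, 130, 140, 150, 160, 170)))
  pr2 <- intron_count_profile(mixed, mixed)
  expect_equal(as.numeric(pr2$freq_a), c(0.5, 0.5))
  expect_equal(names(pr2$freq_a), c("1", "3"))
  # planted novels are mono-exon, so their mean intron count is smaller
  cfg <- small_sim_config(seed = 45)
  out <- file.path(tempdir(), "introns")
  truth <- generate_dataset(cfg, out, overwrite = TRUE)
  aln <- parse_models(file.path(out, "alignments.bed"))
  novel_aligned <- names(truth$novel_categories)[
    truth$novel_categories != "unmapped"]
  pr3 <- intron_count_profile(
    transcript_models(as.data.frame(aln[aln$transcript_id %in% novel_aligned, ])),
    aln)
  expect_lt(pr3$mean_a, pr3$mean_b)
})

test_that("lncRNA calling crosses the homology and ORF channels", {
  set.seed(6)
  no_orf <- gsub("ATG|CAT", "CCC", rand_seq(600))  # no start codon either strand
  with_orf <- paste0(rand_seq(30), "ATG",
                     strrep("GCT", 150), "TAA", rand_seq(30))
  seqs <- c(nc1 = no_orf, cod1 = with_orf, nc2 = no_orf, cod2 = with_orf)
  flags <- data.frame(transcript_id = names(seqs), hit = c(0, 1, 1, 0))
  res <- call_lncrna(seqs, flags, orf_min_codons = 100)
  cls <- setNames(res$calls$venn_class, res$calls$transcript_id)
  expect_equal(unname(cls), c("both", "neither", "potential_only", "homology_only"))
  expect_equal(unname(res$venn[["lncRNA_total"]]), 3)
  expect_equal(sum(res$venn[c("homology_only", "potential_only", "both",
                              "neither")]), length(seqs), ignore_attr = TRUE)
  expect_error(call_lncrna(c(x = "ACGTX"), data.frame(transcript_id = "x", hit = 1)),
               "non-IUPAC")
  # arithmetic helpers used by the report
  expect_equal(unname(novel_isoform_totals(
    c(unmapped = 247, intergenic = 7810, intronic = 54))[["novel_total"]]), 8111)
  expect_equal(unname(lncrna_venn_totals(
    c(homology_only = 1083, potential_only = 804, both = 777))[["lncRNA_total"]]),
    2664)
})

test_that("synthetic non-coding isoforms are recovered exactly at zero label noise", {
  cfg <- small_sim_config(seed = 47, read_error_rate = 0, homology_flip_rate = 0)
  out <- file.path(tempdir(), "lnc")
  truth <- generate_dataset(cfg, out, overwrite = TRUE)
  iso <- Biostrings::readDNAStringSet(file.path(out, "isoforms.fa"))
  hom <- read.delim(file.path(out, "homology.tsv"))
  novel_ids <- names(truth$novel_categories)
  res <- call_lncrna(setNames(as.character(iso[novel_ids]), novel_ids),
                     hom[hom$transcript_id %in% novel_ids, ])
  lnc <- res$calls$transcript_id[res$calls$venn_class != "neither"]
  expect_setequal(lnc, truth$noncoding_ids)
})
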