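test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 7)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_dataset(cfg, d1, overwrite = TRUE)
  generate_dataset(cfg, d2, overwrite = TRUE)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("planted counts are conserved in files and truth", {
  cfg <- small_sim_config(seed = 5)
  out <- file.path(tempdir(), "cons")
  truth <- generate_dataset(cfg, out, overwrite = TRUE)
  # every read is labelled, and labels account for every written read
  reads <- Biostrings::readDNAStringSet(file.path(out, "reads.fa"))
  expect_setequal(names(reads), names(truth$read_labels))
  tb <- table(truth$read_labels)
  expect_equal(unname(tb[["chimeric"]]), cfg$n_chimeric)
  expect_equal(unname(tb[["non_full_length"]]), cfg$n_non_full_length)
  expect_equal(unname(tb[["filtered_short"]]), cfg$n_filtered_short)
  # gene records = true genes + one extra fragment per split pair
  gff <- readLines(file.path(out, "annotation.gff3"))
  n_gene_records <- sum(grepl("\tgene\t", gff, fixed = TRUE))
  expect_equal(n_gene_records, cfg$n_genes + cfg$n_split_gene_pairs)
  # planted AS events: one per configured locus
  expect_equal(nrow(truth$planted_events), sum(cfg$as_events_per_type))
  expect_equal(sort(table(truth$planted_events$type)),
               sort(table(rep(names(cfg$as_events_per_type),
                              cfg$as_events_per_type))),
               ignore_attr = TRUE)
  # paralog pairs: one file per pair, planted Ks as configured
  expect_length(attr(truth, "files")$pairs, cfg$n_paralog_pairs)
  expect_true(all(truth$pair_ks == cfg$target_ks))
  # novel truth categories
  expect_equal(unname(table(truth$novel_categories)[c("intergenic", "intronic", "unmapped")]),
               c(cfg$n_novel_intergenic, cfg$n_novel_intronic, cfg$n_unmapped),
               ignore_attr = TRUE)
  expect_length(truth$noncoding_ids, cfg$n_noncoding)
})

test_that("truth JSON round-trips losslessly", {
  cfg <- small_sim_config(seed = 9)
  out <- file.path(tempdir(), "rt")
  truth <- generate_dataset(cfg, out, overwrite = TRUE)
  back <- read_truth(file.path(out, "truth.json"))
  expect_equal(back$read_labels, truth$read_labels)
  expect_equal(back$split_components, truth$split_components)
  expect_equal(back$novel_categories, truth$novel_categories)
  expect_equal(back$planted_events, truth$planted_events)
  expect_equal(back$noncoding_ids, truth$noncoding_ids)
  expect_equal(back$pair_ks, truth$pair_ks)
})

test_that("emitted annotation and alignments are structurally valid", {
  cfg <- small_sim_config(seed = 13)
  out <- file.path(tempdir(), "valid")
  generate_dataset(cfg, out, overwrite = TRUE)
  ann <- parse_models(file.path(out, "annotation.gff3"))   # validates invariants
  aln <- parse_models(file.path(out, "alignments.bed"))
  genome <- Biostrings::readDNAStringSet(file.path(out, "genome.fa"))
  lens <- setNames(Biostrings::width(genome), names(genome))
  for (m in list(ann, aln)) {
    expect_true(all(m$start >= 0))
    expect_true(all(m$end <= lens[m$chrom]))
  }
  # alignment exon blocks reproduce isoform sequences from the genome
  iso <- Biostrings::readDNAStringSet(file.path(out, "isoforms.fa"))
  sp <- split(as.data.frame(aln), aln$transcript_id)
  for (tx in names(sp)[1:5]) {
    ex <- sp[[tx]]
    s <- paste(vapply(seq_len(nrow(ex)), function(i)
      substr(as.character(genome[[ex$chrom[1]]]), ex$start[i] + 1, ex$end[i]),
      character(1)), collapse = "")
    if (ex$strand[1] == "-") s <- revcomp(s)
    expect_identical(s, as.character(iso[[tx]]))
  }
})

test_that("paralog evolution respects the zero limit and is monotone in target", {
  cds <- random_cds(100)
  p0 <- evolve_paralog_pair(cds, 0)
  expect_identical(p0$seq1, cds)
  expect_identical(p0$seq2, cds)
  expect_equal(p0$realized_syn_substitutions, 0)
  set.seed(42); lo <- evolve_paralog_pair(random_cds(300), 0.1)
  set.seed(42); hi <- evolve_paralog_pair(random_cds(300), 0.6)
  expect_lt(lo$realized_syn_substitutions, hi$realized_syn_substitutions)
  expect_error(evolve_paralog_pair("ATGTAAATG", 0.1), "stop")
  expect_error(evolve_paralog_pair(random_cds(10), -1), ">= 0")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 0), "zero-gene|host")
  expect_error(simulation_config(read_error_rate = 0.5), "read_error_rate")
  expect_error(simulation_config(n_genes = 5), "cannot host")
  expect_error(simulation_config(n_noncoding = 99), "noncoding")
  expect_error(simulation_config(as_events_per_type = c(XX = 1)), "as_events")
})
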