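test_that("BED12 and GFF3 dialects convert to internal half-open coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t1500\ttx1\t0\t+\t1000\t1500\t0\t2\t100,200\t0,300", bed)
  m <- parse_models(bed)
  expect_equal(m$start, c(1000, 1300))
  expect_equal(m$end, c(1100, 1500))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tx\texon\t101\t200\t.\t+\t.\tParent=t1"), gff)
  g <- parse_models(gff)
  expect_equal(c(g$start, g$end), c(100, 200))
  expect_equal(g$gene_id, "g1")
})

test_that("models round-trip through both writers", {
  cfg <- small_sim_config(seed = 31)
  out <- file.path(tempdir(), "roundtrip")
  generate_dataset(cfg, out, overwrite = TRUE)
  ann <- parse_models(file.path(out, "annotation.gff3"))
  f2 <- tempfile(fileext = ".gff3")
  write_models(ann, f2, format = "gff3")
  ann2 <- parse_models(f2)
  o <- function(m) { m <- as.data.frame(m); m[order(m$transcript_id, m$start), ] }
  expect_equal(o(ann2), o(ann), ignore_attr = TRUE)
  fb <- tempfile(fileext = ".bed")
  write_models(ann, fb, format = "bed12")
  ann3 <- parse_models(fb)
  expect_equal(o(ann3)[c("transcript_id", "chrom", "strand", "start", "end")],
               o(ann)[c("transcript_id", "chrom", "strand", "start", "end")],
               ignore_attr = TRUE)
})

test_that("intron-chain collapse merges what it should and nothing else", {
  two_same <- make_models(list(
    a = c(100, 200, 300, 400, 500, 600),
    b = c(120, 200, 300, 400, 500, 580)))
  expect_equal(length(unique(collapse_by_intron_chain(two_same)$transcript_id)), 1)
  # representative spans extremal ends
  col <- collapse_by_intron_chain(two_same)
  expect_equal(min(col$start), 100)
  expect_equal(max(col$end), 600)
  # one differing splice site prevents the merge
  diff_site <- make_models(list(
    a = c(100, 200, 300, 400),
    b = c(100, 210, 300, 400)))
  expect_equal(length(unique(collapse_by_intron_chain(diff_site)$transcript_id)), 2)
  # ends beyond fuzz_end stay separate
  far <- make_models(list(
    a = c(100, 200, 300, 400),
    b = c(100 - 80, 200, 300, 400)))
  expect_equal(length(unique(collapse_by_intron_chain(far, fuzz_end = 50)$transcript_id)), 2)
  expect_equal(length(unique(collapse_by_intron_chain(far, fuzz_end = Inf)$transcript_id)), 1)
  # mono-exon reciprocal overlap
  mono <- make_models(list(a = c(1000, 2000), b = c(1010, 2005), c = c(5000, 6000)))
  expect_equal(length(unique(collapse_by_intron_chain(mono)$transcript_id)), 2)
})

test_that("collapse is idempotent and conserves exonic extent", {
  cfg <- small_sim_config(seed = 33)
  out <- file.path(tempdir(), "collapse")
  generate_dataset(cfg, out, overwrite = TRUE)
  aln <- parse_models(file.path(out, "alignments.bed"))
  # add jittered duplicates of some transcripts
  sp <- split(as.data.frame(aln), aln$transcript_id)
  dup <- do.call(rbind, lapply(head(sp, 8), function(ex) {
    ex$transcript_id <- paste0(ex$transcript_id, "_dup")
    ex$start[1] <- ex$start[1] + 17
    ex$end[nrow(ex)] <- ex$end[nrow(ex)] - 11
    ex
  }))
  all_m <- transcript_models(rbind(as.data.frame(aln), dup))
  c1 <- collapse_by_intron_chain(all_m)
  c2 <- collapse_by_intron_chain(c1)
  o <- function(m) { m <- as.data.frame(m); m[order(m$transcript_id, m$start), ] }
  expect_equal(o(c2), o(c1), ignore_attr = TRUE)
  expect_lte(length(unique(c1$transcript_id)), length(unique(all_m$transcript_id)))
  # exonic base union per chromosome unchanged
  union_bp <- function(m) {
    sum(vapply(split(as.data.frame(m), m$chrom), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
      sum(IRanges::width(ir))
    }, numeric(1)))
  }
  expect_equal(union_bp(c1), union_bp(all_m))
})

test_that("N50 and Ex90N50 follow their definitions", {
  m <- make_models(list(a = c(0, 2), b = c(10, 13), c = c(20, 24),
                        d = c(30, 35), e = c(40, 46)))
  st <- compute_stats(m)
  expect_equal(st$n50, 5)
  expect_equal(st$max_length, 6)
  expect_true(is.na(st$ex90n50))
  # brute-force oracle: N50 = max L among lengths with sum(lengths >= L) >= total/2
  set.seed(4)
  lens <- sample(100:5000, 1000, replace = TRUE)
  rows <- data.frame(transcript_id = sprintf("t%04d", seq_along(lens)),
                     gene_id = NA, chrom = "chr1", strand = "+",
                     start = seq_along(lens) * 10000,
                     end = seq_along(lens) * 10000 + lens)
  big <- transcript_models(rows)
  brute <- max(Filter(function(L) sum(lens[lens >= L]) >= sum(lens) / 2, lens))
  expect_equal(compute_stats(big)$n50, brute)
  # order invariance
  shuf <- transcript_models(rows[sample(nrow(rows)), ])
  expect_equal(compute_stats(shuf)$n50, brute)
  # degenerate Ex90N50: single transcript
  one <- make_models(list(a = c(0, 1234)))
  expect_equal(compute_stats(one, expression = 5)$ex90n50, 1234)
  # uniform expression: top set is the ceiling(90%) most expressed
  expr <- rep(1, 5)
  st2 <- compute_stats(m, expression = expr)
  expect_false(is.na(st2$ex90n50))
})

test_that("model construction enforces its invariants", {
  expect_error(make_models(list(a = c(100, 100))), "end <= start")
  expect_error(transcript_models(data.frame(
    transcript_id = "t", gene_id = NA, chrom = "c", strand = "+",
    start = c(0, 50), end = c(100, 150))), "overlapping")
  expect_error(transcript_models(data.frame(
    transcript_id = "t", gene_id = NA, chrom = "c", strand = "x",
    start = 0, end = 10)), "strand")
})
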