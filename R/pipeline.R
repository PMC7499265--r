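# End-to-end orchestration: simulate (optional) -> FLNC classification ->
# collapse/stats -> annotation refinement -> AS events -> Ks/WGD ->
# expression, with a manifest of checksummed artifacts and a consolidated
# report including planted-truth recovery metrics.

prec_recall <- function(predicted, truth) {
  p <- length(intersect(predicted, truth)) / max(length(predicted), 1L)
  r <- length(intersect(predicted, truth)) / max(length(truth), 1L)
  c(precision = p, recall = r)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_log <- function(stage, ...) {
  message(sprintf("[isoforge] %-10s %s", stage, sprintf(...)))
}

#' Run the full pipeline on a (synthetic) dataset
#'
#' Generates a dataset from `sim_config`, then runs every analysis stage in
#' dependency order, writing plain-text artifacts under `outdir` and a
#' manifest with MD5 checksums. The returned report carries a library-summary
#' block, the five-type AS summary, the lncRNA Venn partition, the Ks peak
#' and dating, expression concordance, and planted-truth recovery metrics
#' (precision/recall per stage).
#'
#' @param sim_config a [simulation_config()].
#' @param outdir output directory.
#' @param params optional per-stage parameter overrides: `flnc`
#'   (classify_read parameters), `collapse` (fuzz_end, mono_overlap),
#'   `refine` (min_exonic_overlap, orf_min_codons), `kswgd` (window, bw),
#'   `rate` (substitution rate per site per year).
#' @param overwrite allow writing into a non-empty directory.
#' @return object of class `isoforge_report`.
#' @export
run_pipeline <- function(sim_config, outdir, params = list(), overwrite = FALSE) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite)
    stop("outdir is not empty; pass overwrite = TRUE to rerun")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  simdir <- file.path(outdir, "sim")
  stage_log("simulate", "seed %d -> %s", sim_config$seed, simdir)
  truth <- generate_dataset(sim_config, simdir, overwrite = TRUE)
  files <- attr(truth, "files")
  artifacts <- character(0)
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  # ---- FLNC --------------------------------------------------------------
  flnc_par <- params$flnc %||% list()
  records <- do.call(classify_reads,
                     c(list(files$reads, sim_config$primer5, sim_config$primer3),
                       flnc_par))
  summ <- summarize_library(records, library_id = "synthetic")
  total <- aggregate_summaries(list(summ))
  keep(write_tsv(records[, setdiff(names(records), "insert_sequence")],
                 file.path(outdir, "flnc_records.tsv")))
  keep(write_library_summaries(list(summ, total), file.path(outdir, "flnc_summary.tsv")))
  pred_class <- ifelse(records$klass == "full_length_chimeric", "chimeric",
                       records$klass)
  flnc_acc <- mean(pred_class == truth$read_labels[records$read_id])
  stage_log("flnc", "%d reads, %d FLNC, truth accuracy %.3f",
            total$n_reads_of_insert, total$n_flnc, flnc_acc)

  # ---- models, collapse, stats --------------------------------------------
  aln <- parse_models(files$alignments, format = "bed12")
  ann <- parse_models(files$annotation, format = "gff3")
  col_par <- params$collapse %||% list()
  collapsed <- do.call(collapse_by_intron_chain, c(list(aln), col_par))
  counts_df <- read.delim(files$counts, check.names = FALSE)
  cmat <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(cmat) <- counts_df$transcript_id
  iso_seq <- Biostrings::readDNAStringSet(files$isoforms)
  lens <- setNames(Biostrings::width(iso_seq), names(iso_seq))
  em <- expression_matrix(cmat, lens)
  aln_tx <- sort(unique(aln$transcript_id))
  stats <- compute_stats(transcript_models(as.data.frame(aln)),
                         expression = rowMeans(em$tpm)[aln_tx])
  keep(write_tsv(as.data.frame(unclass(stats)), file.path(outdir, "assembly_stats.tsv")))
  stage_log("collapse", "%d alignments -> %d models; N50 %d",
            length(aln_tx), length(unique(collapsed$transcript_id)), stats$n50)

  # ---- annotation refinement ----------------------------------------------
  ref_par <- params$refine %||% list()
  merges <- detect_split_genes(aln, ann,
                               min_exonic_overlap = ref_par$min_exonic_overlap %||% 30)
  keep(write_tsv(merges$proposals, file.path(outdir, "merge_proposals.tsv")))
  unaligned <- setdiff(names(iso_seq), unique(aln$transcript_id))
  novel <- classify_novel_isoforms(aln, unaligned, ann)
  keep(write_tsv(novel$calls, file.path(outdir, "novel_calls.tsv")))
  novel_aligned <- novel$calls$transcript_id[novel$calls$category != "unmapped"]
  profile <- if (length(novel_aligned))
    intron_count_profile(
      transcript_models(as.data.frame(aln[aln$transcript_id %in% novel_aligned, ])),
      transcript_models(as.data.frame(aln)))
  else NULL
  homology <- read.delim(files$homology)
  novel_ids <- novel$calls$transcript_id
  lnc <- call_lncrna(setNames(as.character(iso_seq[novel_ids]), novel_ids),
                     homology[homology$transcript_id %in% novel_ids, ],
                     orf_min_codons = ref_par$orf_min_codons %||% 100L)
  keep(write_tsv(lnc$calls, file.path(outdir, "lncrna_calls.tsv")))
  keep(write_tsv(data.frame(class = names(lnc$venn), count = as.integer(lnc$venn)),
                 file.path(outdir, "lncrna_venn.tsv")))
  stage_log("refine", "%d split genes in %d merges; %d novel; %d lncRNA",
            merges$n_split_genes, merges$n_merged, novel$totals[["novel_total"]],
            lnc$venn[["lncRNA_total"]])

  # ---- AS events -----------------------------------------------------------
  events <- enumerate_events_by_locus(ann)
  as_sum <- summarize_events(events)
  keep(write_tsv(events, file.path(outdir, "as_events.tsv")))
  keep(write_tsv(data.frame(type = names(as_sum$counts),
                            count = as.integer(as_sum$counts),
                            percent = as.integer(as_sum$percent)),
                 file.path(outdir, "as_summary.tsv")))
  stage_log("asevents", "%d events (%s)", as_sum$total,
            paste(sprintf("%s=%d", names(as_sum$counts), as_sum$counts),
                  collapse = ", "))

  # ---- Ks / WGD -------------------------------------------------------------
  ks_par <- params$kswgd %||% list()
  est <- ng86_pairs(files$pairs)
  keep(write_tsv(est, file.path(outdir, "ks_estimates.tsv")))
  peak <- ks_distribution_peak(est$Ks, window = ks_par$window %||% c(0.05, 2),
                               bw = ks_par$bw %||% "nrd0",
                               min_pairs = ks_par$min_pairs %||% 30L)
  rate <- params$rate %||% 6.5e-9
  wgd_mya <- ks_to_time(peak$mode_ks, rate) / 1e6
  keep(write_tsv(data.frame(mode_ks = peak$mode_ks,
                            n_pairs_used = peak$n_pairs_used,
                            bandwidth = peak$bandwidth, rate = rate,
                            wgd_time_mya = wgd_mya),
                 file.path(outdir, "ks_peak.tsv")))
  stage_log("kswgd", "Ks peak %.3f -> %.2f MYA", peak$mode_ks, wgd_mya)

  # ---- expression -----------------------------------------------------------
  grouping <- read.delim(files$grouping)
  pcc <- replicate_pcc(em)
  gene_iso <- split(ann$transcript_id[!duplicated(ann$transcript_id)],
                    ann$gene_id[!duplicated(ann$transcript_id)])
  gene_iso <- lapply(gene_iso, function(x) intersect(x, rownames(em$counts)))
  gene_iso <- gene_iso[lengths(gene_iso) > 0]
  reps <- representative_isoform(gene_iso, em)
  prof <- tissue_profile(em, grouping, transcripts = unname(reps))
  keep(write_tsv(data.frame(transcript_id = rownames(em$tpm),
                            round(em$tpm, 4), check.names = FALSE),
                 file.path(outdir, "tpm.tsv")))
  keep(write_tsv(data.frame(sample = rownames(pcc$r), round(pcc$r, 4),
                            check.names = FALSE),
                 file.path(outdir, "pcc.tsv")))
  keep(write_tsv(data.frame(gene_id = names(reps), transcript_id = unname(reps)),
                 file.path(outdir, "representative_isoforms.tsv")))
  keep(write_tsv(data.frame(transcript_id = rownames(prof), round(prof, 4),
                            check.names = FALSE),
                 file.path(outdir, "tissue_profile.tsv")))
  stage_log("expression", "%d transcripts x %d samples; median replicate r %.3f",
            nrow(em$counts), ncol(em$counts),
            median(pcc$r[upper.tri(pcc$r)], na.rm = TRUE))

  # ---- planted-truth recovery ----------------------------------------------
  truth_labels <- truth$read_labels[records$read_id]
  comp_pred <- lapply(seq_len(nrow(merges$proposals)), function(i)
    sort(strsplit(merges$proposals$genes[i], ",")[[1]]))
  comp_truth <- lapply(truth$split_components, sort)
  key <- function(l) vapply(l, paste, character(1), collapse = "|")
  nv_pred <- setNames(novel$calls$category, novel$calls$transcript_id)
  nv_truth <- truth$novel_categories
  lnc_pred <- lnc$calls$transcript_id[lnc$calls$venn_class != "neither"]
  ev_key <- function(df) paste(df$type %||% df$event_type, df$chrom, df$strand,
                               df$var_start, df$var_end)
  five <- events[events$event_type %in% AS_TYPES, , drop = FALSE]
  recovery <- rbind(
    data.frame(task = "flnc_class", precision = mean(pred_class == truth_labels),
               recall = mean(pred_class == truth_labels)),
    data.frame(task = "split_components", t(prec_recall(key(comp_pred), key(comp_truth)))),
    data.frame(task = "novel_categories",
               t(prec_recall(paste(names(nv_pred), nv_pred),
                             paste(names(nv_truth), nv_truth)))),
    data.frame(task = "lncrna_noncoding", t(prec_recall(lnc_pred, truth$noncoding_ids))),
    data.frame(task = "as_events", t(prec_recall(ev_key(five), ev_key(truth$planted_events)))))
  keep(write_tsv(recovery, file.path(outdir, "recovery.tsv")))

  # ---- manifest and report --------------------------------------------------
  artifacts <- c(unlist(files, use.names = FALSE), artifacts)
  manifest <- data.frame(file = sub(paste0("^", outdir, "/?"), "", artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  report <- structure(list(
    library_summary = total,
    flnc_accuracy = flnc_acc,
    assembly_stats = stats,
    merges = merges[c("n_split_genes", "n_merged")],
    novel_totals = novel$totals,
    lncrna_venn = lnc$venn,
    as_summary = as_sum,
    intron_profile = profile,
    ks_peak = peak,
    wgd_time_mya = wgd_mya,
    replicate_pcc_median = median(pcc$r[upper.tri(pcc$r)], na.rm = TRUE),
    recovery = recovery,
    manifest = manifest,
    outdir = outdir
  ), class = "isoforge_report")
  jsonlite::write_json(report[setdiff(names(report), c("as_summary",
    "library_summary", "assembly_stats", "ks_peak", "intron_profile"))],
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.isoforge_report <- function(x, ...) {
  cat("== isoforge pipeline report ==\n\n")
  print(x$library_summary)
  cat(sprintf("\nFLNC truth accuracy: %.3f\n", x$flnc_accuracy))
  print(x$assembly_stats)
  cat(sprintf("Split genes: %d mergeable into %d\n",
              x$merges$n_split_genes, x$merges$n_merged))
  cat("Novel isoforms:", paste(sprintf("%s=%d", names(x$novel_totals),
                                       x$novel_totals), collapse = ", "), "\n")
  cat("lncRNA Venn:", paste(sprintf("%s=%d", names(x$lncrna_venn),
                                    x$lncrna_venn), collapse = ", "), "\n\n")
  print(x$as_summary)
  cat("\n")
  print(x$ks_peak)
  cat(sprintf("WGD time: %.2f MYA\n", x$wgd_time_mya))
  cat(sprintf("Median replicate Pearson r: %.3f\n", x$replicate_pcc_median))
  cat("\nPlanted-truth recovery:\n")
  print(x$recovery, row.names = FALSE)
  invisible(x)
}
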