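# Long-read-driven annotation refinement: split-gene merge proposals, novel
# isoform triage (unmapped / intronic / intergenic), intron-count profiles,
# and two-channel lncRNA calling.

## per-gene reduced exonic intervals, keyed by gene; returns a data.frame
gene_exonic_union <- function(annotation) {
  out <- lapply(split(as.data.frame(annotation), annotation$gene_id), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## total overlap (bp) between exon table `ex` and interval rows `iv`
exonic_overlap_bp <- function(ex, iv) {
  if (!nrow(iv)) return(0)
  tot <- 0
  for (i in seq_len(nrow(ex))) {
    ov <- pmin(ex$end[i], iv$end) - pmax(ex$start[i], iv$start)
    tot <- tot + sum(ov[ov > 0])
  }
  tot
}

#' Detect split genes spanned by single long-read alignments
#'
#' A transcript alignment supports merging a set of annotated genes when its
#' exons overlap the exonic bases of two or more same-strand genes, each by
#' at least `min_exonic_overlap` bp. Merge proposals are the connected
#' components of the resulting gene-gene support graph, so chains (one read
#' spanning A-B, another B-C) merge transitively.
#'
#' @param alignments `transcript_models` of long-read alignments.
#' @param annotation `transcript_models` of the current annotation with
#'   gene_id set.
#' @param min_exonic_overlap minimum exonic overlap per spanned gene (bp).
#' @param min_support minimum number of supporting transcripts per gene pair.
#' @return list with `proposals` (data.frame: component, genes
#'   (comma-separated), n_genes, supporting_transcripts, chrom, strand,
#'   start, end), `n_split_genes` (genes involved) and `n_merged`
#'   (components).
#' @export
detect_split_genes <- function(alignments, annotation, min_exonic_overlap = 30,
                               min_support = 1L) {
  if (all(is.na(annotation$gene_id)))
    stop("annotation must group transcripts by gene_id")
  gu <- gene_exonic_union(annotation)
  sp <- tm_split(alignments)
  edges <- list()
  for (tx_id in names(sp)) {
    ex <- sp[[tx_id]]
    cand <- gu[gu$chrom == ex$chrom[1] & gu$strand == ex$strand[1] &
               gu$start < max(ex$end) & gu$end > min(ex$start), , drop = FALSE]
    if (!nrow(cand)) next
    ov <- vapply(split(cand, cand$gene_id), function(iv) exonic_overlap_bp(ex, iv),
                 numeric(1))
    hit <- names(ov)[ov >= min_exonic_overlap]
    if (length(hit) >= 2L) {
      pairs <- utils::combn(sort(hit), 2L)
      for (k in seq_len(ncol(pairs)))
        edges[[length(edges) + 1L]] <- data.frame(
          a = pairs[1, k], b = pairs[2, k], tx = tx_id, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(component = integer(0), genes = character(0),
                      n_genes = integer(0), supporting_transcripts = character(0),
                      chrom = character(0), strand = character(0),
                      start = numeric(0), end = numeric(0))
  if (!length(edges))
    return(list(proposals = empty, n_split_genes = 0L, n_merged = 0L))
  ed <- do.call(rbind, edges)
  supp <- stats::aggregate(tx ~ a + b, data = ed, FUN = function(x) length(unique(x)))
  supp <- supp[supp$tx >= min_support, , drop = FALSE]
  if (!nrow(supp))
    return(list(proposals = empty, n_split_genes = 0L, n_merged = 0L))
  g <- igraph::graph_from_data_frame(supp[, c("a", "b")], directed = FALSE)
  comp <- igraph::components(g)
  keep_pair <- paste(supp$a, supp$b)
  ed <- ed[paste(ed$a, ed$b) %in% keep_pair, , drop = FALSE]
  props <- lapply(seq_len(comp$no), function(ci) {
    genes <- sort(names(comp$membership)[comp$membership == ci])
    sub <- gu[gu$gene_id %in% genes, , drop = FALSE]
    txs <- sort(unique(ed$tx[ed$a %in% genes | ed$b %in% genes]))
    data.frame(component = ci, genes = paste(genes, collapse = ","),
               n_genes = length(genes),
               supporting_transcripts = paste(txs, collapse = ","),
               chrom = sub$chrom[1], strand = sub$strand[1],
               start = min(sub$start), end = max(sub$end),
               stringsAsFactors = FALSE)
  })
  proposals <- do.call(rbind, props)
  list(proposals = proposals,
       n_split_genes = sum(proposals$n_genes),
       n_merged = nrow(proposals))
}

#' Triage novel isoforms into unmapped / intronic / intergenic
#'
#' An aligned isoform overlapping annotated exons on its own strand is not
#' novel and receives no call. Otherwise it is `intronic` when it lies
#' entirely within a single intron of a same-strand gene, and `intergenic`
#' otherwise; exonic overlap on the opposite strand is retained as
#' `antisense_flag` on intergenic calls. Isoforms named in `unaligned_ids`
#' are `unmapped`.
#'
#' @param alignments `transcript_models` of aligned isoforms.
#' @param unaligned_ids character vector of isoform ids that failed to align.
#' @param annotation `transcript_models` of annotated genes (gene_id set).
#' @return list with `calls` (data.frame: transcript_id, category,
#'   nearest_gene, antisense_flag) and `totals` (named counts per category
#'   plus `novel_total`).
#' @export
classify_novel_isoforms <- function(alignments, unaligned_ids, annotation) {
  if (length(intersect(unaligned_ids, unique(alignments$transcript_id))))
    stop("unaligned_ids must be disjoint from aligned transcript ids")
  gu <- gene_exonic_union(annotation)
  gene_tbl <- tm_transcripts(annotation)
  gene_span <- do.call(rbind, lapply(split(gene_tbl, gene_tbl$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end), stringsAsFactors = FALSE)))
  sp <- tm_split(alignments)
  calls <- list()
  for (tx_id in names(sp)) {
    ex <- sp[[tx_id]]
    chrom <- ex$chrom[1]; strand <- ex$strand[1]
    t0 <- min(ex$start); t1 <- max(ex$end)
    same <- gu[gu$chrom == chrom & gu$strand == strand, , drop = FALSE]
    anti <- gu[gu$chrom == chrom & gu$strand != strand, , drop = FALSE]
    if (exonic_overlap_bp(ex, same) > 0) next  # known exonic structure
    # intronic: contained in one intron of one gene (either strand; the
    # criterion "maps to introns of genes" is positional)
    host <- NA_character_; host_strand <- NA_character_
    gs_chr0 <- gene_span[gene_span$chrom == chrom, , drop = FALSE]
    within <- gs_chr0[gs_chr0$start <= t0 & gs_chr0$end >= t1, , drop = FALSE]
    for (gi in seq_len(nrow(within))) {
      g <- within$gene_id[gi]
      iv <- gu[gu$gene_id == g, , drop = FALSE]
      iv <- iv[order(iv$start), ]
      if (nrow(iv) < 2L) next
      introns <- cbind(iv$end[-nrow(iv)], iv$start[-1])
      if (any(introns[, 1] <= t0 & introns[, 2] >= t1)) {
        host <- g; host_strand <- within$strand[gi]; break
      }
    }
    if (!is.na(host)) {
      calls[[length(calls) + 1L]] <- data.frame(
        transcript_id = tx_id, category = "intronic", nearest_gene = host,
        antisense_flag = host_strand != strand, stringsAsFactors = FALSE)
      next
    }
    gs_chr <- gene_span[gene_span$chrom == chrom, , drop = FALSE]
    nearest <- if (nrow(gs_chr)) {
      d <- pmax(gs_chr$start - t1, t0 - gs_chr$end, 0)
      gs_chr$gene_id[which.min(d)]
    } else NA_character_
    calls[[length(calls) + 1L]] <- data.frame(
      transcript_id = tx_id, category = "intergenic", nearest_gene = nearest,
      antisense_flag = exonic_overlap_bp(ex, anti) > 0, stringsAsFactors = FALSE)
  }
  for (tx_id in unaligned_ids)
    calls[[length(calls) + 1L]] <- data.frame(
      transcript_id = tx_id, category = "unmapped", nearest_gene = NA_character_,
      antisense_flag = FALSE, stringsAsFactors = FALSE)
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(transcript_id = character(0), category = character(0),
               nearest_gene = character(0), antisense_flag = logical(0))
  totals <- c(unmapped = sum(calls$category == "unmapped"),
              intronic = sum(calls$category == "intronic"),
              intergenic = sum(calls$category == "intergenic"))
  list(calls = calls, totals = c(totals, novel_total = sum(totals)))
}

#' Category totals for a novel-isoform trichotomy
#'
#' @param counts named counts with names among unmapped, intronic,
#'   intergenic.
#' @return the counts plus `novel_total`, their sum.
#' @export
novel_isoform_totals <- function(counts) {
  bad <- setdiff(names(counts), c("unmapped", "intronic", "intergenic"))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  c(counts, novel_total = sum(counts))
}

#' Intron-count profiles of two model sets
#'
#' @param models_a,models_b `transcript_models` tables (e.g. novel
#'   transcripts vs all transcripts).
#' @return list with `freq_a`, `freq_b` (named relative frequencies per
#'   intron count) and `mean_a`, `mean_b`.
#' @export
intron_count_profile <- function(models_a, models_b) {
  ic <- function(models) {
    n <- tm_transcripts(models)$n_exons - 1L
    if (!length(n)) stop("empty model set")
    n
  }
  a <- ic(models_a); b <- ic(models_b)
  list(freq_a = table(a) / length(a), freq_b = table(b) / length(b),
       mean_a = mean(a), mean_b = mean(b))
}

## longest AUG-initiated stop-free reading frame (codons, including the AUG),
## over both strands and all three frames
longest_orf_codons <- function(seq) {
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(v)
    for (off in 0:2) {
      k <- (n - off) %/% 3L
      if (k < 1L) next
      idx <- off + seq_len(k * 3L)
      cods <- paste0(v[idx[c(TRUE, FALSE, FALSE)]],
                     v[idx[c(FALSE, TRUE, FALSE)]],
                     v[idx[c(FALSE, FALSE, TRUE)]])
      starts <- which(cods == "ATG")
      if (!length(starts)) next
      stops <- which(cods %in% c("TAA", "TAG", "TGA"))
      for (st in starts) {
        nxt <- stops[stops > st]
        len <- if (length(nxt)) nxt[1] - st else k - st + 1L
        if (len > best) best <- len
      }
    }
  }
  best
}

#' Two-channel lncRNA calling with Venn partition
#'
#' Channel 1 (homology): an externally supplied hit/no-hit flag per isoform
#' (e.g. from a protein-database search). Channel 2 (coding potential): an
#' isoform is `coding` iff its longest AUG-initiated stop-free reading frame,
#' over both strands and all three frames, has at least `orf_min_codons`
#' codons. The lncRNA set is the union of isoforms called non-coding by
#' either channel; its Venn partition separates homology-only,
#' potential-only and both.
#'
#' @param isoform_sequences named character vector of isoform sequences.
#' @param homology_flags data.frame with columns transcript_id and hit (0/1
#'   or logical), covering all sequences.
#' @param orf_min_codons minimum ORF length, in codons, to call coding.
#' @return list with `calls` (data.frame: transcript_id, channel_homology,
#'   channel_coding_potential, venn_class) and `venn` (named counts:
#'   homology_only, potential_only, both, neither, lncRNA_total).
#' @export
call_lncrna <- function(isoform_sequences, homology_flags, orf_min_codons = 100L) {
  if (is.null(names(isoform_sequences))) stop("sequences must be named")
  if (any(grepl("[^ACGTNacgtn]", isoform_sequences)))
    stop("sequence with non-IUPAC characters")
  hv <- setNames(as.logical(homology_flags$hit), homology_flags$transcript_id)
  miss <- setdiff(names(isoform_sequences), names(hv))
  if (length(miss)) stop("homology flags missing for: ", paste(head(miss), collapse = ", "))
  calls <- do.call(rbind, lapply(names(isoform_sequences), function(id) {
    coding <- longest_orf_codons(toupper(isoform_sequences[[id]])) >= orf_min_codons
    hit <- hv[[id]]
    venn <- if (!hit && !coding) "both"
      else if (!hit) "homology_only"
      else if (!coding) "potential_only"
      else "neither"
    data.frame(transcript_id = id,
               channel_homology = if (hit) "hit" else "no_hit",
               channel_coding_potential = if (coding) "coding" else "noncoding",
               venn_class = venn, stringsAsFactors = FALSE)
  }))
  venn <- c(homology_only = sum(calls$venn_class == "homology_only"),
            potential_only = sum(calls$venn_class == "potential_only"),
            both = sum(calls$venn_class == "both"),
            neither = sum(calls$venn_class == "neither"))
  list(calls = calls, venn = c(venn, lncRNA_total = sum(venn[1:3])))
}

#' Venn totals for two-channel lncRNA counts
#'
#' @param counts named counts with names among homology_only, potential_only,
#'   both (and optionally neither, ignored for the total).
#' @return the counts plus `lncRNA_total`, the size of the lncRNA union.
#' @export
lncrna_venn_totals <- function(counts) {
  need <- c("homology_only", "potential_only", "both")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing classes: ", paste(miss, collapse = ", "))
  c(counts, lncRNA_total = sum(counts[need]))
}
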