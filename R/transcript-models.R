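# Transcript models: a plain exon table with one row per exon.
#
# Internal coordinates are 0-based half-open throughout the package; GFF3 is
# converted to/from 1-based inclusive and BED12 to/from 0-based half-open at
# the I/O boundary only.

#' Construct a transcript-model table
#'
#' @param df data.frame with columns transcript_id, gene_id (may be NA),
#'   chrom, strand ("+"/"-"), start, end. Coordinates 0-based half-open.
#' @return data.frame of class `transcript_models`, exons sorted by
#'   transcript and start.
#' @export
transcript_models <- function(df) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  if (any(df$end <= df$start)) stop("exon with end <= start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  # exons of one transcript must be pairwise disjoint
  by_tx <- split(df, df$transcript_id)
  for (tx in by_tx) {
    if (nrow(tx) > 1L && any(tx$start[-1] < tx$end[-nrow(tx)]))
      stop("overlapping exons in transcript ", tx$transcript_id[1])
  }
  class(df) <- c("transcript_models", "data.frame")
  df
}

## list of per-transcript exon tables (ordered by start)
tm_split <- function(models) split(as.data.frame(models), models$transcript_id)

## per-transcript summary table
tm_transcripts <- function(models) {
  sp <- tm_split(models)
  do.call(rbind, lapply(sp, function(tx) data.frame(
    transcript_id = tx$transcript_id[1], gene_id = tx$gene_id[1],
    chrom = tx$chrom[1], strand = tx$strand[1],
    start = min(tx$start), end = max(tx$end),
    n_exons = nrow(tx), length = sum(tx$end - tx$start),
    stringsAsFactors = FALSE)))
}

## introns as a (start, end) matrix in genomic order; 0 rows for mono-exon
tm_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(matrix(numeric(0), ncol = 2))
  cbind(exons$end[-n], exons$start[-1])
}

intron_chain_key <- function(exons) {
  intr <- tm_introns(exons)
  paste(paste(intr[, 1], intr[, 2], sep = "-"), collapse = ",")
}

#' Read transcript models from GFF3 or BED12
#'
#' Files are parsed with rtracklayer and converted to internal 0-based
#' half-open coordinates. GFF3 is expected to follow the gene -> mRNA ->
#' exon hierarchy; BED12 blocks become exons (gene_id is NA).
#'
#' @param path file path.
#' @param format "auto" (by extension), "gff3" or "bed12".
#' @return a `transcript_models` table.
#' @export
parse_models <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed12" else "gff3"
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    typ <- as.character(gr$type)
    tx2gene <- character(0)
    is_tx <- typ %in% c("mRNA", "transcript")
    if (any(is_tx)) {
      par <- vapply(gr$Parent[is_tx],
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
      tx2gene <- setNames(par, gr$ID[is_tx])
    }
    ex <- gr[typ == "exon"]
    if (length(ex) == 0L) stop("no exon records in ", path)
    parent <- vapply(ex$Parent,
                     function(p) if (length(p)) p[[1]] else NA_character_,
                     character(1))
    df <- data.frame(
      transcript_id = parent,
      gene_id = unname(tx2gene[parent]),
      chrom = as.character(GenomicRanges::seqnames(ex)),
      strand = as.character(GenomicRanges::strand(ex)),
      start = GenomicRanges::start(ex) - 1L,  # 1-based incl -> 0-based half-open
      end = GenomicRanges::end(ex),
      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    bl <- rtracklayer::blocks(gr)
    nm <- if (!is.null(gr$name)) gr$name else sprintf("tx_%05d", seq_along(gr))
    names(bl) <- nm
    ub <- unlist(bl, use.names = TRUE)
    df <- data.frame(
      transcript_id = names(ub),
      gene_id = NA_character_,
      chrom = as.character(GenomicRanges::seqnames(ub)),
      strand = as.character(GenomicRanges::strand(ub)),
      start = GenomicRanges::start(ub) - 1L,
      end = GenomicRanges::end(ub),
      stringsAsFactors = FALSE)
    df$strand[df$strand == "*"] <- "+"
  }
  transcript_models(df)
}

#' Write transcript models to GFF3 or BED12
#'
#' @param models a `transcript_models` table.
#' @param path output path.
#' @param format "gff3" or "bed12".
#' @param source source tag for GFF3 column 2.
#' @export
write_models <- function(models, path, format = c("gff3", "bed12"),
                         source = "isoforge") {
  format <- match.arg(format)
  txs <- tm_transcripts(models)
  if (format == "gff3") {
    lines <- c("##gff-version 3")
    gene_of <- ifelse(is.na(txs$gene_id), paste0(txs$transcript_id, ".gene"),
                      txs$gene_id)
    # gene records span their transcripts
    genes <- split(seq_len(nrow(txs)), gene_of)
    gdf <- do.call(rbind, lapply(names(genes), function(g) {
      i <- genes[[g]]
      data.frame(gene_id = g, chrom = txs$chrom[i[1]], strand = txs$strand[i[1]],
                 start = min(txs$start[i]), end = max(txs$end[i]),
                 stringsAsFactors = FALSE)
    }))
    gdf <- gdf[order(gdf$chrom, gdf$start, gdf$gene_id), ]
    sp <- tm_split(models)
    for (k in seq_len(nrow(gdf))) {
      g <- gdf[k, ]
      lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                                g$chrom, source, g$start + 1L, g$end, g$strand, g$gene_id))
      ti <- which(gene_of == g$gene_id)
      ti <- ti[order(txs$start[ti], txs$transcript_id[ti])]
      for (i in ti) {
        tx <- txs[i, ]
        lines <- c(lines, sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                  tx$chrom, source, tx$start + 1L, tx$end,
                                  tx$strand, tx$transcript_id, g$gene_id))
        ex <- sp[[tx$transcript_id]]
        lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                  ex$chrom, source, ex$start + 1L, ex$end,
                                  ex$strand, tx$transcript_id))
      }
    }
    writeLines(lines, path)
  } else {
    sp <- tm_split(models)
    gr <- GenomicRanges::GRanges(
      seqnames = txs$chrom,
      ranges = IRanges::IRanges(start = txs$start + 1L, end = txs$end),
      strand = txs$strand)
    gr$name <- txs$transcript_id
    gr$score <- 0L
    gr$thick <- IRanges::ranges(gr)
    gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(txs)), function(i) {
      ex <- sp[[txs$transcript_id[i]]]
      IRanges::IRanges(start = ex$start - txs$start[i] + 1L,
                       end = ex$end - txs$start[i])
    }))
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

## single-linkage components over an edge predicate within a small group
sl_components <- function(n, edge_fun) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    if (edge_fun(i, j)) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <- ri }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse redundant isoforms by intron chain
#'
#' Multi-exon models on the same chromosome and strand with identical intron
#' chains are merged (single linkage over models whose 5' and 3' terminal
#' ends each differ by at most `fuzz_end`) into one representative spanning
#' the extremal ends. Mono-exon models merge when their reciprocal overlap is
#' at least `mono_overlap`. The union of exonic bases is unchanged.
#'
#' @param models a `transcript_models` table.
#' @param fuzz_end terminal-end tolerance in bp (Inf to merge all
#'   identical-chain models regardless of end variation).
#' @param mono_overlap reciprocal-overlap threshold for mono-exon models.
#' @return a collapsed `transcript_models` table; representative transcript
#'   ids are those of the longest member of each merge group (ties broken
#'   lexicographically).
#' @export
collapse_by_intron_chain <- function(models, fuzz_end = 50, mono_overlap = 0.95) {
  txs <- tm_transcripts(models)
  sp <- tm_split(models)
  txs$chain <- vapply(sp[txs$transcript_id], intron_chain_key, character(1))
  txs$multi <- txs$n_exons > 1L
  out <- list()
  grp_key <- ifelse(txs$multi,
                    paste("M", txs$chrom, txs$strand, txs$chain),
                    paste("S", txs$chrom, txs$strand))
  for (g in split(seq_len(nrow(txs)), grp_key)) {
    sub <- txs[g, , drop = FALSE]
    n <- nrow(sub)
    if (sub$multi[1]) {
      comp <- sl_components(n, function(i, j)
        abs(sub$start[i] - sub$start[j]) <= fuzz_end &&
        abs(sub$end[i] - sub$end[j]) <= fuzz_end)
    } else {
      comp <- sl_components(n, function(i, j) {
        ov <- min(sub$end[i], sub$end[j]) - max(sub$start[i], sub$start[j])
        ov >= mono_overlap * (sub$end[i] - sub$start[i]) &&
          ov >= mono_overlap * (sub$end[j] - sub$start[j])
      })
    }
    for (members in split(seq_len(n), comp)) {
      m <- sub[members, , drop = FALSE]
      rep_i <- members[order(-m$length, m$transcript_id)[1]]
      rep_id <- sub$transcript_id[rep_i]
      ex <- sp[[rep_id]]
      ex$start[1] <- min(m$start)
      ex$end[nrow(ex)] <- max(m$end)
      out[[length(out) + 1L]] <- ex
    }
  }
  res <- do.call(rbind, out)
  transcript_models(res)
}

## N50: largest length L such that transcripts of length >= L sum to at least
## half the total length (descending cumulative sum)
n50_value <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length set")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= sum(s) / 2)[1]]
}

#' Assembly completeness statistics (N50, Ex90N50)
#'
#' N50 is the length-weighted median transcript length. Ex90N50 is the N50
#' restricted to the smallest expression-ranked transcript set accounting for
#' at least 90% of total expression.
#'
#' @param models a `transcript_models` table.
#' @param expression optional non-negative expression vector (e.g. TPM),
#'   aligned with the transcripts of `models` (sorted by transcript_id).
#' @return object of class `assembly_stats`: n_transcripts, max_length, n50,
#'   ex90n50 (NA without expression).
#' @export
compute_stats <- function(models, expression = NULL) {
  txs <- tm_transcripts(models)
  lens <- txs$length
  ex90 <- NA_real_
  if (!is.null(expression)) {
    if (length(expression) != nrow(txs))
      stop("expression must have one value per transcript")
    if (any(expression < 0)) stop("expression must be non-negative")
    if (sum(expression) > 0) {
      o <- order(expression, decreasing = TRUE)
      cs <- cumsum(expression[o])
      k <- which(cs >= 0.9 * sum(expression))[1]
      ex90 <- n50_value(lens[o[seq_len(k)]])
    }
  }
  structure(list(n_transcripts = nrow(txs), max_length = max(lens),
                 n50 = n50_value(lens), ex90n50 = ex90),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("Assembly stats: %d transcripts, max %d bp, N50 %d bp, Ex90N50 %s\n",
              x$n_transcripts, x$max_length, x$n50,
              if (is.na(x$ex90n50)) "NA" else paste0(x$ex90n50, " bp")))
  invisible(x)
}
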