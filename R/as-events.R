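# Five-type alternative-splicing event enumeration between isoforms of a
# locus: exon skipping (ES), intron retention (IR), alternative 5'/3' splice
# site (A5/A3), and alternative (mutually exclusive) exon (AE). Alternative
# first/last exons (AF/AL) are detected but reported separately and excluded
# from five-type totals.

AS_TYPES <- c("ES", "IR", "A5", "A3", "AE")

as_event_row <- function(type, chrom, strand, anchors, var_start, var_end, w1, w2) {
  data.frame(event_type = type, chrom = chrom, strand = strand,
             anchors = anchors, var_start = var_start, var_end = var_end,
             witness1 = w1, witness2 = w2, stringsAsFactors = FALSE)
}

## events produced by the ordered isoform pair (X, Y); directional types
## (ES: exon of X skipped in Y; IR: intron of Y retained in X) are handled by
## calling with both orders and deduplicating on the anchor key.
pair_as_events <- function(ex_x, ex_y, chrom, strand, id_x, id_y) {
  out <- list()
  ix <- tm_introns(ex_x); iy <- tm_introns(ex_y)
  exon_set_y <- paste(ex_y$start, ex_y$end)
  add <- function(...) out[[length(out) + 1L]] <<- as_event_row(...)

  # --- A5 / A3: intron pairs sharing one boundary ------------------------
  if (nrow(ix) && nrow(iy)) {
    for (i in seq_len(nrow(ix))) for (j in seq_len(nrow(iy))) {
      a <- ix[i, ]; b <- iy[j, ]
      if (a[1] == b[1] && a[2] == b[2]) next
      share_end <- a[2] == b[2] && a[1] != b[1]
      share_start <- a[1] == b[1] && a[2] != b[2]
      if (!share_end && !share_start) next
      # the two variable-side flanking exons must overlap, otherwise the
      # variation is an alternative first/last exon, not a splice-site shift
      if (share_end) {
        exl_x <- ex_x[ex_x$end == a[1], , drop = FALSE]
        exl_y <- ex_y[ex_y$end == b[1], , drop = FALSE]
        if (!nrow(exl_x) || !nrow(exl_y)) next
        if (min(exl_x$end[1], exl_y$end[1]) <= max(exl_x$start[1], exl_y$start[1])) next
        type <- if (strand == "+") "A5" else "A3"
        co <- sort(c(a[1], b[1]))
        add(type, chrom, strand,
            sprintf("%s:%d|%d-%d", type, a[2], co[1], co[2]),
            co[1], co[2], id_x, id_y)
      } else {
        exr_x <- ex_x[ex_x$start == a[2], , drop = FALSE]
        exr_y <- ex_y[ex_y$start == b[2], , drop = FALSE]
        if (!nrow(exr_x) || !nrow(exr_y)) next
        if (min(exr_x$end[1], exr_y$end[1]) <= max(exr_x$start[1], exr_y$start[1])) next
        type <- if (strand == "+") "A3" else "A5"
        co <- sort(c(a[2], b[2]))
        add(type, chrom, strand,
            sprintf("%s:%d|%d-%d", type, a[1], co[1], co[2]),
            co[1], co[2], id_x, id_y)
      }
    }
  }

  # --- ES: internal exon of X absent from Y, flanks spliced directly -----
  nx <- nrow(ex_x)
  if (nx >= 3L && nrow(iy)) {
    for (k in 2:(nx - 1L)) {
      p <- ex_x$end[k - 1L]; q <- ex_x$start[k]
      r <- ex_x$end[k]; s <- ex_x$start[k + 1L]
      if (any(iy[, 1] == p & iy[, 2] == s))
        add("ES", chrom, strand, sprintf("ES:%d-%d|%d-%d", p, q, r, s),
            q, r, id_x, id_y)
    }
  }

  # --- IR: intron of Y contained in an exonic block of X -----------------
  if (nrow(iy)) {
    for (j in seq_len(nrow(iy))) {
      d <- iy[j, 1]; a <- iy[j, 2]
      if (any(ex_x$start < d & ex_x$end > a))
        add("IR", chrom, strand, sprintf("IR:%d-%d", d, a), d, a, id_x, id_y)
    }
  }

  # --- AE (mutually exclusive exons) --------------------------------------
  ny <- nrow(ex_y)
  if (nx >= 3L && ny >= 3L) {
    exon_set_x <- paste(ex_x$start, ex_x$end)
    for (k in 2:(nx - 1L)) for (l in 2:(ny - 1L)) {
      p1 <- ex_x$end[k - 1L]; s1 <- ex_x$start[k + 1L]
      p2 <- ex_y$end[l - 1L]; s2 <- ex_y$start[l + 1L]
      if (p1 != p2 || s1 != s2) next
      e1 <- c(ex_x$start[k], ex_x$end[k]); e2 <- c(ex_y$start[l], ex_y$end[l])
      if (min(e1[2], e2[2]) > max(e1[1], e2[1])) next   # exons overlap
      if (paste(e1[1], e1[2]) %in% exon_set_y) next
      if (paste(e2[1], e2[2]) %in% exon_set_x) next
      eo <- if (e1[1] < e2[1]) c(e1, e2) else c(e2, e1)
      add("AE", chrom, strand,
          sprintf("AE:%d|%d-%d|%d-%d|%d", p1, eo[1], eo[2], eo[3], eo[4], s1),
          eo[1], eo[4], id_x, id_y)
    }
  }

  # --- AF / AL (reported separately) --------------------------------------
  if (nrow(ix) && nrow(iy)) {
    fx <- ex_x[1, ]; fy <- ex_y[1, ]
    if (min(fx$end, fy$end) <= max(fx$start, fy$start) && ix[1, 2] == iy[1, 2]) {
      type <- if (strand == "+") "AF" else "AL"
      co <- sort(c(fx$start, fy$start))
      add(type, chrom, strand,
          sprintf("%s:%d|%d-%d", type, ix[1, 2], co[1], co[2]),
          co[1], co[2], id_x, id_y)
    }
    lx <- ex_x[nx, ]; ly <- ex_y[nrow(ex_y), ]
    if (min(lx$end, ly$end) <= max(lx$start, ly$start) &&
        ix[nrow(ix), 1] == iy[nrow(iy), 1]) {
      type <- if (strand == "+") "AL" else "AF"
      co <- sort(c(lx$end, ly$end))
      add(type, chrom, strand,
          sprintf("%s:%d|%d-%d", type, ix[nrow(ix), 1], co[1], co[2]),
          co[1], co[2], id_x, id_y)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Enumerate alternative-splicing events at one locus
#'
#' Pairwise comparison of all isoforms sharing one chromosome and strand.
#' Events are deduplicated by their coordinate signature (type, chromosome,
#' strand, anchors), so each unique local difference is counted once no
#' matter how many isoform pairs witness it. A5/A3 labels are assigned
#' relative to the transcription direction.
#'
#' @param locus_isoforms a `transcript_models` table with >= 2 transcripts on
#'   one chromosome and strand.
#' @return data.frame of events: event_type (ES/IR/A5/A3/AE plus AF/AL
#'   reported separately), chrom, strand, anchors, var_start, var_end,
#'   witness1, witness2. Zero-row when isoforms are structurally identical.
#' @export
enumerate_events <- function(locus_isoforms) {
  sp <- tm_split(locus_isoforms)
  if (length(sp) < 2L) stop("need >= 2 isoforms at a locus")
  chrom <- unique(locus_isoforms$chrom)
  strand <- unique(locus_isoforms$strand)
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("locus isoforms must share one chromosome and strand")
  ids <- names(sp)
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    ev <- pair_as_events(sp[[ids[i]]], sp[[ids[j]]], chrom, strand,
                         ids[i], ids[j])
    if (!is.null(ev)) out[[length(out) + 1L]] <- ev
  }
  if (!length(out))
    return(as_event_row(character(0), character(0), character(0),
                        character(0), numeric(0), numeric(0),
                        character(0), character(0)))
  ev <- do.call(rbind, out)
  ev[!duplicated(paste(ev$chrom, ev$strand, ev$anchors)), , drop = FALSE]
}

#' Enumerate events across many loci
#'
#' Groups isoforms by `gene_id` (loci with a single isoform are skipped) and
#' concatenates per-locus enumerations, deduplicating globally.
#'
#' @param models a `transcript_models` table with gene_id set.
#' @return data.frame as in [enumerate_events()] with a `gene_id` column.
#' @export
enumerate_events_by_locus <- function(models) {
  out <- list()
  for (g in split(as.data.frame(models), models$gene_id)) {
    if (length(unique(g$transcript_id)) < 2L) next
    ev <- enumerate_events(transcript_models(g))
    if (nrow(ev)) { ev$gene_id <- g$gene_id[1]; out[[length(out) + 1L]] <- ev }
  }
  if (!length(out)) {
    ev <- enumerate_events_empty()
    ev$gene_id <- character(0)
    return(ev)
  }
  ev <- do.call(rbind, out)
  ev[!duplicated(paste(ev$chrom, ev$strand, ev$anchors)), , drop = FALSE]
}

enumerate_events_empty <- function() {
  as_event_row(character(0), character(0), character(0), character(0),
               numeric(0), numeric(0), character(0), character(0))
}

#' Summarize alternative-splicing events into per-type counts and percentages
#'
#' @param events either a data.frame from [enumerate_events()] (AF/AL rows
#'   are excluded from the five-type totals) or a named numeric vector of
#'   per-type counts (names among ES, IR, A5, A3, AE).
#' @return object of class `as_summary`: `counts` (named, all five types),
#'   `total`, and `percent` (integer, rounded half-up).
#' @examples
#' summarize_events(c(A5 = 2732, A3 = 4912, AE = 1148, IR = 7666, ES = 2040))
#' @export
summarize_events <- function(events) {
  counts <- setNames(numeric(length(AS_TYPES)), AS_TYPES)
  if (is.data.frame(events)) {
    tb <- table(events$event_type[events$event_type %in% AS_TYPES])
    counts[names(tb)] <- as.numeric(tb)
  } else {
    bad <- setdiff(names(events), AS_TYPES)
    if (length(bad)) stop("unknown event types: ", paste(bad, collapse = ", "))
    counts[names(events)] <- as.numeric(events)
  }
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(counts / total * 100) else counts * 0
  structure(list(counts = counts, total = total, percent = pct),
            class = "as_summary")
}

#' @export
print.as_summary <- function(x, ...) {
  cat("AS events:", format(x$total, big.mark = ","), "total\n")
  for (t in AS_TYPES)
    cat(sprintf("  %-3s %10s  (%d%%)\n", t,
                format(x$counts[[t]], big.mark = ","), x$percent[[t]]))
  invisible(x)
}

#' Per-tissue isoform shares
#'
#' @param per_tissue_counts named non-negative counts (isoforms per tissue).
#' @return named percentages of the total, rounded half-up to 2 decimal
#'   places.
#' @examples
#' tissue_isoform_shares(c(flower = 16224, root = 15084, leaf = 14246,
#'                         stem = 13903, rhizome = 13342))
#' @export
tissue_isoform_shares <- function(per_tissue_counts) {
  if (any(per_tissue_counts < 0)) stop("counts must be >= 0")
  tot <- sum(per_tissue_counts)
  if (tot == 0) stop("all counts are zero")
  round_half_up(per_tissue_counts / tot * 100, 2)
}
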