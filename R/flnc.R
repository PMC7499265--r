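# Full-length non-chimeric (FLNC) read classification.
#
# A full-length read carries the 5' primer near its start, a poly(A) tail and
# the (reverse-complemented) 3' primer near its end; an extra primer copy in
# the interior marks a chimera. Reads below a length cutoff are filtered
# before any structural test, mirroring the usual library-summary ordering
# (short -> non-full-length -> full-length -> FLNC).

## mismatch counts of `pat` against `readv` (char vector) at 0-based offsets
hamming_scan <- function(readv, patv, offsets) {
  np <- length(patv)
  vapply(offsets, function(o) sum(readv[(o + 1L):(o + np)] != patv), integer(1))
}

## greedy backward scan for a poly(A) run ending at 0-based position `end0`
## (exclusive); allows one non-A per 10 bases. Returns run length and 0-based
## start, or NULL.
polya_scan <- function(readv, end0, min_run) {
  i <- end0            # 1-based index of last tail base
  len <- 0L; non_a <- 0L; start <- end0 + 1L
  prev_non_a <- FALSE
  while (i >= 1L) {
    if (readv[i] == "A") {
      len <- len + 1L; start <- i; prev_non_a <- FALSE
    } else {
      # tolerate isolated interruptions (1 per 10 bases); two in a row end
      # the tail so the scan cannot creep into the transcript body
      if (prev_non_a || non_a + 1L > ceiling((len + 1L) / 10)) break
      non_a <- non_a + 1L; len <- len + 1L; start <- i; prev_non_a <- TRUE
    }
    i <- i - 1L
  }
  # trim leading non-A
  while (len > 0L && readv[start] != "A") { start <- start + 1L; len <- len - 1L }
  if (len >= min_run) list(length = len, start0 = start - 1L) else NULL
}

#' Classify one long read by primer and poly(A) structure
#'
#' Searches the 5' primer (Hamming distance <= `max_mismatch`) within the
#' leading `search_window` bases and the reverse complement of the 3' primer
#' within the trailing window; a poly(A) tail is a run of at least
#' `min_polyA_run` A's (one non-A tolerated per 10 bases) immediately
#' upstream of the 3' primer match. Reads shorter than `min_length` are
#' `filtered_short` regardless of structure; full-length reads (all three
#' signals) with an additional interior primer match are
#' `full_length_chimeric`; full-length reads without one are `FLNC`; all
#' other reads are `non_full_length`.
#'
#' @param read read sequence (character).
#' @param primer5,primer3 primer sequences as synthesized (the 3' primer is
#'   searched as its reverse complement).
#' @param max_mismatch maximum Hamming mismatches for a primer match.
#' @param search_window terminal window size (bp) for primer search.
#' @param min_polyA_run minimum poly(A) run length (bp).
#' @param min_length reads shorter than this are filtered out.
#' @param read_id identifier carried into the record.
#' @return a one-row data.frame (an `FlncRecord`): read_id, length,
#'   has_primer5, primer5_offset, has_primer3, primer3_offset, has_polyA,
#'   polyA_start, internal_primer_hits, klass, insert_length,
#'   insert_sequence (NA unless full-length).
#' @export
classify_read <- function(read, primer5, primer3, max_mismatch = 2L,
                          search_window = 100L, min_polyA_run = 20L,
                          min_length = 300L, read_id = NA_character_) {
  if (!nzchar(read)) stop("empty read")
  if (!nzchar(primer5) || !nzchar(primer3)) stop("empty primer")
  readv <- strsplit(toupper(read), "", fixed = TRUE)[[1]]
  L <- length(readv)
  p5v <- strsplit(toupper(primer5), "", fixed = TRUE)[[1]]
  p3rc <- strsplit(revcomp(toupper(primer3)), "", fixed = TRUE)[[1]]
  n5 <- length(p5v); n3 <- length(p3rc)

  p5_off <- NA_integer_
  offs5 <- 0:max(0L, min(search_window, L) - n5)
  if (L >= n5) {
    mm <- hamming_scan(readv, p5v, offs5)
    hit <- which(mm <= max_mismatch)
    if (length(hit)) p5_off <- offs5[hit[1]]
  }
  p3_off <- NA_integer_
  if (L >= n3) {
    lo <- max(0L, L - search_window)
    offs3 <- lo:(L - n3)
    mm <- hamming_scan(readv, p3rc, offs3)
    hit <- which(mm <= max_mismatch)
    if (length(hit)) p3_off <- offs3[hit[length(hit)]]  # closest to the end
  }

  polyA <- NULL
  if (!is.na(p3_off) && p3_off >= 1L)
    polyA <- polya_scan(readv, p3_off, min_polyA_run)

  internal_hits <- 0L
  if (!is.na(p5_off) && !is.na(p3_off)) {
    int_lo <- p5_off + n5          # 0-based first interior position
    int_hi <- p3_off               # exclusive
    for (patv in list(p5v, p3rc)) {
      np <- length(patv)
      if (int_hi - int_lo >= np) {
        offs <- int_lo:(int_hi - np)
        mm <- hamming_scan(readv, patv, offs)
        hits <- offs[mm <= max_mismatch]
        # count non-overlapping hits
        last_end <- -1L
        for (h in hits) {
          if (h >= last_end) { internal_hits <- internal_hits + 1L; last_end <- h + np }
        }
      }
    }
  }

  full_length <- !is.na(p5_off) && !is.na(p3_off) && !is.null(polyA)
  klass <- if (L < min_length) "filtered_short"
    else if (full_length && internal_hits > 0L) "full_length_chimeric"
    else if (full_length) "FLNC"
    else "non_full_length"

  insert <- NA_character_
  if (klass %in% c("FLNC", "full_length_chimeric")) {
    ins_from <- p5_off + n5 + 1L               # 1-based
    ins_to <- polyA$start0                     # 1-based end = polyA start0
    insert <- if (ins_to >= ins_from) paste(readv[ins_from:ins_to], collapse = "") else ""
  }
  data.frame(
    read_id = read_id, length = L,
    has_primer5 = !is.na(p5_off), primer5_offset = p5_off,
    has_primer3 = !is.na(p3_off), primer3_offset = p3_off,
    has_polyA = !is.null(polyA),
    polyA_start = if (is.null(polyA)) NA_integer_ else polyA$start0,
    internal_primer_hits = internal_hits, klass = klass,
    insert_length = ifelse(is.na(insert), NA_integer_, nchar(insert)),
    insert_sequence = insert, stringsAsFactors = FALSE
  )
}

#' Classify a set of long reads
#'
#' @param reads named character vector of read sequences, or a path to a
#'   FASTA/FASTQ file (read with Biostrings).
#' @param ... parameters passed to [classify_read()].
#' @inheritParams classify_read
#' @return data.frame of `FlncRecord` rows, one per read.
#' @export
classify_reads <- function(reads, primer5, primer3, ...) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    ss <- if (grepl("\\.f(ast)?q($|\\.)", reads))
      Biostrings::readDNAStringSet(reads, format = "fastq")
    else Biostrings::readDNAStringSet(reads)
    reads <- setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read_%05d", seq_along(reads))
  out <- lapply(names(reads), function(id)
    classify_read(reads[[id]], primer5, primer3, read_id = id, ...))
  do.call(rbind, out)
}

#' Construct a library summary directly from counts
#'
#' Useful for aggregating published per-library summaries; fields not
#' supplied are NA and are skipped by [aggregate_summaries()].
#'
#' @param library_id library label.
#' @param n_reads_of_insert,n_5prime,n_3prime,n_polyA,n_filtered_short,n_non_full_length,n_full_length,n_flnc counts.
#' @param mean_flnc_length mean FLNC insert length (bp).
#' @return object of class `library_summary`.
#' @export
library_summary <- function(library_id, n_reads_of_insert = NA,
                            n_5prime = NA, n_3prime = NA, n_polyA = NA,
                            n_filtered_short = NA, n_non_full_length = NA,
                            n_full_length = NA, n_flnc = NA,
                            mean_flnc_length = NA) {
  structure(list(
    library_id = library_id, n_reads_of_insert = n_reads_of_insert,
    n_5prime = n_5prime, n_3prime = n_3prime, n_polyA = n_polyA,
    n_filtered_short = n_filtered_short,
    n_non_full_length = n_non_full_length,
    n_full_length = n_full_length, n_flnc = n_flnc,
    mean_flnc_length = mean_flnc_length
  ), class = "library_summary")
}

#' Summarize classified reads into a library summary
#'
#' @param records data.frame of `FlncRecord` rows from [classify_reads()].
#' @param library_id library label.
#' @return object of class `library_summary`: reads-of-insert, per-signal
#'   counts (5' primer, 3' primer, poly(A)), class counts (full-length counts
#'   include chimeric full-length reads) and the mean FLNC insert length
#'   rounded to the nearest bp.
#' @export
summarize_library <- function(records, library_id = "library") {
  if (is.null(records) || nrow(records) == 0L) stop("no records to summarize")
  flnc <- records$klass == "FLNC"
  library_summary(
    library_id = library_id,
    n_reads_of_insert = nrow(records),
    n_5prime = sum(records$has_primer5),
    n_3prime = sum(records$has_primer3),
    n_polyA = sum(records$has_polyA),
    n_filtered_short = sum(records$klass == "filtered_short"),
    n_non_full_length = sum(records$klass == "non_full_length"),
    n_full_length = sum(records$klass %in% c("FLNC", "full_length_chimeric")),
    n_flnc = sum(flnc),
    mean_flnc_length = if (any(flnc))
      round(mean(records$insert_length[flnc])) else NA_real_
  )
}

#' Aggregate per-library summaries into a total
#'
#' Count fields are summed; the mean FLNC length is the FLNC-count-weighted
#' mean. Fields that are NA in every input stay NA.
#'
#' @param summaries list of `library_summary` objects.
#' @param library_id label for the aggregate (default "Total").
#' @return object of class `library_summary`.
#' @export
aggregate_summaries <- function(summaries, library_id = "Total") {
  if (length(summaries) == 0L) stop("need at least one summary")
  if (inherits(summaries, "library_summary")) summaries <- list(summaries)
  count_fields <- c("n_reads_of_insert", "n_5prime", "n_3prime", "n_polyA",
                    "n_filtered_short", "n_non_full_length", "n_full_length",
                    "n_flnc")
  tot <- lapply(count_fields, function(f) {
    v <- vapply(summaries, function(s) as.numeric(s[[f]]), numeric(1))
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  })
  names(tot) <- count_fields
  w <- vapply(summaries, function(s) as.numeric(s$n_flnc), numeric(1))
  m <- vapply(summaries, function(s) as.numeric(s$mean_flnc_length), numeric(1))
  ok <- !is.na(w) & !is.na(m)
  mean_len <- if (any(ok)) sum(w[ok] * m[ok]) / sum(w[ok]) else NA_real_
  do.call(library_summary,
          c(list(library_id = library_id), tot, list(mean_flnc_length = mean_len)))
}

#' @export
print.library_summary <- function(x, ...) {
  cat("Library summary:", x$library_id, "\n")
  lab <- c(n_reads_of_insert = "Number of reads of insert",
           n_5prime = "Number of 5' reads",
           n_3prime = "Number of 3' reads",
           n_polyA = "Number of poly(A) reads",
           n_filtered_short = "Number of filtered short reads",
           n_non_full_length = "Number of non-full-length reads",
           n_full_length = "Number of full-length reads",
           n_flnc = "Number of full-length non-chimeric reads",
           mean_flnc_length = "Average FLNC insert length")
  for (f in names(lab))
    cat(sprintf("  %-42s %s\n", lab[[f]], format(x[[f]], big.mark = ",")))
  invisible(x)
}

#' Write library summaries as a TSV table
#'
#' One row per summary, columns in the conventional nine-field layout.
#'
#' @param summaries list of `library_summary` objects.
#' @param path output TSV path.
#' @export
write_library_summaries <- function(summaries, path) {
  if (inherits(summaries, "library_summary")) summaries <- list(summaries)
  df <- do.call(rbind, lapply(summaries, function(s)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
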