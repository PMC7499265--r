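# Deterministic synthetic-dataset generator with machine-readable planted
# truth. Every input the pipeline consumes is emulated: genome FASTA,
# annotation GFF3 (with deliberately split gene models), isoform and
# long-read FASTA, BED12 alignments, homology flags, negative-binomial count
# tables, paralog codon pairs and a truth JSON.

## spliced transcript sequence from a chromosome string (exons genomic,
## 0-based half-open); reverse-complemented on the minus strand
splice_seq <- function(chrom_seq, exons, strand) {
  s <- paste(vapply(seq_len(nrow(exons)),
                    function(i) substr(chrom_seq, exons$start[i] + 1L, exons$end[i]),
                    character(1)), collapse = "")
  if (strand == "-") revcomp(s) else s
}

## relative exon layouts per gene role; coordinates 0-based half-open,
## genomic order (left to right)
build_locus <- function(role, strand, as_type = NULL) {
  ex <- function(starts, lens) data.frame(start = starts, end = starts + lens)
  rand_exons <- function(n_ex, lens = NULL, introns = NULL) {
    if (is.null(lens)) lens <- sample(150:350, n_ex, replace = TRUE)
    if (is.null(introns)) introns <- sample(90:250, max(n_ex - 1L, 0L), replace = TRUE)
    starts <- cumsum(c(0L, head(lens, -1L) + introns))
    ex(starts, lens)
  }
  if (role == "plain") {
    e <- rand_exons(sample(2:5, 1L))
    return(list(isoforms = list(t1 = e), event = NULL, split_k = NA))
  }
  if (role == "split") {
    n_ex <- sample(4:6, 1L)
    e <- rand_exons(n_ex)
    return(list(isoforms = list(t1 = e), event = NULL,
                split_k = sample(2:(n_ex - 2L), 1L)))
  }
  if (role == "intronic_host") {
    e <- ex(c(0L, 1500L), c(200L, 250L))  # 1300-bp intron hosts a novel
    return(list(isoforms = list(t1 = e), event = NULL, split_k = NA))
  }
  # AS locus: two isoforms differing by exactly one event of `as_type`
  l <- sample(150:300, 4L, replace = TRUE)
  i <- sample(120:260, 3L, replace = TRUE)
  delta <- 30L
  if (as_type == "ES") {
    a <- ex(cumsum(c(0L, l[1] + i[1], l[2] + i[2])), l[1:3])
    iso1 <- a; iso2 <- a[c(1, 3), ]
    event <- list(var_start = a$start[2], var_end = a$end[2])
  } else if (as_type == "IR") {
    a <- ex(c(0L, l[1] + i[1]), l[1:2])
    iso1 <- a
    iso2 <- ex(0L, a$end[2])
    event <- list(var_start = a$end[1], var_end = a$start[2])
  } else if (as_type %in% c("A5", "A3")) {
    a <- ex(c(0L, l[1] + i[1]), l[1:2])
    vary_left <- (as_type == "A5") == (strand == "+")
    iso1 <- a; iso2 <- a
    if (vary_left) {
      iso2$end[1] <- a$end[1] + delta
      event <- list(var_start = a$end[1], var_end = a$end[1] + delta)
    } else {
      iso2$start[2] <- a$start[2] + delta
      event <- list(var_start = a$start[2], var_end = a$start[2] + delta)
    }
  } else { # AE: mutually exclusive middle exons
    sA <- l[1] + i[1]
    sB <- sA + l[2] + 80L
    sC <- sB + l[3] + i[2]
    iso1 <- ex(c(0L, sA, sC), c(l[1], l[2], l[4]))
    iso2 <- ex(c(0L, sB, sC), c(l[1], l[3], l[4]))
    event <- list(var_start = sA, var_end = sB + l[3])
  }
  list(isoforms = list(t1 = iso1, t2 = iso2),
       event = c(list(type = as_type), event), split_k = NA)
}

## non-coding sequence: no AUG-initiated ORF of >= min_codons on either strand
make_noncoding_seq <- function(len, min_codons = 100L) {
  repeat {
    s <- random_dna(len)
    if (longest_orf_codons(s) < min_codons) return(s)
  }
}

## coding sequence: short 5' UTR, AUG + `n_codons` sense codons + stop, UTR tail
make_coding_seq <- function(len, n_codons = 120L) {
  ct <- codon_tables()
  sense <- setdiff(setdiff(ct$codons, ct$stops), "ATG")
  orf <- paste0("ATG", paste(sample(sense, n_codons - 1L, replace = TRUE),
                             collapse = ""), "TAA")
  utr5 <- random_dna(30L)
  rest <- len - nchar(orf) - 30L
  if (rest < 0L) stop("coding transcript too short for its ORF")
  paste0(utr5, orf, random_dna(rest))
}

apply_read_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  mutate_dna(seq, stats::rbinom(1L, nchar(seq), rate))
}

#' Simulate a replicate-structured negative-binomial count matrix
#'
#' Per-transcript baseline means are log-normal; each tissue multiplies the
#' baseline by a log-normal effect shared across its replicates; replicate
#' counts are negative binomial with the given dispersion (Poisson at 0).
#' Uses the current RNG state.
#'
#' @param transcript_ids row names.
#' @param tissues character vector of tissue names.
#' @param n_replicates replicates per tissue.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @return integer matrix, columns named `<tissue>_r<k>`.
#' @export
simulate_count_matrix <- function(transcript_ids, tissues, n_replicates,
                                  dispersion = 0.1) {
  n <- length(transcript_ids)
  # wide log-normal baseline: transcript abundances span several orders of
  # magnitude, as in real transcriptomes
  mu0 <- rlnorm(n, log(50), 2)
  fac <- matrix(rlnorm(n * length(tissues), 0, 0.4), nrow = n)
  cols <- list()
  for (t in seq_along(tissues)) for (r in seq_len(n_replicates)) {
    mu <- mu0 * fac[, t]
    cols[[paste0(tissues[t], "_r", r)]] <-
      if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
      else rpois(n, mu)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- transcript_ids
  m
}

default_tissues <- function(n) {
  base <- c("root", "stem", "leaf", "flower", "rhizome")
  if (n <= 5L) base[seq_len(n)] else c(base, sprintf("tissue%02d", 6:n))
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Writes, under `outdir`: `genome.fa`, `annotation.gff3` (split genes
#' emitted as adjacent fragment gene models), `isoforms.fa` (all
#' read-producing transcripts), `reads.fa` (full-length reads as
#' primer5 + transcript + poly(A) + revcomp(primer3), plus planted chimeric,
#' non-full-length and short reads), `alignments.bed` (BED12 for every
#' mappable transcript, including the full span of split genes),
#' `homology.tsv`, `counts.tsv`, `grouping.tsv`, `pairs/pair_*.fa` (evolved
#' paralog codon pairs) and `truth.json`. Output is byte-identical for a
#' fixed config (including seed).
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created; must be empty unless
#'   `overwrite`).
#' @param overwrite allow writing into a non-empty directory.
#' @return (invisibly) the truth set, class `truth_set`: read_labels,
#'   split_components, novel_categories, planted_events, noncoding_ids,
#'   pair_ks, plus a `files` attribute of output paths.
#' @export
generate_dataset <- function(config, outdir, overwrite = FALSE) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config")
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite)
    stop("outdir is not empty (use overwrite = TRUE)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "pairs"), showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) stop("outdir is not writable")
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  cursor <- setNames(rep(3000L, length(chroms)), chroms)

  roles <- c(rep("split", config$n_split_gene_pairs),
             unlist(lapply(names(config$as_events_per_type), function(t)
               rep(paste0("AS:", t), config$as_events_per_type[[t]]))),
             rep("intronic_host", config$n_novel_intronic))
  roles <- c(roles, rep("plain", config$n_genes - length(roles)))

  ann <- list()      # annotation exon rows
  aln <- list()      # alignment exon rows
  seq_tx <- list()   # tx_id -> list(chrom, strand, exons) for extraction
  split_components <- list()
  planted_events <- list()
  host_introns <- list()   # free intron intervals for intronic novels

  add_rows <- function(store, tx, gene, chrom, strand, exons) {
    c(store, list(data.frame(transcript_id = tx, gene_id = gene, chrom = chrom,
                             strand = strand, start = exons$start,
                             end = exons$end, stringsAsFactors = FALSE)))
  }

  for (i in seq_len(config$n_genes)) {
    gene <- sprintf("g%03d", i)
    chrom <- chroms[(i - 1L) %% length(chroms) + 1L]
    strand <- sample(c("+", "-"), 1L)
    role <- roles[i]
    as_type <- if (startsWith(role, "AS:")) sub("AS:", "", role) else NULL
    loc <- build_locus(if (is.null(as_type)) role else "AS", strand, as_type)
    base <- cursor[[chrom]] + sample(1500:4000, 1L)
    span <- max(vapply(loc$isoforms, function(e) max(e$end), numeric(1)))
    if (base + span > config$chrom_length - 2000L)
      stop("chrom_length too small for the configured loci")
    cursor[[chrom]] <- base + span

    iso_g <- lapply(loc$isoforms, function(e)
      data.frame(start = e$start + base, end = e$end + base))
    for (k in seq_along(iso_g)) {
      tx <- paste0(gene, ".", names(iso_g)[k])
      aln <- add_rows(aln, tx, gene, chrom, strand, iso_g[[k]])
      seq_tx[[tx]] <- list(chrom = chrom, strand = strand, exons = iso_g[[k]])
    }
    if (role == "split") {
      e <- iso_g[[1]]
      k <- loc$split_k
      ga <- paste0(gene, "a"); gb <- paste0(gene, "b")
      ann <- add_rows(ann, paste0(ga, ".t1"), ga, chrom, strand,
                      e[seq_len(k), , drop = FALSE])
      ann <- add_rows(ann, paste0(gb, ".t1"), gb, chrom, strand,
                      e[(k + 1L):nrow(e), , drop = FALSE])
      split_components[[length(split_components) + 1L]] <- sort(c(ga, gb))
    } else {
      for (k in seq_along(iso_g))
        ann <- add_rows(ann, paste0(gene, ".", names(iso_g)[k]), gene,
                        chrom, strand, iso_g[[k]])
    }
    if (!is.null(loc$event))
      planted_events[[length(planted_events) + 1L]] <- data.frame(
        type = loc$event$type, gene_id = gene, chrom = chrom, strand = strand,
        var_start = loc$event$var_start + base,
        var_end = loc$event$var_end + base, stringsAsFactors = FALSE)
    if (role == "intronic_host") {
      e <- iso_g[[1]]
      host_introns[[length(host_introns) + 1L]] <-
        list(chrom = chrom, host = gene, start = e$end[1], end = e$start[2])
    }
  }

  # ---- planted novel isoforms -------------------------------------------
  novel_ids <- c(
    if (config$n_novel_intergenic) sprintf("novel_ig_%02d", seq_len(config$n_novel_intergenic)),
    if (config$n_novel_intronic) sprintf("novel_in_%02d", seq_len(config$n_novel_intronic)),
    if (config$n_unmapped) sprintf("novel_um_%02d", seq_len(config$n_unmapped)))
  novel_cat <- c(rep("intergenic", config$n_novel_intergenic),
                 rep("intronic", config$n_novel_intronic),
                 rep("unmapped", config$n_unmapped))
  names(novel_cat) <- novel_ids
  noncoding_ids <- sort(sample(novel_ids, config$n_noncoding))

  paint <- list()  # chrom, start, seq (genomic-strand sequence) to overwrite
  novel_seqs <- character(0)
  for (id in novel_ids) {
    len <- if (id %in% noncoding_ids) sample(450:800, 1L) else sample(520:900, 1L)
    s <- if (id %in% noncoding_ids) make_noncoding_seq(len) else make_coding_seq(len)
    novel_seqs[[id]] <- s
    cat_i <- novel_cat[[id]]
    if (cat_i == "unmapped") next
    strand <- sample(c("+", "-"), 1L)
    if (cat_i == "intergenic") {
      chrom <- chroms[sample.int(length(chroms), 1L)]
      start <- cursor[[chrom]] + sample(2000:4000, 1L)
      if (start + len > config$chrom_length - 1000L)
        stop("chrom_length too small for intergenic novels")
      cursor[[chrom]] <- start + len
    } else {
      hi <- host_introns[[match(id, novel_ids[novel_cat == "intronic"])]]
      chrom <- hi$chrom
      start <- hi$start + 100L
      if (start + len > hi$end - 100L) len <- hi$end - 100L - start
      s <- substr(s, 1L, len)
      novel_seqs[[id]] <- s
    }
    exons <- data.frame(start = start, end = start + len)
    aln <- add_rows(aln, id, NA_character_, chrom, strand, exons)
    paint[[length(paint) + 1L]] <-
      list(chrom = chrom, start = start,
           seq = if (strand == "+") s else revcomp(s))
  }

  # ---- genome ------------------------------------------------------------
  genome <- setNames(vapply(chroms, function(x) random_dna(config$chrom_length),
                            character(1)), chroms)
  for (p in paint)
    substr(genome[[p$chrom]], p$start + 1L, p$start + nchar(p$seq)) <- p$seq

  # ---- transcript sequences ---------------------------------------------
  mrna <- vapply(names(seq_tx), function(tx) {
    st <- seq_tx[[tx]]
    splice_seq(genome[[st$chrom]], st$exons, st$strand)
  }, character(1))
  # painted novels read back from the genome; unmapped keep their sequences
  for (id in novel_ids) {
    if (novel_cat[[id]] == "unmapped") mrna[[id]] <- novel_seqs[[id]]
  }
  # genome-placed novels were registered in seq_tx via aln only; extract them
  aln_df <- do.call(rbind, aln)
  placed_novels <- setdiff(intersect(novel_ids, unique(aln_df$transcript_id)),
                           names(mrna))
  for (id in placed_novels) {
    rows <- aln_df[aln_df$transcript_id == id, , drop = FALSE]
    mrna[[id]] <- splice_seq(genome[[rows$chrom[1]]],
                             rows[, c("start", "end")], rows$strand[1])
  }

  # ---- reads -------------------------------------------------------------
  p5 <- config$primer5; p3rc <- revcomp(config$primer3)
  tail_a <- strrep("A", config$polyA_length)
  reads <- character(0); read_labels <- character(0)
  rid <- 0L
  next_id <- function() { rid <<- rid + 1L; sprintf("read_%05d", rid) }
  for (tx in names(mrna)) for (k in seq_len(config$reads_per_isoform)) {
    id <- next_id()
    reads[[id]] <- apply_read_errors(paste0(p5, mrna[[tx]], tail_a, p3rc),
                                     config$read_error_rate)
    read_labels[[id]] <- "FLNC"
  }
  for (k in seq_len(config$n_chimeric)) {
    id <- next_id()
    ab <- sample(names(mrna), 2L)
    reads[[id]] <- apply_read_errors(
      paste0(p5, mrna[[ab[1]]], tail_a, p3rc, p5, mrna[[ab[2]]], tail_a, p3rc),
      config$read_error_rate)
    read_labels[[id]] <- "chimeric"
  }
  for (k in seq_len(config$n_non_full_length)) {
    id <- next_id()
    tx <- sample(names(mrna), 1L)
    reads[[id]] <- apply_read_errors(switch((k - 1L) %% 3L + 1L,
      paste0(mrna[[tx]], tail_a, p3rc),   # 5' primer lost
      paste0(p5, mrna[[tx]], p3rc),       # poly(A) lost
      paste0(p5, mrna[[tx]], tail_a)),    # 3' primer lost
      config$read_error_rate)
    read_labels[[id]] <- "non_full_length"
  }
  for (k in seq_len(config$n_filtered_short)) {
    id <- next_id()
    tx <- sample(names(mrna), 1L)
    reads[[id]] <- apply_read_errors(
      paste0(p5, substr(mrna[[tx]], 1L, 80L), tail_a, p3rc),
      config$read_error_rate)
    read_labels[[id]] <- "filtered_short"
  }

  # ---- expression counts and homology flags ------------------------------
  tissues <- default_tissues(config$n_tissues)
  counts <- simulate_count_matrix(sort(names(mrna)), tissues,
                                  config$n_replicates,
                                  config$counts_dispersion)
  grouping <- data.frame(
    sample = colnames(counts),
    tissue = sub("_r\\d+$", "", colnames(counts)),
    replicate = as.integer(sub("^.*_r", "", colnames(counts))),
    stringsAsFactors = FALSE)

  coding_truth <- !(names(mrna) %in% noncoding_ids)
  flip <- runif(length(mrna)) < config$homology_flip_rate
  homology <- data.frame(transcript_id = names(mrna),
                         hit = as.integer(xor(coding_truth, flip)),
                         stringsAsFactors = FALSE)

  # ---- paralog pairs ------------------------------------------------------
  pair_ks <- numeric(0)
  tks <- rep_len(config$target_ks, config$n_paralog_pairs)
  pair_files <- character(0)
  for (j in seq_len(config$n_paralog_pairs)) {
    pid <- sprintf("pair_%04d", j)
    cds <- random_cds(config$paralog_codons)
    pr <- evolve_paralog_pair(cds, tks[j])
    f <- file.path(outdir, "pairs", paste0(pid, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(c(pr$seq1, pr$seq2),
                                        paste0(pid, c("_a", "_b")))), f)
    pair_ks[[pid]] <- tks[j]
    pair_files <- c(pair_files, f)
  }

  # ---- write everything ---------------------------------------------------
  files <- list(
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.gff3"),
    isoforms = file.path(outdir, "isoforms.fa"),
    reads = file.path(outdir, "reads.fa"),
    alignments = file.path(outdir, "alignments.bed"),
    homology = file.path(outdir, "homology.tsv"),
    counts = file.path(outdir, "counts.tsv"),
    grouping = file.path(outdir, "grouping.tsv"),
    pairs = pair_files,
    truth = file.path(outdir, "truth.json"))

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), files$genome)
  write_models(transcript_models(do.call(rbind, ann)), files$annotation,
               format = "gff3", source = "isoforge_sim")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(mrna), files$isoforms)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), files$reads)
  write_models(transcript_models(aln_df), files$alignments, format = "bed12")
  write.table(homology, files$homology, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(transcript_id = rownames(counts), counts,
                         check.names = FALSE, stringsAsFactors = FALSE),
              files$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(grouping, files$grouping, sep = "\t", quote = FALSE, row.names = FALSE)

  pe <- if (length(planted_events)) do.call(rbind, planted_events) else
    data.frame(type = character(0), gene_id = character(0),
               chrom = character(0), strand = character(0),
               var_start = numeric(0), var_end = numeric(0))
  truth <- structure(list(
    read_labels = read_labels,
    split_components = split_components,
    novel_categories = novel_cat,
    planted_events = pe,
    noncoding_ids = noncoding_ids,
    pair_ks = pair_ks
  ), class = "truth_set", files = files)
  jsonlite::write_json(
    list(read_labels = as.list(read_labels),
         split_components = split_components,
         novel_categories = as.list(novel_cat),
         planted_events = pe,
         noncoding_ids = noncoding_ids,
         pair_ks = as.list(pair_ks)),
    files$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Read a planted-truth JSON back into a truth set
#'
#' @param path path to a `truth.json` written by [generate_dataset()].
#' @return object of class `truth_set` equal to the one returned by the
#'   generator (modulo the `files` attribute).
#' @export
read_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE, simplifyMatrix = FALSE)
  pe <- x$planted_events
  if (!is.data.frame(pe))
    pe <- data.frame(type = character(0), gene_id = character(0),
                     chrom = character(0), strand = character(0),
                     var_start = numeric(0), var_end = numeric(0))
  structure(list(
    read_labels = unlist(x$read_labels),
    split_components = lapply(x$split_components, as.character),
    novel_categories = unlist(x$novel_categories),
    planted_events = pe,
    noncoding_ids = as.character(x$noncoding_ids),
    pair_ks = unlist(x$pair_ks)
  ), class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Planted truth:\n")
  cat("  reads:", length(x$read_labels), "(",
      paste(sprintf("%s=%d", names(table(x$read_labels)), table(x$read_labels)),
            collapse = ", "), ")\n")
  cat("  split components:", length(x$split_components), "\n")
  cat("  novel isoforms:", length(x$novel_categories), "(",
      paste(sprintf("%s=%d", names(table(x$novel_categories)),
                    table(x$novel_categories)), collapse = ", "), ")\n")
  cat("  planted AS events:", nrow(x$planted_events), "\n")
  cat("  non-coding isoforms:", length(x$noncoding_ids), "\n")
  cat("  paralog pairs:", length(x$pair_ks), "\n")
  invisible(x)
}
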