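# Abundance layers (TPM, FPKM), replicate concordance and representative
# isoform selection.

#' Transcripts per million (TPM)
#'
#' \eqn{rate_i = counts_i / length_i}; \eqn{TPM_i = rate_i / \sum rate \times 10^6}.
#' TPM is invariant to uniform count scaling and sums to 1e6 per sample.
#'
#' @param counts non-negative count vector (not all zero).
#' @param lengths positive transcript lengths (bp), same order.
#' @return TPM vector.
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) stop("counts and lengths differ in length")
  if (any(lengths <= 0)) stop("lengths must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("all counts are zero")
  rate <- counts / lengths
  rate / sum(rate) * 1e6
}

#' Fragments per kilobase per million mapped reads (FPKM)
#'
#' \eqn{FPKM_i = counts_i \times 10^9 / (length_i \times total)}.
#'
#' @param counts non-negative count vector.
#' @param lengths positive transcript lengths (bp).
#' @param total_mapped total mapped fragments in the sample (> 0); defaults
#'   to `sum(counts)`.
#' @return FPKM vector.
#' @export
compute_fpkm <- function(counts, lengths, total_mapped = sum(counts)) {
  if (length(counts) != length(lengths)) stop("counts and lengths differ in length")
  if (any(lengths <= 0)) stop("lengths must be > 0")
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  counts * 1e9 / (lengths * total_mapped)
}

#' Build an expression matrix with TPM and FPKM layers
#'
#' @param counts matrix (transcripts x samples) of non-negative integers,
#'   with row and column names.
#' @param lengths named transcript lengths (bp) covering all rows.
#' @return object of class `expression_matrix`: list with `counts`, `tpm`,
#'   `fpkm`, `lengths`.
#' @export
expression_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have transcript rownames")
  lens <- lengths[rownames(counts)]
  if (any(is.na(lens))) stop("lengths missing for some transcripts")
  tpm <- apply(counts, 2, compute_tpm, lengths = lens)
  fpkm <- apply(counts, 2, function(x) compute_fpkm(x, lens))
  structure(list(counts = counts, tpm = tpm, fpkm = fpkm, lengths = lens),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d transcripts x %d samples (layers: counts, TPM, FPKM)\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Pairwise Pearson correlation of samples on log2(TPM + 1)
#'
#' @param em an `expression_matrix`, or a TPM matrix (transcripts x samples).
#' @return object of class `replicate_concordance`: list with `r` (symmetric
#'   correlation matrix, unit diagonal; NA where a sample has zero variance)
#'   and `transform` ("log2(TPM+1)").
#' @export
replicate_pcc <- function(em) {
  tpm <- if (inherits(em, "expression_matrix")) em$tpm else as.matrix(em)
  if (ncol(tpm) < 2L) stop("need >= 2 samples")
  if (nrow(tpm) < 3L) stop("need >= 3 transcripts")
  lt <- log2(tpm + 1)
  sds <- apply(lt, 2, stats::sd)
  r <- suppressWarnings(cor(lt, method = "pearson"))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r) <- 1
  structure(list(r = r, transform = "log2(TPM+1)",
                 zero_variance = colnames(tpm)[sds == 0]),
            class = "replicate_concordance")
}

#' @export
print.replicate_concordance <- function(x, ...) {
  cat("Replicate concordance (Pearson r on", x$transform, ")\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Select one representative isoform per gene
#'
#' The longest isoform represents its gene; ties are broken by higher mean
#' TPM, then lexicographically smallest id. With
#' `priority = "expression"` the ordering is reversed (highest mean TPM
#' first, length as tie-break).
#'
#' @param gene_to_isoforms named list: gene id -> character vector of
#'   isoform ids.
#' @param em an `expression_matrix` covering all isoforms.
#' @param priority "length" (default) or "expression".
#' @return named character vector: gene id -> representative isoform id.
#' @export
representative_isoform <- function(gene_to_isoforms, em,
                                   priority = c("length", "expression")) {
  priority <- match.arg(priority)
  mean_tpm <- rowMeans(em$tpm)
  vapply(names(gene_to_isoforms), function(g) {
    iso <- gene_to_isoforms[[g]]
    if (!length(iso)) stop("gene with no isoforms: ", g)
    if (any(!iso %in% names(em$lengths))) stop("isoform missing from matrix for gene ", g)
    o <- if (priority == "length")
      order(-em$lengths[iso], -mean_tpm[iso], iso)
    else
      order(-mean_tpm[iso], -em$lengths[iso], iso)
    iso[o[1]]
  }, character(1))
}

#' Mean TPM per tissue for representative isoforms
#'
#' Averages replicate TPM within each tissue, the quantity behind tissue
#' expression heat maps.
#'
#' @param em an `expression_matrix`.
#' @param grouping data.frame with columns sample and tissue (samples =
#'   column names of the matrix).
#' @param transcripts optional transcript subset (e.g. representatives).
#' @return matrix transcripts x tissues of mean TPM.
#' @export
tissue_profile <- function(em, grouping, transcripts = NULL) {
  if (!all(colnames(em$tpm) %in% grouping$sample))
    stop("grouping must cover all samples")
  tpm <- em$tpm
  if (!is.null(transcripts)) tpm <- tpm[transcripts, , drop = FALSE]
  tiss <- split(grouping$sample, grouping$tissue)
  out <- vapply(tiss, function(s) rowMeans(tpm[, s, drop = FALSE]),
                numeric(nrow(tpm)))
  rownames(out) <- rownames(tpm)
  out
}
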