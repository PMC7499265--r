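#' @importFrom stats density median rnbinom rpois runif setNames cor rlnorm
#' @importFrom utils write.table read.delim head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## round half away from zero, matching how the study's percentages print
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

## substitute `n_sub` random positions with a different base; returns string
mutate_dna <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1L)
  paste(v, collapse = "")
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
}
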