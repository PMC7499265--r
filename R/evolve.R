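# Forward simulation of paralog divergence used for Ks-recovery testing.

#' Random stop-free coding sequence
#'
#' @param n_codons number of codons (no start/stop requirement; the sequence
#'   is only required to be translatable without internal stops).
#' @return a DNA string of `3 * n_codons` bases.
#' @export
random_cds <- function(n_codons) {
  stopifnot_scalar_count(n_codons, "n_codons")
  ct <- codon_tables()
  sense <- setdiff(ct$codons, ct$stops)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Evolve a codon sequence into two paralogous descendants
#'
#' Applies Poisson-distributed single-nucleotide substitutions independently
#' along two lineages descending from `cds`. Substitutions are uniform over
#' positions and alternative bases, so the expected number of synonymous
#' substitutions per synonymous site equals the expected number of
#' substitutions per site; each lineage therefore draws
#' `Poisson(target_ks/2 * 3L)` events (L = codon count), giving the pair an
#' expected synonymous divergence of `target_ks`. Substitutions that would
#' create a stop codon are redrawn.
#'
#' @param cds ancestral coding sequence (length divisible by 3, no internal
#'   stop codons).
#' @param target_ks target synonymous substitutions per synonymous site
#'   between the two descendants (>= 0).
#' @return list with `seq1`, `seq2` (descendant sequences) and
#'   `realized_syn_substitutions`, the number of substitution events across
#'   both lineages that preserved the amino acid at the time they occurred.
#' @export
evolve_paralog_pair <- function(cds, target_ks) {
  if (target_ks < 0) stop("target_ks must be >= 0")
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L) stop("cds length must be divisible by 3")
  ct <- codon_tables()
  if (any(split_codons(cds) %in% ct$stops)) stop("cds contains internal stop codon")
  nsites <- nchar(cds)
  evolve_one <- function(seq) {
    n_events <- rpois(1L, target_ks / 2 * nsites)
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    syn <- 0L
    for (e in seq_len(n_events)) {
      repeat {
        p <- sample.int(nsites, 1L)
        b <- sample(setdiff(BASES, v[p]), 1L)
        ci <- (p - 1L) %/% 3L
        old_codon <- paste(v[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
        w <- v; w[p] <- b
        new_codon <- paste(w[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
        if (!(new_codon %in% ct$stops)) {
          if (ct$aa[[new_codon]] == ct$aa[[old_codon]]) syn <- syn + 1L
          v <- w
          break
        }
      }
    }
    list(seq = paste(v, collapse = ""), syn = syn)
  }
  a <- evolve_one(cds)
  b <- evolve_one(cds)
  list(seq1 = a$seq, seq2 = b$seq,
       realized_syn_substitutions = a$syn + b$syn)
}
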