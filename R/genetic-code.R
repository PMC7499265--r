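# Standard-code codon bookkeeping shared by the NG86 estimator and the
# paralog-pair simulator. Everything is precomputed once per session.

codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(codon_env$aa)) return(codon_env)
  gc <- Biostrings::GENETIC_CODE  # standard code; "*" marks stops
  codon_env$aa <- gc
  codon_env$codons <- names(gc)
  codon_env$stops <- names(gc)[gc == "*"]
  # per-codon synonymous site count: at each of the 3 positions, the fraction
  # of the 3 possible single-nucleotide changes that preserve the amino acid.
  # Changes that create a stop codon count as nonsynonymous; stop codons
  # themselves get NA (they are rejected upstream).
  syn <- setNames(numeric(length(gc)), names(gc))
  for (cod in names(gc)) {
    if (gc[[cod]] == "*") { syn[[cod]] <- NA_real_; next }
    v <- strsplit(cod, "", fixed = TRUE)[[1]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(BASES, v[p])) {
        w <- v; w[p] <- b
        alt <- paste(w, collapse = "")
        if (gc[[alt]] == gc[[cod]]) s <- s + 1 / 3
      }
    }
    syn[[cod]] <- s
  }
  codon_env$syn_sites <- syn
  codon_env
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

codon_aa <- function(codon) {
  ct <- codon_tables()
  ifelse(codon %in% ct$codons, unname(ct$aa[codon]), NA_character_)
}
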