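# NG86 Ka/Ks estimation, Ks-distribution peak detection and WGD dating.
#
# The estimator follows the Nei-Gojobori (1986) counting method: fractional
# synonymous/nonsynonymous site counts per codon, multi-hit codon differences
# averaged over all substitution orders (paths through stop codons excluded),
# and a Jukes-Cantor correction of the proportions.

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

perm_orders <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

## average synonymous/nonsynonymous difference counts between two codons over
## all substitution orders, excluding paths that pass through a stop codon.
## Returns c(sd, nd) or NULL when every path is blocked by a stop.
codon_path_diffs <- function(c1, c2) {
  ct <- codon_tables()
  v1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  v2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  dpos <- which(v1 != v2)
  k <- length(dpos)
  if (k == 0L) return(c(0, 0))
  sd_tot <- 0; nd_tot <- 0; n_valid <- 0L
  for (ord in perm_orders[[as.character(k)]]) {
    cur <- v1
    sd <- 0L; nd <- 0L; ok <- TRUE
    for (i in ord) {
      p <- dpos[i]
      nxt <- cur; nxt[p] <- v2[p]
      cod_cur <- paste(cur, collapse = "")
      cod_nxt <- paste(nxt, collapse = "")
      if (cod_nxt %in% ct$stops) { ok <- FALSE; break }
      if (ct$aa[[cod_cur]] == ct$aa[[cod_nxt]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) return(NULL)
  c(sd_tot / n_valid, nd_tot / n_valid)
}

#' Nei-Gojobori (NG86) Ka/Ks for one codon-aligned sequence pair
#'
#' Counts synonymous (S) and nonsynonymous (N) sites as the per-codon fraction
#' of single-nucleotide changes preserving the amino acid (averaged between
#' the two sequences), counts synonymous/nonsynonymous differences with
#' multi-hit codons averaged over all substitution orders (excluding pathways
#' through stop codons), and applies the Jukes-Cantor correction
#' \eqn{d = -3/4 \log(1 - 4p/3)} to the proportions.
#'
#' Codon pairs containing gaps or ambiguity codes are dropped (pairwise
#' complete deletion); a codon pair whose every substitution path crosses a
#' stop codon is dropped and counted in `n_codons_dropped`. When
#' \eqn{p_s \ge 3/4} the synonymous distance is saturated: `Ks` is `NA` and
#' `saturated` is set.
#'
#' @param seq1,seq2 equal-length, in-frame aligned CDS strings (length a
#'   multiple of 3). A shared terminal stop codon is tolerated and dropped.
#' @param pair_id optional identifier carried into the result.
#' @return an object of class `ks_estimate`: a list with fields `pair_id`,
#'   `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`, `n_codons_used`,
#'   `n_codons_dropped`, `saturated`.
#' @examples
#' ng86("GGGGGG", "GGAGGG")$Ks   # one synonymous third-position change
#' @export
ng86 <- function(seq1, seq2, pair_id = NA_character_) {
  ct <- codon_tables()
  s1 <- toupper(as.character(seq1)); s2 <- toupper(as.character(seq2))
  if (nchar(s1) != nchar(s2)) stop("aligned sequences must have equal length")
  if (nchar(s1) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  cod1 <- split_codons(s1); cod2 <- split_codons(s2)
  usable <- cod1 %in% ct$codons & cod2 %in% ct$codons &
    !(cod1 %in% ct$stops) & !(cod2 %in% ct$stops)
  # tolerate an aligned terminal stop; any other stop is an error
  n <- length(cod1)
  stop_hit <- which((cod1 %in% ct$stops) | (cod2 %in% ct$stops))
  if (length(stop_hit) > 0L) {
    if (!identical(stop_hit, n) || !(cod1[n] %in% ct$stops && cod2[n] %in% ct$stops))
      stop("internal stop codon in alignment")
  }
  cod1 <- cod1[usable]; cod2 <- cod2[usable]
  sd_sum <- 0; nd_sum <- 0; dropped <- 0L
  keep <- logical(length(cod1))
  for (i in seq_along(cod1)) {
    d <- codon_path_diffs(cod1[i], cod2[i])
    if (is.null(d)) { dropped <- dropped + 1L; next }
    keep[i] <- TRUE
    sd_sum <- sd_sum + d[1]; nd_sum <- nd_sum + d[2]
  }
  cod1 <- cod1[keep]; cod2 <- cod2[keep]
  n_used <- length(cod1)
  if (n_used == 0L) stop("no usable codons in alignment")
  S <- (sum(ct$syn_sites[cod1]) + sum(ct$syn_sites[cod2])) / 2
  N <- 3 * n_used - S
  ps <- if (S > 0) sd_sum / S else 0
  pn <- if (N > 0) nd_sum / N else 0
  structure(list(
    pair_id = pair_id, S = S, N = N, Sd = sd_sum, Nd = nd_sum,
    ps = ps, pn = pn,
    Ks = jc_correct(ps), Ka = jc_correct(pn),
    n_codons_used = n_used, n_codons_dropped = dropped,
    saturated = ps >= 0.75
  ), class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf(
    "NG86 estimate%s: %d codons (%d dropped)\n  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n  Ks = %s  Ka = %s%s\n",
    if (is.na(x$pair_id)) "" else paste0(" [", x$pair_id, "]"),
    x$n_codons_used, x$n_codons_dropped, x$S, x$N, x$Sd, x$Nd,
    format(x$Ks, digits = 4), format(x$Ka, digits = 4),
    if (x$saturated) "  (saturated)" else ""))
  invisible(x)
}

#' NG86 estimates for a set of paralog-pair FASTA files
#'
#' Each file holds two aligned CDS records (the convention used by the
#' synthetic-data generator and by per-pair exports of alignment tools).
#'
#' @param files character vector of two-record FASTA paths.
#' @return data.frame with one row per pair: pair_id (file base name), S, N,
#'   Sd, Nd, ps, pn, Ks, Ka, n_codons_used, n_codons_dropped, saturated.
#' @export
ng86_pairs <- function(files) {
  rows <- lapply(files, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    if (length(ss) != 2L) stop("pair file must contain exactly 2 records: ", f)
    e <- ng86(as.character(ss[[1]]), as.character(ss[[2]]),
              pair_id = sub("\\.(fa|fasta)$", "", basename(f)))
    as.data.frame(unclass(e), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mode of a paralog Ks distribution
#'
#' Gaussian kernel density estimate of the Ks distribution inside an analysis
#' window; the mode locates the whole-genome-duplication (WGD) peak. Values
#' below `window[1]` (recent tandem duplicates), above `window[2]`, saturated
#' or non-finite are excluded and counted.
#'
#' @param ks numeric vector of Ks estimates (NA/saturated allowed).
#' @param window numeric length-2, analysis window in Ks units.
#' @param bw kernel bandwidth; default Silverman's rule-of-thumb
#'   (`"nrd0"`, as in [stats::density()]).
#' @param min_pairs minimum number of in-window values required.
#' @return object of class `ks_peak`: list with `mode_ks`, `n_pairs_used`,
#'   `n_excluded`, `bandwidth`, `window`, and the density (`x`, `y`).
#' @export
ks_distribution_peak <- function(ks, window = c(0.05, 2), bw = "nrd0",
                                 min_pairs = 30L) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("`window` must be c(ks_min, ks_max) with ks_min < ks_max")
  use <- is.finite(ks) & ks >= window[1] & ks <= window[2]
  x <- ks[use]
  if (length(x) < min_pairs)
    stop(sprintf("only %d finite Ks values inside the window (need >= %d)",
                 length(x), min_pairs))
  if (length(unique(x)) == 1L) {
    # point mass: density bandwidth selection degenerates; mode is the value
    return(structure(list(mode_ks = x[1], n_pairs_used = length(x),
                          n_excluded = sum(!use), bandwidth = 0,
                          window = window, density = NULL),
                     class = "ks_peak"))
  }
  d <- density(x, bw = bw, from = window[1], to = window[2], n = 2048)
  structure(list(
    mode_ks = d$x[which.max(d$y)],
    n_pairs_used = length(x),
    n_excluded = sum(!use),
    bandwidth = d$bw,
    window = window,
    density = list(x = d$x, y = d$y)
  ), class = "ks_peak")
}

#' @export
print.ks_peak <- function(x, ...) {
  cat(sprintf("Ks peak: mode = %.4f (%d pairs used, %d excluded, bw = %.4g, window [%g, %g])\n",
              x$mode_ks, x$n_pairs_used, x$n_excluded, x$bandwidth,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Convert a Ks value to a divergence time
#'
#' \eqn{T = Ks / (2r)} with \eqn{r} the per-site annual substitution rate;
#' the factor 2 accounts for the two lineages diverging from the duplication.
#'
#' @param ks synonymous substitutions per synonymous site (>= 0).
#' @param rate substitution rate in mutations per site per year; default the
#'   widely used plant nuclear rate 6.5e-9.
#' @return divergence time in years.
#' @examples
#' ks_to_time(0.34) / 1e6   # ~26.15 million years
#' @export
ks_to_time <- function(ks, rate = 6.5e-9) {
  if (any(ks < 0)) stop("ks must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  ks / (2 * rate)
}

#' Simulate-estimate-date recovery harness
#'
#' Evolves paralog pairs to a target Ks, re-estimates each pair with
#' [ng86()], locates the distribution peak and converts it to a divergence
#' time, reporting bias and RMSE of the per-pair estimates. Used to validate
#' the whole Ks/WGD stage against planted truth.
#'
#' @param n_pairs number of simulated paralog pairs.
#' @param n_codons codons per ancestral CDS.
#' @param target_ks planted synonymous divergence.
#' @param rate substitution rate for dating (per site per year).
#' @param window,bw passed to [ks_distribution_peak()].
#' @return list with `estimates` (data.frame), `median_ks`, `peak` (ks_peak),
#'   `time_mya`, `bias`, `rmse`.
#' @export
ks_recovery <- function(n_pairs = 200L, n_codons = 300L, target_ks = 0.34,
                        rate = 6.5e-9, window = c(0.05, 2), bw = "nrd0") {
  est <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    cds <- random_cds(n_codons)
    pair <- evolve_paralog_pair(cds, target_ks)
    est[i] <- ng86(pair$seq1, pair$seq2)$Ks
  }
  med <- median(est, na.rm = TRUE)
  pk <- if (target_ks > 0) ks_distribution_peak(est, window = window, bw = bw)
        else NULL
  mode_ks <- if (is.null(pk)) 0 else pk$mode_ks
  list(
    estimates = data.frame(pair = seq_len(n_pairs), ks = est),
    median_ks = med,
    peak = pk,
    time_mya = ks_to_time(mode_ks, rate) / 1e6,
    bias = mean(est - target_ks, na.rm = TRUE),
    rmse = sqrt(mean((est - target_ks)^2, na.rm = TRUE))
  )
}
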