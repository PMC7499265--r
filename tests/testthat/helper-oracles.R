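# Independent oracles used to check the package implementations.

GC_TAB <- Biostrings::GENETIC_CODE
STOPS <- names(GC_TAB)[GC_TAB == "*"]

## ---- NG86 oracle: exhaustive site and path enumeration --------------------
## Recomputes everything from the definitions with a different structure
## (recursive path expansion, explicit per-sequence site sums) so it can
## serve as an oracle for ng86().

oracle_codon_syn_sites <- function(codon) {
  v <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == v[pos]) next
    w <- v; w[pos] <- b
    if (GC_TAB[[paste(w, collapse = "")]] == GC_TAB[[codon]]) s <- s + 1
  }
  s / 3
}

## all substitution paths from c1 to c2, recursively; each path is a list of
## (from, to) codon steps; paths through stops are discarded
oracle_paths <- function(c1, c2) {
  if (c1 == c2) return(list(list()))
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  out <- list()
  for (pos in which(v1 != v2)) {
    w <- v1; w[pos] <- v2[pos]
    mid <- paste(w, collapse = "")
    if (mid %in% STOPS) next
    for (rest in oracle_paths(mid, c2))
      out[[length(out) + 1L]] <- c(list(c(c1, mid)), rest)
  }
  out
}

oracle_ng86 <- function(s1, s2) {
  cods1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  cods2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(cods1)) {
    paths <- oracle_paths(cods1[i], cods2[i])
    if (!length(paths)) next
    used <- used + 1
    S1 <- S1 + oracle_codon_syn_sites(cods1[i])
    S2 <- S2 + oracle_codon_syn_sites(cods2[i])
    sd <- 0; nd <- 0
    for (p in paths) for (step in p) {
      if (GC_TAB[[step[1]]] == GC_TAB[[step[2]]]) sd <- sd + 1 else nd <- nd + 1
    }
    Sd <- Sd + sd / length(paths)
    Nd <- Nd + nd / length(paths)
  }
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn), n_codons_used = used)
}

random_codon_seq <- function(n_codons) {
  sense <- setdiff(names(GC_TAB), STOPS)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

## random pair that differs by point mutations (possibly multiple per codon)
random_ng86_pair <- function(n_codons, n_mut) {
  a <- random_codon_seq(n_codons)
  v <- strsplit(a, "")[[1]]
  tries <- 0
  while (n_mut > 0 && tries < 50 * n_mut) {
    tries <- tries + 1
    p <- sample.int(length(v), 1)
    b <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    w <- v; w[p] <- b
    ci <- (p - 1) %/% 3
    cod <- paste(w[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
    if (cod %in% STOPS) next
    v <- w; n_mut <- n_mut - 1
  }
  list(a = a, b = paste(v, collapse = ""))
}

## ---- AS-event oracle: base-mask brute force --------------------------------
## Represents each isoform as an exonic base mask plus a junction list and
## re-derives the event definitions from those primitives.

oracle_as_events <- function(models) {
  sp <- split(as.data.frame(models), models$transcript_id)
  strand <- models$strand[1]
  lo <- min(models$start); hi <- max(models$end)
  masks <- lapply(sp, function(ex) {
    m <- logical(hi - lo)
    for (i in seq_len(nrow(ex))) m[(ex$start[i] - lo + 1):(ex$end[i] - lo)] <- TRUE
    m
  })
  introns <- lapply(sp, function(ex) {
    n <- nrow(ex)
    if (n < 2) return(matrix(numeric(0), ncol = 2))
    cbind(ex$end[-n], ex$start[-1])
  })
  keys <- character(0)
  add <- function(type, nums) keys <<- c(keys, paste(type, paste(nums, collapse = " ")))
  ids <- names(sp)
  for (x in ids) for (y in ids) {
    if (x == y) next
    ex <- sp[[x]]; ey <- sp[[y]]
    ix <- introns[[x]]; iy <- introns[[y]]
    # IR: intron of y fully exonic in x including both flanking bases
    if (nrow(iy)) for (j in seq_len(nrow(iy))) {
      d <- iy[j, 1]; a <- iy[j, 2]
      span <- (d - lo):(a - lo + 1)   # bases d-1 .. a (1-based in mask)
      if (all(masks[[x]][span])) add("IR", c(d, a))
    }
    # ES: internal exon of x, y has the exact bridging junction
    if (nrow(ex) >= 3 && nrow(iy)) for (k in 2:(nrow(ex) - 1)) {
      p <- ex$end[k - 1]; s <- ex$start[k + 1]
      if (any(iy[, 1] == p & iy[, 2] == s))
        add("ES", c(p, ex$start[k], ex$end[k], s))
    }
    # A5/A3: introns sharing one boundary, variable-side exons overlapping
    if (nrow(ix) && nrow(iy)) for (i in seq_len(nrow(ix))) for (j in seq_len(nrow(iy))) {
      a <- ix[i, ]; b <- iy[j, ]
      if (a[1] != b[1] && a[2] == b[2]) {
        co <- sort(c(a[1], b[1]))
        # overlap of the exons ending at the two alternative boundaries
        exl_x <- ex[ex$end == a[1], ][1, ]; exl_y <- ey[ey$end == b[1], ][1, ]
        if (min(exl_x$end, exl_y$end) > max(exl_x$start, exl_y$start))
          add(if (strand == "+") "A5" else "A3", c(a[2], co))
      }
      if (a[1] == b[1] && a[2] != b[2]) {
        co <- sort(c(a[2], b[2]))
        exr_x <- ex[ex$start == a[2], ][1, ]; exr_y <- ey[ey$start == b[2], ][1, ]
        if (min(exr_x$end, exr_y$end) > max(exr_x$start, exr_y$start))
          add(if (strand == "+") "A3" else "A5", c(a[1], co))
      }
    }
    # AE: mutually exclusive internal exons between identical flanking sites
    if (nrow(ex) >= 3 && nrow(ey) >= 3)
      for (k in 2:(nrow(ex) - 1)) for (l in 2:(nrow(ey) - 1)) {
        if (ex$end[k - 1] != ey$end[l - 1] || ex$start[k + 1] != ey$start[l + 1]) next
        e1 <- c(ex$start[k], ex$end[k]); e2 <- c(ey$start[l], ey$end[l])
        if (min(e1[2], e2[2]) > max(e1[1], e2[1])) next
        if (any(ey$start == e1[1] & ey$end == e1[2])) next
        if (any(ex$start == e2[1] & ex$end == e2[2])) next
        eo <- if (e1[1] < e2[1]) c(e1, e2) else c(e2, e1)
        add("AE", c(ex$end[k - 1], eo, ex$start[k + 1]))
      }
  }
  sort(unique(keys))
}

## event keys of the package enumeration, canonicalized to match
## oracle_as_events(): type followed by the anchor coordinates in order
impl_as_keys <- function(events) {
  five <- events[events$event_type %in% c("ES", "IR", "A5", "A3", "AE"), ,
                 drop = FALSE]
  nums <- vapply(five$anchors, function(a) {
    a <- sub("^[A-Za-z0-9]+:", "", a)  # drop the type prefix (A5:, A3:, ...)
    paste(regmatches(a, gregexpr("[0-9]+", a))[[1]], collapse = " ")
  }, character(1))
  sort(unique(paste(five$event_type, nums)))
}
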