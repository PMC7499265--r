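test_that("constructed two-isoform loci yield exactly their planted event", {
  cassette <- make_models(list(
    full = c(100, 200, 300, 400, 500, 600),
    skip = c(100, 200, 500, 600)))
  ev <- enumerate_events(cassette)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "ES")
  expect_equal(c(ev$var_start, ev$var_end), c(300, 400))

  retained <- make_models(list(
    spliced = c(100, 200, 300, 400),
    retains = c(100, 400)))
  ev <- enumerate_events(retained)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "IR")
  expect_equal(c(ev$var_start, ev$var_end), c(200, 300))

  alt_donor <- make_models(list(
    a = c(100, 200, 300, 400),
    b = c(100, 230, 300, 400)))
  ev <- enumerate_events(alt_donor)
  expect_equal(ev$event_type, "A5")
  # same geometry on the minus strand is an alternative 3' site
  ev_minus <- enumerate_events(make_models(list(
    a = c(100, 200, 300, 400),
    b = c(100, 230, 300, 400)), strand = "-"))
  expect_equal(ev_minus$event_type, "A3")

  mx <- make_models(list(
    a = c(100, 200, 300, 400, 700, 800),
    b = c(100, 200, 500, 600, 700, 800)))
  ev <- enumerate_events(mx)
  expect_equal(ev$event_type, "AE")
})

test_that("strand reversal swaps A5 and A3 and fixes ES/IR/AE", {
  set.seed(8)
  loci <- list(
    make_models(list(a = c(100, 200, 300, 400, 500, 600),
                     b = c(100, 200, 500, 600))),
    make_models(list(a = c(100, 200, 300, 400), b = c(100, 400))),
    make_models(list(a = c(100, 200, 300, 400), b = c(100, 230, 300, 400))),
    make_models(list(a = c(100, 200, 300, 400), b = c(100, 200, 330, 400))),
    make_models(list(a = c(100, 200, 300, 400, 700, 800),
                     b = c(100, 200, 500, 600, 700, 800))))
  L <- 1000
  swap <- c(ES = "ES", IR = "IR", AE = "AE", A5 = "A3", A3 = "A5",
            AF = "AL", AL = "AF")
  for (m in loci) {
    fwd <- enumerate_events(m)
    mirrored <- as.data.frame(m)
    new_start <- L - mirrored$end; new_end <- L - mirrored$start
    mirrored$start <- new_start; mirrored$end <- new_end
    # mirrored coordinates, same strand annotation: donor/acceptor roles swap
    mir <- enumerate_events(transcript_models(mirrored))
    expect_equal(sort(unname(swap[fwd$event_type])), sort(mir$event_type))
    # mirrored coordinates with the strand flipped is the same molecule
    # written on the other strand: labels are invariant
    mirrored$strand <- "-"
    rc <- enumerate_events(transcript_models(mirrored))
    expect_equal(sort(fwd$event_type), sort(rc$event_type))
  }
})

test_that("enumeration equals the base-mask brute force on random small loci", {
  set.seed(9)
  random_locus <- function() {
    # random isoforms over a shared splice-site scaffold
    n_ex <- sample(4:8, 1)
    bounds <- sort(sample(seq(100, 4000, by = 10), 2 * n_ex))
    exons <- matrix(bounds, ncol = 2, byrow = TRUE)
    iso <- list()
    for (k in seq_len(sample(2:4, 1))) {
      keep <- sort(sample(seq_len(n_ex), sample(2:n_ex, 1)))
      ex <- exons[keep, , drop = FALSE]
      # occasionally merge two adjacent kept exons into a retention block
      if (nrow(ex) > 2 && runif(1) < 0.4) {
        i <- sample(nrow(ex) - 1, 1)
        ex[i, 2] <- ex[i + 1, 2]
        ex <- ex[-(i + 1), , drop = FALSE]
      }
      iso[[paste0("t", k)]] <- as.vector(t(ex))
    }
    if (length(unique(names(iso))) < 2) return(NULL)
    make_models(iso, strand = sample(c("+", "-"), 1))
  }
  n_checked <- 0
  for (rep in 1:40) {
    m <- random_locus()
    if (is.null(m)) next
    ev <- enumerate_events(m)
    expect_identical(impl_as_keys(ev), oracle_as_events(m))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 30)
})

test_that("events deduplicate across isoform orderings and witness pairs", {
  m <- make_models(list(
    a = c(100, 200, 300, 400, 500, 600),
    b = c(100, 200, 500, 600),
    c = c(120, 200, 500, 600)))
  ev1 <- enumerate_events(m)
  perm <- as.data.frame(m)
  perm <- transcript_models(perm[rev(seq_len(nrow(perm))), ])
  ev2 <- enumerate_events(perm)
  expect_setequal(paste(ev1$event_type, ev1$anchors),
                  paste(ev2$event_type, ev2$anchors))
  # the same skipped exon witnessed by two pairs counts once
  expect_equal(sum(ev1$event_type == "ES"), 1)
})

test_that("planted synthetic events are recovered exactly per type", {
  cfg <- small_sim_config(seed = 51)
  out <- file.path(tempdir(), "asrec")
  truth <- generate_dataset(cfg, out, overwrite = TRUE)
  ann <- parse_models(file.path(out, "annotation.gff3"))
  ev <- enumerate_events_by_locus(ann)
  five <- ev[ev$event_type %in% c("ES", "IR", "A5", "A3", "AE"), ]
  expect_equal(nrow(five), nrow(truth$planted_events))
  expect_setequal(paste(five$event_type, five$chrom, five$strand,
                        five$var_start, five$var_end),
                  paste(truth$planted_events$type, truth$planted_events$chrom,
                        truth$planted_events$strand,
                        truth$planted_events$var_start,
                        truth$planted_events$var_end))
})

test_that("summaries compute totals, percentages and tissue shares", {
  s <- summarize_events(c(ES = 1))
  expect_equal(unname(s$percent[["ES"]]), 100)
  expect_equal(sum(s$percent), 100)
  ev <- enumerate_events(make_models(list(
    a = c(100, 200, 300, 400, 500, 600), b = c(100, 200, 500, 600))))
  s2 <- summarize_events(ev)
  expect_equal(s2$total, 1)
  expect_equal(unname(s2$counts[["ES"]]), 1)
  expect_error(summarize_events(c(ZZ = 1)), "unknown")
  expect_equal(unname(tissue_isoform_shares(c(x = 10))), 100)
  expect_error(tissue_isoform_shares(c(a = 0, b = 0)), "zero")
})
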