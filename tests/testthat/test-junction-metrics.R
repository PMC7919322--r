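make_calls <- function(jads, start = 1000L, end = 1120L, motif = "GTAG",
                       strand = "+", chrom = "chr1") {
  n <- length(jads)
  data.frame(chrom = rep(chrom, n), start = rep(start, n), end = rep(end, n),
             motif = rep(motif, n), strand = rep(strand, n), read_jad = jads,
             read_id = sprintf("r%d", seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("aggregation takes the count and the maximum per-read JAD", {
  rec <- aggregate_junctions(make_calls(c(0L, 3L, 7L)))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$count, 3L)
  expect_equal(rec$max_jad, 7L)
  expect_true(rec$is_canonical)
  expect_equal(nrow(aggregate_junctions(make_calls(integer(0)))), 0L)
})

test_that("canonical motif set is species-configurable", {
  default_cfg <- filter_config()
  yeast_cfg <- filter_config(canonical_motifs = "GTAG")
  gt <- aggregate_junctions(make_calls(1L, motif = "GTAG"), yeast_cfg)
  gc <- aggregate_junctions(make_calls(1L, motif = "GCAG"), yeast_cfg)
  expect_true(gt$is_canonical)
  expect_false(gc$is_canonical)
  expect_true(aggregate_junctions(make_calls(1L, motif = "GCAG"), default_cfg)$is_canonical)
  expect_false(aggregate_junctions(make_calls(1L, motif = "CTAC"), default_cfg)$is_canonical)
})

test_that("conflicting read strands warn and junctions are keyed strand-free", {
  calls <- rbind(make_calls(c(2L, 3L), strand = "+"),
                 make_calls(1L, strand = "-"))
  expect_warning(rec <- aggregate_junctions(calls), "conflicting strands")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$count, 3L)
  expect_equal(rec$strand, "+")
})

test_that("donor/acceptor positions follow the strand convention", {
  rec <- data.frame(start = 1025L, end = 1145L, strand = c("+", "-", "."))
  pos <- donor_acceptor_positions(rec)
  expect_equal(pos$donor_pos, c(1025L, 1145L, 1025L))
  expect_equal(pos$acceptor_pos, c(1145L, 1025L, 1145L))
})

two_junction_records <- function(counts, jads, donor_pos = c(100L, 110L)) {
  data.frame(chrom = "chr1", start = donor_pos, end = donor_pos + 500L,
             strand = "+", motif = "GTAG", count = counts, max_jad = jads,
             is_canonical = TRUE, key = junction_key("chr1", donor_pos, donor_pos + 500L),
             is_primary_donor = NA, is_primary_acceptor = NA,
             donor_score = NA_real_, acceptor_score = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("primary donor assignment follows count, then JAD, then neither", {
  # higher count wins
  rec <- assign_primary_status(two_junction_records(c(5L, 2L), c(4L, 4L)), 20L)
  expect_equal(rec$is_primary_donor, c(TRUE, FALSE))
  # count tie broken by JAD
  rec <- assign_primary_status(two_junction_records(c(1L, 1L), c(4L, 2L)), 20L)
  expect_equal(rec$is_primary_donor, c(TRUE, FALSE))
  # full tie: neither is primary
  rec <- assign_primary_status(two_junction_records(c(1L, 1L), c(4L, 4L)), 20L)
  expect_equal(rec$is_primary_donor, c(FALSE, FALSE))
  # outside the window both are isolated, hence primary
  rec <- assign_primary_status(two_junction_records(c(1L, 1L), c(4L, 4L),
                                                    donor_pos = c(100L, 150L)), 20L)
  expect_equal(rec$is_primary_donor, c(TRUE, TRUE))
  # the window is inclusive: exactly `window` nt apart still competes
  rec <- assign_primary_status(two_junction_records(c(1L, 1L), c(4L, 4L),
                                                    donor_pos = c(100L, 120L)), 20L)
  expect_equal(rec$is_primary_donor, c(FALSE, FALSE))
})

test_that("primary assignment equals the all-pairs oracle on random sets", {
  for (seed in 1:25) {
    rec <- random_records(sample(5:50, 1L), seed)
    rec$key <- junction_key(rec$chrom, rec$start, rec$end)
    rec$is_canonical <- TRUE
    rec$is_primary_donor <- NA
    rec$is_primary_acceptor <- NA
    got <- assign_primary_status(rec, 20L)
    pos <- donor_acceptor_positions(rec)
    sclass <- ifelse(rec$strand == "-", "-", "+")
    expect_equal(got$is_primary_donor,
                 unname(oracle_primary_sites(rec$chrom, sclass, pos$donor_pos,
                                             rec$count, rec$max_jad, 20L)),
                 info = paste("seed", seed))
    expect_equal(got$is_primary_acceptor,
                 unname(oracle_primary_sites(rec$chrom, sclass, pos$acceptor_pos,
                                             rec$count, rec$max_jad, 20L)),
                 info = paste("seed", seed))
  }
})

test_that("at most one donor site per window-cluster is primary, and raising a count never revokes primary status", {
  for (seed in 26:35) {
    rec <- random_records(30L, seed)
    got <- assign_primary_status(rec, 20L)
    pos <- donor_acceptor_positions(got)
    sclass <- ifelse(got$strand == "-", "-", "+")
    # cluster = sites within the window on one chrom/strand class
    prim <- got$is_primary_donor
    for (i in which(prim)) {
      rivals <- which(got$chrom == got$chrom[i] & sclass == sclass[i] &
                        abs(pos$donor_pos - pos$donor_pos[i]) <= 20L &
                        pos$donor_pos != pos$donor_pos[i])
      expect_false(any(prim[rivals]))
    }
    # monotonicity for one randomly chosen primary junction
    if (any(prim)) {
      k <- sample(which(prim), 1L)
      rec2 <- rec
      rec2$count[k] <- rec2$count[k] + 10L
      got2 <- assign_primary_status(rec2, 20L)
      expect_true(got2$is_primary_donor[k])
    }
  }
})

test_that("read support correlates positively with the junction JAD on fixture data", {
  rec <- big_records()
  expect_gt(cor(rec$count, rec$max_jad, method = "spearman"), 0)
})
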