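# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# Small world: 6 genes, quick enough for unit tests.
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    spec <- fixture_spec(n_genes = 6L, seed = 101L)
    fix <- make_genome_and_annotation(spec)
    fix <- make_reads_with_errors(fix, spec)
    fix$spec <- spec
    fix$bam <- write_fixture_bam(fix, tempfile(pattern = "small_fix"))
    .fixture_cache$small <- fix
  }
  .fixture_cache$small
}

# Benchmark-scale world: >= 500 genuine junctions plus their shifted
# spurious variants, used by the recovery tests.
big_fixture <- function() {
  if (is.null(.fixture_cache$big)) {
    spec <- fixture_spec(n_genes = 140L, seed = 2024L)
    fix <- make_genome_and_annotation(spec)
    fix <- make_reads_with_errors(fix, spec)
    fix$spec <- spec
    fix$bam <- write_fixture_bam(fix, tempfile(pattern = "big_fix"))
    .fixture_cache$big <- fix
  }
  .fixture_cache$big
}

# Scored records for the big fixture (metrics + primary status), memoized.
big_records <- function() {
  if (is.null(.fixture_cache$big_records)) {
    fix <- big_fixture()
    calls <- extract_intron_calls(fix$bam, fix$genome)
    rec <- aggregate_junctions(calls)
    rec <- assign_primary_status(rec)
    .fixture_cache$big_records <- rec
  }
  .fixture_cache$big_records
}

# A flat genome for coordinate-only tests of the cs parser.
flat_genome <- function(len = 5000L, chrom = "chr1") {
  Biostrings::DNAStringSet(setNames(paste(rep("A", len), collapse = ""), chrom))
}

# Independent O(n^2) oracle for primary donor/acceptor assignment:
# aggregates sites by position and compares every pair of sites within the
# window by pooled count, then max JAD.
oracle_primary_sites <- function(chrom, sclass, pos, count, jad, window) {
  id <- paste(chrom, sclass, pos, sep = "|")
  agg <- aggregate(cbind(count = count), by = list(id = id, chrom = chrom,
                                                   sclass = sclass, pos = pos),
                   FUN = sum)
  agg$jad <- tapply(jad, id, max)[agg$id]
  primary <- logical(nrow(agg))
  for (i in seq_len(nrow(agg))) {
    ok <- TRUE
    for (j in seq_len(nrow(agg))) {
      if (i == j) next
      if (agg$chrom[j] != agg$chrom[i] || agg$sclass[j] != agg$sclass[i]) next
      if (abs(agg$pos[j] - agg$pos[i]) > window) next
      if (agg$count[i] < agg$count[j] ||
          (agg$count[i] == agg$count[j] && agg$jad[i] <= agg$jad[j])) {
        ok <- FALSE
        break
      }
    }
    primary[i] <- ok
  }
  setNames(primary, agg$id)[id]
}

# Naive Spearman: Pearson correlation of average ranks.
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random junction records for property tests.
random_records <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample(100:2000, n))
  len <- sample(60:200, n, replace = TRUE)
  data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = pos, end = pos + len,
    strand = sample(c("+", "-", "."), n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    motif = sample(c("GTAG", "GCAG", "CTAC", "TTTT"), n, replace = TRUE),
    count = sample(1:20, n, replace = TRUE),
    max_jad = sample(0:30, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Hand-traced table: cs string -> first intron (start, end, JAD) at
# alignment start 100. JAD = min of flanking match lengths, 0 when a
# mismatch/indel (or alignment boundary) abuts the intron.
jad_cases <- data.frame(
  cs = c(":10~gt50ag:10", ":25~gt120ag:30", ":5*ga:3~gt50ag:7",
         ":5*ga~gt50ag:7", ":7~gt50ag*ga:5", ":8-acg~gt50ag:9",
         ":8+acg~gt50ag:9", "~gt50ag:9", ":9~gt50ag",
         ":7~gt50ag:3~gt60ag:9", "=ACGT~gt100ag=AC", ":4~at50ag:4",
         ":20~gt1000ag:6", ":3*tc:2~gt50ag:50", ":50~gt50ag:2*tc:3",
         ":6-aa:4~gt50ag:8", ":1~gt50ag:1", ":30+tttt:10~gt44ag:9",
         "=AAAA*ac=AAA~gt50ag=AAAAA", ":10~gt50ag+tt:10"),
  start = c(110, 125, 109, 106, 107, 111, 108, 100, 109, 107, 104, 104,
            120, 106, 150, 112, 101, 140, 108, 110),
  end = c(160, 245, 159, 156, 157, 161, 158, 150, 159, 157, 204, 154,
          1120, 156, 200, 162, 151, 184, 158, 160),
  jad = c(10, 25, 3, 0, 0, 0, 0, 0, 0, 3, 2, 4, 6, 2, 2, 4, 1, 9, 3, 0),
  stringsAsFactors = FALSE
)

# Mismatch-only cs corpus for simulator tests: reads are full-length copies
# of the transcripts with iid substitutions at `rate`.
mutate_corpus <- function(transcripts, reads_per_tx, rate, seed) {
  set.seed(seed)
  cs <- character(0); tx_id <- character(0); n_mm <- 0L; n_bases <- 0L
  for (tx in names(transcripts)) {
    chars <- strsplit(transcripts[[tx]], NULL)[[1]]
    for (r in seq_len(reads_per_tx)) {
      mm <- which(runif(length(chars)) < rate)
      tok <- character(0)
      prev <- 0L
      for (m in mm) {
        if (m - 1L > prev) tok <- c(tok, paste0(":", m - 1L - prev))
        q <- sample(setdiff(c("a", "c", "g", "t"), tolower(chars[m])), 1L)
        tok <- c(tok, paste0("*", tolower(chars[m]), q))
        prev <- m
      }
      if (length(chars) > prev) tok <- c(tok, paste0(":", length(chars) - prev))
      cs <- c(cs, paste(tok, collapse = ""))
      tx_id <- c(tx_id, tx)
      n_mm <- n_mm + length(mm)
      n_bases <- n_bases + length(chars)
    }
  }
  list(cs = cs, tx_id = tx_id, pos = rep(0L, length(cs)),
       corpus_rate = n_mm / n_bases)
}

random_transcripts <- function(n, len, seed) {
  set.seed(seed)
  setNames(
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, ""),
    sprintf("tx%02d", seq_len(n))
  )
}
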