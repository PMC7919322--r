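test_that("a perfect corpus yields a point-mass transition model", {
  tx <- random_transcripts(3L, 200L, seed = 1L)
  cs <- paste0("=", unname(tx))
  model <- error_model_from_cs(cs, names(tx), rep(0L, 3L), tx)
  probs <- unlist(lapply(model$transition$l0, `[[`, "prob"))
  expect_true(all(probs == 1))
  # emissions are error-free copies of the current reference base
  for (key in names(model$transition$l0)) {
    cur <- substr(key, 5L, 5L)
    expect_equal(model$transition$l0[[key]]$emission, paste0(cur, "|="))
  }
})

test_that("distributions normalize over observed alternatives", {
  # one A->G mismatch in an otherwise repeated context
  tx <- c(t1 = "CCCCCCACCCCCC")
  cs <- c("=CCCCCCACCCCCC", "=CCCCCC*ag=CCCCCC")
  model <- error_model_from_cs(cs, c("t1", "t1"), c(0L, 0L), tx)
  # every context distribution sums to 1
  for (lvl in model$transition) {
    for (d in lvl) expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  }
  two_atoms <- Filter(function(d) length(d$emission) == 2L, model$transition$l0)
  expect_gte(length(two_atoms), 1L)
})

test_that("homopolymer emissions are harvested into the call table", {
  tx <- c(t1 = "GGTTTAAAAAACCGG")
  # every read drops one A from the reference 6-mer run
  cs <- rep("=GGTTTAAAAA-a=CCGG", 3L)
  model <- error_model_from_cs(cs, rep("t1", 3L), rep(0L, 3L), tx)
  expect_true("A|6" %in% names(model$homopolymer))
  d <- model$homopolymer[["A|6"]]
  expect_equal(d$emission, "AAAAA")
  expect_equal(d$prob, 1)
})

test_that("zero-error simulation is an exact oligo(A)-shifted round trip", {
  tx <- random_transcripts(5L, 300L, seed = 2L)
  cs <- paste0("=", unname(tx))
  model <- error_model_from_cs(cs, names(tx), rep(0L, 5L), tx)
  counts <- setNames(rep(3L, 5L), names(tx))
  sim <- simulate_reads(tx, counts, model, seed = 10L)
  expect_equal(length(sim$reads), 15L)
  for (i in seq_along(sim$reads)) {
    src <- tx[[sim$truth$transcript_id[i]]]
    expected <- paste0(substring(src, 11L), strrep("A", 10L))
    expect_equal(unname(sim$reads[i]), expected)
    expect_equal(nchar(sim$reads[[i]]), nchar(src))
  }
})

test_that("simulation is byte-deterministic under a seed and conserves read counts", {
  tx <- random_transcripts(4L, 250L, seed = 3L)
  corpus <- mutate_corpus(tx, reads_per_tx = 5L, rate = 0.05, seed = 4L)
  model <- error_model_from_cs(corpus$cs, corpus$tx_id, corpus$pos, tx)
  counts <- setNames(c(4L, 0L, 2L, 1L), names(tx))
  sim1 <- simulate_reads(tx, counts, model, seed = 77L)
  sim2 <- simulate_reads(tx, counts, model, seed = 77L)
  expect_identical(sim1$reads, sim2$reads)
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(length(sim1$reads), sum(counts))
  expect_equal(nrow(sim1$truth), sum(counts))
  # transcript with count 0 contributes nothing
  expect_false("tx02" %in% sim1$truth$transcript_id)
  # different seed changes at least one read
  sim3 <- simulate_reads(tx, counts, model, seed = 78L)
  expect_false(identical(sim1$reads, sim3$reads))
})

test_that("FASTQ output carries constant placeholder qualities", {
  reads <- c(r1 = "ACGT", r2 = "GGGCC")
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  lines <- readLines(path)
  expect_equal(lines[1], "@r1")
  expect_equal(lines[2], "ACGT")
  expect_equal(lines[4], "IIII")
  expect_equal(length(lines), 8L)
})

test_that("error models survive a JSON round trip", {
  tx <- random_transcripts(2L, 150L, seed = 5L)
  corpus <- mutate_corpus(tx, reads_per_tx = 3L, rate = 0.05, seed = 6L)
  model <- error_model_from_cs(corpus$cs, corpus$tx_id, corpus$pos, tx)
  path <- tempfile(fileext = ".json")
  write_error_model(model, path)
  model2 <- read_error_model(path)
  sim1 <- simulate_reads(tx, c(tx01 = 2L), model, seed = 1L)
  sim2 <- simulate_reads(tx, c(tx01 = 2L), model2, seed = 1L)
  expect_identical(sim1$reads, sim2$reads)
})

test_that("simulated mismatch rate tracks the training corpus", {
  tx <- random_transcripts(8L, 400L, seed = 7L)
  corpus <- mutate_corpus(tx, reads_per_tx = 8L, rate = 0.06, seed = 8L)
  model <- error_model_from_cs(corpus$cs, corpus$tx_id, corpus$pos, tx)
  counts <- setNames(rep(8L, 8L), names(tx))
  sim <- simulate_reads(tx, counts, model, seed = 9L)
  mm <- 0L; total <- 0L
  for (i in seq_along(sim$reads)) {
    src <- tx[[sim$truth$transcript_id[i]]]
    body <- substr(sim$reads[[i]], 1L, nchar(src) - 10L)
    ref <- substring(src, 11L)
    a <- strsplit(body, NULL)[[1]]; b <- strsplit(ref, NULL)[[1]]
    expect_equal(length(a), length(b))  # mismatch-only corpus keeps lengths
    mm <- mm + sum(a != b)
    total <- total + length(a)
  }
  rate <- mm / total
  expect_lt(abs(rate - corpus$corpus_rate) / corpus$corpus_rate, 0.25)
})
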