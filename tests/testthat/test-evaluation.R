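test_that("precision/recall/F1 follow the standard definitions", {
  truth <- sprintf("chr1:%d-%d", 1:10, 101:110)
  pred <- c(truth[1:9], "chr1:999-1099")
  prf <- junction_prf(pred, truth)
  expect_equal(unname(prf), c(0.9, 0.9, 0.9))
  expect_equal(unname(junction_prf(truth, truth)), c(1, 1, 1))
  # disjoint nonempty sets: all zero by convention
  expect_equal(unname(junction_prf("chr1:1-2", "chr1:3-4")), c(0, 0, 0))
  # empty prediction conventions
  expect_message(prf <- junction_prf(character(0), truth), "precision")
  expect_equal(unname(prf[1]), 0)
  expect_message(prf <- junction_prf(character(0), character(0)), "precision")
  expect_equal(unname(prf), c(1, 1, 1))
})

test_that("junction_prf agrees with a brute-force set comparison", {
  set.seed(42)
  for (i in 1:20) {
    universe <- sprintf("chr1:%d-%d", 1:60, 201:260)
    pred <- sample(universe, sample(0:40, 1))
    truth <- sample(universe, sample(1:40, 1))
    prf <- junction_prf(pred, truth)
    tp <- sum(pred %in% truth)
    fp <- sum(!pred %in% truth)
    fn <- sum(!truth %in% pred)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    suppressMessages(expect_equal(unname(junction_prf(pred, truth)), c(p, r, f)))
  }
})

chains_fixture <- function() {
  ref <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    chrom = "chr1", strand = "+",
    n_introns = c(2L, 1L, 0L, 2L),
    chain = c("chr1:100-200;300-400", "chr1:100-200", "",
              "chr1:100-210;300-400"),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    read_id = sprintf("r%d", 1:6),
    transcript_id = c("t1", "t1", "t2", "t3", "t4", "t1"),
    stringsAsFactors = FALSE
  )
  list(ref = ref, truth = truth)
}

test_that("chain classification follows the category definitions and partitions reads", {
  fx <- chains_fixture()
  observed <- data.frame(
    read_id = sprintf("r%d", 1:6),
    chain = c("chr1:100-200;300-400",  # equals source -> correct
              "chr1:100-210;300-400",  # another transcript's chain -> misassigned
              "chr1:100-205",          # chain not in reference -> novel_spurious
              "",                      # intronless truth, intronless read -> unspliced_correct
              "",                      # spliced truth aligned intronless -> novel_spurious
              "chr1:100-200"),         # t2's chain but simulated from t1 -> misassigned
    stringsAsFactors = FALSE
  )
  v <- classify_alignments(observed, fx$truth, fx$ref)
  expect_equal(v$category,
               c("correct", "misassigned", "novel_spurious",
                 "unspliced_correct", "novel_spurious", "misassigned"))
  expect_equal(v$matched_transcript[1], "t1")
  expect_equal(v$matched_transcript[2], "t4")
  expect_true(is.na(v$matched_transcript[3]))
  # partition: categories cover every read exactly once
  expect_equal(sum(table(v$category)), nrow(observed))
  # unknown read ids are an error
  expect_error(
    classify_alignments(data.frame(read_id = "zz", chain = ""), fx$truth, fx$ref),
    "absent"
  )
})

test_that("chain-based quantification counts matched transcripts", {
  fx <- chains_fixture()
  v <- data.frame(read_id = sprintf("r%d", 1:4),
                  category = c("correct", "correct", "misassigned", "novel_spurious"),
                  matched_transcript = c("t1", "t1", "t2", NA),
                  stringsAsFactors = FALSE)
  counts <- quantify_by_chain(v, c("t1", "t2", "t3"))
  expect_equal(counts, c(t1 = 2, t2 = 1, t3 = 0))
})

test_that("Spearman correlation matches hand values and a naive oracle", {
  expect_equal(quantification_correlation(c(a = 1, b = 2, c = 3, d = 4),
                                          c(a = 1, b = 2, c = 3, d = 4)), 1)
  expect_equal(quantification_correlation(c(a = 4, b = 3, c = 2, d = 1),
                                          c(a = 1, b = 2, c = 3, d = 4)), -1)
  expect_equal(quantification_correlation(c(a = 1, b = 3, c = 2, d = 4),
                                          c(a = 1, b = 2, c = 3, d = 4)), 0.8)
  # missing transcripts count as zero
  expect_equal(
    quantification_correlation(c(a = 2, b = 1), c(a = 5, b = 4, c = 1)),
    quantification_correlation(c(a = 2, b = 1, c = 0), c(a = 5, b = 4, c = 1))
  )
  expect_error(quantification_correlation(c(a = 1), c(a = 2)), "fewer than 2")
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:100, 1)
    x <- setNames(rpois(n, 5), sprintf("t%d", 1:n))
    y <- setNames(rpois(n, 5), sprintf("t%d", 1:n))
    expect_equal(quantification_correlation(x, y), naive_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("annotation subsampling drops isoforms reproducibly", {
  fix <- small_fixture()
  expect_identical(subsample_annotation(fix$exons, 0), fix$exons)
  r1 <- subsample_annotation(fix$exons, 0.5, seed = 7L)
  r2 <- subsample_annotation(fix$exons, 0.5, seed = 7L)
  expect_identical(r1, r2)
  kept <- unique(r1$transcript_id)
  total <- unique(fix$exons$transcript_id)
  expect_lt(length(kept), length(total))
  expect_gt(length(kept), 0L)
  expect_error(subsample_annotation(fix$exons, 1), "\\[0, 1\\)")
  # junctions unique to dropped isoforms vanish from the reduced set
  dropped <- setdiff(total, kept)
  if (length(dropped)) {
    per_tx_keys <- lapply(split(fix$exons, fix$exons$transcript_id),
                          function(e) annotation_junctions(e)$key)
    gone <- setdiff(annotation_junctions(fix$exons)$key,
                    annotation_junctions(r1)$key)
    for (k in gone) {
      carrying <- names(per_tx_keys)[vapply(per_tx_keys, function(x) k %in% x,
                                            logical(1))]
      # every junction that vanished was carried only by dropped isoforms
      expect_true(all(carrying %in% dropped))
    }
  }
})
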