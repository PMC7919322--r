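test_that("tree 1 reproduces its boolean rule over the full metric grid", {
  cfg <- filter_config()
  grid <- expand.grid(max_jad = c(0L, 3L, 4L, 10L),
                      is_canonical = c(TRUE, FALSE),
                      is_primary_donor = c(TRUE, FALSE),
                      is_primary_acceptor = c(TRUE, FALSE))
  got <- decision_tree_1(grid, cfg)
  want <- grid$is_canonical &
    (grid$max_jad >= cfg$jad_threshold |
       (grid$is_primary_donor & grid$is_primary_acceptor))
  expect_equal(got, want)
})

test_that("tree 2 reproduces its boolean rule over a score grid", {
  cfg <- filter_config()
  grid <- expand.grid(max_jad = c(0L, 1L, 4L, 8L),
                      is_canonical = c(TRUE, FALSE),
                      is_primary_donor = c(TRUE, FALSE),
                      is_primary_acceptor = c(TRUE, FALSE),
                      donor_score = c(0.05, 0.1, 0.3, 0.6, 0.9),
                      acceptor_score = c(0.05, 0.3, 0.9))
  got <- decision_tree_2(grid, config = cfg)
  m <- pmin(grid$donor_score, grid$acceptor_score)
  want <- ifelse(grid$max_jad >= cfg$jad_threshold,
                 m >= cfg$lr_low,
                 grid$is_primary_donor & grid$is_primary_acceptor & m >= cfg$lr_high)
  expect_equal(got, want)
})

test_that("rule trees ship with five decision nodes and expose their rule text", {
  expect_equal(tree_node_count(shipped_tree1()), 5L)
  expect_equal(tree_node_count(shipped_tree2()), 5L)
  expr <- tree_rule_expression(shipped_tree1())
  expect_match(expr, "max_jad >= 4")
  expect_match(expr, "is_canonical")
})

test_that("unset metrics are a hard error for the rule trees", {
  rec <- data.frame(max_jad = 5L, is_canonical = TRUE,
                    is_primary_donor = NA, is_primary_acceptor = TRUE)
  expect_error(decision_tree_1(rec), "unset")
  rec2 <- data.frame(max_jad = 5L, is_canonical = TRUE,
                     is_primary_donor = TRUE, is_primary_acceptor = TRUE,
                     donor_score = NA_real_, acceptor_score = 0.5)
  expect_error(decision_tree_2(rec2), "unset|scores")
})

test_that("tree-2 thresholds are monotone in the kept set", {
  rec <- big_records()
  cfg <- filter_config()
  rec$verdict_tree1 <- decision_tree_1(rec, cfg)
  set.seed(9)
  rec$donor_score <- runif(nrow(rec))
  rec$acceptor_score <- runif(nrow(rec))
  base_keep <- rec$key[decision_tree_2(rec, config = cfg)]
  # raising the rescue threshold never adds junctions
  stricter <- filter_config(lr_high = 0.8)
  expect_true(all(rec$key[decision_tree_2(rec, config = stricter)] %in% base_keep))
  # lowering the removal threshold never drops junctions
  laxer <- filter_config(lr_low = 0.02)
  expect_true(all(base_keep %in% rec$key[decision_tree_2(rec, config = laxer)]))
})

test_that("one-hot encoding produces 4 features per position with N as zeros", {
  v <- one_hot(strrep("A", 128))
  expect_length(v, 512L)
  expect_equal(sum(v), 128)
  v <- one_hot(paste0("N", strrep("C", 127)))
  expect_equal(v[1:4], rep(0, 4))
  expect_equal(sum(v), 127)
  v <- one_hot("ACGT", seq_window = 4L)
  expect_equal(v, c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1))
  expect_error(one_hot("ACGT", seq_window = 8L), "length")
})

test_that("site windows are centred, padded and orientation-fixed", {
  seqs <- paste(rep(c("A", "C", "G", "T"), length.out = 128), collapse = "")
  g <- Biostrings::DNAStringSet(setNames(seqs, "chr1"))
  rec <- data.frame(chrom = "chr1", start = 64L, end = 120L,
                    strand = "+", stringsAsFactors = FALSE)
  sites <- extract_site_sequences(rec, g, 128L)
  # donor at 64 on a 128 nt contig: exact fit
  expect_equal(sites$donors$seq, as.character(g[[1]]))
  # acceptor at 120: right overhang padded with 56 N
  expect_equal(nchar(sites$acceptors$seq), 128L)
  expect_equal(substr(sites$acceptors$seq, 73, 128), strrep("N", 56))
  # left padding
  rec$start <- 10L
  sites <- extract_site_sequences(rec, g, 128L)
  expect_equal(substr(sites$donors$seq, 1, 54), strrep("N", 54))
  # minus-strand site: reverse complement of the forward window
  rec <- data.frame(chrom = "chr1", start = 64L, end = 64L, strand = "-",
                    stringsAsFactors = FALSE)
  sites <- extract_site_sequences(rec, g, 128L)
  rc <- as.character(Biostrings::reverseComplement(g[[1]]))
  expect_equal(sites$acceptors$seq, rc)  # acceptor of "-" sits at start
})

test_that("junctions sharing a site share one unique site entry", {
  rec <- data.frame(chrom = "chr1", start = c(100L, 100L, 300L),
                    end = c(500L, 700L, 500L), strand = "+",
                    stringsAsFactors = FALSE)
  g <- flat_genome()
  sites <- extract_site_sequences(rec, g, 16L)
  expect_equal(nrow(sites$donors), 2L)     # 100 shared, 300
  expect_equal(nrow(sites$acceptors), 2L)  # 500 shared, 700
  expect_equal(sites$donor_site[1], sites$donor_site[2])
})

test_that("sequence models score out-of-bag, recover planted consensus, and degrade gracefully", {
  cfg <- filter_config(seed = 7L)
  set.seed(11)
  n <- 120L
  consensus <- "AGGTAAGT"
  make_site <- function(has_consensus) {
    s <- paste(sample(c("A", "C", "G", "T"), 128, replace = TRUE), collapse = "")
    if (has_consensus) {
      s <- paste0(substr(s, 1, 61), consensus, substr(s, 70, 128))
    }
    s
  }
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  seqs <- vapply(labels, make_site, "")
  sites <- list(
    donors = data.frame(site_id = sprintf("d%d", 1:n), chrom = "chr1",
                        pos = 1:n, minus = FALSE, seq = seqs,
                        stringsAsFactors = FALSE),
    acceptors = data.frame(site_id = sprintf("a%d", 1:n), chrom = "chr1",
                           pos = 1:n, minus = FALSE, seq = seqs,
                           stringsAsFactors = FALSE)
  )
  bundle <- train_sequence_models(sites, labels, labels, cfg)
  # every site sits in exactly one fold and has an OOB score
  expect_true(all(bundle$donor$fold_assignment %in% 1:6))
  expect_false(any(is.na(bundle$donor$scores)))
  expect_true(all(bundle$donor$scores >= 0 & bundle$donor$scores <= 1))
  # fold sizes balanced: each model trains on roughly 5/6 of the data
  tab <- table(bundle$donor$fold_assignment)
  expect_true(all(abs(as.numeric(tab) - n / 6) <= 1))
  # consensus-bearing positives score higher than negatives
  expect_gt(mean(bundle$donor$scores[labels]) - mean(bundle$donor$scores[!labels]), 0.2)
  # determinism
  bundle2 <- train_sequence_models(sites, labels, labels, cfg)
  expect_identical(bundle$donor$scores, bundle2$donor$scores)
  # single-class labels: flat scores with a prominent warning
  expect_warning(
    deg <- train_sequence_models(sites, rep(TRUE, n), labels, cfg),
    "degenerate"
  )
  expect_true(all(deg$donor$scores == 0.5))
})

test_that("model bundles serialize to JSON", {
  cfg <- filter_config(seq_window = 16L)
  rec <- big_records()[1:40, ]
  fix <- big_fixture()
  res <- add_sequence_scores(rec, fix$genome, rep(c(TRUE, FALSE), 20), cfg)
  path <- tempfile(fileext = ".json")
  write_model_bundle(res$bundle, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$format, "spliceguide-seqmodel")
  expect_equal(obj$meta$folds, 6L)
})
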