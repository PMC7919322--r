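# Annotation-aided filtering: an existing (possibly incomplete) annotation
# provides noisy labels; a randomized-forest stage on junction metrics
# refines them, sequence models are trained on the refined labels, and a
# final forest over metrics + sequence scores produces the verdicts.
# Out-of-bag scoring by seeded k-fold keeps every stage leak-free.

#' Label observed junctions from an annotation
#'
#' Annotated junctions are labeled genuine; unannotated junctions
#' discovered in alignments are assumed to be mainly spurious. These labels
#' are deliberately noisy -- refining them is the cascade's job.
#'
#' @param records Junction record table.
#' @param annotated_set Junction set from [read_annotation_junctions()]
#'   (a data.frame with a `key` column, or a character vector of keys).
#' @return Logical vector, one per record.
#' @export
label_from_annotation <- function(records, annotated_set) {
  keys <- if (is.data.frame(annotated_set)) annotated_set$key else as.character(annotated_set)
  if (length(keys) == 0L) {
    stop("the annotation contains no junctions; use the annotation-free mode (score_junctions) instead")
  }
  records$key %in% keys
}

cascade_features <- function(records, config) {
  f <- data.frame(
    count = as.numeric(records$count),
    max_jad = as.numeric(records$max_jad),
    is_canonical = as.numeric(records$is_canonical),
    is_primary_donor = as.numeric(records$is_primary_donor),
    is_primary_acceptor = as.numeric(records$is_primary_acceptor)
  )
  if (isTRUE(config$motif_features)) {
    for (p in 1:4) {
      ch <- substr(records$motif, p, p)
      for (b in c("A", "C", "G", "T")) {
        f[[sprintf("motif%d%s", p, b)]] <- as.numeric(ch == b)
      }
    }
  }
  f
}

# Out-of-bag probabilities from an ensemble of fully randomized trees
# (extra-trees splitting), scored by seeded k-fold so no junction is scored
# by a model trained on it.
forest_oob <- function(features, labels, config) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    warning("single-class labels for forest stage; returning the labels as probabilities",
            call. = FALSE)
    return(as.numeric(labels))
  }
  fold <- stratified_folds(labels, config$folds, config$seed)
  probs <- rep(NA_real_, n)
  dat <- cbind(features, .y = factor(labels, levels = c(0L, 1L)))
  for (f in seq_len(config$folds)) {
    held <- fold == f
    if (!any(held)) next
    train <- dat[!held, , drop = FALSE]
    if (length(unique(train$.y)) < 2L) {
      probs[held] <- mean(as.integer(as.character(train$.y)))
      next
    }
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = droplevels(train),
      num.trees = config$trees, probability = TRUE,
      splitrule = "extratrees", num.random.splits = 1L,
      seed = config$seed + f, num.threads = 1L,
      respect.unordered.factors = TRUE
    )
    pred <- predict(fit, data = dat[held, , drop = FALSE], num.threads = 1L)
    probs[held] <- pred$predictions[, "1"]
  }
  probs
}

#' Run the annotation-aided filtering cascade
#'
#' Stage 1 trains a randomized forest on junction metrics with
#' annotation-derived labels and produces out-of-bag probabilities; the
#' refined label of a junction is `stage1_prob >= 0.5`. Stage 2 trains the
#' splice-site sequence models on the refined labels. Stage 3 trains a
#' final randomized forest on metrics plus both sequence scores, again
#' scored out-of-bag; `final_verdict = final_prob >= 0.5`. When
#' `retain_annotated` is `TRUE`, every observed annotated junction is kept
#' regardless of its verdict (annotation false negatives are retained).
#'
#' @param records Junction record table with metrics and primary status set.
#' @param genome Named [Biostrings::DNAStringSet] of the reference genome.
#' @param annotated_set Junction set from [read_annotation_junctions()].
#' @param config A [filter_config()].
#' @param retain_annotated Keep observed annotated junctions even when the
#'   final model rejects them. Default `TRUE`.
#' @return `records` augmented with `annotated`, `stage1_prob`,
#'   `donor_score`, `acceptor_score`, `final_prob`, `final_verdict` and
#'   `retained_by_annotation` columns.
#' @export
run_cascade <- function(records, genome, annotated_set,
                        config = filter_config(), retain_annotated = TRUE) {
  labels <- label_from_annotation(records, annotated_set)
  feats <- cascade_features(records, config)
  stage1 <- forest_oob(feats, labels, config)
  refined <- stage1 >= 0.5
  if (length(unique(refined)) < 2L) {
    warning("refined labels are single-class; falling back to stage-1 probabilities",
            call. = FALSE)
    final_prob <- stage1
  } else {
    scored <- add_sequence_scores(records, genome, positive = refined, config = config)
    records <- scored$records
    feats3 <- cbind(feats,
                    donor_score = records$donor_score,
                    acceptor_score = records$acceptor_score)
    final_prob <- forest_oob(feats3, refined, config)
  }
  verdict <- final_prob >= 0.5
  retained <- retain_annotated & labels & !verdict
  records$annotated <- labels
  records$stage1_prob <- stage1
  records$final_prob <- final_prob
  records$final_verdict <- verdict | retained
  records$retained_by_annotation <- retained
  records
}
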