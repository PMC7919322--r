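# Evaluation procedures: junction-level precision/recall/F1 against a
# ground-truth set, intron-chain classification of read alignments, rank
# correlation of quantification, and annotation subsampling for
# missingness experiments.

#' Junction-level precision, recall and F1
#'
#' Precision is true positives over all positive predictions; recall is
#' true positives over all real positives; F1 is their harmonic mean. An
#' empty prediction set has precision 1 when the truth set is also empty
#' and 0 otherwise (reported via a message).
#'
#' @param predicted_set,truth_set Character vectors of junction keys (see
#'   [junction_key()]).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
junction_prf <- function(predicted_set, truth_set) {
  predicted_set <- unique(predicted_set)
  truth_set <- unique(truth_set)
  tp <- length(intersect(predicted_set, truth_set))
  if (length(predicted_set) == 0L) {
    message("empty prediction set; precision defined as ",
            if (length(truth_set) == 0L) 1 else 0)
    precision <- if (length(truth_set) == 0L) 1 else 0
  } else {
    precision <- tp / length(predicted_set)
  }
  recall <- if (length(truth_set) == 0L) 1 else tp / length(truth_set)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Classify read alignments by intron chain
#'
#' An alignment is `correct` when its intron chain equals the chain of the
#' transcript the read was simulated from (every intron, both coordinates;
#' alignment start/end are disregarded). A spliced read aligned without
#' introns, or with a chain absent from the reference, is
#' `novel_spurious`. A read aligned with the chain of a different reference
#' transcript is `misassigned`. Intronless reads from intronless
#' transcripts are `unspliced_correct` and flagged for exclusion from
#' percentage summaries.
#'
#' @param read_chains data.frame with `read_id` and `chain` columns (chain
#'   format as in [transcript_chains()]; `""` = unspliced alignment).
#' @param truth data.frame with `read_id` and `transcript_id` (the truth
#'   assignment from simulation).
#' @param reference_chains data.frame from [transcript_chains()].
#' @return data.frame with `read_id`, `category` and `matched_transcript`
#'   (`NA` for novel spurious alignments).
#' @export
classify_alignments <- function(read_chains, truth, reference_chains) {
  missing_ids <- setdiff(read_chains$read_id, truth$read_id)
  if (length(missing_ids)) {
    stop(sprintf("%d read ids absent from the truth table (first: %s)",
                 length(missing_ids), missing_ids[1]))
  }
  truth_tx <- setNames(truth$transcript_id, truth$read_id)
  tx_chain <- setNames(reference_chains$chain, reference_chains$transcript_id)
  chain_tx <- setNames(reference_chains$transcript_id, reference_chains$chain)
  src <- unname(truth_tx[read_chains$read_id])
  expected <- unname(tx_chain[src])
  got <- read_chains$chain
  category <- character(nrow(read_chains))
  matched <- rep(NA_character_, nrow(read_chains))
  for (i in seq_len(nrow(read_chains))) {
    if (identical(got[i], expected[i])) {
      category[i] <- if (nzchar(got[i])) "correct" else "unspliced_correct"
      matched[i] <- src[i]
    } else if (!nzchar(got[i])) {
      # intron-less when it should have splicing
      category[i] <- "novel_spurious"
    } else if (got[i] %in% names(chain_tx)) {
      category[i] <- "misassigned"
      matched[i] <- unname(chain_tx[got[i]])
    } else {
      category[i] <- "novel_spurious"
    }
  }
  data.frame(read_id = read_chains$read_id, category = category,
             matched_transcript = matched, stringsAsFactors = FALSE)
}

#' Per-transcript counts from chain-classified alignments
#'
#' Counts the reads whose alignment reproduced the intron chain of each
#' reference transcript (correct, unspliced-correct and misassigned reads
#' contribute to the transcript whose chain they matched).
#'
#' @param verdicts data.frame from [classify_alignments()].
#' @param transcripts Character vector defining the transcript universe.
#' @return Named numeric vector of counts over `transcripts`.
#' @export
quantify_by_chain <- function(verdicts, transcripts) {
  hit <- verdicts$matched_transcript[!is.na(verdicts$matched_transcript)]
  tab <- table(factor(hit, levels = transcripts))
  setNames(as.numeric(tab), transcripts)
}

#' Spearman correlation of estimated vs true transcript counts
#'
#' @param estimated_counts,truth_counts Named numeric vectors; the
#'   transcript universe is the union of names and missing entries count
#'   as 0. Rank ties are averaged.
#' @return Spearman's rho.
#' @export
quantification_correlation <- function(estimated_counts, truth_counts) {
  universe <- union(names(estimated_counts), names(truth_counts))
  if (length(universe) < 2L) {
    stop("Spearman correlation is undefined for fewer than 2 transcripts")
  }
  e <- setNames(rep(0, length(universe)), universe)
  t0 <- e
  e[names(estimated_counts)] <- estimated_counts
  t0[names(truth_counts)] <- truth_counts
  cor(e, t0, method = "spearman")
}

#' Subsample transcript isoforms from an annotation
#'
#' Removes isoforms (not genes) independently with the given probability,
#' to emulate an incomplete reference annotation for missingness
#' experiments.
#'
#' @param exons Exon table (see [read_exon_table()]).
#' @param missingness_rate Probability in `[0, 1)` that an isoform is
#'   dropped.
#' @param seed Integer seed.
#' @return The reduced exon table.
#' @export
subsample_annotation <- function(exons, missingness_rate, seed = 1L) {
  if (missingness_rate < 0 || missingness_rate >= 1) {
    stop("missingness_rate must be in [0, 1)")
  }
  if (missingness_rate == 0) return(exons)
  tx <- unique(exons$transcript_id)
  set.seed(seed)
  drop <- tx[runif(length(tx)) < missingness_rate]
  exons[!exons$transcript_id %in% drop, , drop = FALSE]
}
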