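#' Filtering configuration
#'
#' Collects every threshold used by the junction filtering method in one
#' object. Defaults correspond to the published method: a junction is
#' supported at high confidence when at least one read aligns it with a JAD
#' of at least 4 nt; alternative donor/acceptor sites compete within a 20 nt
#' window; splice-site sequence models see 128 nt windows one-hot encoded to
#' 512 features and are trained with 6-fold cross-validation; their
#' probabilities are thresholded at 0.6 (rescue) and 0.1 (removal).
#'
#' @param jad_threshold Minimum per-junction maximum JAD (nt) for the
#'   high-confidence alignment-evidence branch of the rule trees. Default 4.
#' @param primary_window Window (nt) within which alternative donor/acceptor
#'   sites compete for primary status; inclusive. Default 20.
#' @param canonical_motifs Character vector of 4-mer intron motifs (first two
#'   + last two intron bases) considered canonical. Default
#'   `c("GTAG", "GCAG", "ATAG")` (GU/AG, GC/AG, AU/AG in RNA space). For
#'   budding yeast use `canonical_motifs = "GTAG"` only.
#' @param lr_high High-confidence sequence-score threshold used to rescue
#'   junctions that fail the JAD criterion. Default 0.6.
#' @param lr_low Low-confidence sequence-score threshold used to remove
#'   likely false positives that pass the JAD criterion. Default 0.1.
#' @param seq_window Width (nt, even) of the genomic window centred on each
#'   donor/acceptor site fed to the sequence models. Default 128.
#' @param folds Number of cross-validation folds for out-of-bag scoring.
#'   Default 6.
#' @param lambda L2 regularization strength of the logistic-regression
#'   sequence models. Inputs are binary one-hot columns so no scaling is
#'   applied. Default 0.01.
#' @param trees Number of trees per randomized-forest stage of the
#'   annotation-aided cascade. Default 100.
#' @param motif_features Should the cascade forests see a one-hot encoding of
#'   the four intron motif characters in addition to the canonical flag?
#'   Default TRUE.
#' @param seed Integer seed controlling fold shuffling and forest growth.
#'
#' @return A list of class `"filter_config"`.
#' @examples
#' cfg <- filter_config()
#' cfg$jad_threshold
#' @export
filter_config <- function(jad_threshold = 4L,
                          primary_window = 20L,
                          canonical_motifs = c("GTAG", "GCAG", "ATAG"),
                          lr_high = 0.6,
                          lr_low = 0.1,
                          seq_window = 128L,
                          folds = 6L,
                          lambda = 0.01,
                          trees = 100L,
                          motif_features = TRUE,
                          seed = 42L) {
  jad_threshold <- as.integer(jad_threshold)
  primary_window <- as.integer(primary_window)
  seq_window <- as.integer(seq_window)
  folds <- as.integer(folds)
  stopifnot(
    jad_threshold >= 0L,
    primary_window >= 0L,
    seq_window > 0L, seq_window %% 2L == 0L,
    folds >= 2L,
    lr_low >= 0, lr_high <= 1, lr_low <= lr_high,
    lambda > 0,
    trees >= 1L
  )
  canonical_motifs <- toupper(canonical_motifs)
  if (!all(nchar(canonical_motifs) == 4L)) {
    stop("canonical motifs must be 4-character strings (donor + acceptor dinucleotides)")
  }
  structure(
    list(
      jad_threshold = jad_threshold,
      primary_window = primary_window,
      canonical_motifs = canonical_motifs,
      lr_high = lr_high,
      lr_low = lr_low,
      seq_window = seq_window,
      folds = folds,
      lambda = lambda,
      trees = as.integer(trees),
      motif_features = isTRUE(motif_features),
      seed = as.integer(seed)
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("spliceguide filter configuration\n")
  cat(sprintf("  JAD threshold        : %d nt\n", x$jad_threshold))
  cat(sprintf("  primary-site window  : +/- %d nt\n", x$primary_window))
  cat(sprintf("  canonical motifs     : %s\n", paste(x$canonical_motifs, collapse = ", ")))
  cat(sprintf("  sequence window      : %d nt (%d one-hot features)\n",
              x$seq_window, 4L * x$seq_window))
  cat(sprintf("  CV folds             : %d\n", x$folds))
  cat(sprintf("  score thresholds     : rescue >= %.2f, remove < %.2f\n",
              x$lr_high, x$lr_low))
  cat(sprintf("  seed                 : %d\n", x$seed))
  invisible(x)
}
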