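# Splice-site sequence models: ridge logistic regression on one-hot encoded
# genomic windows centred on unique donor/acceptor sites, scored strictly
# out-of-bag via seeded stratified k-fold cross-validation.

#' One-hot encode a nucleotide sequence
#'
#' Position-major encoding over the alphabet A, C, G, T: a window of
#' `seq_window` nt becomes a binary vector of length `4 * seq_window`
#' (128 nt -> 512 features). `N` positions contribute an all-zero block.
#'
#' @param seq A single uppercase/lowercase string over `{A,C,G,T,N}`.
#' @param seq_window Required sequence length.
#' @return Numeric 0/1 vector of length `4 * seq_window`.
#' @export
one_hot <- function(seq, seq_window = 128L) {
  seq <- toupper(seq)
  if (nchar(seq) != seq_window) {
    stop(sprintf("sequence length %d does not match the %d nt window",
                 nchar(seq), seq_window))
  }
  chars <- strsplit(seq, NULL)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  out <- numeric(4L * seq_window)
  hit <- match(chars, c("A", "C", "G", "T"))  # NA for N
  ok <- !is.na(hit)
  out[(which(ok) - 1L) * 4L + hit[ok]] <- 1
  out
}

one_hot_matrix <- function(seqs, seq_window) {
  t(vapply(seqs, one_hot, numeric(4L * seq_window), seq_window = seq_window,
           USE.NAMES = FALSE))
}

#' Extract genomic windows around unique donor and acceptor sites
#'
#' Junction records are separated into unique donor sites and unique
#' acceptor sites. Each site yields the genomic window
#' `[pos - seq_window/2, pos + seq_window/2)` on the forward strand,
#' reverse-complemented for minus-strand sites so the splice signal sits in
#' a fixed orientation; overhang beyond the chromosome is padded with N.
#'
#' @param records Junction record table.
#' @param genome Named [Biostrings::DNAStringSet] (or named character
#'   vector) of the reference genome.
#' @param seq_window Window width in nt (even).
#' @return A list with data.frames `donors` and `acceptors` (`site_id`,
#'   `chrom`, `pos`, `minus`, `seq`) and character vectors `donor_site` /
#'   `acceptor_site` mapping each junction row to its site ids.
#' @export
extract_site_sequences <- function(records, genome, seq_window = 128L) {
  pos <- donor_acceptor_positions(records)
  minus <- records$strand == "-"
  site_table <- function(p) {
    id <- paste0(records$chrom, ":", p, ":", ifelse(minus, "-", "+"))
    u <- !duplicated(id)
    seqs <- vapply(which(u), function(i) {
      w <- genome_slice(genome, records$chrom[i],
                        p[i] - seq_window %/% 2L, p[i] + seq_window %/% 2L)
      if (minus[i]) revcomp_chr(w) else w
    }, "")
    list(tab = data.frame(site_id = id[u], chrom = records$chrom[u],
                          pos = p[u], minus = minus[u], seq = seqs,
                          stringsAsFactors = FALSE),
         map = id)
  }
  d <- site_table(pos$donor_pos)
  a <- site_table(pos$acceptor_pos)
  list(donors = d$tab, acceptors = a$tab,
       donor_site = d$map, acceptor_site = a$map)
}

# Seeded stratified fold assignment: members of each class are shuffled and
# dealt round-robin so every fold sees both classes whenever possible.
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

fit_site_model <- function(seqs, labels, config, what = "site") {
  n <- length(seqs)
  stopifnot(length(labels) == n)
  degenerate <- function(msg) {
    warning(sprintf("%s sequence model degenerate (%s); all scores set to 0.5", what, msg),
            call. = FALSE)
    list(models = NULL, fold = rep(NA_integer_, n), scores = rep(0.5, n))
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) return(degenerate("single-class labels"))
  if (min(table(labels)) < 2L) return(degenerate("fewer than 2 examples in a class"))
  fold <- stratified_folds(labels, config$folds, config$seed)
  x <- one_hot_matrix(seqs, config$seq_window)
  scores <- rep(NA_real_, n)
  models <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    held <- fold == f
    if (!any(held)) next
    if (length(unique(labels[!held])) < 2L) {
      return(degenerate(sprintf("a class is absent from the training split of fold %d", f)))
    }
    fit <- glmnet::glmnet(x[!held, , drop = FALSE], labels[!held],
                          family = "binomial", alpha = 0,
                          lambda = config$lambda, standardize = FALSE)
    models[[f]] <- fit
    scores[held] <- as.numeric(predict(fit, x[held, , drop = FALSE],
                                       type = "response"))
  }
  list(models = models, fold = fold, scores = scores)
}

#' Train donor/acceptor splice-site sequence models
#'
#' Independent ridge logistic-regression models are trained for donor and
#' acceptor sites on one-hot encoded genomic windows, using seeded
#' stratified k-fold cross-validation; every site is scored only by the
#' model whose training fold excluded it (out-of-bag prediction), so scores
#' can be reused as features without leakage.
#'
#' @param sites Site tables from [extract_site_sequences()].
#' @param donor_labels,acceptor_labels Logical/0-1 vectors, one per row of
#'   `sites$donors` / `sites$acceptors`; typically whether the site
#'   participates in at least one junction passing tree 1.
#' @param config A [filter_config()].
#' @return An object of class `sequence_model_bundle`: per-site-type fold
#'   models, fold assignment and out-of-bag scores (named by `site_id`),
#'   plus training metadata.
#' @export
train_sequence_models <- function(sites, donor_labels, acceptor_labels,
                                  config = filter_config()) {
  d <- fit_site_model(sites$donors$seq, donor_labels, config, what = "donor")
  a <- fit_site_model(sites$acceptors$seq, acceptor_labels, config, what = "acceptor")
  structure(list(
    donor = list(models = d$models,
                 fold_assignment = setNames(d$fold, sites$donors$site_id),
                 scores = setNames(d$scores, sites$donors$site_id)),
    acceptor = list(models = a$models,
                    fold_assignment = setNames(a$fold, sites$acceptors$site_id),
                    scores = setNames(a$scores, sites$acceptors$site_id)),
    meta = list(seed = config$seed, folds = config$folds,
                lambda = config$lambda, seq_window = config$seq_window)
  ), class = "sequence_model_bundle")
}

#' Attach out-of-bag sequence scores to junction records
#'
#' Builds the unique donor/acceptor site tables, derives site labels from a
#' per-junction positive indicator (a site is positive when it participates
#' in at least one positive junction), trains the sequence models and
#' writes each junction's site scores into the `donor_score` /
#' `acceptor_score` columns.
#'
#' @param records Junction record table.
#' @param genome Named [Biostrings::DNAStringSet] of the reference genome.
#' @param positive Logical vector, one per junction record (typically the
#'   tree-1 verdicts, or refined labels in the annotation-aided cascade).
#' @param config A [filter_config()].
#' @return A list with elements `records` (scores filled in) and `bundle`
#'   (the trained `sequence_model_bundle`).
#' @export
add_sequence_scores <- function(records, genome, positive,
                                config = filter_config()) {
  stopifnot(length(positive) == nrow(records))
  sites <- extract_site_sequences(records, genome, config$seq_window)
  site_label <- function(tab, map) {
    pos_sites <- unique(map[as.logical(positive)])
    tab$site_id %in% pos_sites
  }
  bundle <- train_sequence_models(
    sites,
    donor_labels = site_label(sites$donors, sites$donor_site),
    acceptor_labels = site_label(sites$acceptors, sites$acceptor_site),
    config = config
  )
  records$donor_score <- unname(bundle$donor$scores[sites$donor_site])
  records$acceptor_score <- unname(bundle$acceptor$scores[sites$acceptor_site])
  list(records = records, bundle = bundle)
}

#' Serialize a sequence model bundle to versioned JSON
#'
#' Stores coefficient vectors, fold assignments, out-of-bag scores and
#' training metadata so a scoring run can be audited or reapplied.
#'
#' @param bundle A `sequence_model_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_bundle <- function(bundle, path) {
  side <- function(s) {
    list(
      coefficients = lapply(s$models, function(m) {
        if (is.null(m)) return(NULL)
        as.numeric(as.matrix(stats::coef(m)))
      }),
      fold_assignment = as.list(s$fold_assignment),
      scores = as.list(s$scores)
    )
  }
  obj <- list(format = "spliceguide-seqmodel", version = 1L,
              meta = bundle$meta,
              donor = side(bundle$donor), acceptor = side(bundle$acceptor))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
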