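# End-to-end scoring pipelines binding the modules together: extraction ->
# metrics -> tree 1 -> sequence models -> tree 2 (annotation-free), or the
# randomized-forest cascade (annotation-aided).

#' Score and filter junctions from a first-pass BAM (annotation-free)
#'
#' Runs the full annotation-free workflow: per-read intron extraction,
#' per-junction metric aggregation, primary donor/acceptor assignment, the
#' junction-metric rule tree, out-of-bag splice-site sequence models
#' trained on the tree-1 labels, and the combined rule tree.
#'
#' @param bam_path Indexed BAM of first-pass spliced alignments with
#'   long-form cs tags.
#' @param genome Named [Biostrings::DNAStringSet] (or path to a FASTA).
#' @param config A [filter_config()].
#' @return A list with `records` (junction table with `verdict_tree1`,
#'   `donor_score`, `acceptor_score`, `verdict_tree2`) and `bundle` (the
#'   trained `sequence_model_bundle`, `NULL` when there were no junctions).
#' @export
score_junctions <- function(bam_path, genome, config = filter_config()) {
  genome <- load_genome(genome)
  calls <- extract_intron_calls(bam_path, genome)
  records <- aggregate_junctions(calls, config)
  if (nrow(records) == 0L) {
    records$verdict_tree1 <- logical(0)
    records$verdict_tree2 <- logical(0)
    return(list(records = records, bundle = NULL))
  }
  records <- assign_primary_status(records, config$primary_window)
  records$verdict_tree1 <- decision_tree_1(records, config)
  scored <- add_sequence_scores(records, genome, positive = records$verdict_tree1,
                                config = config)
  records <- scored$records
  records$verdict_tree2 <- decision_tree_2(records, config = config)
  list(records = records, bundle = scored$bundle)
}

#' Score and filter junctions with an annotation (annotation-aided)
#'
#' Wraps [run_cascade()]: extraction and metric aggregation as in
#' [score_junctions()], then the randomized-forest cascade seeded with
#' annotation-derived labels.
#'
#' @param bam_path Indexed BAM of first-pass spliced alignments.
#' @param genome Named [Biostrings::DNAStringSet] (or path to a FASTA).
#' @param annotation Path to a GTF/GFF3/BED annotation, or a junction
#'   data.frame from [read_annotation_junctions()].
#' @param config A [filter_config()].
#' @param retain_annotated Keep observed annotated junctions regardless of
#'   the model verdict. Default `TRUE`.
#' @return Junction record table with cascade columns (see
#'   [run_cascade()]).
#' @export
score_junctions_annotated <- function(bam_path, genome, annotation,
                                      config = filter_config(),
                                      retain_annotated = TRUE) {
  genome <- load_genome(genome)
  annotated_set <- if (is.data.frame(annotation)) annotation else {
    read_annotation_junctions(annotation)
  }
  calls <- extract_intron_calls(bam_path, genome)
  records <- aggregate_junctions(calls, config)
  if (nrow(records) == 0L) {
    records$annotated <- logical(0)
    records$final_verdict <- logical(0)
    return(records)
  }
  records <- assign_primary_status(records, config$primary_window)
  run_cascade(records, genome, annotated_set, config, retain_annotated)
}

#' Observed intron chain of every primary alignment in a BAM
#'
#' Reads with no reference-skip operations get the empty chain `""`.
#'
#' @param bam_path Indexed BAM with cs tags.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return data.frame with `read_id` and `chain` (format as in
#'   [transcript_chains()]).
#' @export
chains_from_bam <- function(bam_path, genome) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  ids <- Rsamtools::scanBam(bam_path, param = param)[[1]]$qname
  calls <- extract_intron_calls(bam_path, genome)
  chains <- setNames(rep("", length(unique(ids))), unique(ids))
  if (nrow(calls)) {
    by_read <- split(calls, calls$read_id)
    for (rid in names(by_read)) {
      cc <- by_read[[rid]]
      cc <- cc[order(cc$start), , drop = FALSE]
      chains[rid] <- paste0(cc$chrom[1], ":",
                            paste(sprintf("%d-%d", cc$start, cc$end), collapse = ";"))
    }
  }
  data.frame(read_id = names(chains), chain = unname(chains),
             stringsAsFactors = FALSE)
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  genome
}

#' Merge junction BEDs across replicates
#'
#' Union keeps every junction seen in any replicate; intersection keeps
#' junctions present in all replicates. Supporting read counts are summed
#' across replicates and the strand is taken from the first file carrying
#' the junction.
#'
#' @param paths Character vector of 6-column junction BED paths.
#' @param mode `"union"` or `"intersection"`.
#' @return Merged junction data.frame.
#' @export
merge_junction_beds <- function(paths, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  tabs <- lapply(paths, read_junction_bed)
  all <- do.call(rbind, tabs)
  if (nrow(all) == 0L) return(all)
  keys <- unique(all$key)
  if (mode == "intersection") {
    present <- Reduce(intersect, lapply(tabs, `[[`, "key"))
    keys <- keys[keys %in% present]
  }
  merged <- lapply(keys, function(k) {
    rows <- all[all$key == k, , drop = FALSE]
    data.frame(chrom = rows$chrom[1], start = rows$start[1], end = rows$end[1],
               count = sum(rows$count), strand = rows$strand[1], key = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}
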