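# I/O surfaces: first-pass BAM in, guide-junction BED out, GTF/GFF3/BED
# annotations in. Coordinates are 0-based half-open everywhere internally;
# GTF/GFF3 (1-based inclusive) is converted on read, BED is passed through.

#' Junction identity key
#'
#' Junctions are keyed by `(chrom, start, end)` only; strand is a property
#' of the junction, not part of its identity.
#'
#' @param chrom,start,end Vectors of junction coordinates (0-based
#'   half-open).
#' @return Character vector `"chrom:start-end"`.
#' @export
junction_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Extract per-read intron calls from a coordinate-sorted BAM
#'
#' Reads primary alignments carrying long-form cs tags and emits one intron
#' call per reference-skip operation, with per-read JADs. Secondary and
#' supplementary alignments are skipped, as are records without a cs tag
#' (counted and reported via a message).
#'
#' @param bam_path Path to an indexed BAM of first-pass spliced alignments.
#' @param genome Named [Biostrings::DNAStringSet] of the reference genome.
#' @return A data.frame of intron calls, see [introns_from_alignment()].
#' @export
extract_intron_calls <- function(bam_path, genome) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos"),
    tag = "cs",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(introns_from_alignment(parse_cs_tag(""), "", 0L, "", genome))
  flag <- res$flag
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  non_primary <- secondary | supplementary
  cs <- res$tag$cs
  if (is.null(cs)) cs <- rep(NA_character_, n)
  no_cs <- !non_primary & is.na(cs)
  if (any(non_primary)) {
    message(sprintf("skipped %d secondary/supplementary alignments", sum(non_primary)))
  }
  if (any(no_cs)) {
    warning(sprintf("skipped %d primary alignments without a cs tag; rerun the aligner with long-form cs output", sum(no_cs)))
  }
  use <- which(!non_primary & !is.na(cs))
  calls <- vector("list", length(use))
  for (k in seq_along(use)) {
    i <- use[k]
    ops <- parse_cs_tag(cs[i])
    calls[[k]] <- introns_from_alignment(
      ops, as.character(res$rname[i]), res$pos[i] - 1L, res$qname[i], genome
    )
  }
  out <- do.call(rbind, calls)
  if (is.null(out) || nrow(out) == 0L) {
    return(introns_from_alignment(parse_cs_tag(""), "", 0L, "", genome))
  }
  rownames(out) <- NULL
  out
}

#' Write junctions as a 6-column BED guide set
#'
#' One intron per line, 0-based half-open, score column carrying the
#' supporting read count, sorted by (chrom, start, end). This is the format
#' spliced aligners accept as a guide-junction set for a second pass.
#'
#' @param junctions data.frame with columns `chrom`, `start`, `end`, `count`
#'   and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  stopifnot(all(c("chrom", "start", "end", "count", "strand") %in% names(junctions)))
  j <- junctions[order(junctions$chrom, junctions$start, junctions$end), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t.\t%d\t%s",
                   j$chrom, as.integer(j$start), as.integer(j$end),
                   as.integer(j$count), j$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a 6-column junction BED
#' @param path Path to a BED file whose rows are introns.
#' @return data.frame with `chrom`, `start`, `end`, `count`, `strand`, `key`.
#' @export
read_junction_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      count = integer(), strand = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  b <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  col.names = c("chrom", "start", "end", "name", "score", "strand"),
                  colClasses = c("character", "integer", "integer",
                                 "character", "integer", "character"))
  data.frame(chrom = b$chrom, start = b$start, end = b$end,
             count = b$score, strand = b$strand,
             key = junction_key(b$chrom, b$start, b$end),
             stringsAsFactors = FALSE)
}

#' Read transcript exon models from a GTF/GFF3 annotation
#'
#' @param path Path to a GTF or GFF3 file.
#' @return data.frame of exons with 0-based half-open `start`/`end` and
#'   columns `transcript_id`, `gene_id`, `chrom`, `strand`.
#' @export
read_exon_table <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  mc <- S4Vectors::mcols(gr)
  tid <- if ("transcript_id" %in% names(mc)) {
    as.character(mc$transcript_id)
  } else if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) as.character(p)[1], "")
  } else {
    stop("annotation exons carry neither transcript_id nor Parent attributes")
  }
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else tid
  data.frame(
    transcript_id = tid,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Derive the junction set of an annotation
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' deduplicated across transcripts. Transcripts whose exons overlap each
#' other are skipped with a warning.
#'
#' @param exons Exon table as returned by [read_exon_table()].
#' @return data.frame of unique junctions with `chrom`, `start`, `end`,
#'   `strand` and `key` columns.
#' @export
annotation_junctions <- function(exons) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), key = character(),
                      stringsAsFactors = FALSE)
  if (nrow(exons) == 0L) return(empty)
  parts <- split(exons, exons$transcript_id)
  out <- lapply(parts, function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) < 2L) return(NULL)
    if (any(tx$start[-1L] < tx$end[-nrow(tx)])) {
      warning(sprintf("transcript %s has overlapping exons; skipped",
                      tx$transcript_id[1]))
      return(NULL)
    }
    data.frame(chrom = tx$chrom[1],
               start = tx$end[-nrow(tx)],
               end = tx$start[-1L],
               strand = tx$strand[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out$key <- junction_key(out$chrom, out$start, out$end)
  out <- out[!duplicated(out$key), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an annotation into a junction key set
#'
#' Accepts either a GTF/GFF3 transcript annotation (introns are derived as
#' gaps between consecutive exons of each transcript) or a 6-column BED
#' whose rows are introns.
#'
#' @param path Annotation path; format chosen by extension (`.bed` vs
#'   `.gtf`/`.gff`/`.gff3`).
#' @return data.frame of unique junctions (see [annotation_junctions()]).
#' @export
read_annotation_junctions <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    b <- read_junction_bed(path)
    b <- b[!duplicated(b$key), c("chrom", "start", "end", "strand", "key")]
    rownames(b) <- NULL
    return(b)
  }
  annotation_junctions(read_exon_table(path))
}

#' Intron chains of annotated transcripts
#'
#' The intron chain is the ordered set of introns of a transcript, ignoring
#' its start and end coordinates; it is the unit of alignment-level
#' evaluation. Single-exon transcripts have the empty chain `""`.
#'
#' @param exons Exon table as returned by [read_exon_table()].
#' @return data.frame with `transcript_id`, `chrom`, `strand`, `n_introns`
#'   and `chain` (`"chrom:start-end;start-end;..."`, `""` when intronless).
#' @export
transcript_chains <- function(exons) {
  parts <- split(exons, exons$transcript_id)
  rows <- lapply(parts, function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    chain <- if (nrow(tx) < 2L) "" else {
      paste0(tx$chrom[1], ":",
             paste(sprintf("%d-%d", tx$end[-nrow(tx)], tx$start[-1L]), collapse = ";"))
    }
    data.frame(transcript_id = tx$transcript_id[1], chrom = tx$chrom[1],
               strand = tx$strand[1], n_introns = max(0L, nrow(tx) - 1L),
               chain = chain, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
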