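# Per-junction metric records. A junction is identified by (chrom, start,
# end); strand is a property inferred from the motif, with a warning when
# reads disagree.

#' Aggregate per-read intron calls into junction records
#'
#' One record per unique `(chrom, start, end)`. The per-junction JAD is the
#' maximum of the per-read JADs; the supporting read count is the number of
#' contributing primary alignments.
#'
#' @param calls Intron call table from [extract_intron_calls()] /
#'   [introns_from_alignment()].
#' @param config A [filter_config()]; controls which motifs count as
#'   canonical.
#' @return data.frame of junction records with columns `chrom`, `start`,
#'   `end`, `strand`, `motif`, `count`, `max_jad`, `is_canonical`, `key`,
#'   and placeholder columns (`NA`) for `is_primary_donor`,
#'   `is_primary_acceptor`, `donor_score`, `acceptor_score`.
#' @export
aggregate_junctions <- function(calls, config = filter_config()) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), motif = character(),
                      count = integer(), max_jad = integer(),
                      is_canonical = logical(), key = character(),
                      is_primary_donor = logical(), is_primary_acceptor = logical(),
                      donor_score = numeric(), acceptor_score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  key <- junction_key(calls$chrom, calls$start, calls$end)
  parts <- split(seq_len(nrow(calls)), key)
  rows <- lapply(parts, function(idx) {
    strands <- unique(calls$strand[idx])
    strand <- strands[1]
    if (length(strands) > 1L) {
      tab <- sort(table(calls$strand[idx]), decreasing = TRUE)
      strand <- if (length(tab) > 1L && tab[1] == tab[2]) "." else names(tab)[1]
      warning(sprintf("junction %s observed with conflicting strands (%s); using %s",
                      junction_key(calls$chrom[idx[1]], calls$start[idx[1]], calls$end[idx[1]]),
                      paste(strands, collapse = "/"), strand))
    }
    data.frame(chrom = calls$chrom[idx[1]], start = calls$start[idx[1]],
               end = calls$end[idx[1]], strand = strand,
               motif = calls$motif[idx[1]],
               count = length(idx),
               max_jad = max(calls$read_jad[idx]),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$is_canonical <- rec$motif %in% config$canonical_motifs
  rec$key <- junction_key(rec$chrom, rec$start, rec$end)
  rec$is_primary_donor <- NA
  rec$is_primary_acceptor <- NA
  rec$donor_score <- NA_real_
  rec$acceptor_score <- NA_real_
  rec <- rec[order(rec$chrom, rec$start, rec$end), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Donor and acceptor genomic positions of junction records
#'
#' On the `"+"` strand (and for unstranded junctions) the donor is the
#' intron start and the acceptor the intron end; on `"-"` the roles swap.
#'
#' @param records Junction record table.
#' @return data.frame with columns `donor_pos` and `acceptor_pos`.
#' @export
donor_acceptor_positions <- function(records) {
  minus <- records$strand == "-"
  data.frame(
    donor_pos = ifelse(minus, records$end, records$start),
    acceptor_pos = ifelse(minus, records$start, records$end)
  )
}

# Site-level primary assignment shared by donors and acceptors. Sites are
# pooled positions on one chromosome/strand-class; read counts are summed
# and JADs maxed over junctions sharing the site before comparison.
primary_sites <- function(chrom, sclass, pos, count, jad, window) {
  df <- data.frame(chrom, sclass, pos, count = as.numeric(count),
                   jad = as.numeric(jad), stringsAsFactors = FALSE)
  site_id <- paste(df$chrom, df$sclass, df$pos, sep = "|")
  agg <- do.call(rbind, lapply(split(df, site_id), function(s) {
    data.frame(chrom = s$chrom[1], sclass = s$sclass[1], pos = s$pos[1],
               count = sum(s$count), jad = max(s$jad),
               stringsAsFactors = FALSE)
  }))
  agg$primary <- TRUE
  for (grp in split(seq_len(nrow(agg)), paste(agg$chrom, agg$sclass, sep = "|"))) {
    sub <- agg[grp, , drop = FALSE]
    q <- IRanges::IRanges(sub$pos - window, sub$pos + window)
    s <- IRanges::IRanges(sub$pos, width = 1L)
    hits <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- qh != sh
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh)) {
      beaten <- sub$count[qh] < sub$count[sh] |
        (sub$count[qh] == sub$count[sh] & sub$jad[qh] <= sub$jad[sh])
      lose <- unique(qh[beaten])
      agg$primary[grp[lose]] <- FALSE
    }
  }
  lookup <- setNames(agg$primary, paste(agg$chrom, agg$sclass, agg$pos, sep = "|"))
  unname(lookup[site_id])
}

#' Assign primary donor/acceptor status to junction records
#'
#' A donor site is primary when no alternative donor site within the window
#' has greater pooled read support; read-count ties are broken by the site
#' JAD (larger wins), and a tie on both leaves neither site primary.
#' Acceptors are treated symmetrically. Sites on the `"+"` and `"."`
#' strands compete together; `"-"`-strand sites compete separately.
#'
#' @param records Junction record table from [aggregate_junctions()].
#' @param window Competition window in nt (inclusive); defaults to 20.
#' @return `records` with logical `is_primary_donor` and
#'   `is_primary_acceptor` filled in.
#' @export
assign_primary_status <- function(records, window = 20L) {
  if (nrow(records) == 0L) return(records)
  pos <- donor_acceptor_positions(records)
  sclass <- ifelse(records$strand == "-", "-", "+")
  records$is_primary_donor <- primary_sites(
    records$chrom, sclass, pos$donor_pos, records$count, records$max_jad, window
  )
  records$is_primary_acceptor <- primary_sites(
    records$chrom, sclass, pos$acceptor_pos, records$count, records$max_jad, window
  )
  records
}

#' Write a junction metrics/score table as TSV
#' @param records Junction record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
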