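# Long-form cs difference strings are the substrate of the whole method:
# every junction, motif and JAD is read off them rather than off CIGAR/MD.

CS_TOKEN_RE <- "(:[0-9]+)|(=[A-Za-z]+)|(\\*[a-z]{2})|(\\+[a-z]+)|(-[a-z]+)|(~[a-z]{2}[0-9]+[a-z]{2})"

#' Parse a long-form cs tag into alignment operations
#'
#' Tokenizes a cs difference string (as produced by spliced aligners run with
#' long-form cs output) into a table of alignment operations. Both the
#' long-form match token (`=ACGT`) and the length-coded match token (`:4`)
#' are accepted.
#'
#' @param cs A single cs string. Tokens: `:`/`=` match, `*` mismatch (one
#'   reference/query base pair per token), `+` insertion, `-` deletion,
#'   `~` reference skip (intron) written as donor dinucleotide, intron
#'   length, acceptor dinucleotide.
#' @return A data.frame with columns `kind` (one of `"match"`, `"mismatch"`,
#'   `"insertion"`, `"deletion"`, `"refskip"`), `length` (nt on the reference
#'   for match/deletion/refskip, on the query for insertion, 1 per mismatch)
#'   and `bases` (the literal token payload; `NA` for length-coded matches).
#' @examples
#' parse_cs_tag("=ACGT~gt100ag=AC")
#' parse_cs_tag(":5*ga:3")
#' @export
parse_cs_tag <- function(cs) {
  stopifnot(is.character(cs), length(cs) == 1L, !is.na(cs))
  if (!nzchar(cs)) {
    return(data.frame(kind = character(), length = integer(),
                      bases = character(), stringsAsFactors = FALSE))
  }
  m_list <- gregexpr(CS_TOKEN_RE, cs, perl = TRUE)
  m <- m_list[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1L || starts[1] != 1L) {
    stop(sprintf("malformed cs token at offset %d in %s",
                 if (starts[1] == -1L) 1L else 1L, shQuote(cs)))
  }
  # tokens must tile the string with no gaps
  ends <- starts + lens - 1L
  gap <- which(starts[-1] != ends[-length(ends)] + 1L)
  if (length(gap)) {
    stop(sprintf("malformed cs token at offset %d in %s",
                 ends[gap[1]] + 1L, shQuote(cs)))
  }
  if (ends[length(ends)] != nchar(cs)) {
    stop(sprintf("malformed cs token at offset %d in %s",
                 ends[length(ends)] + 1L, shQuote(cs)))
  }
  toks <- regmatches(cs, m_list)[[1]]
  op <- substr(toks, 1L, 1L)
  payload <- substring(toks, 2L)
  kind <- c(":" = "match", "=" = "match", "*" = "mismatch",
            "+" = "insertion", "-" = "deletion", "~" = "refskip")[op]
  len <- integer(length(toks))
  bases <- payload
  for (i in seq_along(toks)) {
    len[i] <- switch(
      op[i],
      ":" = as.integer(payload[i]),
      "=" = nchar(payload[i]),
      "*" = 1L,
      "+" = nchar(payload[i]),
      "-" = nchar(payload[i]),
      "~" = {
        n <- as.integer(gsub("[a-z]", "", payload[i]))
        if (n < 4L) {
          stop(sprintf("refskip of length %d (< 4 nt) at offset %d in %s: no room for splice dinucleotides",
                       n, starts[i], shQuote(cs)))
        }
        n
      }
    )
    if (op[i] == ":") bases[i] <- NA_character_
  }
  keep <- len > 0L
  data.frame(kind = unname(kind[keep]), length = len[keep],
             bases = bases[keep], stringsAsFactors = FALSE)
}

#' Reference span consumed by a set of cs operations
#'
#' Matches, mismatches, deletions and reference skips consume reference
#' bases; insertions do not.
#'
#' @param ops Operation table from [parse_cs_tag()].
#' @return Integer reference span in nt.
#' @export
cs_reference_span <- function(ops) {
  if (nrow(ops) == 0L) return(0L)
  sum(ops$length[ops$kind %in% c("match", "mismatch", "deletion", "refskip")])
}

#' Query span consumed by a set of cs operations
#' @param ops Operation table from [parse_cs_tag()].
#' @return Integer query span in nt.
#' @export
cs_query_span <- function(ops) {
  if (nrow(ops) == 0L) return(0L)
  sum(ops$length[ops$kind %in% c("match", "mismatch", "insertion")])
}

# reverse complement for plain character vectors (ACGTN alphabet)
revcomp_chr <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, NULL), function(s) paste(rev(s), collapse = ""), "")
}

# Strand inference from the forward-genome motif: the three canonical motifs
# are treated as canonical irrespective of gene strand, so a forward motif
# that is the reverse complement of a canonical motif marks a minus-strand
# intron and is reported in canonical orientation.
STRAND_MOTIFS <- c("GTAG", "GCAG", "ATAG")

orient_motif <- function(motif_fwd) {
  rc <- revcomp_chr(motif_fwd)
  strand <- ifelse(motif_fwd %in% STRAND_MOTIFS, "+",
                   ifelse(rc %in% STRAND_MOTIFS, "-", "."))
  motif <- ifelse(strand == "-", rc, motif_fwd)
  list(motif = motif, strand = strand)
}

#' Extract per-read intron calls from parsed cs operations
#'
#' Walks the operations of one alignment, accumulating reference coordinates,
#' and emits one intron call per reference-skip operation. The per-read JAD
#' (junction alignment distance) is the length of the shorter of the two
#' match operations immediately flanking the skip; if either immediate
#' neighbour is a mismatch or indel (or the skip sits at an alignment
#' boundary), the JAD is zero.
#'
#' @param ops Operation table from [parse_cs_tag()].
#' @param chrom Reference sequence name.
#' @param aln_start Leftmost reference coordinate of the alignment, 0-based.
#' @param read_id Read name, carried through to the calls.
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector) holding the reference genome; used to read the intron motif.
#' @return A data.frame of intron calls with columns `chrom`, `start`
#'   (0-based first intron base), `end` (0-based exclusive), `motif` (4
#'   uppercase characters, reported in canonical orientation when the locus
#'   matches a canonical motif on either strand), `strand` (`"+"`, `"-"` or
#'   `"."`), `read_jad` and `read_id`. Zero rows when the alignment has no
#'   reference skip.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 2000), collapse = "")))
#' ops <- parse_cs_tag(":25~gt120ag:30")
#' introns_from_alignment(ops, "chr1", 1000L, "read1", genome)
#' @export
introns_from_alignment <- function(ops, chrom, aln_start, read_id, genome) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      motif = character(), strand = character(),
                      read_jad = integer(), read_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(ops) == 0L) return(empty)
  ref_consumes <- ops$kind %in% c("match", "mismatch", "deletion", "refskip")
  pos_before <- aln_start + c(0L, cumsum(ops$length * ref_consumes))[seq_len(nrow(ops))]
  idx <- which(ops$kind == "refskip")
  if (!length(idx)) return(empty)
  calls <- lapply(idx, function(i) {
    start <- pos_before[i]
    end <- start + ops$length[i]
    left_ok <- i > 1L && ops$kind[i - 1L] == "match"
    right_ok <- i < nrow(ops) && ops$kind[i + 1L] == "match"
    jad <- if (left_ok && right_ok) {
      min(ops$length[i - 1L], ops$length[i + 1L])
    } else 0L
    motif_fwd <- paste0(genome_slice(genome, chrom, start, start + 2L),
                        genome_slice(genome, chrom, end - 2L, end))
    om <- orient_motif(motif_fwd)
    data.frame(chrom = chrom, start = start, end = end,
               motif = om$motif, strand = om$strand,
               read_jad = as.integer(jad), read_id = read_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

# Uppercase genome slice [start, end) in 0-based half-open coordinates,
# N-padded where the window overhangs the sequence.
genome_slice <- function(genome, chrom, start, end) {
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop(sprintf("unknown reference sequence %s", chrom))
    seq_len_chr <- nchar(genome[[chrom]])
    lo <- max(start, 0L); hi <- min(end, seq_len_chr)
    core <- if (hi > lo) substr(genome[[chrom]], lo + 1L, hi) else ""
  } else {
    if (!chrom %in% names(genome)) stop(sprintf("unknown reference sequence %s", chrom))
    seq_len_chr <- Biostrings::width(genome[chrom])
    lo <- max(start, 0L); hi <- min(end, seq_len_chr)
    core <- if (hi > lo) as.character(Biostrings::subseq(genome[[chrom]], lo + 1L, hi)) else ""
  }
  paste0(strrep("N", max(0L, -start)), toupper(core),
         strrep("N", max(0L, end - seq_len_chr)))
}
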