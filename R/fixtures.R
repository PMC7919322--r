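# Self-contained test world: a small multi-gene genome with canonical
# introns and extended splice-site consensus, a transcript annotation with
# exon-skipping isoforms, and cs-tagged read alignments carrying controlled
# mismatch noise, JAD degradation at junctions, and injected spurious
# junctions shifted by 1-10 nt -- the qualitative regime that spliced
# long-read alignments of direct-RNA data show.

#' Fixture generation parameters
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Isoforms per gene; isoform 1 uses all exons,
#'   further isoforms each skip one internal exon (adding one novel
#'   junction per isoform).
#' @param n_exons Exons per gene (>= 3 when isoforms_per_gene > 1).
#' @param exon_length,intron_length Length ranges (nt), inclusive.
#' @param motif_freqs Named sampling frequencies of canonical intron
#'   motifs for genuine introns.
#' @param shift_fraction Probability that a read realizes the spurious
#'   (shifted) variant of a junction instead of the genuine one.
#' @param shift_canonical_fraction Fraction of spurious junction variants
#'   whose shifted termini are planted with canonical dinucleotides,
#'   mimicking a spliced aligner's preference for GT/AG at misplaced
#'   junctions.
#' @param shift_high_jad_fraction Fraction of spurious variants whose
#'   reads align cleanly (high JAD); the rest get a mismatch within 0-3 nt
#'   of the junction, capping the JAD below the filtering threshold.
#' @param junction_error_fraction Per read-junction probability of a
#'   mismatch immediately adjacent to a genuine junction (JAD 0 for that
#'   read).
#' @param error_rate Per-base mismatch probability in exon interiors.
#' @param reads_per_isoform Range of read counts per isoform.
#' @param intergenic Range of intergenic gap lengths (nt).
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 30L,
                         isoforms_per_gene = 2L,
                         n_exons = 5L,
                         exon_length = c(80L, 160L),
                         intron_length = c(60L, 120L),
                         motif_freqs = c(GTAG = 0.94, GCAG = 0.04, ATAG = 0.02),
                         shift_fraction = 0.2,
                         shift_canonical_fraction = 0.67,
                         shift_high_jad_fraction = 0.1,
                         junction_error_fraction = 0.15,
                         error_rate = 0.02,
                         reads_per_isoform = c(4L, 10L),
                         intergenic = c(200L, 400L),
                         seed = 42L) {
  stopifnot(n_genes >= 1L, n_exons >= 2L,
            exon_length[1] >= 20L, intron_length[1] >= 30L,
            all(c(shift_fraction, shift_canonical_fraction,
                  shift_high_jad_fraction, junction_error_fraction,
                  error_rate) >= 0),
            all(c(shift_fraction, shift_canonical_fraction,
                  shift_high_jad_fraction, junction_error_fraction,
                  error_rate) <= 1))
  if (isoforms_per_gene > 1L && n_exons < 3L) {
    stop("exon-skipping isoforms need at least 3 exons per gene")
  }
  structure(as.list(environment()), class = "fixture_spec")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

plant <- function(chars, at0, motif) {
  # overwrite genome characters at 0-based position `at0`
  b <- strsplit(motif, NULL)[[1]]
  chars[at0 + seq_along(b)] <- b
  chars
}

# Extended splice consensus planted at genuine sites (beyond the bare
# dinucleotides) so sequence models have signal to learn.
DONOR_EXT <- "AAGT"    # intron positions 3-6 after the donor dinucleotide
ACCEPTOR_EXT <- "TTTTTC"  # polypyrimidine run before the acceptor AG

#' Generate the fixture genome, annotation and truth junctions
#'
#' Builds `n_genes` genes of `n_exons` exons on one chromosome with
#' canonical intron motifs (majority GT..AG) and extended donor/acceptor
#' consensus, plus exon-skipping isoforms. Minus-strand genes carry the
#' reverse complement of the motif on the forward genome strand.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `exons`
#'   (0-based exon table), `junctions` (truth junction data.frame with
#'   `key`, `motif`, `strand`) and `chrom_len`.
#' @export
make_genome_and_annotation <- function(spec) {
  set.seed(spec$seed)
  chrom <- "chr1"
  chars <- character(0)
  exon_rows <- list()
  junc_rows <- list()
  cursor <- sample(seq(spec$intergenic[1], spec$intergenic[2]), 1L)
  pad_chars <- strsplit(rand_dna(cursor), NULL)[[1]]
  chars <- pad_chars
  for (g in seq_len(spec$n_genes)) {
    strand <- if (g %% 2L == 0L) "-" else "+"
    exon_len <- sample(seq(spec$exon_length[1], spec$exon_length[2]),
                       spec$n_exons, replace = TRUE)
    intron_len <- sample(seq(spec$intron_length[1], spec$intron_length[2]),
                         spec$n_exons - 1L, replace = TRUE)
    motifs <- sample(names(spec$motif_freqs), spec$n_exons - 1L,
                     replace = TRUE, prob = spec$motif_freqs)
    gene_len <- sum(exon_len) + sum(intron_len)
    gene_chars <- strsplit(rand_dna(gene_len), NULL)[[1]]
    # exon/intron layout within the gene (0-based, gene-local)
    ex_start <- integer(spec$n_exons); ex_end <- integer(spec$n_exons)
    p <- 0L
    for (e in seq_len(spec$n_exons)) {
      ex_start[e] <- p; ex_end[e] <- p + exon_len[e]
      p <- ex_end[e] + if (e < spec$n_exons) intron_len[e] else 0L
    }
    for (j in seq_len(spec$n_exons - 1L)) {
      i_start <- ex_end[j]; i_end <- ex_start[j + 1L]
      m <- motifs[j]
      if (strand == "+") {
        gene_chars <- plant(gene_chars, i_start,
                            paste0(substr(m, 1, 2), DONOR_EXT))
        gene_chars <- plant(gene_chars, i_end - 8L,
                            paste0(ACCEPTOR_EXT, substr(m, 3, 4)))
      } else {
        rc <- revcomp_chr(paste0(substr(m, 1, 2), DONOR_EXT))
        gene_chars <- plant(gene_chars, i_end - 6L, rc)
        rc <- revcomp_chr(paste0(ACCEPTOR_EXT, substr(m, 3, 4)))
        gene_chars <- plant(gene_chars, i_start, rc)
      }
      junc_rows[[length(junc_rows) + 1L]] <- data.frame(
        gene = g, chrom = chrom,
        start = cursor + i_start, end = cursor + i_end,
        motif = m, strand = strand, skip = FALSE, stringsAsFactors = FALSE)
    }
    gene_id <- sprintf("gene%03d", g)
    # isoform 1: all exons; further isoforms skip one internal exon each
    skippable <- if (spec$n_exons > 2L) seq(2L, spec$n_exons - 1L) else integer(0)
    for (iso in seq_len(spec$isoforms_per_gene)) {
      use <- seq_len(spec$n_exons)
      if (iso > 1L) {
        sk <- skippable[(iso - 2L) %% length(skippable) + 1L]
        use <- setdiff(use, sk)
        junc_rows[[length(junc_rows) + 1L]] <- data.frame(
          gene = g, chrom = chrom,
          start = cursor + ex_end[sk - 1L], end = cursor + ex_start[sk + 1L],
          motif = if (strand == "+") {
            paste0(substr(motifs[sk - 1L], 1, 2), substr(motifs[sk], 3, 4))
          } else {
            paste0(substr(motifs[sk], 1, 2), substr(motifs[sk - 1L], 3, 4))
          },
          strand = strand, skip = TRUE, stringsAsFactors = FALSE)
      }
      tid <- sprintf("%s.%d", gene_id, iso)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gene_id, chrom = chrom,
        start = cursor + ex_start[use], end = cursor + ex_end[use],
        strand = strand, stringsAsFactors = FALSE)
    }
    chars <- c(chars, gene_chars)
    cursor <- cursor + gene_len
    gap <- sample(seq(spec$intergenic[1], spec$intergenic[2]), 1L)
    chars <- c(chars, strsplit(rand_dna(gap), NULL)[[1]])
    cursor <- cursor + gap
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), chrom))
  junctions <- do.call(rbind, junc_rows)
  junctions <- junctions[!duplicated(junction_key(junctions$chrom, junctions$start,
                                                  junctions$end)), , drop = FALSE]
  junctions$key <- junction_key(junctions$chrom, junctions$start, junctions$end)
  rownames(junctions) <- NULL
  list(genome = genome,
       exons = do.call(rbind, exon_rows),
       junctions = junctions,
       chrom_len = length(chars))
}

# Plan one spurious (shifted) variant per genuine junction. Canonical
# variants get their shifted termini planted with the donor/acceptor
# dinucleotides (shift magnitude >= 3 so planting cannot disturb the
# genuine motif).
plan_spurious <- function(fix, spec) {
  set.seed(spec$seed + 1L)
  j <- fix$junctions
  truth_keys <- j$key
  genome_chars <- strsplit(as.character(fix$genome[[1]]), NULL)[[1]]
  plan <- list()
  for (i in seq_len(nrow(j))) {
    canonical <- runif(1) < spec$shift_canonical_fraction
    repeat {
      mag <- if (canonical) sample(3:10, 1L) else sample(1:10, 1L)
      delta <- mag * sample(c(-1L, 1L), 1L)
      s <- j$start[i] + delta; e <- j$end[i] + delta
      if (!junction_key(j$chrom[i], s, e) %in% truth_keys) break
    }
    if (canonical) {
      if (j$strand[i] == "+") {
        genome_chars <- plant(genome_chars, s, "GT")
        genome_chars <- plant(genome_chars, e - 2L, "AG")
      } else {
        genome_chars <- plant(genome_chars, s, "CT")
        genome_chars <- plant(genome_chars, e - 2L, "AC")
      }
    }
    plan[[i]] <- data.frame(
      key = j$key[i], chrom = j$chrom[i],
      start = s, end = e, delta = delta,
      canonical = canonical,
      high_jad = runif(1) < spec$shift_high_jad_fraction,
      stringsAsFactors = FALSE)
  }
  fix$genome <- Biostrings::DNAStringSet(
    setNames(paste(genome_chars, collapse = ""), names(fix$genome)))
  fix$spurious <- do.call(rbind, plan)
  fix
}

# Build cs string + SEQ for one read from its aligned segments, junction
# payloads and mismatch offsets.
build_read_alignment <- function(segments, mismatches, genome_chars) {
  cs <- character(0); seqs <- character(0); cig <- character(0)
  for (s in seq_along(segments)) {
    seg <- segments[[s]]
    ref <- genome_chars[(seg[1] + 1L):seg[2]]
    mm <- sort(unique(mismatches[[s]]))  # 0-based offsets within segment
    qry <- ref
    prev <- 0L
    seg_cs <- character(0)
    for (m in mm) {
      if (m > prev) seg_cs <- c(seg_cs, paste0(":", m - prev))
      rbase <- ref[m + 1L]
      qbase <- sample(setdiff(c("A", "C", "G", "T"), rbase), 1L)
      qry[m + 1L] <- qbase
      seg_cs <- c(seg_cs, paste0("*", tolower(rbase), tolower(qbase)))
      prev <- m + 1L
    }
    len <- seg[2] - seg[1]
    if (len > prev) seg_cs <- c(seg_cs, paste0(":", len - prev))
    cs <- c(cs, paste(seg_cs, collapse = ""))
    seqs <- c(seqs, paste(qry, collapse = ""))
    cig <- c(cig, paste0(len, "M"))
    if (s < length(segments)) {
      nxt <- segments[[s + 1L]]
      ilen <- nxt[1] - seg[2]
      donor <- tolower(paste(genome_chars[(seg[2] + 1L):(seg[2] + 2L)], collapse = ""))
      acceptor <- tolower(paste(genome_chars[(nxt[1] - 1L):nxt[1]], collapse = ""))
      cs <- c(cs, paste0("~", donor, ilen, acceptor))
      cig <- c(cig, paste0(ilen, "N"))
    }
  }
  list(cs = paste(cs, collapse = ""), seq = paste(seqs, collapse = ""),
       cigar = paste(cig, collapse = ""))
}

#' Generate cs-tagged read alignments with controlled errors
#'
#' Emits synthetic alignment records (SAM fields plus long-form cs tags)
#' whose junctions realize three regimes: clean genuine junctions (high
#' JAD), error-adjacent genuine junctions (JAD 0), and injected spurious
#' junctions shifted by 1-10 nt with low read counts. Reads cover their
#' full source isoform.
#'
#' @param fix Fixture from [make_genome_and_annotation()].
#' @param spec The [fixture_spec()] used to build `fix`.
#' @return `fix` extended with `alignments` (data.frame of SAM fields),
#'   `read_truth` (read -> source transcript + chain) and `spurious`
#'   (the spurious junction plan).
#' @export
make_reads_with_errors <- function(fix, spec) {
  fix <- plan_spurious(fix, spec)
  set.seed(spec$seed + 2L)
  genome_chars <- strsplit(as.character(fix$genome[[1]]), NULL)[[1]]
  chains <- transcript_chains(fix$exons)
  chain_of <- setNames(chains$chain, chains$transcript_id)
  spur <- fix$spurious
  spur_of <- split(spur, spur$key)
  aln <- list(); truth <- list()
  n_read <- 0L
  for (tid in unique(fix$exons$transcript_id)) {
    tx <- fix$exons[fix$exons$transcript_id == tid, , drop = FALSE]
    tx <- tx[order(tx$start), , drop = FALSE]
    n_reads <- sample(seq(spec$reads_per_isoform[1], spec$reads_per_isoform[2]), 1L)
    for (r in seq_len(n_reads)) {
      n_read <- n_read + 1L
      segments <- lapply(seq_len(nrow(tx)), function(e) c(tx$start[e], tx$end[e]))
      mismatches <- rep(list(integer(0)), length(segments))
      # junction treatment: spurious shift, JAD capping, adjacent errors
      if (length(segments) > 1L) {
        for (jn in seq_len(length(segments) - 1L)) {
          jkey <- junction_key(tx$chrom[1], segments[[jn]][2], segments[[jn + 1L]][1])
          use_spur <- spec$shift_fraction > 0 && jkey %in% names(spur_of) &&
            runif(1) < spec$shift_fraction
          if (use_spur) {
            sp <- spur_of[[jkey]]
            segments[[jn]][2] <- segments[[jn]][2] + sp$delta
            segments[[jn + 1L]][1] <- segments[[jn + 1L]][1] + sp$delta
            if (!sp$high_jad) {
              k <- sample(0:3, 1L)
              seg_len <- segments[[jn]][2] - segments[[jn]][1]
              mismatches[[jn]] <- c(mismatches[[jn]], seg_len - 1L - k)
            }
          } else if (runif(1) < spec$junction_error_fraction) {
            seg_len <- segments[[jn]][2] - segments[[jn]][1]
            mismatches[[jn]] <- c(mismatches[[jn]], seg_len - 1L)
          }
        }
      }
      # background mismatches away from segment edges
      if (spec$error_rate > 0) {
        for (s in seq_along(segments)) {
          seg_len <- segments[[s]][2] - segments[[s]][1]
          if (seg_len > 12L) {
            interior <- 5:(seg_len - 6L)
            hits <- interior[runif(length(interior)) < spec$error_rate]
            mismatches[[s]] <- c(mismatches[[s]], hits)
          }
        }
      }
      built <- build_read_alignment(segments, mismatches, genome_chars)
      read_id <- sprintf("read%05d", n_read)
      aln[[n_read]] <- data.frame(
        qname = read_id, flag = 0L, chrom = tx$chrom[1],
        pos0 = segments[[1]][1], mapq = 60L,
        cigar = built$cigar, seq = built$seq, cs = built$cs,
        stringsAsFactors = FALSE)
      truth[[n_read]] <- data.frame(
        read_id = read_id, transcript_id = tid,
        chain = unname(chain_of[tid]), stringsAsFactors = FALSE)
    }
  }
  fix$alignments <- do.call(rbind, aln)
  fix$read_truth <- do.call(rbind, truth)
  fix
}

#' Write fixture alignments as an indexed BAM
#'
#' Renders the alignment table as SAM (with cs tags), converts it to a
#' coordinate-sorted indexed BAM via Rsamtools.
#'
#' @param fix Fixture from [make_reads_with_errors()].
#' @param path Output BAM path (without or with `.bam`).
#' @param extra_sam_lines Optional extra SAM record lines appended before
#'   conversion (e.g. secondary alignments for testing skip logic).
#' @return The BAM path.
#' @export
write_fixture_bam <- function(fix, path, extra_sam_lines = character(0)) {
  path <- sub("\\.bam$", "", path)
  sam <- tempfile(fileext = ".sam")
  a <- fix$alignments[order(fix$alignments$chrom, fix$alignments$pos0), , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(fix$genome),
                      Biostrings::width(fix$genome)))
  records <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tcs:Z:%s",
                     a$qname, a$flag, a$chrom, a$pos0 + 1L, a$mapq,
                     a$cigar, a$seq, a$cs)
  writeLines(c(header, records, extra_sam_lines), sam)
  bam <- Rsamtools::asBam(sam, destination = path, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Write a genome as FASTA
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write an exon table as GTF
#' @param exons 0-based exon table (see [read_exon_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  lines <- sprintf(
    '%s\tspliceguide\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Build a complete on-disk fixture
#'
#' Writes `genome.fa`, `annotation.gtf`, `reads.bam` (+ index) and
#' `truth.tsv` (read truth) plus `truth_junctions.tsv` into `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the fixture list with a `paths` element.
#' @export
make_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix <- make_genome_and_annotation(spec)
  fix <- make_reads_with_errors(fix, spec)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    bam = file.path(dir, "reads.bam"),
    truth = file.path(dir, "truth.tsv"),
    truth_junctions = file.path(dir, "truth_junctions.tsv")
  )
  write_fasta(fix$genome, paths$genome)
  write_gtf(fix$exons, paths$annotation)
  write_fixture_bam(fix, paths$bam)
  write.table(fix$read_truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fix$junctions, paths$truth_junctions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fix$paths <- paths
  invisible(fix)
}
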