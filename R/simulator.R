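# Direct-RNA read simulator. Error profiles are learned from splicing-free
# transcriptome alignments (long-form cs tags): a homopolymer call table for
# reference runs of >= 5 nt, and a Markov chain over basecall emissions
# conditioned on the current + previous four reference bases and the
# previous four alignment states. Reads are simulated 3' -> 5' (the
# direction nanopore direct RNA sequencing proceeds in), primed with a
# 10 nt oligo(A) tail, then reverted and trimmed by 10 nt at the 5' end to
# mimic signal loss at the end of sequencing.

revstr <- function(x) {
  vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), "")
}

# ---- pairwise alignment columns -------------------------------------------

# One column per reference base: the aligned query fragment (possibly empty
# for a deletion, multi-base when an insertion is attached to the preceding
# reference base) and the alignment state (=, *, + or -).
alignment_columns <- function(ops, refseq, aln_start = 0L) {
  ref <- character(0); frag <- character(0); state <- character(0)
  pos <- aln_start  # 0-based on the reference
  pending_ins <- ""
  push <- function(r, f, s) {
    if (nzchar(pending_ins)) {
      f <- paste0(pending_ins, f); s <- "+"
      pending_ins <<- ""
    }
    ref[length(ref) + 1L] <<- r
    frag[length(frag) + 1L] <<- f
    state[length(state) + 1L] <<- s
  }
  for (i in seq_len(nrow(ops))) {
    kind <- ops$kind[i]; len <- ops$length[i]
    if (kind == "match") {
      bases <- strsplit(toupper(substr(refseq, pos + 1L, pos + len)), NULL)[[1]]
      for (b in bases) push(b, b, "=")
      pos <- pos + len
    } else if (kind == "mismatch") {
      r <- toupper(substr(ops$bases[i], 1L, 1L))
      q <- toupper(substr(ops$bases[i], 2L, 2L))
      push(r, q, "*")
      pos <- pos + 1L
    } else if (kind == "deletion") {
      bases <- strsplit(toupper(ops$bases[i]), NULL)[[1]]
      for (b in bases) push(b, "", "-")
      pos <- pos + len
    } else if (kind == "insertion") {
      ins <- toupper(ops$bases[i])
      if (length(ref)) {
        frag[length(frag)] <- paste0(frag[length(frag)], ins)
        state[length(state)] <- "+"
      } else {
        pending_ins <- paste0(pending_ins, ins)
      }
    } else if (kind == "refskip") {
      pos <- pos + len  # ignored when modelling transcriptome alignments
    }
  }
  list(ref = ref, frag = frag, state = state)
}

# Invert a column set to the 3' -> 5' sequencing direction.
invert_columns <- function(cols) {
  n <- length(cols$ref)
  if (n == 0L) return(cols)
  idx <- rev(seq_len(n))
  frag <- cols$frag[idx]
  multi <- nchar(frag) > 1L
  frag[multi] <- revstr(frag[multi])
  list(ref = cols$ref[idx], frag = frag, state = cols$state[idx])
}

# Harvest homopolymer emissions (reference runs >= min_len) into `acc`
# (an environment of key -> named count vectors) and replace each run with
# its basecall, aligned as matches.
harvest_homopolymers <- function(cols, acc, min_len = 5L) {
  n <- length(cols$ref)
  if (n == 0L) return(cols)
  r <- rle(cols$ref)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list(); si <- 0L
  for (k in seq_along(r$lengths)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (r$lengths[k] >= min_len) {
      emission <- paste(cols$frag[i0:i1], collapse = "")
      key <- paste0(r$values[k], "|", r$lengths[k])
      cur <- if (exists(key, envir = acc, inherits = FALSE)) get(key, envir = acc) else numeric(0)
      cur[emission] <- if (emission %in% names(cur)) cur[[emission]] + 1 else 1
      assign(key, cur, envir = acc)
      if (nzchar(emission)) {
        eb <- strsplit(emission, NULL)[[1]]
        si <- si + 1L
        segs[[si]] <- list(ref = eb, frag = eb, state = rep("=", length(eb)))
      }
    } else {
      si <- si + 1L
      segs[[si]] <- list(ref = cols$ref[i0:i1], frag = cols$frag[i0:i1],
                         state = cols$state[i0:i1])
    }
  }
  list(ref = unlist(lapply(segs, `[[`, "ref")),
       frag = unlist(lapply(segs, `[[`, "frag")),
       state = unlist(lapply(segs, `[[`, "state")))
}

lagged <- function(x, k, pad) {
  n <- length(x)
  if (k == 0L) return(x)
  c(rep(pad, min(k, n)), x[seq_len(max(0L, n - k))])
}

# Context keys at three backoff levels. Bases and states run oldest ->
# newest; the initial context is oligo(A)/all-match, matching the
# simulation prime.
transition_keys <- function(cols) {
  b0 <- cols$ref
  b1 <- lagged(b0, 1L, "A"); b2 <- lagged(b0, 2L, "A")
  b3 <- lagged(b0, 3L, "A"); b4 <- lagged(b0, 4L, "A")
  s1 <- lagged(cols$state, 1L, "="); s2 <- lagged(cols$state, 2L, "=")
  s3 <- lagged(cols$state, 3L, "="); s4 <- lagged(cols$state, 4L, "=")
  list(
    l0 = paste0(b4, b3, b2, b1, b0, "|", s4, s3, s2, s1),
    l1 = paste0(b4, b3, b2, b1, b0, "|", s3, s2, s1),
    l2 = paste0(b3, b2, b1, b0, "|", s3, s2, s1),
    emission = paste0(cols$frag, "|", cols$state)
  )
}

normalize_counts <- function(counted) {
  lapply(counted, function(cnt) {
    list(emission = names(cnt), prob = as.numeric(cnt) / sum(cnt))
  })
}

#' Build a basecall error model from alignment difference strings
#'
#' Core of [build_error_model()], usable directly on in-memory cs strings.
#' Pairwise alignments are reconstructed per reference base, inverted to
#' the 3' -> 5' sequencing direction, homopolymer emissions (reference
#' runs >= 5 nt) are harvested and the run replaced by its basecall, and
#' the resulting alignments feed a Markov model of emissions conditioned
#' on the current + previous four reference bases and previous four
#' alignment states (with two shorter-context backoff tables).
#'
#' @param cs Character vector of long-form cs tags, one per primary
#'   alignment.
#' @param tx_id Character vector of reference transcript names, parallel
#'   to `cs`.
#' @param pos Integer vector of 0-based leftmost alignment coordinates.
#' @param transcriptome Named [Biostrings::DNAStringSet] (or named
#'   character vector) of transcript sequences.
#' @param min_homopolymer Minimum reference run length modelled by the
#'   homopolymer table. Default 5.
#' @return An object of class `error_model`.
#' @export
error_model_from_cs <- function(cs, tx_id, pos, transcriptome,
                                min_homopolymer = 5L) {
  stopifnot(length(cs) == length(tx_id), length(cs) == length(pos))
  if (!length(cs)) stop("no alignments supplied")
  hp_acc <- new.env(parent = emptyenv())
  keys <- list(l0 = list(), l1 = list(), l2 = list(), emission = list())
  tx_cache <- new.env(parent = emptyenv())
  get_tx <- function(id) {
    if (!exists(id, envir = tx_cache, inherits = FALSE)) {
      s <- if (is.character(transcriptome)) {
        if (!id %in% names(transcriptome)) stop(sprintf("transcript %s absent from FASTA", id))
        transcriptome[[id]]
      } else {
        if (!id %in% names(transcriptome)) stop(sprintf("transcript %s absent from FASTA", id))
        as.character(transcriptome[[id]])
      }
      assign(id, toupper(s), envir = tx_cache)
    }
    get(id, envir = tx_cache)
  }
  n_cols <- 0L
  for (i in seq_along(cs)) {
    ops <- parse_cs_tag(cs[i])
    cols <- alignment_columns(ops, get_tx(tx_id[i]), pos[i])
    cols <- invert_columns(cols)
    cols <- harvest_homopolymers(cols, hp_acc, min_homopolymer)
    if (!length(cols$ref)) next
    tk <- transition_keys(cols)
    keys$l0[[length(keys$l0) + 1L]] <- tk$l0
    keys$l1[[length(keys$l1) + 1L]] <- tk$l1
    keys$l2[[length(keys$l2) + 1L]] <- tk$l2
    keys$emission[[length(keys$emission) + 1L]] <- tk$emission
    n_cols <- n_cols + length(cols$ref)
  }
  em <- unlist(keys$emission)
  count_level <- function(k) {
    k <- unlist(k)
    tab <- table(paste(k, em, sep = "@"))
    parts <- strsplit(names(tab), "@", fixed = TRUE)
    ctx <- vapply(parts, `[[`, "", 1L)
    emi <- vapply(parts, `[[`, "", 2L)
    split_counts <- split(setNames(as.numeric(tab), emi), ctx)
    normalize_counts(split_counts)
  }
  hp_counts <- mget(ls(hp_acc), envir = hp_acc)
  structure(list(
    homopolymer = normalize_counts(hp_counts),
    transition = list(l0 = count_level(keys$l0),
                      l1 = count_level(keys$l1),
                      l2 = count_level(keys$l2)),
    meta = list(alignments = length(cs), columns = n_cols,
                min_homopolymer = as.integer(min_homopolymer))
  ), class = "error_model")
}

#' Build a basecall error model from a transcriptome BAM
#'
#' Reads primary, splicing-free transcriptome alignments carrying
#' long-form cs tags and learns the homopolymer and Markov-chain basecall
#' error model used by [simulate_reads()].
#'
#' @param transcriptome_bam Path to a BAM of reads aligned to the
#'   reference transcriptome (splicing-free alignment mode).
#' @param transcriptome Named [Biostrings::DNAStringSet] of transcript
#'   sequences, or a path to the transcriptome FASTA.
#' @param min_homopolymer Minimum reference run length for the
#'   homopolymer table. Default 5.
#' @return An object of class `error_model`.
#' @export
build_error_model <- function(transcriptome_bam, transcriptome,
                              min_homopolymer = 5L) {
  if (is.character(transcriptome) && length(transcriptome) == 1L &&
      file.exists(transcriptome)) {
    transcriptome <- Biostrings::readDNAStringSet(transcriptome)
    names(transcriptome) <- sub("\\s.*$", "", names(transcriptome))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos"),
    tag = "cs",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(transcriptome_bam, param = param)[[1]]
  cs <- res$tag$cs
  if (is.null(cs) || all(is.na(cs))) {
    stop("no cs tags in ", transcriptome_bam,
         "; realign with long-form cs output enabled")
  }
  ok <- !is.na(cs)
  error_model_from_cs(cs[ok], as.character(res$rname)[ok], res$pos[ok] - 1L,
                      transcriptome, min_homopolymer)
}

#' @export
print.error_model <- function(x, ...) {
  cat("spliceguide basecall error model\n")
  cat(sprintf("  alignments modelled : %d (%d columns)\n",
              x$meta$alignments, x$meta$columns))
  cat(sprintf("  homopolymer contexts: %d (runs >= %d nt)\n",
              length(x$homopolymer), x$meta$min_homopolymer))
  cat(sprintf("  transition contexts : %d (full) / %d / %d (backoff)\n",
              length(x$transition$l0), length(x$transition$l1),
              length(x$transition$l2)))
  invisible(x)
}

draw_from <- function(dist) {
  if (length(dist$emission) == 1L) return(dist$emission)
  dist$emission[sample.int(length(dist$emission), 1L, prob = dist$prob)]
}

last_n <- function(s, n) substring(s, max(1L, nchar(s) - n + 1L))

# Simulate one basecalled sequence along a 3'->5' primed reference.
simulate_emission <- function(chars, model, env0, env1, env2, hp_env,
                              counters) {
  pieces <- character(0)
  pb <- "AAAA"; ps <- "===="
  r <- rle(chars)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  min_hp <- model$meta$min_homopolymer
  for (k in seq_along(r$lengths)) {
    base <- r$values[k]; len <- r$lengths[k]
    if (len >= min_hp) {
      key <- paste0(base, "|", len)
      emission <- if (exists(key, envir = hp_env, inherits = FALSE)) {
        draw_from(get(key, envir = hp_env))
      } else {
        counters$hp_backoff <- counters$hp_backoff + 1L
        strrep(base, len)
      }
      pieces[length(pieces) + 1L] <- emission
      pb <- last_n(paste0(pb, if (nzchar(emission)) emission else base), 4L)
      ps <- "===="
    } else {
      for (j in seq_len(len)) {
        k0 <- paste0(pb, base, "|", ps)
        dist <- NULL
        if (exists(k0, envir = env0, inherits = FALSE)) {
          dist <- get(k0, envir = env0)
        } else {
          counters$backoff1 <- counters$backoff1 + 1L
          k1 <- paste0(pb, base, "|", substr(ps, 2L, 4L))
          if (exists(k1, envir = env1, inherits = FALSE)) {
            dist <- get(k1, envir = env1)
          } else {
            k2 <- paste0(substr(pb, 2L, 4L), base, "|", substr(ps, 2L, 4L))
            if (exists(k2, envir = env2, inherits = FALSE)) {
              dist <- get(k2, envir = env2)
            } else {
              counters$backoff_copy <- counters$backoff_copy + 1L
            }
          }
        }
        if (is.null(dist)) {
          frag <- base; state <- "="
        } else {
          em <- draw_from(dist)
          bar <- regexpr("\\|[^|]*$", em)
          frag <- substr(em, 1L, bar - 1L)
          state <- substring(em, bar + 1L)
        }
        if (nzchar(frag)) pieces[length(pieces) + 1L] <- frag
        pb <- paste0(substr(pb, 2L, 4L), base)
        ps <- paste0(substr(ps, 2L, 4L), state)
      }
    }
  }
  paste(pieces, collapse = "")
}

#' Simulate direct-RNA reads from a transcriptome
#'
#' Each transcript is inverted to the 3' -> 5' sequencing direction and
#' primed with a 10 nt oligo(A) tail so the Markov chain starts from the
#' all-A/all-match context. Reference homopolymers of at least 5 nt are
#' replaced by draws from the homopolymer call table; all other positions
#' are emitted from the Markov transition table (with context backoff for
#' unseen states, falling back to an error-free copy). The simulated
#' sequence is reverted to 5' -> 3' and 10 nt are removed from its 5' end
#' to mimic signal loss at the end of sequencing. No 3' coverage bias is
#' modelled: reads are full length.
#'
#' @param transcriptome Named [Biostrings::DNAStringSet] (or named
#'   character vector) of transcript sequences.
#' @param per_transcript_counts Named integer vector: reads to simulate
#'   per transcript (typically the primary-alignment counts of a real
#'   dataset).
#' @param model An `error_model` from [build_error_model()].
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @param chains Optional data.frame from [transcript_chains()] used to
#'   fill the truth table's intron chains.
#' @return A list with `reads` (named character vector of read sequences),
#'   `truth` (data.frame `read_id`, `transcript_id`, `chain`, `length`)
#'   and `backoffs` (context backoff counters).
#' @export
simulate_reads <- function(transcriptome, per_transcript_counts, model,
                           seed = 1L, chains = NULL) {
  stopifnot(inherits(model, "error_model"))
  bad <- setdiff(names(per_transcript_counts), names(transcriptome))
  if (length(bad)) {
    stop(sprintf("transcripts in counts but not in FASTA: %s",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  env0 <- list2env(model$transition$l0, parent = emptyenv())
  env1 <- list2env(model$transition$l1, parent = emptyenv())
  env2 <- list2env(model$transition$l2, parent = emptyenv())
  hp_env <- list2env(model$homopolymer, parent = emptyenv())
  counters <- new.env(parent = emptyenv())
  counters$hp_backoff <- 0L; counters$backoff1 <- 0L; counters$backoff_copy <- 0L
  chain_of <- if (is.null(chains)) function(tx) "" else {
    lk <- setNames(chains$chain, chains$transcript_id)
    function(tx) if (tx %in% names(lk)) unname(lk[tx]) else ""
  }
  set.seed(seed)
  reads <- character(0); ids <- character(0)
  truth <- list()
  tx_names <- names(per_transcript_counts)[per_transcript_counts > 0L]
  for (tx in tx_names) {
    seq_fwd <- if (is.character(transcriptome)) transcriptome[[tx]] else as.character(transcriptome[[tx]])
    primed <- paste0(strrep("A", 10L), revstr(toupper(seq_fwd)))
    chars <- strsplit(primed, NULL)[[1]]
    for (r in seq_len(per_transcript_counts[[tx]])) {
      emission <- simulate_emission(chars, model, env0, env1, env2, hp_env, counters)
      read <- substring(revstr(emission), 11L)
      id <- sprintf("sim_%s_%d", tx, r)
      ids[length(ids) + 1L] <- id
      reads[length(reads) + 1L] <- read
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = id, transcript_id = tx, chain = chain_of(tx),
        length = nchar(read), stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(read_id = character(), transcript_id = character(),
               chain = character(), length = integer(), stringsAsFactors = FALSE)
  }
  if (counters$backoff_copy > 0L) {
    message(sprintf("simulation context backoffs: %d partial, %d to error-free copy",
                    counters$backoff1, counters$backoff_copy))
  }
  list(reads = setNames(reads, ids), truth = truth,
       backoffs = list(homopolymer = counters$hp_backoff,
                       partial = counters$backoff1,
                       copy = counters$backoff_copy))
}

#' Write simulated reads as FASTQ
#'
#' Base qualities are a constant placeholder (the method never uses
#' qualities).
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(reads)) {
    writeLines(c(paste0("@", id), reads[[id]], "+",
                 strrep("I", nchar(reads[[id]]))), con)
  }
  invisible(path)
}

#' Serialize an error model to versioned JSON
#' @param model An `error_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_model <- function(model, path) {
  obj <- list(format = "spliceguide-errormodel", version = 1L,
              meta = model$meta,
              homopolymer = model$homopolymer,
              transition = model$transition)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an error model from JSON
#' @param path Path written by [write_error_model()].
#' @return An `error_model`.
#' @export
read_error_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "spliceguide-errormodel")) {
    stop(path, " is not a spliceguide error model")
  }
  structure(list(homopolymer = obj$homopolymer,
                 transition = obj$transition,
                 meta = obj$meta),
            class = "error_model")
}
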