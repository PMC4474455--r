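## Three-letter paired-end bisulfite alignment with anchored mate rescue
##
## The aligner works on two converted reference genomes (C->T and G->A).
## Read 1 is C->T-converted and searched forward on the C2T genome (top
## bisulfite strand) and as its reverse complement on the G2A genome
## (bottom strand); read 2 is G->A-converted and searched symmetrically.
## Candidates are found by exact seed lookup (pigeonhole over disjoint
## seeds covers every alignment within the mismatch budget) and verified
## against two conjunctive budgets: at most `max_mm` mismatches in the
## leading `lead` bases, and a summed Phred score at mismatched positions
## of at most `phred_budget`. A mate with multiple candidates is rescued by
## its uniquely aligned partner when exactly one candidate yields a
## convergent fragment inside the fragment-length window.

#' Build converted-genome indexes
#'
#' @param genome named character vector of chromosome sequences.
#' @param seed_length exact-match seed length (>= 12).
#' @return a `converted_index` list holding both converted genomes, their
#'   raw-byte forms, and seed hash tables.
#' @export
build_index <- function(genome, seed_length = 18L) {
  stopifnot(seed_length >= 12L)
  keep <- nchar(genome) >= seed_length
  if (!all(keep)) {
    warning("skipping chromosomes shorter than seed_length: ",
            paste(names(genome)[!keep], collapse = ", "))
    genome <- genome[keep]
  }
  stopifnot(length(genome) > 0)
  build_one <- function(conv) {
    gg <- vapply(genome, conv, "")
    env <- new.env(hash = TRUE, parent = emptyenv())
    for (ch in names(gg)) {
      s <- gg[[ch]]
      n <- nchar(s) - seed_length + 1L
      seeds <- substring(s, 1:n, seed_length:(n + seed_length - 1L))
      hit <- split(0:(n - 1L), seeds)
      for (k in names(hit)) {
        prev <- env[[k]]
        env[[k]] <- if (is.null(prev)) list(ch = ch, pos = hit[[k]])
          else list(ch = c(prev$ch, rep(ch, length(hit[[k]]))),
                    pos = c(prev$pos, hit[[k]]))
      }
    }
    ## normalise: ch recycled to one per position
    for (k in ls(env)) {
      v <- env[[k]]
      if (length(v$ch) != length(v$pos))
        v$ch <- rep(v$ch, length.out = length(v$pos))
      env[[k]] <- v
    }
    list(seq = gg, raw = lapply(gg, charToRaw), env = env)
  }
  structure(list(c2t = build_one(c2t), g2a = build_one(g2a),
                 seed_length = as.integer(seed_length),
                 chrom_lengths = nchar(genome)),
            class = "converted_index")
}

#' Convert a read pair for three-letter alignment
#'
#' @param read1,read2 character vectors of raw read sequences.
#' @return list with `read1` (C->T converted) and `read2` (G->A converted);
#'   originals are kept by the caller for methylation calling.
#' @export
convert_reads <- function(read1, read2) {
  list(read1 = c2t(read1), read2 = g2a(read2))
}

## verify candidate starts of query q (raw) on converted chromosome graw;
## returns data.frame(pos, mm, phred) of survivors
.verify <- function(q, graw, starts, max_mm, lead, phred_budget, qual) {
  L <- length(q)
  keep_pos <- integer(0); keep_mm <- integer(0)
  glen <- length(graw)
  for (p in starts) {
    if (p < 0L || p + L > glen) next
    d <- graw[(p + 1L):(p + L)] != q
    mm_lead <- sum(d[seq_len(min(lead, L))])
    mm_tot <- sum(d)
    if (mm_lead <= max_mm && mm_tot * qual <= phred_budget) {
      keep_pos <- c(keep_pos, p); keep_mm <- c(keep_mm, mm_tot)
    }
  }
  list(pos = keep_pos, mm = keep_mm)
}

## seed offsets guaranteeing pigeonhole completeness for <= max_total
## mismatches (max_total + 1 disjoint seeds when the read is long enough)
.seed_offsets <- function(L, sl, n_seeds) {
  n <- min(n_seeds, L %/% sl)
  if (n <= 1L) return(0L)
  as.integer(round(seq(0L, L - sl, length.out = n)))
}

#' Align one converted read against the converted genomes
#'
#' Searches the strand combinations of the directional protocol for the
#' given mate and returns all candidate placements passing both budgets,
#' ranked by summed Phred at mismatches (ascending), capped at `max_hits`.
#'
#' @param query converted read sequence (C->T for mate 1, G->A for mate 2).
#' @param index a [build_index()] result.
#' @param mate 1 or 2; selects which converted genome is searched forward.
#' @param max_mm mismatch budget in the leading `lead` bases.
#' @param lead length of the leading window (bases).
#' @param phred_budget maximum summed base quality at mismatched positions.
#' @param qual Phred value assumed per base.
#' @param max_hits maximum number of retained candidates.
#' @return data.table: chrom, start (0-based read start), frag_strand,
#'   mm, phred, unique.
#' @export
align_read <- function(query, index, mate = 1L, max_mm = 3L, lead = 40L,
                       phred_budget = 140L, qual = 40L, max_hits = 20L) {
  r <- .align_read_core(query, revcomp1(query), index, mate, max_mm, lead,
                        phred_budget, qual, max_hits)
  data.table::data.table(chrom = r$chrom, start = r$start,
                         frag_strand = r$frag_strand, mm = r$mm,
                         phred = r$phred, unique = r$unique)
}

## vector-based core shared with align_pairs(); returns a list of columns
.align_read_core <- function(query, query_rc, index, mate, max_mm, lead,
                             phred_budget, qual, max_hits) {
  L <- nchar(query)
  sl <- index$seed_length
  stopifnot(L >= sl)
  n_seeds <- floor(phred_budget / qual) + 1L
  offs <- .seed_offsets(L, sl, n_seeds)

  search <- function(q, side) {
    env <- index[[side]]$env
    seeds <- substring(q, offs + 1L, offs + sl)
    ch <- character(0); pos <- integer(0)
    for (i in seq_along(seeds)) {
      h <- env[[seeds[i]]]
      if (is.null(h)) next
      ch <- c(ch, h$ch); pos <- c(pos, h$pos - offs[i])
    }
    if (!length(pos)) return(NULL)
    dup <- duplicated(paste0(ch, "\r", pos))
    ch <- ch[!dup]; pos <- pos[!dup]
    qr <- charToRaw(q)
    och <- character(0); opos <- integer(0); omm <- integer(0)
    for (c1 in unique(ch)) {
      v <- .verify(qr, index[[side]]$raw[[c1]], pos[ch == c1], max_mm,
                   lead, phred_budget, qual)
      if (length(v$pos)) {
        och <- c(och, rep(c1, length(v$pos)))
        opos <- c(opos, v$pos); omm <- c(omm, v$mm)
      }
    }
    if (!length(opos)) return(NULL)
    list(ch = och, pos = opos, mm = omm)
  }

  if (mate == 1L) {
    fwd <- search(query, "c2t");   fs_f <- "+"  # read1 fwd on C2T: top
    rev <- search(query_rc, "g2a"); fs_r <- "-"
  } else {
    fwd <- search(query, "g2a");   fs_f <- "-"  # read2 fwd on G2A: bottom
    rev <- search(query_rc, "c2t"); fs_r <- "+"
  }
  chrom <- c(fwd$ch, rev$ch)
  if (!length(chrom))
    return(list(chrom = character(0), start = integer(0),
                frag_strand = character(0), mm = integer(0),
                phred = integer(0), unique = logical(0)))
  start <- c(fwd$pos, rev$pos)
  mm <- c(fwd$mm, rev$mm)
  strand <- c(rep(fs_f, length(fwd$pos)), rep(fs_r, length(rev$pos)))
  phred <- mm * qual
  o <- order(phred, chrom, start)
  if (length(o) > max_hits) o <- o[seq_len(max_hits)]
  list(chrom = chrom[o], start = as.integer(start[o]),
       frag_strand = strand[o], mm = as.integer(mm[o]),
       phred = as.integer(phred[o]), unique = length(o) == 1L)
}

#' Resolve a read pair from its candidate lists
#'
#' Implements anchored cluster end-mapping: both-unique concordant pairs
#' pass through; a multi-mapping mate is rescued by its unique partner when
#' exactly one of its candidates gives a same-chromosome, convergent
#' fragment whose length falls in `fragment_window`; anything else is
#' unresolved.
#'
#' @param cands1,cands2 candidate tables from [align_read()] for mates 1
#'   and 2.
#' @param read_len1,read_len2 read lengths.
#' @param fragment_window numeric length-2 vector, inclusive fragment
#'   length bounds.
#' @return one-row data.table: chrom, start, end, strand, score,
#'   resolution ("both_unique", "rescued" or "unresolved").
#' @export
resolve_pair <- function(cands1, cands2, read_len1, read_len2,
                         fragment_window = c(300, 600)) {
  r <- .resolve_core(as.list(cands1), as.list(cands2), read_len1,
                     read_len2, fragment_window)
  data.table::as.data.table(r)
}

## list-based core: cands are lists with chrom, start, frag_strand, phred
.resolve_core <- function(c1, c2, read_len1, read_len2, fragment_window) {
  unresolved <- list(chrom = NA_character_, start = NA_integer_,
                     end = NA_integer_, strand = NA_character_,
                     score = NA_integer_, resolution = "unresolved")
  n1 <- length(c1$start); n2 <- length(c2$start)
  if (n1 == 0L || n2 == 0L) return(unresolved)

  ## fragment implied by candidate pair (i anchors read1, j read2):
  ## strand "+": read1 starts the fragment, read2 ends it; "-" mirrored.
  frag <- function(i, j) {
    if (c1$chrom[i] != c2$chrom[j] ||
        c1$frag_strand[i] != c2$frag_strand[j]) return(NULL)
    if (c1$frag_strand[i] == "+") {
      s <- c1$start[i]; e <- c2$start[j] + read_len2
    } else {
      s <- c2$start[j]; e <- c1$start[i] + read_len1
    }
    len <- e - s
    if (len < fragment_window[1] || len > fragment_window[2] || s >= e)
      return(NULL)
    list(chrom = c1$chrom[i], start = as.integer(s), end = as.integer(e),
         strand = c1$frag_strand[i],
         score = as.integer(c1$phred[i] + c2$phred[j]))
  }

  u1 <- n1 == 1L; u2 <- n2 == 1L
  if (u1 && u2) {
    f <- frag(1L, 1L)
    if (is.null(f)) return(unresolved)
    return(c(f, list(resolution = "both_unique")))
  }
  if (u1 != u2) {
    hits <- list()
    idx <- seq_len(if (u1) n2 else n1)
    for (k in idx) {
      f <- if (u1) frag(1L, k) else frag(k, 1L)
      if (!is.null(f)) hits[[length(hits) + 1L]] <- f
    }
    if (length(hits) == 1L)
      return(c(hits[[1]], list(resolution = "rescued")))
  }
  unresolved
}

#' Align a table of read pairs
#'
#' Drives [align_read()] and [resolve_pair()] over a pairs table (columns
#' read_id, seq1, seq2) and returns resolved alignments with original read
#' sequences attached for methylation calling.
#'
#' @param reads data.table with read_id, seq1, seq2 (raw sequences), e.g.
#'   the `pairs` table of [simulate_bsseq_reads()] or
#'   [read_fastq_pairs()] output.
#' @param index a [build_index()] result.
#' @param fragment_window inclusive fragment-length window.
#' @param keep_unresolved keep unresolved rows (default drops them).
#' @inheritParams align_read
#' @return data.table: read_id, chrom, start, end, strand, score,
#'   resolution, seq1, seq2.
#' @export
align_pairs <- function(reads, index, fragment_window = c(300, 600),
                        max_mm = 3L, lead = 40L, phred_budget = 140L,
                        qual = 40L, max_hits = 20L,
                        keep_unresolved = FALSE) {
  conv <- convert_reads(reads$seq1, reads$seq2)
  rc1 <- revcomp(conv$read1); rc2 <- revcomp(conv$read2)
  n <- nrow(reads)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    c1 <- .align_read_core(conv$read1[i], rc1[i], index, 1L, max_mm, lead,
                           phred_budget, qual, max_hits)
    c2 <- .align_read_core(conv$read2[i], rc2[i], index, 2L, max_mm, lead,
                           phred_budget, qual, max_hits)
    out[[i]] <- .resolve_core(c1, c2, nchar(reads$seq1[i]),
                              nchar(reads$seq2[i]), fragment_window)
  }
  res <- data.table::rbindlist(out)
  res[, `:=`(read_id = reads$read_id, seq1 = reads$seq1,
             seq2 = reads$seq2)]
  data.table::setcolorder(res, c("read_id", "chrom", "start", "end",
                                 "strand", "score", "resolution",
                                 "seq1", "seq2"))
  if (!keep_unresolved) res <- res[res$resolution != "unresolved"]
  res[]
}
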