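## Per-cytosine methylation calling
##
## The unit of observation is one strand-specific cytosine with rC (reads
## retaining C after bisulfite treatment) and rT (reads converted to T).
## The methylation rate is S = rC / (rC + rT); regional values pool counts,
## never average per-site rates. Internally every position is a top-strand
## coordinate: a "-" strand call at pos refers to the bottom-strand C whose
## paired top-strand base (a G) sits at pos.

#' Reference cytosine table for one chromosome sequence
#'
#' Enumerates every cytosine on both strands with its sequence context.
#' Context labels are CG / CHG / CHH (mutually exclusive); the overlapping
#' special contexts CWG (C[A/T]G), GC and GWC (G[A/T]C) are carried as
#' logical flags since a site can be, e.g., both CHG and CWG, or both CG
#' and GC.
#'
#' @param seq one chromosome sequence (character scalar).
#' @return data.table: pos (0-based top-strand coordinate), strand,
#'   context, cwg, gc, gwc.
#' @export
cytosine_reference <- function(seq) {
  ch <- seq_chars(seq)
  n <- length(ch)
  at <- function(i) {
    out <- rep("N", length(i))
    ok <- i >= 1L & i <= n
    out[ok] <- ch[i[ok]]
    out
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ref_one <- function(strand) {
    if (strand == "+") {
      pos <- which(ch == "C")
      nxt1 <- at(pos + 1L); nxt2 <- at(pos + 2L)
      prv1 <- at(pos - 1L); prv2 <- at(pos - 2L)
    } else {
      ## bottom-strand C = top-strand G; neighbours read 3'->5' on top,
      ## complemented
      pos <- which(ch == "G")
      nxt1 <- unname(comp[at(pos - 1L)]); nxt2 <- unname(comp[at(pos - 2L)])
      prv1 <- unname(comp[at(pos + 1L)]); prv2 <- unname(comp[at(pos + 2L)])
    }
    context <- ifelse(nxt1 == "G", "CG",
                      ifelse(nxt2 == "G", "CHG", "CHH"))
    data.table::data.table(
      pos = pos - 1L, strand = strand, context = context,
      cwg = nxt1 %in% c("A", "T") & nxt2 == "G",
      gc = prv1 == "G",
      gwc = prv1 %in% c("A", "T") & prv2 == "G")
  }
  out <- rbind(ref_one("+"), ref_one("-"))
  data.table::setorder(out, pos, strand)
  out[]
}

#' Classify the context of one cytosine
#'
#' @param genome named character vector.
#' @param chrom chromosome name.
#' @param pos 0-based top-strand coordinate of the cytosine (its G for the
#'   "-" strand).
#' @param strand "+" or "-".
#' @return list with `context` ("CG"/"CHG"/"CHH") and logical flags `cwg`,
#'   `gc`, `gwc`.
#' @export
classify_context <- function(genome, chrom, pos, strand = "+") {
  ref <- cytosine_reference(genome[[chrom]])
  sel <- which(ref$pos == pos & ref$strand == strand)
  row <- ref[sel]
  if (!nrow(row))
    stop("domain error: position ", pos, " (", strand,
         ") is not a cytosine")
  as.list(row[1, c("context", "cwg", "gc", "gwc")])
}

#' Methylation rate
#'
#' @param rC,rT read counts retaining C / converted to T.
#' @return rC / (rC + rT), or NA when uncovered.
#' @export
methylation_rate <- function(rC, rT) {
  tot <- rC + rT
  ifelse(tot > 0, rC / tot, NA_real_)
}

#' Overall (pooled) methylation of a set of calls
#'
#' Count-weighted: S = sum(rC) / (sum(rC) + sum(rT)). This is not the mean
#' of per-site rates.
#'
#' @param calls data.frame with rC and rT columns.
#' @return pooled methylation rate, NA when total coverage is zero.
#' @export
overall_methylation <- function(calls) {
  methylation_rate(sum(calls$rC), sum(calls$rT))
}

#' Pile up deduplicated alignments into per-cytosine calls
#'
#' For every reference cytosine covered at least once, counts reads showing
#' C (rC) versus T (rT) on the bisulfite strand that interrogates it; "+"
#' strand fragments interrogate top-strand cytosines, "-" fragments
#' bottom-strand ones. Read bases other than C/T (in bottom-orientation:
#' G/A) at a cytosine are excluded from both counts.
#'
#' @param clones alignment table (monoclonized or not): chrom, start, end,
#'   strand, seq1, seq2.
#' @param genome named character vector.
#' @param min_cov minimum coverage for a site to be reported.
#' @return data.table: chrom, pos, strand, context, cwg, gc, gwc, rC, rT,
#'   coverage.
#' @export
pileup <- function(clones, genome, min_cov = 1L) {
  clones <- data.table::as.data.table(clones)
  glen <- nchar(genome)
  ok <- clones$chrom %in% names(genome) & clones$start >= 0 &
    clones$end <= glen[clones$chrom]
  if (any(!ok)) {
    warning(sum(!ok), " alignment(s) beyond chromosome bounds skipped")
    clones <- clones[ok]
  }
  if (!nrow(clones))
    return(data.table::data.table(
      chrom = character(0), pos = integer(0), strand = character(0),
      context = character(0), cwg = logical(0), gc = logical(0),
      gwc = logical(0), rC = integer(0), rT = integer(0),
      coverage = integer(0)))

  L1 <- nchar(clones$seq1); L2 <- nchar(clones$seq2)
  plus <- clones$strand == "+"
  ## two top-oriented segments per clone (read1 end and read2 end of the
  ## fragment); for "-" fragments the segment strings carry the complement
  ## of the bottom-strand bases, so retained C shows as G, converted as A
  seg <- data.table::data.table(
    chrom = rep(clones$chrom, 2L),
    start = c(ifelse(plus, clones$start, clones$end - L1),
              ifelse(plus, clones$end - L2, clones$start)),
    seq = c(ifelse(plus, clones$seq1, revcomp(clones$seq1)),
            ifelse(plus, revcomp(clones$seq2), clones$seq2)),
    strand = rep(ifelse(plus, "+", "-"), 2L))

  len <- nchar(seg$seq)
  idx <- sequence(len)
  rows <- rep(seq_len(nrow(seg)), len)
  clone_id <- rep(seq_len(nrow(clones)), 2L)
  long <- data.table::data.table(
    clone = clone_id[rows],
    chrom = seg$chrom[rows],
    pos = seg$start[rows] + idx - 1L,
    strand = seg$strand[rows],
    base = substring(seg$seq[rows], idx, idx))
  ## mates of one clone overlapping in the fragment middle interrogate the
  ## same molecule: count each clone once per position
  long <- unique(long, by = c("clone", "chrom", "pos", "strand"))

  retained <- ifelse(long$strand == "+", "C", "G")
  converted <- ifelse(long$strand == "+", "T", "A")
  long <- long[long$base == retained | long$base == converted]
  long[, isC := base == ifelse(strand == "+", "C", "G")]

  counts <- long[, list(rC = sum(isC), rT = sum(!isC)),
                 by = c("chrom", "pos", "strand")]

  ## keep only reference cytosines and attach context
  refs <- data.table::rbindlist(lapply(names(genome), function(chn) {
    r <- cytosine_reference(genome[[chn]])
    r[, chrom := chn]
    r
  }))
  out <- merge(counts, refs, by = c("chrom", "pos", "strand"))
  out[, coverage := rC + rT]
  out <- out[out$coverage >= min_cov]
  data.table::setorder(out, chrom, pos, strand)
  data.table::setcolorder(out, c("chrom", "pos", "strand", "context",
                                 "cwg", "gc", "gwc", "rC", "rT",
                                 "coverage"))
  out[]
}

#' Combine the two strands of each CG site
#'
#' One record per CG dinucleotide, keyed by the top-strand C position; the
#' per-strand rates Sp/Sn are retained for strand-bias analyses, and the
#' combined rate pools counts from both strands.
#'
#' @param calls pileup table (CG-context rows are used).
#' @param genome optional genome to annotate CG density per site.
#' @return data.table: chrom, pos, rC_p, rT_p, rC_n, rT_n, Sp, Sn,
#'   S_combined, cov_p, cov_n, coverage (combined), and cg_density if a
#'   genome is given.
#' @export
combine_cg_strands <- function(calls, genome = NULL) {
  cg <- data.table::as.data.table(calls)[context == "CG"]
  p <- cg[strand == "+", list(chrom, pos, rC_p = rC, rT_p = rT)]
  n <- cg[strand == "-", list(chrom, pos = pos - 1L, rC_n = rC,
                              rT_n = rT)]
  out <- merge(p, n, by = c("chrom", "pos"), all = TRUE)
  for (col in c("rC_p", "rT_p", "rC_n", "rT_n"))
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  out[, `:=`(Sp = methylation_rate(rC_p, rT_p),
             Sn = methylation_rate(rC_n, rT_n),
             S_combined = methylation_rate(rC_p + rC_n, rT_p + rT_n),
             cov_p = rC_p + rT_p, cov_n = rC_n + rT_n)]
  out[, coverage := cov_p + cov_n]
  if (!is.null(genome)) {
    out[, cg_density := cg_density_vec(genome, chrom, pos), by = chrom]
  }
  data.table::setorder(out, chrom, pos)
  out[]
}

#' CG density around one CG site
#'
#' Number of CG dinucleotides (top-strand C positions) within the 600-bp
#' window centred on the site (300 bp each side, focal site included);
#' windows truncated at chromosome ends are counted as-is.
#'
#' @param genome named character vector.
#' @param chrom chromosome name.
#' @param pos 0-based top-strand C position of the focal CG.
#' @param halfwin half-window in bases (default 300).
#' @return integer CG count.
#' @export
cg_density <- function(genome, chrom, pos, halfwin = 300L) {
  cg_density_vec(genome, rep(chrom, length(pos)), pos, halfwin)
}

## vectorised over positions of (possibly) several chromosomes
cg_density_vec <- function(genome, chrom, pos, halfwin = 300L) {
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    cgs <- cg_positions(genome[[ch]])
    lo <- findInterval(pos[sel] - halfwin - 0.5, cgs)
    hi <- findInterval(pos[sel] + halfwin + 0.5, cgs)
    out[sel] <- hi - lo
  }
  out
}

#' Write a CX-style cytosine report
#'
#' Tab-delimited with 1-based positions: chrom, pos, strand, context, rC,
#' rT. A bedGraph of per-site methylation rates can be written alongside.
#'
#' @param calls pileup table.
#' @param file output TSV path.
#' @param bedgraph optional bedGraph path (0-based half-open, MR column).
#' @return invisibly, `file`.
#' @export
write_cx_report <- function(calls, file, bedgraph = NULL) {
  cx <- data.frame(chrom = calls$chrom, pos = calls$pos + 1L,
                   strand = calls$strand, context = calls$context,
                   rC = calls$rC, rT = calls$rT)
  write.table(cx, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedgraph)) {
    bg <- data.frame(chrom = calls$chrom, start = calls$pos,
                     end = calls$pos + 1L,
                     mr = round(methylation_rate(calls$rC, calls$rT), 4))
    write.table(bg, bedgraph, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
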