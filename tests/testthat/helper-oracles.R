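## Independent brute-force oracles used to cross-check the package's
## aligner, RRMR scanner, interval assignment and enrichment test. These
## are deliberately naive re-implementations (full scans, explicit loops)
## that share no code with the package internals.

## --- brute-force three-letter aligner -----------------------------------

bf_convert_genomes <- function(genome) {
  list(c2t = lapply(genome, function(s) charToRaw(chartr("C", "T", s))),
       g2a = lapply(genome, function(s) charToRaw(chartr("G", "A", s))))
}

## all positions of query q in every chromosome of one converted genome
## passing the leading-window mismatch and Phred budgets
bf_scan <- function(q, conv, max_mm = 3L, lead = 40L, phred = 140L,
                    qual = 40L) {
  qr <- charToRaw(q)
  L <- length(qr)
  ch_out <- character(0); pos_out <- integer(0); mm_out <- integer(0)
  for (ch in names(conv)) {
    g <- conv[[ch]]
    N <- length(g) - L + 1L
    if (N < 1L) next
    mmt <- integer(N); mml <- integer(N)
    for (j in seq_len(L)) {
      d <- g[j:(j + N - 1L)] != qr[j]
      mmt <- mmt + d
      if (j <= lead) mml <- mml + d
    }
    hit <- which(mml <= max_mm & mmt * qual <= phred)
    if (length(hit)) {
      ch_out <- c(ch_out, rep(ch, length(hit)))
      pos_out <- c(pos_out, hit - 1L)
      mm_out <- c(mm_out, mmt[hit])
    }
  }
  list(ch = ch_out, pos = pos_out, mm = mm_out)
}

bf_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## full brute-force resolution of one read pair; mirrors the directional
## protocol and the rescue policy, independently of the package code
bf_align_pair <- function(seq1, seq2, cg, window = c(300, 600),
                          max_mm = 3L, lead = 40L, phred = 140L,
                          qual = 40L) {
  q1 <- chartr("C", "T", seq1); q2 <- chartr("G", "A", seq2)
  L1 <- nchar(seq1); L2 <- nchar(seq2)
  f1 <- bf_scan(q1, cg$c2t, max_mm, lead, phred, qual)
  r1 <- bf_scan(bf_rc(q1), cg$g2a, max_mm, lead, phred, qual)
  f2 <- bf_scan(q2, cg$g2a, max_mm, lead, phred, qual)
  r2 <- bf_scan(bf_rc(q2), cg$c2t, max_mm, lead, phred, qual)
  c1 <- list(ch = c(f1$ch, r1$ch), pos = c(f1$pos, r1$pos),
             st = c(rep("+", length(f1$pos)), rep("-", length(r1$pos))),
             mm = c(f1$mm, r1$mm))
  c2 <- list(ch = c(f2$ch, r2$ch), pos = c(f2$pos, r2$pos),
             st = c(rep("-", length(f2$pos)), rep("+", length(r2$pos))),
             mm = c(f2$mm, r2$mm))
  n1 <- length(c1$pos); n2 <- length(c2$pos)
  none <- list(resolution = "unresolved", chrom = NA, start = NA,
               end = NA, strand = NA)
  if (n1 == 0L || n2 == 0L) return(none)
  ok <- NULL
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (c1$ch[i] != c2$ch[j] || c1$st[i] != c2$st[j]) next
    if (c1$st[i] == "+") { s <- c1$pos[i]; e <- c2$pos[j] + L2 }
    else { s <- c2$pos[j]; e <- c1$pos[i] + L1 }
    if (e - s >= window[1] && e - s <= window[2] && s < e)
      ok <- rbind(ok, data.frame(i = i, j = j, chrom = c1$ch[i],
                                 start = s, end = e, strand = c1$st[i]))
  }
  if (n1 == 1L && n2 == 1L) {
    if (!is.null(ok) && nrow(ok) == 1L)
      return(list(resolution = "both_unique", chrom = ok$chrom,
                  start = ok$start, end = ok$end, strand = ok$strand))
    return(none)
  }
  if (xor(n1 == 1L, n2 == 1L) && !is.null(ok)) {
    anchored <- if (n1 == 1L) ok[ok$i == 1L, ] else ok[ok$j == 1L, ]
    if (nrow(anchored) == 1L)
      return(list(resolution = "rescued", chrom = anchored$chrom,
                  start = anchored$start, end = anchored$end,
                  strand = anchored$strand))
  }
  none
}

## --- brute-force maximal-run RRMR enumeration ---------------------------

bf_rrmr <- function(wt, ko, min_run, di_thr = 0.3, min_cov = 6L) {
  res <- NULL
  for (ch in sort(unique(wt$chrom))) {
    w <- wt[wt$chrom == ch, ]; k <- ko[ko$chrom == ch, ]
    common <- sort(intersect(w$pos, k$pos))
    w <- w[match(common, w$pos), ]; k <- k[match(common, k$pos), ]
    keep <- w$coverage > min_cov & k$coverage > min_cov
    w <- w[keep, ]; k <- k[keep, ]
    nq <- nrow(w)
    if (!nq) next
    q <- logical(nq)
    for (i in seq_len(nq)) {
      swt <- w$S_combined[i]; sko <- k$S_combined[i]
      q[i] <- !is.na(swt) && !is.na(sko) && swt > 0 &&
        ((swt - sko) / swt) < di_thr
    }
    i <- 1L
    while (i <= nq) {
      if (q[i]) {
        j <- i
        while (j < nq && q[j + 1L]) j <- j + 1L
        if (j - i + 1L >= min_run)
          res <- rbind(res, data.frame(chrom = ch, start = w$pos[i],
                                       end = w$pos[j] + 2L,
                                       n_cg = j - i + 1L))
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (is.null(res))
    data.frame(chrom = character(0), start = integer(0),
               end = integer(0), n_cg = integer(0))
  else res
}

## --- brute-force interval assignment ------------------------------------

bf_assign <- function(rrmrs, repeats, gap) {
  out <- rep(NA_integer_, nrow(rrmrs))
  for (i in seq_len(nrow(rrmrs))) {
    best <- NA_integer_; bd <- Inf; bov <- -1L; bs <- Inf
    for (j in seq_len(nrow(repeats))) {
      if (rrmrs$chrom[i] != repeats$chrom[j]) next
      d <- max(0L, max(rrmrs$start[i], repeats$start[j]) -
                 min(rrmrs$end[i], repeats$end[j]))
      if (d > gap) next
      ov <- max(0L, min(rrmrs$end[i], repeats$end[j]) -
                  max(rrmrs$start[i], repeats$start[j]))
      if (d < bd || (d == bd && ov > bov) ||
          (d == bd && ov == bov && repeats$start[j] < bs)) {
        best <- j; bd <- d; bov <- ov; bs <- repeats$start[j]
      }
    }
    out[i] <- best
  }
  out
}

## --- exact two-sided Fisher p by hypergeometric enumeration -------------

bf_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(m, k)
  ps <- stats::dhyper(xs, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(ps[ps <= p0 * (1 + 1e-7)])
}

## --- small builders ------------------------------------------------------

## combined CG-site table from raw per-strand counts
cg_table <- function(pos, rc_p, rt_p, rc_n, rt_n, chrom = "chr1") {
  data.table::data.table(
    chrom = chrom, pos = as.integer(pos),
    rC_p = as.integer(rc_p), rT_p = as.integer(rt_p),
    rC_n = as.integer(rc_n), rT_n = as.integer(rt_n),
    Sp = methylation_rate(rc_p, rt_p),
    Sn = methylation_rate(rc_n, rt_n),
    S_combined = methylation_rate(rc_p + rc_n, rt_p + rt_n),
    cov_p = as.integer(rc_p + rt_p), cov_n = as.integer(rc_n + rt_n),
    coverage = as.integer(rc_p + rt_p + rc_n + rt_n))
}
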