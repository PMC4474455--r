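## Paired-end bisulfite read simulation
##
## Directional (Lister-style) libraries only: read 1 reports the
## bisulfite-converted original strand of the sonication fragment, read 2
## its reverse complement from the far end. PCR bias is modelled as a
## per-fragment amplification factor applied to whole fragments before
## read emission, exactly the situation monoclonization is designed to
## undo.

#' Sequencing-library parameters
#'
#' @param fragment_min,fragment_max sonication fragment-length range in
#'   bases (size-selected range; default 300-600).
#' @param read_length read length in bases.
#' @param conversion_rate probability that an unmethylated cytosine is read
#'   as T (bisulfite conversion efficiency, in (0.95, 1]).
#' @param depth target mean read coverage per base (e.g. 30 for 30x).
#' @param error_rate per-base sequencing substitution rate (default 0).
#' @param quality constant Phred quality character for emitted bases.
#' @return a `library_params` list.
#' @export
library_params <- function(fragment_min = 300L, fragment_max = 600L,
                           read_length = 75L, conversion_rate = 0.995,
                           depth = 30, error_rate = 0, quality = "I") {
  stopifnot(fragment_min < fragment_max,
            conversion_rate > 0.95, conversion_rate <= 1,
            error_rate >= 0, error_rate < 1)
  if (read_length > fragment_min)
    stop("parameter error: read_length exceeds fragment_min")
  structure(list(fragment_min = as.integer(fragment_min),
                 fragment_max = as.integer(fragment_max),
                 read_length = as.integer(read_length),
                 conversion_rate = conversion_rate, depth = depth,
                 error_rate = error_rate, quality = quality),
            class = "library_params")
}

.add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- seq_chars(s)
    hit <- which(runif(length(ch)) < rate)
    for (i in hit)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate paired-end bisulfite reads
#'
#' Fragments are drawn uniformly over the genome with lengths uniform in
#' the library's fragment window, or supplied explicitly. Each cytosine of
#' a fragment's original strand is methylated with its assigned probability
#' (independently per fragment/molecule); unmethylated cytosines read as T
#' with probability `conversion_rate`. Amplification duplicates whole
#' fragments before read emission, so the emitted pair count equals the sum
#' of amplification factors.
#'
#' @param genome named character vector of chromosome sequences.
#' @param probs probability table from [assign_methylome()].
#' @param lib a [library_params()].
#' @param n_fragments number of distinct fragments; default derived from
#'   `lib$depth`.
#' @param fragments optional explicit fragments: data.frame with chrom,
#'   start, end, strand and optionally `amplification` (integer >= 1) and
#'   `force_meth` (0/1/NA: force the methylation state of every cytosine in
#'   the fragment, NA = draw from `probs`).
#' @param amplification optional integer vector of per-fragment
#'   amplification factors for randomly drawn fragments (recycled).
#' @param seed integer seed.
#' @return list with `pairs` (one row per emitted read pair: read_id,
#'   frag_id, chrom, start, end, strand, seq1, seq2), `truth` (one row per
#'   fragment: frag_id, chrom, start, end, strand, amplification,
#'   meth -- comma-separated "pos:state" of its cytosines) and `lib`.
#' @export
simulate_bsseq_reads <- function(genome, probs, lib = library_params(),
                                 n_fragments = NULL, fragments = NULL,
                                 amplification = 1L, seed = 1L) {
  stopifnot(inherits(lib, "library_params"))
  L <- lib$read_length
  with_seed(seed, {
    if (is.null(fragments)) {
      glen <- nchar(genome)
      if (is.null(n_fragments))
        n_fragments <- ceiling(lib$depth * sum(glen) / (2 * L))
      chrom <- sample(names(genome), n_fragments, replace = TRUE,
                      prob = glen / sum(glen))
      flen <- sample(seq.int(lib$fragment_min, lib$fragment_max),
                     n_fragments, replace = TRUE)
      start <- floor(runif(n_fragments) *
                       (glen[chrom] - flen)) |> as.integer()
      fragments <- data.table::data.table(
        chrom = chrom, start = start, end = start + flen,
        strand = sample(c("+", "-"), n_fragments, replace = TRUE),
        amplification = as.integer(rep_len(amplification, n_fragments)),
        force_meth = NA_integer_)
    } else {
      fragments <- data.table::as.data.table(fragments)
      if (is.null(fragments$amplification))
        fragments$amplification <- 1L
      if (is.null(fragments$force_meth))
        fragments$force_meth <- NA_integer_
      stopifnot(all(fragments$amplification >= 1L))
    }
    nf <- nrow(fragments)
    frag_id <- sprintf("frag%06d", seq_len(nf))

    ## per-(chrom, strand) dense probability lookup indexed by pos + 1
    pr <- list()
    for (ch in names(genome)) for (sd in c("+", "-")) {
      v <- numeric(nchar(genome[[ch]]))
      d <- probs[probs$chrom == ch & probs$strand == sd]
      v[d$pos + 1L] <- d$p
      pr[[paste0(ch, sd)]] <- v
    }
    graw <- lapply(genome, charToRaw)
    rawC <- charToRaw("C"); rawG <- charToRaw("G"); rawT <- charToRaw("T")

    o_seq <- character(nf)
    meth_str <- character(nf)
    for (i in seq_len(nf)) {
      ch <- fragments$chrom[i]; s <- fragments$start[i]
      e <- fragments$end[i]; sd <- fragments$strand[i]
      topr <- graw[[ch]][(s + 1L):e]
      ## cytosine positions of the original strand, as top-strand coords
      cpos <- if (sd == "+") s - 1L + which(topr == rawC)
              else s - 1L + which(topr == rawG)
      p <- pr[[paste0(ch, sd)]][cpos + 1L]
      state <- if (!is.na(fragments$force_meth[i]))
        rep(as.integer(fragments$force_meth[i]), length(cpos))
      else rbinom(length(cpos), 1L, p)
      converted <- state == 0L & runif(length(cpos)) < lib$conversion_rate
      orig <- if (sd == "+") topr
              else .RC_TABLE[as.integer(rev(topr)) + 1L]
      ## index of each cytosine within the original-strand sequence
      idx <- if (sd == "+") cpos - s + 1L else e - cpos
      orig[idx[converted]] <- rawT
      o_seq[i] <- rawToChar(orig)
      meth_str[i] <- paste(cpos, state, sep = ":", collapse = ",")
    }

    truth <- data.table::data.table(
      frag_id = frag_id, chrom = fragments$chrom,
      start = as.integer(fragments$start), end = as.integer(fragments$end),
      strand = fragments$strand,
      amplification = fragments$amplification, meth = meth_str)

    rep_i <- rep(seq_len(nf), fragments$amplification)
    copy_n <- sequence(fragments$amplification)
    flen <- (fragments$end - fragments$start)[rep_i]
    r1 <- substr(o_seq[rep_i], 1L, L)
    r2 <- revcomp(substr(o_seq[rep_i], flen - L + 1L, flen))
    r1 <- .add_errors(r1, lib$error_rate)
    r2 <- .add_errors(r2, lib$error_rate)
    pairs <- data.table::data.table(
      read_id = paste0(frag_id[rep_i], ".", copy_n),
      frag_id = frag_id[rep_i],
      chrom = fragments$chrom[rep_i],
      start = as.integer(fragments$start[rep_i]),
      end = as.integer(fragments$end[rep_i]),
      strand = fragments$strand[rep_i],
      seq1 = r1, seq2 = r2)
    list(pairs = pairs, truth = truth, lib = lib)
  })
}

#' Worked PCR-bias demonstration scenario
#'
#' Builds the canonical monoclonization example: one CG site covered by
#' three top-strand sonication fragments from three different cells, two
#' methylated and one unmethylated, PCR-amplified 10/10/50-fold, plus
#' three unbiased bottom-strand fragments with the same methylation
#' states. Without deduplication the top-strand methylation rate is
#' distorted to 20/70; collapsing to clones restores 2/3. The bottom
#' strand reads 2/3 throughout.
#'
#' @param seed integer seed for the backdrop genome.
#' @param amplification amplification factors of the three top-strand
#'   fragments (set to c(1,1,1) for the pre-PCR library).
#' @return list with `genome`, `sim` (a [simulate_bsseq_reads()] result)
#'   and `cg_pos` (0-based top-strand C position of the interrogated CG).
#' @export
simulate_pcr_bias_demo <- function(seed = 1L,
                                   amplification = c(10L, 10L, 50L)) {
  stopifnot(length(amplification) == 3L)
  g <- generate_toy_genome(toy_genome_spec(1L, 12000L, 0.45), seed = seed)
  cgs <- cg_positions(g$genome[[1]])
  cg <- cgs[which.min(abs(cgs - 6000L))]
  frags <- data.frame(
    chrom = "chr1",
    start = c(cg - 50L, cg - 20L, cg - 40L,
              cg + 30L - 400L, cg + 40L - 380L, cg + 50L - 350L),
    end = c(cg - 50L + 400L, cg - 20L + 380L, cg - 40L + 350L,
            cg + 30L, cg + 40L, cg + 50L),
    strand = rep(c("+", "-"), each = 3L),
    amplification = c(as.integer(amplification), 1L, 1L, 1L),
    force_meth = c(1L, 1L, 0L, 1L, 1L, 0L))
  probs <- assign_methylome(g$genome, g, methylome_profile("WT"),
                            seed = seed)
  lib <- library_params(conversion_rate = 1)
  sim <- simulate_bsseq_reads(g$genome, probs, lib, fragments = frags,
                              seed = seed)
  list(genome = g$genome, sim = sim, cg_pos = cg)
}

#' Write simulated read pairs as FASTQ
#'
#' @param pairs the `pairs` table from [simulate_bsseq_reads()].
#' @param prefix output path prefix; writes `<prefix>_1.fq` and
#'   `<prefix>_2.fq` (Phred+33, constant quality).
#' @param quality quality character.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(pairs, prefix, quality = "I") {
  f1 <- paste0(prefix, "_1.fq"); f2 <- paste0(prefix, "_2.fq")
  q1 <- strrep(quality, nchar(pairs$seq1))
  q2 <- strrep(quality, nchar(pairs$seq2))
  writeLines(paste0("@", pairs$read_id, "/1\n", pairs$seq1, "\n+\n", q1), f1)
  writeLines(paste0("@", pairs$read_id, "/2\n", pairs$seq2, "\n+\n", q2), f2)
  invisible(c(f1, f2))
}

#' Read paired FASTQ files into a pairs table
#'
#' @param fq1,fq2 paths to mate FASTQ files.
#' @return data.table with read_id, seq1, seq2.
#' @export
read_fastq_pairs <- function(fq1, fq2) {
  l1 <- readLines(fq1); l2 <- readLines(fq2)
  id <- sub("/1$", "", sub("^@", "", l1[seq(1, length(l1), by = 4)]))
  data.table::data.table(read_id = id,
                         seq1 = l1[seq(2, length(l1), by = 4)],
                         seq2 = l2[seq(2, length(l2), by = 4)])
}

#' Convert simulator truth to perfectly aligned pairs
#'
#' Uses the fragment-origin truth table to produce an alignment table with
#' the same schema as [align_pairs()] output (resolution "truth"), i.e. a
#' perfect aligner. Useful for isolating downstream statistics from
#' alignment behaviour.
#'
#' @param sim result of [simulate_bsseq_reads()].
#' @return data.table compatible with [monoclonize()] / [pileup()].
#' @export
truth_alignments <- function(sim) {
  p <- sim$pairs
  data.table::data.table(read_id = p$read_id, chrom = p$chrom,
                         start = p$start, end = p$end, strand = p$strand,
                         score = 0L, resolution = "truth",
                         seq1 = p$seq1, seq2 = p$seq2)
}
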