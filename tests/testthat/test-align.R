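make_ref <- function(seed = 13) {
  generate_toy_genome(toy_genome_spec(1, 20000, 0.45), seed = seed)$genome
}

test_that("read and genome conversions substitute the right letters", {
  cv <- convert_reads("TTCG", "TTCG")
  expect_identical(cv$read1, "TTTG")
  expect_identical(cv$read2, "TTCA")
  expect_identical(convert_reads("TTAG", "x")$read1, "TTAG")

  ## chromosomes shorter than the seed are skipped with a warning
  expect_warning(build_index(c(make_ref(), tiny = "ACGT"),
                             seed_length = 12L), "seed_length")
  idx <- build_index(make_ref(), seed_length = 16L)
  expect_false(grepl("C", idx$c2t$seq[["chr1"]], fixed = TRUE))
  expect_false(grepl("G", idx$g2a$seq[["chr1"]], fixed = TRUE))
})

test_that("index lookup returns every occurrence of a seed", {
  genome <- make_ref()
  genome <- duplicate_region(genome, "chr1", 2000, 400,
                             dest_starts = 9000, seed = 1)
  idx <- build_index(genome, seed_length = 18L)
  seed <- substr(chartr("C", "T", genome[["chr1"]]), 2001, 2018)
  hits <- idx$c2t$env[[seed]]
  ## oracle: brute-force substring scan on the converted chromosome
  conv <- chartr("C", "T", genome[["chr1"]])
  expected <- integer(0)
  for (i in seq_len(nchar(conv) - 17)) {
    if (substr(conv, i, i + 17) == seed) expected <- c(expected, i - 1L)
  }
  expect_setequal(hits$pos, expected)
  expect_true(all(c(2000L, 9000L) %in% hits$pos))
})

test_that("alignment budgets admit and reject reads as specified", {
  genome <- make_ref()
  idx <- build_index(genome)
  read <- substr(genome[["chr1"]], 5001, 5075)   # verbatim + strand read1

  cand <- align_read(c2t(read), idx, mate = 1)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 5000L)
  expect_equal(cand$mm, 0L)
  expect_true(cand$unique)
  expect_equal(cand$frag_strand, "+")

  ## locus duplicated 5x: five candidates, none unique
  g5 <- genome
  for (d in c(9000, 11000, 13000, 15000))
    g5 <- duplicate_region(g5, "chr1", 5000, 200, dest_starts = d,
                           seed = 1)
  idx5 <- build_index(g5)
  read5 <- substr(g5[["chr1"]], 5001, 5075)
  cand5 <- align_read(c2t(read5), idx5, mate = 1)
  expect_equal(nrow(cand5), 5L)
  expect_false(any(cand5$unique))
  expect_setequal(cand5$start, c(5000L, 9000L, 11000L, 13000L, 15000L))

  ## four mismatches in the leading 40 bases: rejected everywhere
  mut <- read
  for (i in c(5, 15, 25, 35))
    substr(mut, i, i) <- setdiff(c("A", "G", "T"),
                                 substr(read, i, i))[1]
  ## mutate away from C so the three-letter conversion cannot mask it
  cand_bad <- align_read(c2t(mut), idx, mate = 1)
  expect_equal(nrow(cand_bad), 0L)

  ## three mismatches pass the leading budget and the Phred budget
  mut3 <- read
  for (i in c(5, 15, 25))
    substr(mut3, i, i) <- setdiff(c("A", "G", "T"),
                                  substr(read, i, i))[1]
  cand3 <- align_read(c2t(mut3), idx, mate = 1)
  expect_equal(nrow(cand3), 1L)
  expect_equal(cand3$mm, 3L)
})

test_that("pair resolution rescues through a unique anchor", {
  mk <- function(starts, strand, phred = 0L) {
    data.table::data.table(chrom = "chr1", start = as.integer(starts),
                           frag_strand = strand,
                           mm = 0L, phred = as.integer(phred),
                           unique = length(starts) == 1L)
  }
  ## unique mate1 anchors; one of mate2's candidates is in the window
  c1 <- mk(10000L, "+")
  c2 <- mk(c(10275L, 41925L), "+")
  r <- resolve_pair(c1, c2, 75L, 75L, c(300, 600))
  expect_equal(r$resolution, "rescued")
  expect_equal(r$start, 10000L)
  expect_equal(r$end, 10350L)

  ## two candidates inside the window: ambiguity forces a discard
  c2amb <- mk(c(10275L, 10325L), "+")
  r2 <- resolve_pair(c1, c2amb, 75L, 75L, c(300, 600))
  expect_equal(r2$resolution, "unresolved")

  ## both unique and concordant passes through
  r3 <- resolve_pair(mk(10000L, "+"), mk(10275L, "+"), 75L, 75L,
                     c(300, 600))
  expect_equal(r3$resolution, "both_unique")
  expect_equal(r3$end - r3$start, 350L)

  ## both unique but discordant (fragment too long) is unresolved
  r4 <- resolve_pair(mk(10000L, "+"), mk(10800L, "+"), 75L, 75L,
                     c(300, 600))
  expect_equal(r4$resolution, "unresolved")
})

test_that("resolved pairs recover their true origins and obey the window", {
  genome <- make_ref(seed = 31)
  ## a diverged repeat family to exercise multi-mapping + rescue
  genome <- duplicate_region(genome, "chr1", 3000, 1500,
                             dest_starts = c(8000, 12000),
                             divergence = 0.01, seed = 32)
  gg <- list(genome = genome,
             repeats = data.table::data.table(
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), subtype = character(0),
               family = character(0), class = character(0)),
             genes = NULL, islands = NULL)
  probs <- assign_methylome(genome, gg, methylome_profile("WT"), seed = 33)
  lib <- library_params(depth = 3, error_rate = 0.002)
  sim <- simulate_bsseq_reads(genome, probs, lib, seed = 34)
  idx <- build_index(genome)
  aln <- align_pairs(sim$pairs, idx)
  expect_gt(nrow(aln), 0)

  ## every resolved pair satisfies the window and convergent orientation
  expect_true(all(aln$end - aln$start >= 300 & aln$end - aln$start <= 600))

  ## >= 99% of resolved single-copy pairs map to their true origin
  tr <- merge(aln, sim$pairs[, c("read_id", "start", "end", "strand")],
              by = "read_id", suffixes = c("", ".true"))
  in_repeat <- (tr$start.true < 4500 & tr$end.true > 3000) |
    (tr$start.true < 9500 & tr$end.true > 8000) |
    (tr$start.true < 13500 & tr$end.true > 12000)
  single <- tr[!in_repeat, ]
  hit <- single$start == single$start.true &
    single$end == single$end.true & single$strand == single$strand.true
  expect_gte(mean(hit), 0.99)
})
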