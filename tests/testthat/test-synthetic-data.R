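test_that("toy genomes are deterministic and honour the declared layout", {
  spec <- toy_genome_spec(
    1, 50000, 0.42,
    features = data.frame(chrom = 1, start = c(10000, 30000),
                          length = c(6000, 500),
                          kind = c("LINE", "LTR"),
                          subtype = c("L1Md_A", "IAP-like"),
                          strand = c("+", "-"),
                          cg_density_class = c("high", "high")))
  g1 <- generate_toy_genome(spec, seed = 7)
  g2 <- generate_toy_genome(spec, seed = 7)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$repeats, g2$repeats)
  expect_equal(nchar(g1$genome[["chr1"]]), 50000L)
  expect_equal(nrow(g1$repeats), 2L)
  expect_equal(g1$repeats$end - g1$repeats$start, c(6000L, 500L))
  expect_equal(g1$repeats$strand, c("+", "-"))

  empty <- generate_toy_genome(toy_genome_spec(1, 10000, 0.4), seed = 1)
  expect_equal(nrow(empty$repeats), 0L)
  expect_equal(nrow(empty$genes), 0L)

  bad <- data.frame(chrom = 1, start = 48000, length = 6000,
                    kind = "LINE", subtype = "L1", strand = "+",
                    cg_density_class = "high")
  expect_error(toy_genome_spec(1, 50000, 0.42, features = bad), "layout")
})

test_that("CG islands realise their target density", {
  spec <- toy_genome_spec(
    1, 20000, 0.42,
    cg_islands = data.frame(chrom = 1, start = 5000, length = 1000,
                            density = 60))
  g <- generate_toy_genome(spec, seed = 11)
  isl <- substr(g$genome[["chr1"]], 5001, 6000)
  n_cg <- sum(gregexpr("CG", isl, fixed = TRUE)[[1]] > 0)
  dens <- n_cg * 600 / 1000          # per-600-bp density over the island
  expect_gte(dens, 48)               # within 20% of 60
  expect_lte(dens, 72)
})

test_that("methylome assignment maps feature classes to probabilities", {
  spec <- toy_genome_spec(
    1, 20000, 0.42,
    features = data.frame(chrom = 1, start = 8000, length = 1500,
                          kind = "LTR", subtype = "IAP-like",
                          strand = "+", cg_density_class = "high"))
  g <- generate_toy_genome(spec, seed = 3)

  tko <- assign_methylome(g$genome, g, methylome_profile("TKO"), seed = 1)
  expect_true(all(tko$p <= 0.01))

  dko <- assign_methylome(g$genome, g, methylome_profile("DKO"), seed = 1)
  cg <- dko[dko$context == "CG"]
  expect_true(all(cg$p[cg$class == "LTR"] == 0.78))
  expect_true(all(cg$p[cg$class == "background"] == 0.18))

  ## symmetric mode with site dispersion: both strands of each CG share
  ## one probability
  wt <- assign_methylome(g$genome, g,
                         methylome_profile("WT", site_dispersion = TRUE),
                         seed = 5)
  cg <- wt[wt$context == "CG"]
  key <- ifelse(cg$strand == "+", cg$pos, cg$pos - 1L)
  per_site <- tapply(cg$p, key, function(x) length(unique(x)))
  expect_true(all(per_site == 1L))

  broken <- g
  broken$repeats$class <- "SINE"
  expect_error(assign_methylome(broken$genome, broken,
                                methylome_profile("WT"), seed = 1),
               "unknown repeat class")
})

test_that("fully methylated and fully unmethylated limits are exact", {
  g <- generate_toy_genome(toy_genome_spec(1, 10000, 0.45), seed = 2)
  lib <- library_params(conversion_rate = 1, depth = 2)
  all1 <- c(background = 1, cg_island = 1, LTR = 1,
            LINE_promoter = 1, LINE_body = 1, gene = 1)
  p1 <- assign_methylome(g$genome, g,
                         methylome_profile("WT", class_probs = all1,
                                           chh_rate = 1), seed = 1)
  sim1 <- simulate_bsseq_reads(g$genome, p1, lib, n_fragments = 30,
                               seed = 4)
  plus <- sim1$pairs[sim1$pairs$strand == "+"]
  for (i in seq_len(nrow(plus))) {
    ref <- substr(g$genome[["chr1"]], plus$start[i] + 1,
                  plus$start[i] + nchar(plus$seq1[i]))
    expect_identical(plus$seq1[i], ref)   # no C->T conversion anywhere
  }

  all0 <- c(background = 0, cg_island = 0, LTR = 0,
            LINE_promoter = 0, LINE_body = 0, gene = 0)
  p0 <- assign_methylome(g$genome, g,
                         methylome_profile("WT", class_probs = all0,
                                           chh_rate = 0), seed = 1)
  sim0 <- simulate_bsseq_reads(g$genome, p0, lib, n_fragments = 30,
                               seed = 4)
  plus <- sim0$pairs[sim0$pairs$strand == "+"]
  expect_false(any(grepl("C", plus$seq1, fixed = TRUE)))
})

test_that("emitted pair count equals the summed amplification factors", {
  g <- generate_toy_genome(toy_genome_spec(1, 10000, 0.45), seed = 2)
  probs <- assign_methylome(g$genome, g, methylome_profile("WT"),
                            seed = 1)
  amp <- c(1L, 3L, 7L, 2L)
  sim <- simulate_bsseq_reads(g$genome, probs, library_params(depth = 1),
                              n_fragments = 4, amplification = amp,
                              seed = 9)
  expect_equal(nrow(sim$pairs), sum(amp))
  expect_equal(sum(sim$truth$amplification), sum(amp))
  ## determinism
  sim2 <- simulate_bsseq_reads(g$genome, probs, library_params(depth = 1),
                               n_fragments = 4, amplification = amp,
                               seed = 9)
  expect_identical(sim$pairs, sim2$pairs)
})

test_that("simulated methylation rates recover assigned probabilities", {
  ## ~40x coverage, perfect alignment via the truth table
  spec <- toy_genome_spec(
    1, 12000, 0.42,
    features = data.frame(chrom = 1, start = 4000, length = 1500,
                          kind = "LTR", subtype = "IAP-like",
                          strand = "+", cg_density_class = "high"))
  g <- generate_toy_genome(spec, seed = 21)
  probs <- assign_methylome(g$genome, g, methylome_profile("DKO"),
                            seed = 22)
  lib <- library_params(depth = 40, conversion_rate = 1)
  sim <- simulate_bsseq_reads(g$genome, probs, lib, seed = 23)
  calls <- pileup(truth_alignments(sim), g$genome)

  m <- merge(calls, probs, by = c("chrom", "pos", "strand"))
  m <- m[m$coverage >= 30]
  mr <- m$rC / m$coverage
  se <- sqrt(m$p * (1 - m$p) / m$coverage)
  within3 <- abs(mr - m$p) <= 3 * se + 1e-12
  ## per-site 3-SE coverage is ~99.7% binomially; allow the expected tail
  expect_gte(mean(within3), 0.985)

  ## pooled per-class overall MR lands on the class probability
  cgm <- m[m$context.x == "CG"]
  for (cls in c("LTR", "background")) {
    sub <- cgm[cgm$class == cls]
    pool <- overall_methylation(sub)
    p0 <- unique(sub$p)[1]
    se_pool <- sqrt(p0 * (1 - p0) / sum(sub$coverage))
    expect_lt(abs(pool - p0), 3 * se_pool + 0.005)
  }
})

test_that("expression simulator separates deregulated gene classes", {
  tab <- simulate_expression(n_genes = 2000, seed = 5)
  fc <- log2(tab$fpkm_tko / tab$fpkm_wt)
  expect_true(all(abs(fc[tab$class == "up"]) > 2.5))
  expect_true(all(fc[tab$class == "down"] < -2.5))
  expect_true(all(abs(fc[tab$class == "unchanged"]) < 0.5))
  expect_true(all(tab$fpkm_wt >= 0 & tab$fpkm_tko >= 0))
  ## class means reflect the promoter methylation / CG density coupling
  up <- tab[tab$class == "up"]
  un <- tab[tab$class == "unchanged"]
  expect_gt(mean(up$promoter_mr_wt), 0.5)
  expect_lt(mean(up$promoter_cg), 30)
  expect_lt(mean(un$promoter_mr_wt), 0.05)
  expect_gt(mean(un$promoter_cg), 50)
  expect_identical(tab, simulate_expression(n_genes = 2000, seed = 5))
})
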