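test_that("LINE promoter intervals are strand-aware with a quarter rule", {
  expect_equal(line_promoter(10000, 16000, "+"), c(9900L, 11000L))
  expect_equal(line_promoter(10000, 16000, "-"), c(15000L, 16100L))
  expect_equal(line_promoter(10000, 16000, "+", rule = "quarter"),
               c(10000L, 11500L))
  expect_equal(line_promoter(10000, 16000, "-", rule = "quarter"),
               c(14500L, 16000L))
  ## clipping at the chromosome
  expect_equal(line_promoter(50, 4000, "+"), c(0L, 1050L))
  expect_equal(line_promoter(10000, 16000, "-", chrom_length = 16050),
               c(15000L, 16050L))
})

test_that("element filters are strict and span all genotypes", {
  els <- data.table::data.table(
    chrom = "chr1", start = c(0L, 3000L, 6000L),
    end = c(1200L, 5000L, 8000L), strand = "+",
    id = c("short", "poor", "good"))
  mk_sites <- function(per_site_cov) {
    ## 40 CG sites per element at the given per-site combined coverage
    do.call(rbind, lapply(seq_len(nrow(els)), function(i) {
      pos <- seq(els$start[i], els$end[i] - 2L, length.out = 40)
      cg_table(pos = as.integer(pos), rc_p = per_site_cov[i], rt_p = 0,
               rc_n = 0, rt_n = 0)
    }))
  }
  filt <- list(min_length = 1500L, min_cg = 30L, min_coverage = 50L)
  sites <- list(WT = mk_sites(c(10L, 1L, 10L)),
                KO = mk_sites(c(10L, 1L, 10L)))
  kept <- filter_elements(els, sites, filt)
  ## "short" fails the length filter, "poor" sums to coverage 40 <= 50
  expect_equal(kept$id, "good")
  expect_equal(kept$n_cg, 40L)
  expect_equal(kept$coverage_WT, 400)

  ## thresholds are strict: summed coverage exactly 50 still fails
  filt2 <- list(min_length = 0L, min_cg = 0L, min_coverage = 50L)
  el1 <- els[3]
  exact50 <- cg_table(pos = seq(6000L, 7998L, length.out = 25),
                      rc_p = 2L, rt_p = 0L, rc_n = 0L, rt_n = 0L)
  expect_equal(nrow(filter_elements(el1, list(WT = exact50), filt2)), 0L)

  ## a low-coverage genotype vetoes the element for all genotypes
  mixed <- list(WT = mk_sites(c(10L, 10L, 10L)),
                KO = mk_sites(c(10L, 10L, 1L)))
  expect_false("good" %in% filter_elements(els, mixed, filt)$id)

  ## CG-count filter is strict too (element CG count must exceed min_cg)
  filt3 <- list(min_length = 0L, min_cg = 40L, min_coverage = 0L)
  expect_equal(nrow(filter_elements(el1, list(WT = sites$WT), filt3)), 0L)
})

test_that("equal-CG binning distributes sites with the remainder first", {
  el <- data.frame(chrom = "chr1", start = 0L, end = 2000L, strand = "+")
  sites20 <- cg_table(pos = seq(0, 1900, 100), rc_p = 1, rt_p = 1,
                      rc_n = 1, rt_n = 1)
  b <- bin_equal_cg(el, sites20, 4)
  expect_equal(as.integer(table(b$bin)), c(5L, 5L, 5L, 5L))

  sites22 <- cg_table(pos = seq(0, 2100, 100)[1:22] , rc_p = 1, rt_p = 1,
                      rc_n = 1, rt_n = 1)
  el22 <- data.frame(chrom = "chr1", start = 0L, end = 2200L,
                     strand = "+")
  b22 <- bin_equal_cg(el22, sites22, 4)
  expect_equal(as.integer(table(b22$bin)), c(6L, 6L, 5L, 5L))

  ## minus-strand elements order bins 5'->3' in element orientation
  el_m <- data.frame(chrom = "chr1", start = 0L, end = 2000L,
                     strand = "-")
  bm <- bin_equal_cg(el_m, sites20, 4)
  expect_equal(sort(bm$pos[bm$bin == 1]), seq(1500, 1900, 100))
  ## strand reversal reverses bin order exactly
  expect_equal(bm$bin[order(bm$pos)], rev(b$bin[order(b$pos)]))

  expect_error(bin_equal_cg(el, sites20, 30), "exceeds")
})

test_that("grouped profiles pool counts and split elements evenly", {
  set.seed(31)
  n_el <- 20
  els <- data.table::data.table(
    chrom = "chr1", start = seq(0L, by = 5000L, length.out = n_el))
  els$end <- els$start + 4000L
  els$strand <- "+"
  sites <- do.call(rbind, lapply(seq_len(n_el), function(i) {
    pos <- as.integer(seq(els$start[i], els$end[i] - 2, length.out = 10))
    cg_table(pos = pos, rc_p = 5, rt_p = 5, rc_n = 5, rt_n = 5)
  }))
  filt <- list(min_length = 0L, min_cg = 0L, min_coverage = 0L)
  kept <- filter_elements(els, list(WT = sites), filt)
  prof <- profile_groups(kept, sites, group_by = "cg_density",
                         n_groups = 10, n_bins = 5)
  ## homogeneous input: every cell is 0.5 and groups hold 2 elements
  expect_true(all(abs(prof$mr - 0.5) < 1e-12))
  expect_equal(nrow(prof), 50L)
  expect_true(all(prof$n_sites == 4L))  # 2 elements x 2 sites per bin

  ## pooling consistency: group-level MR equals the rate of summed counts
  expect_equal(prof$mr, methylation_rate(prof$rC, prof$rT))
})

test_that("gene promoter profile bins 200 bp windows strand-aware", {
  genes <- data.table::data.table(
    chrom = "chr1", start = 10000L, end = 15000L, strand = "+",
    gene_id = "g1")
  sites <- cg_table(pos = seq(6000, 13990, 10), rc_p = 1, rt_p = 4,
                    rc_n = 1, rt_n = 4)
  expr <- data.frame(gene_id = "g1", fpkm = 5)
  p <- gene_promoter_profile(genes, sites, expr, n_groups = 1,
                             n_bins = 40, flank = 4000)
  expect_equal(p$bin_width, 200L)
  expect_equal(dim(p$matrix), c(1L, 40L))
  expect_true(all(abs(p$matrix - 0.2) < 1e-12))

  ## a minus-strand gene (TSS = end) mirrors the bin order of a plus
  ## gene sharing the same TSS
  pos <- seq(11000, 18990, 10)
  rc <- ifelse(pos < 15000, 5L, 0L)
  grad <- cg_table(pos = pos, rc_p = rc, rt_p = 5L - rc,
                   rc_n = rc, rt_n = 5L - rc)
  minus <- data.table::data.table(chrom = "chr1", start = 9000L,
                                  end = 15000L, strand = "-",
                                  gene_id = "g1")
  plus <- data.table::data.table(chrom = "chr1", start = 15000L,
                                 end = 21000L, strand = "+",
                                 gene_id = "g1")
  pm <- gene_promoter_profile(minus, grad, expr, 1, 40, 4000)
  pf <- gene_promoter_profile(plus, grad, expr, 1, 40, 4000)
  expect_equal(pm$matrix[1, ], rev(pf$matrix[1, ]))
  expect_equal(p$genes_used, 1L)
})
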