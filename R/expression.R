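## Promoter methylation vs expression change
##
## Links WT promoter methylation and CG density to the log2 expression
## fold change between WT and TKO cells. Sign convention: positive log2 FC
## = up-regulated (induced) in TKO.

#' Filter a WT/TKO FPKM table
#'
#' Applies the three cascade criteria: (1) both FPKM > 0; (2) FPKM sum
#' > 1; (3) log2 FC within [-6, 6]. Removal counts are reported per
#' criterion (applied in order).
#'
#' @param table data.frame with fpkm_wt and fpkm_tko columns.
#' @param fc_range allowed log2 fold-change range.
#' @return list with `genes` (filtered table, log2_fc column added) and
#'   `removed` (named counts per criterion).
#' @export
filter_genes <- function(table, fc_range = c(-6, 6)) {
  t0 <- data.table::as.data.table(table)
  c1 <- t0$fpkm_wt > 0 & t0$fpkm_tko > 0
  t1 <- t0[c1]
  c2 <- (t1$fpkm_wt + t1$fpkm_tko) > 1
  t2 <- t1[c2]
  fc <- log2(t2$fpkm_tko / t2$fpkm_wt)
  c3 <- fc >= fc_range[1] & fc <= fc_range[2]
  out <- t2[c3]
  out[, log2_fc := fc[c3]]
  list(genes = out[],
       removed = c(nonzero_fpkm = sum(!c1), fpkm_sum = sum(!c2),
                   fc_range = sum(!c3)))
}

#' Classify deregulation status
#'
#' @param log2_fc log2 fold change (TKO over WT).
#' @param threshold strict threshold (default 2.5).
#' @return factor with levels up / down / unchanged.
#' @export
classify_deregulated <- function(log2_fc, threshold = 2.5) {
  factor(ifelse(log2_fc > threshold, "up",
                ifelse(log2_fc < -threshold, "down", "unchanged")),
         levels = c("up", "down", "unchanged"))
}

#' Subgroup analysis of fold change vs promoter methylation
#'
#' Sorts filtered genes by the chosen key, partitions them into
#' `n_groups` equal-count subgroups (remainder to the earliest groups) and
#' summarises each subgroup: median log2 FC, pooled overall promoter
#' methylation, mean promoter CG count, median WT FPKM.
#'
#' Promoter methylation counts can be supplied per gene (`rc_promoter` /
#' `rt_promoter` columns, e.g. from [simulate_expression()]), or computed
#' from a site table and gene annotation via [promoter_methylation()].
#'
#' @param genes filtered gene table with log2_fc, fpkm_wt, rc_promoter,
#'   rt_promoter, promoter_cg columns.
#' @param n_groups number of subgroups (500 at full scale).
#' @param sort_by "fc" or "fpkm".
#' @return data.table: group, n_genes, median_fc, mr, cg, median_fpkm_wt.
#' @export
subgroup_analysis <- function(genes, n_groups = 500L,
                              sort_by = c("fc", "fpkm")) {
  sort_by <- match.arg(sort_by)
  g <- data.table::as.data.table(genes)
  if (nrow(g) < n_groups)
    stop("fewer genes (", nrow(g), ") than groups (", n_groups,
         "); use a smaller n_groups")
  key <- if (sort_by == "fc") g$log2_fc else g$fpkm_wt
  ord <- order(key)
  sizes <- rep(nrow(g) %/% n_groups, n_groups)
  extra <- nrow(g) %% n_groups
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- integer(nrow(g))
  grp[ord] <- rep(seq_len(n_groups), sizes)
  g[, .grp := grp]
  out <- g[, list(n_genes = .N,
                  median_fc = median(log2_fc),
                  mr = methylation_rate(sum(rc_promoter),
                                        sum(rt_promoter)),
                  cg = mean(promoter_cg),
                  median_fpkm_wt = median(fpkm_wt)),
           by = .grp]
  data.table::setnames(out, ".grp", "group")
  data.table::setorder(out, group)
  out[]
}

#' Per-gene promoter methylation from a site table
#'
#' Pools CG-site counts in the TSS +/- `halfwin` window of each gene.
#'
#' @param genes gene table (chrom, start, end, strand, gene_id).
#' @param sites combined CG-site table from [combine_cg_strands()].
#' @param halfwin promoter half-window around the TSS (default 500).
#' @return the gene table with rc_promoter, rt_promoter, promoter_cg
#'   columns.
#' @export
promoter_methylation <- function(genes, sites, halfwin = 500L) {
  g <- data.table::as.data.table(genes)
  sites <- data.table::as.data.table(sites)
  rc <- integer(nrow(g)); rt <- integer(nrow(g)); ncg <- integer(nrow(g))
  tss <- ifelse(g$strand == "+", g$start, g$end)
  for (i in seq_len(nrow(g))) {
    s <- .sites_in(sites, g$chrom[i], tss[i] - halfwin, tss[i] + halfwin)
    rc[i] <- sum(s$rC_p + s$rC_n); rt[i] <- sum(s$rT_p + s$rT_n)
    ncg[i] <- nrow(s)
  }
  g[, `:=`(rc_promoter = rc, rt_promoter = rt, promoter_cg = ncg)]
  g[]
}
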