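## Binned methylation profiles of genes, LINEs and LTRs
##
## Elements are filtered on length, CG count and summed site coverage
## (across all genotypes under comparison), then divided into equal-CG
## bins (body profiles) or equal-length bins (gene promoters). Bins are
## ordered 5'->3' in element orientation.

#' LINE promoter interval
#'
#' Strand-aware: 100 bp upstream to 1000 bp downstream of the TSS by
#' default, or the downstream quarter of the element (`rule = "quarter"`,
#' used when intersecting with RRMRs). Clipped to the chromosome.
#'
#' @param start,end 0-based half-open element interval.
#' @param strand "+" or "-".
#' @param upstream,downstream extent around the TSS (fixed rule).
#' @param rule "fixed" or "quarter".
#' @param chrom_length optional clip bound.
#' @return integer length-2 vector (0-based half-open interval).
#' @export
line_promoter <- function(start, end, strand, upstream = 100L,
                          downstream = 1000L, rule = c("fixed", "quarter"),
                          chrom_length = NULL) {
  rule <- match.arg(rule)
  if (rule == "quarter") {
    q <- (end - start) %/% 4L
    iv <- if (strand == "+") c(start, start + q) else c(end - q, end)
  } else {
    iv <- if (strand == "+") c(start - upstream, start + downstream)
          else c(end - downstream, end + upstream)
  }
  iv[1] <- max(iv[1], 0L)
  if (!is.null(chrom_length)) iv[2] <- min(iv[2], chrom_length)
  as.integer(iv)
}

#' Element filter presets
#'
#' Full-scale defaults: LINE promoter analysis (length > 1500, CG > 30,
#' coverage > 50, promoter region); LTR analysis (CG > 9, coverage > 50,
#' full region); body profiles (gene CG > 50 & length > 3000; LINE CG > 20
#' & length > 1000; LTR CG > 15 & length > 300). "CG" thresholds are the
#' element's CG count.
#'
#' @param kind "gene", "LINE" or "LTR".
#' @param purpose "promoter_analysis" (LINE/LTR methylation analysis) or
#'   "body_profile" (equal-CG binned profiles).
#' @return list of thresholds (min_length, min_cg, min_coverage,
#'   region_rule).
#' @export
element_filter <- function(kind = c("gene", "LINE", "LTR"),
                           purpose = c("promoter_analysis",
                                       "body_profile")) {
  kind <- match.arg(kind); purpose <- match.arg(purpose)
  if (purpose == "promoter_analysis") {
    switch(kind,
      LINE = list(min_length = 1500L, min_cg = 30L, min_coverage = 50L,
                  region_rule = "LINE_promoter"),
      LTR = list(min_length = 0L, min_cg = 9L, min_coverage = 50L,
                 region_rule = "full"),
      gene = list(min_length = 0L, min_cg = 0L, min_coverage = 50L,
                  region_rule = "gene_promoter"))
  } else {
    switch(kind,
      gene = list(min_length = 3000L, min_cg = 50L, min_coverage = 50L,
                  region_rule = "full"),
      LINE = list(min_length = 1000L, min_cg = 20L, min_coverage = 50L,
                  region_rule = "full"),
      LTR = list(min_length = 300L, min_cg = 15L, min_coverage = 50L,
                 region_rule = "full"))
  }
}

## CG sites of a combined table falling in [start, end) of one chromosome
.sites_in <- function(sites, chrom, start, end) {
  sel <- which(sites$chrom == chrom & sites$pos >= start &
                 sites$pos < end)
  sites[sel]
}

#' Filter elements on length, CG count and coverage
#'
#' All thresholds are strict (>). Coverage is the summed combined coverage
#' of the element's CG sites, and must clear the threshold in every
#' genotype supplied.
#'
#' @param elements annotation table (chrom, start, end, strand, ...).
#' @param sites_by_genotype named list of [combine_cg_strands()] tables,
#'   one per genotype under comparison.
#' @param filter an [element_filter()] list (or compatible).
#' @return the retained elements with n_cg and coverage_<genotype>
#'   columns.
#' @export
filter_elements <- function(elements, sites_by_genotype, filter) {
  e <- data.table::as.data.table(elements)
  if (!nrow(e)) return(e)
  len_ok <- (e$end - e$start) > filter$min_length
  first <- sites_by_genotype[[1]]
  n_cg <- integer(nrow(e))
  cov <- matrix(0, nrow(e), length(sites_by_genotype))
  for (i in seq_len(nrow(e))) {
    for (g in seq_along(sites_by_genotype)) {
      s <- .sites_in(sites_by_genotype[[g]], e$chrom[i], e$start[i],
                     e$end[i])
      cov[i, g] <- sum(s$coverage)
      if (g == 1L) n_cg[i] <- nrow(s)
    }
  }
  keep <- len_ok & n_cg > filter$min_cg &
    apply(cov > filter$min_coverage, 1, all)
  out <- e[keep]
  out[, n_cg := n_cg[keep]]
  for (g in seq_along(sites_by_genotype)) {
    nm <- names(sites_by_genotype)[g]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("g", g)
    out[, (paste0("coverage_", nm)) := cov[keep, g]]
  }
  out[]
}

#' Split an element's CG sites into equal-CG bins
#'
#' Bins are ordered 5'->3' in element orientation; CG counts differ by at
#' most one between bins, with the remainder given to the earliest bins.
#'
#' @param element one-row data.frame (chrom, start, end, strand).
#' @param sites combined CG-site table.
#' @param n_bins number of bins; must not exceed the element's CG count.
#' @return the element's sites with a `bin` column (1 = 5'-most).
#' @export
bin_equal_cg <- function(element, sites, n_bins) {
  s <- .sites_in(data.table::as.data.table(sites), element$chrom,
                 element$start, element$end)
  n <- nrow(s)
  if (n_bins > n)
    stop("n_bins (", n_bins, ") exceeds the element's CG count (", n, ")")
  data.table::setorder(s, pos)
  if (element$strand == "-") s <- s[rev(seq_len(n))]
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  s[, bin := rep(seq_len(n_bins), sizes)]
  s[]
}

#' Grouped, binned methylation profiles
#'
#' Elements are grouped into equal-count groups by CG count (deciles by
#' default) or by summed coverage (tertiles), then each element is split
#' into `n_bins` equal-CG bins; bins of the same ordinal are pooled within
#' a group to one overall methylation rate and a median CG density.
#'
#' @param elements filtered element table (with n_cg and coverage
#'   columns from [filter_elements()]).
#' @param sites combined CG-site table (with cg_density column for the
#'   density summary).
#' @param group_by "cg_density" (element CG count) or "coverage".
#' @param n_groups number of equal-count groups (10 for CG-density groups,
#'   3 for coverage groups GR1-GR3).
#' @param n_bins equal-CG bins per element.
#' @return data.table: group, bin, n_sites, rC, rT, mr, median_density.
#' @export
profile_groups <- function(elements, sites, group_by = c("cg_density",
                                                         "coverage"),
                           n_groups = 10L, n_bins = 20L) {
  group_by <- match.arg(group_by)
  e <- data.table::as.data.table(elements)
  stopifnot(nrow(e) >= n_groups)
  key <- if (group_by == "cg_density") e$n_cg
         else rowSums(as.matrix(e[, grep("^coverage_", names(e)),
                                  with = FALSE]))
  ord <- order(key)
  grp <- integer(nrow(e))
  sizes <- rep(nrow(e) %/% n_groups, n_groups)
  extra <- nrow(e) %% n_groups
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp[ord] <- rep(seq_len(n_groups), sizes)

  per <- lapply(seq_len(nrow(e)), function(i) {
    b <- bin_equal_cg(e[i], sites, n_bins)
    b[, `:=`(group = grp[i])]
    b
  })
  all_b <- data.table::rbindlist(per)
  out <- all_b[, list(
    n_sites = .N,
    rC = sum(rC_p + rC_n), rT = sum(rT_p + rT_n),
    mr = methylation_rate(sum(rC_p + rC_n), sum(rT_p + rT_n)),
    median_density = if ("cg_density" %in% names(all_b))
      as.numeric(median(cg_density)) else NA_real_),
    by = c("group", "bin")]
  data.table::setorder(out, group, bin)
  out[]
}

#' Gene-promoter methylation matrix
#'
#' Promoters (TSS +/- `flank`, strand-aware) are cut into `n_bins`
#' equal-length bins; genes are sorted by expression (FPKM) then promoter
#' CG count and partitioned into `n_groups` equal-count groups; each
#' group x bin cell holds the pooled overall methylation rate.
#'
#' @param genes gene table (chrom, start, end, strand, gene_id).
#' @param sites combined CG-site table.
#' @param expression data.frame with gene_id and fpkm columns.
#' @param n_groups,n_bins matrix dimensions (500 x 40 at full scale).
#' @param flank bases each side of the TSS (default 4000; bin width
#'   2*flank/n_bins).
#' @return list with `matrix` (n_groups x n_bins overall MR), `genes_used`,
#'   `n_excluded` (genes without expression values).
#' @export
gene_promoter_profile <- function(genes, sites, expression,
                                  n_groups = 500L, n_bins = 40L,
                                  flank = 4000L) {
  g <- data.table::as.data.table(genes)
  expr <- data.table::as.data.table(expression)
  m <- merge(g, expr[, list(gene_id, fpkm)], by = "gene_id")
  n_excluded <- nrow(g) - nrow(m)
  stopifnot(nrow(m) >= n_groups)
  tss <- ifelse(m$strand == "+", m$start, m$end)
  width <- (2L * flank) %/% n_bins
  ## promoter CG count for the sort key
  cg_n <- vapply(seq_len(nrow(m)), function(i)
    nrow(.sites_in(sites, m$chrom[i], tss[i] - flank, tss[i] + flank)),
    1L)
  ord <- order(m$fpkm, cg_n)
  grp <- integer(nrow(m))
  sizes <- rep(nrow(m) %/% n_groups, n_groups)
  extra <- nrow(m) %% n_groups
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp[ord] <- rep(seq_len(n_groups), sizes)

  rc <- matrix(0, n_groups, n_bins); rt <- matrix(0, n_groups, n_bins)
  for (i in seq_len(nrow(m))) {
    s <- .sites_in(sites, m$chrom[i], tss[i] - flank, tss[i] + flank)
    if (!nrow(s)) next
    off <- s$pos - (tss[i] - flank)
    bin <- pmin(off %/% width + 1L, n_bins)
    if (m$strand[i] == "-") bin <- n_bins + 1L - bin
    for (k in seq_len(nrow(s))) {
      rc[grp[i], bin[k]] <- rc[grp[i], bin[k]] + s$rC_p[k] + s$rC_n[k]
      rt[grp[i], bin[k]] <- rt[grp[i], bin[k]] + s$rT_p[k] + s$rT_n[k]
    }
  }
  mat <- rc / (rc + rt)
  list(matrix = mat, genes_used = nrow(m), n_excluded = n_excluded,
       bin_width = width)
}
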