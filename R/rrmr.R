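## Reduction-resistant methylation regions (RRMRs)
##
## The deletion index Di = (Swt - Sko) / Swt measures the fractional loss
## of methylation in a knockout relative to wild type. An RRMR is a maximal
## run of >= min_run consecutive CG sites (consecutive among sites covered
## in both genotypes) each with Di below the threshold; run lengths of 7
## (DKO vs WT) and 5 (1KO vs WT) are the full-scale defaults.

#' Deletion index
#'
#' @param Swt,Sko methylation rates in wild type / knockout.
#' @return (Swt - Sko) / Swt, NA where Swt = 0 (vectorised).
#' @export
deletion_index <- function(Swt, Sko) {
  ifelse(Swt > 0, (Swt - Sko) / Swt, NA_real_)
}

#' Find RRMRs
#'
#' Joins WT and KO combined CG-site tables on position, keeps sites with
#' combined coverage above `min_cov` in both genotypes (uncovered sites are
#' transparent, not run-breakers), computes Di per site, and returns all
#' maximal runs of at least `min_run` consecutive qualifying sites.
#'
#' @param wt_sites,ko_sites [combine_cg_strands()] tables.
#' @param min_run minimum number of consecutive qualifying CG sites
#'   (7 for DKO-vs-WT, 5 for 1KO-vs-WT).
#' @param di_threshold strict upper bound on Di (default 0.3).
#' @param min_cov combined-coverage floor applied to both genotypes
#'   (strictly greater than; default 6).
#' @return data.table: chrom, start, end (spanning first to last CG,
#'   G included), n_cg, mr_wt, mr_ko (pooled overall rates over the run).
#' @export
find_rrmrs <- function(wt_sites, ko_sites, min_run = 7L,
                       di_threshold = 0.3, min_cov = 6L) {
  empty <- data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    n_cg = integer(0), mr_wt = numeric(0), mr_ko = numeric(0))
  if (!nrow(wt_sites) || !nrow(ko_sites)) return(empty)
  wt <- data.table::as.data.table(wt_sites)[
    , list(chrom, pos, wt_rc = rC_p + rC_n, wt_rt = rT_p + rT_n,
           Swt = S_combined, wt_cov = coverage)]
  ko <- data.table::as.data.table(ko_sites)[
    , list(chrom, pos, ko_rc = rC_p + rC_n, ko_rt = rT_p + rT_n,
           Sko = S_combined, ko_cov = coverage)]
  m <- merge(wt, ko, by = c("chrom", "pos"))
  m <- m[m$wt_cov > min_cov & m$ko_cov > min_cov]
  if (!nrow(m)) return(empty)
  data.table::setorder(m, chrom, pos)
  m[, di := deletion_index(Swt, Sko)]
  m[, ok := !is.na(di) & di < di_threshold]

  out <- m[, {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (any(keep)) {
      i1 <- starts[keep]; i2 <- ends[keep]
      data.table::data.table(
        start = pos[i1], end = pos[i2] + 2L,
        n_cg = i2 - i1 + 1L,
        mr_wt = vapply(seq_along(i1), function(k)
          methylation_rate(sum(wt_rc[i1[k]:i2[k]]),
                           sum(wt_rt[i1[k]:i2[k]])), 1),
        mr_ko = vapply(seq_along(i1), function(k)
          methylation_rate(sum(ko_rc[i1[k]:i2[k]]),
                           sum(ko_rt[i1[k]:i2[k]])), 1))
    } else NULL
  }, by = chrom]
  if (!nrow(out)) return(empty)
  out[]
}

#' Assign RRMRs to nearby repeat elements
#'
#' An RRMR is assigned to repeats within `gap` bases (overlap = distance
#' 0); an RRMR hitting several repeats resolves to the nearest one, ties
#' broken by larger overlap, then by repeat coordinate.
#'
#' @param rrmrs [find_rrmrs()] table.
#' @param repeats repeat annotation (chrom, start, end, strand, subtype,
#'   family, class).
#' @param gap maximum interval distance in bases (50 for DKO RRMRs, 200
#'   for 1KO RRMRs).
#' @return the RRMR table with repeat_idx, subtype, family, class columns
#'   (NA where unassigned).
#' @export
overlap_repeats <- function(rrmrs, repeats, gap = 50L) {
  rrmrs <- data.table::as.data.table(rrmrs)
  repeats <- data.table::as.data.table(repeats)
  out <- data.table::copy(rrmrs)
  out[, `:=`(repeat_idx = NA_integer_, subtype = NA_character_,
             family = NA_character_, class = NA_character_)]
  if (!nrow(rrmrs) || !nrow(repeats)) return(out[])
  gr_r <- GenomicRanges::GRanges(
    rrmrs$chrom, IRanges::IRanges(rrmrs$start + 1L, rrmrs$end))
  gr_e <- GenomicRanges::GRanges(
    repeats$chrom, IRanges::IRanges(repeats$start + 1L, repeats$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_e, maxgap = gap)
  if (!length(hits)) return(out[])
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(gr_r[q], gr_e[s])
  ov <- pmin(rrmrs$end[q], repeats$end[s]) -
    pmax(rrmrs$start[q], repeats$start[s])
  ov <- pmax(ov, 0L)
  h <- data.table::data.table(q = q, s = s, dist = dist, ov = ov,
                              rs = repeats$start[s])
  data.table::setorder(h, q, dist, -ov, rs)
  best <- h[!duplicated(q)]
  out[best$q, `:=`(repeat_idx = best$s,
                   subtype = repeats$subtype[best$s],
                   family = repeats$family[best$s],
                   class = repeats$class[best$s])]
  out[]
}

#' Fisher enrichment of RRMR assignments by repeat category
#'
#' For each level of `by`, tests whether RRMR-assigned elements are
#' enriched in that category relative to the genome-wide repeat
#' composition (element counts), with a two-sided Fisher exact test. The
#' reported odds ratio is the sample (cross-product) odds ratio.
#'
#' @param assigned [overlap_repeats()] output (unassigned rows ignored).
#' @param repeats full repeat annotation table.
#' @param by grouping column: "class", "family" or "subtype".
#' @return data.table: level, rrmr_in, rrmr_out, genome_in, genome_out,
#'   odds_ratio, p_value.
#' @export
enrichment_test <- function(assigned, repeats, by = "class") {
  a <- data.table::as.data.table(assigned)
  a <- a[!is.na(a[[by]])]
  repeats <- data.table::as.data.table(repeats)
  levels <- sort(unique(repeats[[by]]))
  out <- lapply(levels, function(lv) {
    r_in <- sum(a[[by]] == lv); r_out <- nrow(a) - r_in
    g_in <- sum(repeats[[by]] == lv)
    g_out <- nrow(repeats) - g_in
    tab <- matrix(c(r_in, r_out, g_in, g_out), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("zero margin for level ", lv, "; p set to 1")
      p <- 1
    } else p <- fisher.test(tab)$p.value
    or <- (r_in * g_out) / (r_out * g_in)
    data.table::data.table(level = lv, rrmr_in = r_in, rrmr_out = r_out,
                           genome_in = g_in, genome_out = g_out,
                           odds_ratio = or, p_value = p)
  })
  data.table::rbindlist(out)
}

#' LTR-subtype methylation-range table
#'
#' Splits the members of each LTR subtype into six methylation ranges
#' ([0,0.1), [0.1,0.2), ..., [0.4,0.5), [0.5,1]) and reports the fraction
#' per range; subtypes are ordered by the fraction in the highest range,
#' then the second highest.
#'
#' @param elements data.frame with `subtype` and `mr` (per-element overall
#'   methylation) columns, already filtered.
#' @param min_members subtypes with fewer members are dropped (full-scale
#'   default 50).
#' @return data.table: subtype, n_members, and fraction columns r1..r6,
#'   each row summing to 1.
#' @export
ltr_subtype_table <- function(elements, min_members = 50L) {
  e <- data.table::as.data.table(elements)
  stopifnot(all(e$mr >= 0 & e$mr <= 1))
  e <- e[, if (.N > min_members) .SD, by = subtype]
  if (!nrow(e))
    return(data.table::data.table(subtype = character(0),
                                  n_members = integer(0)))
  bin <- findInterval(e$mr, c(0.1, 0.2, 0.3, 0.4, 0.5)) + 1L
  e[, bin := bin]
  tab <- e[, {
    f <- tabulate(bin, nbins = 6L) / .N
    c(list(n_members = .N), as.list(setNames(f, paste0("r", 1:6))))
  }, by = subtype]
  data.table::setorder(tab, -r6, -r5, subtype)
  tab[]
}
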