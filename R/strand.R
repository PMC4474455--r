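## Strand-symmetry statistics
##
## Maintenance methylation copies methylation template-wise, so wild-type
## CG sites are near-symmetric between strands; loss of maintenance
## activity decouples the strands. The bias index quantifies per-site
## asymmetry; the sense/antisense Pearson correlation summarises it
## genome-wide.

#' Bias index of a CG site
#'
#' BI = (Sn - Sp) / (Sn + Sp), in [-1, 1]. Sites with Sn = Sp = 0 are
#' defined as unbiased (BI = 0) rather than undefined.
#'
#' @param Sn,Sp methylation rates on the antisense / sense strand.
#' @return numeric bias index (vectorised).
#' @export
bias_index <- function(Sn, Sp) {
  tot <- Sn + Sp
  ifelse(tot == 0, 0, (Sn - Sp) / tot)
}

#' Sense/antisense methylation correlation
#'
#' Pearson correlation of (Sp, Sn) over CG sites with per-strand coverage
#' at least `min_cov_per_strand`.
#'
#' @param sites combined CG-site table from [combine_cg_strands()].
#' @param min_cov_per_strand per-strand coverage floor (default 10).
#' @return list with `pcc`, `n_sites`.
#' @export
strand_correlation <- function(sites, min_cov_per_strand = 10L) {
  keep <- sites$cov_p >= min_cov_per_strand &
    sites$cov_n >= min_cov_per_strand
  s <- sites[keep]
  if (nrow(s) < 2L) {
    warning("fewer than 2 CG sites pass the per-strand coverage filter")
    return(list(pcc = NA_real_, n_sites = nrow(s)))
  }
  if (stats::sd(s$Sp) == 0 || stats::sd(s$Sn) == 0) {
    warning("zero variance on one strand; correlation undefined")
    return(list(pcc = NA_real_, n_sites = nrow(s)))
  }
  list(pcc = cor(s$Sp, s$Sn), n_sites = nrow(s))
}

#' Bias-index distribution
#'
#' @param sites combined CG-site table (per-strand rates present).
#' @param range_lo,range_hi BI range of interest (default [-0.2, 0.2]).
#' @param min_cov_per_strand per-strand coverage floor.
#' @param bin_width histogram bin width over [-1, 1].
#' @return list with `fraction_in_range`, `n_sites` and `histogram`
#'   (data.table: lo, hi, count).
#' @export
bi_distribution <- function(sites, range_lo = -0.2, range_hi = 0.2,
                            min_cov_per_strand = 10L, bin_width = 0.05) {
  keep <- sites$cov_p >= min_cov_per_strand &
    sites$cov_n >= min_cov_per_strand
  s <- sites[keep]
  if (!nrow(s))
    return(list(fraction_in_range = NA_real_, n_sites = 0L,
                histogram = NULL))
  bi <- bias_index(s$Sn, s$Sp)
  breaks <- seq(-1, 1, by = bin_width)
  idx <- pmin(pmax(findInterval(bi, breaks, rightmost.closed = TRUE), 1L),
              length(breaks) - 1L)
  list(fraction_in_range = mean(bi >= range_lo & bi <= range_hi),
       n_sites = length(bi),
       histogram = data.table::data.table(
         lo = breaks[-length(breaks)], hi = breaks[-1],
         count = tabulate(idx, nbins = length(breaks) - 1L)))
}
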