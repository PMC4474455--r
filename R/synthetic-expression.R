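## Synthetic WT/TKO expression tables
##
## Emulates the observed coupling between promoter methylation, promoter CG
## density and transcriptional deregulation upon global hypomethylation:
## genes silenced by dense promoter methylation at low CG density are
## induced (or, for a minority, suppressed) in TKO cells; everything else
## barely moves.

.gene_classes <- data.frame(
  class   = c("up", "down", "unchanged"),
  meth    = c(0.75, 0.75, 0.02),    # WT promoter methylation (mean)
  density = c(24, 28, 60),          # promoter CG count (mean)
  fc_mean = c(3.5, -3.5, 0),        # log2(TKO/WT)
  fc_sd   = c(0.45, 0.45, 0.15),
  stringsAsFactors = FALSE)

#' Simulate a WT/TKO FPKM table with promoter methylation
#'
#' Genes whose WT promoter methylation is >= 0.5 at CG density < 30 are
#' deregulated (|log2 FC| > 2.5, mostly induced in TKO); all other genes
#' draw a fold change near 0. Per-gene promoter methylation counts (rC/rT)
#' are emitted binomially at `coverage_per_cg` so downstream pooled overall
#' methylation recovers the class means.
#'
#' @param n_genes total number of genes.
#' @param dereg_fraction fraction of genes in the deregulated (high
#'   methylation, low density) class.
#' @param down_fraction fraction of deregulated genes that are suppressed
#'   rather than induced.
#' @param coverage_per_cg mean read coverage per promoter CG site.
#' @param seed integer seed.
#' @return data.table: gene_id, class, promoter_cg, promoter_mr_wt,
#'   rc_promoter, rt_promoter, fpkm_wt, fpkm_tko.
#' @export
simulate_expression <- function(n_genes = 6000L, dereg_fraction = 0.08,
                                down_fraction = 0.2, coverage_per_cg = 30,
                                seed = 1L) {
  with_seed(seed, {
    n_dereg <- round(n_genes * dereg_fraction)
    n_down <- round(n_dereg * down_fraction)
    cls <- c(rep("up", n_dereg - n_down), rep("down", n_down),
             rep("unchanged", n_genes - n_dereg))
    par <- .gene_classes[match(cls, .gene_classes$class), ]

    cg <- pmax(5L, rpois(n_genes, par$density))
    mr <- pmin(pmax(rnorm(n_genes, par$meth, 0.03), 0), 1)
    cov <- rpois(n_genes, cg * coverage_per_cg)
    rc <- rbinom(n_genes, cov, mr)
    rt <- cov - rc

    fc <- rnorm(n_genes, par$fc_mean, par$fc_sd)
    ## deregulated classes must clear the 2.5 threshold; everything stays
    ## inside the [-6, 6] analysis window
    fc[cls == "up"] <- pmin(pmax(fc[cls == "up"], 2.6), 5.8)
    fc[cls == "down"] <- pmax(pmin(fc[cls == "down"], -2.6), -5.8)
    fc[cls == "unchanged"] <- pmin(pmax(fc[cls == "unchanged"], -0.49), 0.49)

    fpkm_wt <- 2^rnorm(n_genes, 4, 1.2)
    fpkm_wt[cls == "up"] <- 2^rnorm(sum(cls == "up"), 0.5, 0.5)
    fpkm_tko <- fpkm_wt * 2^fc
    ## keep every gene past the FPKM-sum filter so class recovery is exact
    bump <- (fpkm_wt + fpkm_tko) <= 1.05
    fpkm_wt[bump] <- fpkm_wt[bump] + 1.05 / (1 + 2^fc[bump])
    fpkm_tko[bump] <- fpkm_wt[bump] * 2^fc[bump]

    data.table::data.table(
      gene_id = sprintf("gene%05d", seq_len(n_genes)), class = cls,
      promoter_cg = as.integer(cg), promoter_mr_wt = mr,
      rc_promoter = as.integer(rc), rt_promoter = as.integer(rt),
      fpkm_wt = fpkm_wt, fpkm_tko = fpkm_tko)
  })
}
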