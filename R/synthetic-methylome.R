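## Genotype-specific synthetic methylomes
##
## Each cytosine in the toy genome receives a methylation probability
## according to the feature class it falls in. Feature classes mirror the
## biology being modelled: wild-type (WT) cells are highly methylated
## (~0.78) outside CG islands; DNMT1-knockout (KO1) cells retain high
## methylation at LINE promoters but lose it elsewhere; DNMT3a/3b double
## knockouts (DKO) retain it at LTRs (IAP-like elements); triple knockouts
## (TKO) are essentially unmethylated.

.profile_defaults <- list(
  WT  = c(background = 0.78, cg_island = 0.02, LTR = 0.78,
          LINE_promoter = 0.78, LINE_body = 0.78, gene = 0.78),
  KO1 = c(background = 0.18, cg_island = 0.02, LTR = 0.18,
          LINE_promoter = 0.78, LINE_body = 0.18, gene = 0.18),
  DKO = c(background = 0.18, cg_island = 0.02, LTR = 0.78,
          LINE_promoter = 0.18, LINE_body = 0.18, gene = 0.18),
  TKO = c(background = 0.005, cg_island = 0.005, LTR = 0.005,
          LINE_promoter = 0.005, LINE_body = 0.005, gene = 0.005))

.profile_chh <- c(WT = 0.02, KO1 = 0.02, DKO = 0.005, TKO = 0.001)

#' Genotype methylome profile
#'
#' @param genotype one of "WT", "KO1", "DKO", "TKO".
#' @param class_probs named numeric vector mapping feature classes
#'   (background, cg_island, LTR, LINE_promoter, LINE_body, gene) to CG
#'   methylation probabilities; defaults are genotype-specific.
#' @param strand_mode "symmetric" (the two strands of a CG share one
#'   probability) or "independent" (each strand drawn separately; only
#'   meaningful with `site_dispersion = TRUE`).
#' @param chh_rate CHH/CHG methylation probability.
#' @param site_dispersion if TRUE, per-site probabilities are drawn from a
#'   two-component mixture (unmethylated ~0.03 / methylated ~0.9) whose
#'   weight matches the class mean, giving realistic between-site variance;
#'   if FALSE every site takes the class probability verbatim.
#' @return a `methylome_profile` list.
#' @export
methylome_profile <- function(genotype = c("WT", "KO1", "DKO", "TKO"),
                              class_probs = NULL,
                              strand_mode = c("symmetric", "independent"),
                              chh_rate = NULL,
                              site_dispersion = FALSE) {
  genotype <- match.arg(genotype)
  strand_mode <- match.arg(strand_mode)
  probs <- if (is.null(class_probs)) .profile_defaults[[genotype]]
           else class_probs
  if (is.null(chh_rate)) chh_rate <- .profile_chh[[genotype]]
  stopifnot(all(probs >= 0 & probs <= 1), chh_rate >= 0, chh_rate <= 1)
  if (genotype == "TKO" && any(probs > 0.01))
    stop("TKO class probabilities must be <= 0.01")
  structure(list(genotype = genotype, class_probs = probs,
                 strand_mode = strand_mode, chh_rate = chh_rate,
                 site_dispersion = site_dispersion),
            class = "methylome_profile")
}

## mixture endpoints for dispersed site-level probabilities
.disp_lo <- 0.03
.disp_hi <- 0.90

## classify every position of a chromosome into a feature class
.class_vector <- function(len, chrom, annotations) {
  cls <- rep("background", len)
  isl <- annotations$islands
  if (!is.null(isl) && nrow(isl)) {
    isl <- isl[which(isl$chrom == chrom)]
    for (i in seq_len(nrow(isl)))
      cls[(isl$start[i] + 1L):isl$end[i]] <- "cg_island"
  }
  gn <- annotations$genes
  if (!is.null(gn) && nrow(gn)) {
    gn <- gn[which(gn$chrom == chrom)]
    for (i in seq_len(nrow(gn)))
      cls[(gn$start[i] + 1L):gn$end[i]] <- "gene"
  }
  rp <- annotations$repeats
  if (!is.null(rp) && nrow(rp)) {
    rp <- rp[which(rp$chrom == chrom)]
    for (i in seq_len(nrow(rp))) {
      if (rp$class[i] == "LTR") {
        cls[(rp$start[i] + 1L):rp$end[i]] <- "LTR"
      } else if (rp$class[i] == "LINE") {
        cls[(rp$start[i] + 1L):rp$end[i]] <- "LINE_body"
        pr <- line_promoter(rp$start[i], rp$end[i], rp$strand[i],
                            chrom_length = len)
        if (pr[2] > pr[1])
          cls[(pr[1] + 1L):pr[2]] <- "LINE_promoter"
      } else {
        stop("configuration error: unknown repeat class ", rp$class[i])
      }
    }
  }
  cls
}

#' Assign per-cytosine methylation probabilities
#'
#' Every cytosine on both strands receives a probability: CG-context
#' cytosines take their feature-class probability (or a dispersed draw, see
#' [methylome_profile()]); CHG/CHH cytosines take `chh_rate`. In symmetric
#' mode the two strands of a CG share one probability.
#'
#' @param genome named character vector of chromosome sequences.
#' @param annotations list with `repeats`, `genes`, `islands` tables as
#'   produced by [generate_toy_genome()] (any may be empty).
#' @param profile a [methylome_profile()].
#' @param seed integer seed for dispersed draws.
#' @return data.table: chrom, pos (0-based, position of the cytosine on the
#'   top strand: the C itself for "+", the paired G for "-"), strand,
#'   context ("CG"/"CHG"/"CHH"), class, p.
#' @export
assign_methylome <- function(genome, annotations, profile, seed = 1L) {
  stopifnot(inherits(profile, "methylome_profile"))
  known <- names(profile$class_probs)
  with_seed(seed, {
    out <- lapply(names(genome), function(chrom) {
      seq <- genome[[chrom]]
      len <- nchar(seq)
      ref <- cytosine_reference(seq)     # chrom-local context table
      cls <- .class_vector(len, chrom, annotations)
      site_cls <- cls[ref$pos + 1L]
      bad <- setdiff(unique(site_cls), c(known))
      if (length(bad))
        stop("configuration error: unknown feature class ", bad[1])
      p <- rep(profile$chh_rate, nrow(ref))
      is_cg <- ref$context == "CG"
      if (any(is_cg)) {
        cg_mean <- unname(profile$class_probs[site_cls[is_cg]])
        if (profile$site_dispersion) {
          ## one CG dinucleotide = the +C at pos and the -C at pos + 1
          key <- ifelse(ref$strand[is_cg] == "+", ref$pos[is_cg],
                        ref$pos[is_cg] - 1L)
          if (profile$strand_mode == "symmetric") {
            u <- !duplicated(key)
            shared <- .dispersed_p_by_mean(cg_mean[u])
            names(shared) <- as.character(key[u])
            p[which(is_cg)] <- unname(shared[as.character(key)])
          } else {
            p[which(is_cg)] <- .dispersed_p_by_mean(cg_mean)
          }
        } else {
          p[which(is_cg)] <- cg_mean
        }
      }
      data.table::data.table(chrom = chrom, pos = ref$pos,
                             strand = ref$strand, context = ref$context,
                             class = site_cls, p = p)
    })
    data.table::rbindlist(out)
  })
}

## vectorised dispersed draw with per-site means
.dispersed_p_by_mean <- function(mean_p) {
  n <- length(mean_p)
  w <- (mean_p - .disp_lo) / (.disp_hi - .disp_lo)
  fixed <- mean_p <= .disp_lo | mean_p >= .disp_hi
  out <- ifelse(runif(n) < w, .disp_hi, .disp_lo)
  out[fixed] <- mean_p[fixed]
  out
}
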