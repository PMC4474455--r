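## Synthetic toy genomes
##
## The generator emits small genomes that mimic the structure the pipeline
## needs to see: background sequence of a chosen GC fraction, CG-dense
## islands, and annotated gene / LINE / LTR features with controllable CG
## density. Everything is deterministic under a seed.

#' Describe a toy genome
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bases (>= 10000).
#' @param gc_fraction background GC fraction in (0, 1).
#' @param cg_islands data.frame with columns `chrom` (1-based index),
#'   `start` (0-based), `length`, `density` (target CG count per 600 bp),
#'   or NULL.
#' @param features data.frame with columns `chrom`, `start` (0-based),
#'   `length`, `kind` ("gene", "LINE" or "LTR"), `subtype`, `strand`,
#'   `cg_density_class` ("low"/"high"), or NULL.
#' @return a validated spec list for [generate_toy_genome()].
#' @export
toy_genome_spec <- function(n_chromosomes = 1L, chrom_length = 50000L,
                            gc_fraction = 0.42, cg_islands = NULL,
                            features = NULL) {
  stopifnot(n_chromosomes >= 1L, chrom_length >= 10000L,
            gc_fraction > 0, gc_fraction < 1)
  if (!is.null(features) && nrow(features)) {
    features <- as.data.frame(features)
    stopifnot(all(c("chrom", "start", "length", "kind", "subtype", "strand",
                    "cg_density_class") %in% names(features)))
    stopifnot(all(features$kind %in% c("gene", "LINE", "LTR")),
              all(features$strand %in% c("+", "-")),
              all(features$cg_density_class %in% c("low", "high")))
    if (any(features$start < 0 |
            features$start + features$length > chrom_length))
      stop("layout error: feature interval exceeds chromosome bounds")
    ## non-overlap check within each chromosome
    for (ch in unique(features$chrom)) {
      f <- features[features$chrom == ch, ]
      f <- f[order(f$start), ]
      if (nrow(f) > 1L &&
          any(f$start[-1L] < (f$start + f$length)[-nrow(f)]))
        stop("layout error: overlapping features on chromosome ", ch)
    }
  }
  if (!is.null(cg_islands) && nrow(cg_islands)) {
    cg_islands <- as.data.frame(cg_islands)
    stopifnot(all(c("chrom", "start", "length", "density") %in%
                  names(cg_islands)))
    if (any(cg_islands$start < 0 |
            cg_islands$start + cg_islands$length > chrom_length))
      stop("layout error: island interval exceeds chromosome bounds")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 gc_fraction = gc_fraction,
                 cg_islands = cg_islands, features = features),
            class = "toy_genome_spec")
}

## CG-controlled sequence: tokens are "CG" with probability p, otherwise a
## single filler base from {A, T, G}. Filler never contains C, so the
## realised CG count is exactly the token count and the per-600-bp density
## is tightly controlled around `density`.
cg_controlled_seq <- function(len, density, gc_fill = 0.4) {
  rate <- density / 600                      # CG starts per bp
  p <- rate / (1 - rate)                     # token-level CG probability
  p <- min(max(p, 0), 0.95)
  out <- character(0)
  total <- 0L
  fill <- c("A", "T", "G")
  pfill <- c((1 - gc_fill) / 2, (1 - gc_fill) / 2, gc_fill)
  ## draw in chunks to stay vectorised
  while (total < len) {
    n <- max(64L, ceiling((len - total) / (1 + p)))
    tok <- ifelse(runif(n) < p, "CG",
                  sample(fill, n, replace = TRUE, prob = pfill))
    out <- c(out, tok)
    total <- total + sum(nchar(tok))
  }
  substr(paste(out, collapse = ""), 1L, len)
}

random_background <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## CG density (per 600 bp) handed to feature interiors by class
.feature_density <- c(low = 10, high = 45)

#' Generate a toy genome with annotations
#'
#' Produces the genome sequence plus repeat (LINE/LTR) and gene annotation
#' tables in 0-based half-open coordinates. Feature interiors are emitted
#' with a CG rate set by their `cg_density_class`; islands hit their target
#' CG-per-600-bp density within sampling noise.
#'
#' @param spec a [toy_genome_spec()].
#' @param seed integer seed; the same spec and seed reproduce the genome.
#' @return list with `genome` (named character vector), `repeats`
#'   (data.table: chrom, start, end, strand, subtype, family, class),
#'   `genes` (data.table: chrom, start, end, strand, gene_id) and
#'   `islands` (data.table of realised islands).
#' @export
generate_toy_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(spec$n_chromosomes))
    genome <- vapply(chroms, function(ch)
      random_background(spec$chrom_length, spec$gc_fraction), "")
    names(genome) <- chroms

    paste_in <- function(seqs, chrom_i, start0, piece) {
      s <- seqs[[chrom_i]]
      substr(s, start0 + 1L, start0 + nchar(piece)) <- piece
      seqs[[chrom_i]] <- s
      seqs
    }

    isl <- spec$cg_islands
    if (!is.null(isl) && nrow(isl)) {
      for (i in seq_len(nrow(isl)))
        genome <- paste_in(genome, isl$chrom[i], isl$start[i],
                           cg_controlled_seq(isl$length[i], isl$density[i],
                                             gc_fill = 0.55))
      islands <- data.table::data.table(
        chrom = chroms[isl$chrom], start = as.integer(isl$start),
        end = as.integer(isl$start + isl$length),
        density = isl$density)
    } else {
      islands <- data.table::data.table(
        chrom = character(0), start = integer(0), end = integer(0),
        density = numeric(0))
    }

    fts <- spec$features
    if (!is.null(fts) && nrow(fts)) {
      for (i in seq_len(nrow(fts)))
        genome <- paste_in(genome, fts$chrom[i], fts$start[i],
                           cg_controlled_seq(
                             fts$length[i],
                             .feature_density[[fts$cg_density_class[i]]],
                             gc_fill = spec$gc_fraction))
      fam <- c(gene = "gene", LINE = "L1", LTR = "ERVK")
      cls <- c(gene = "gene", LINE = "LINE", LTR = "LTR")
      ann <- data.table::data.table(
        chrom = chroms[fts$chrom], start = as.integer(fts$start),
        end = as.integer(fts$start + fts$length),
        strand = fts$strand, subtype = fts$subtype,
        family = fam[fts$kind], class = cls[fts$kind])
      repeats <- ann[ann$class != "gene"]
      genes <- ann[ann$class == "gene",
                   list(chrom, start, end, strand,
                        gene_id = paste0("gene", seq_len(sum(ann$class == "gene"))))]
    } else {
      repeats <- data.table::data.table(
        chrom = character(0), start = integer(0), end = integer(0),
        strand = character(0), subtype = character(0), family = character(0),
        class = character(0))
      genes <- data.table::data.table(
        chrom = character(0), start = integer(0), end = integer(0),
        strand = character(0), gene_id = character(0))
    }
    list(genome = genome, repeats = repeats, genes = genes,
         islands = islands)
  })
}

#' Copy a genomic segment to new locations with optional divergence
#'
#' Utility for building repeat families: the source segment is pasted at
#' each destination start, with each copy independently mutated at
#' `divergence` substitutions per base.
#'
#' @param genome named character vector.
#' @param chrom chromosome name.
#' @param src_start,length 0-based source interval.
#' @param dest_starts 0-based destination starts (same chromosome).
#' @param divergence per-base substitution probability for each copy.
#' @param seed integer seed.
#' @return the modified genome.
#' @export
duplicate_region <- function(genome, chrom, src_start, length, dest_starts,
                             divergence = 0, seed = 1L) {
  with_seed(seed, {
    src <- seq_window(genome[[chrom]], src_start, src_start + length)
    for (d in dest_starts) {
      piece <- src
      if (divergence > 0) {
        ch <- seq_chars(piece)
        hit <- which(runif(length(ch)) < divergence)
        for (i in hit)
          ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
        piece <- paste(ch, collapse = "")
      }
      s <- genome[[chrom]]
      substr(s, d + 1L, d + length) <- piece
      genome[[chrom]] <- s
    }
    genome
  })
}
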