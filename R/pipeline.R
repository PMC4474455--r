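## End-to-end pipeline
##
## run_pipeline() wires the stages together: (optional) simulation ->
## three-letter alignment -> monoclonization -> cytosine calling ->
## strand statistics, RRMR discovery and repeat enrichment. Every
## threshold of the analysis is surfaced in pipeline_config() with its
## full-scale default.

#' Read / write FASTA genomes
#'
#' Thin wrappers around Biostrings keeping the package's plain character
#' representation.
#'
#' @param file FASTA path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), names(x))
}

#' @rdname read_genome_fasta
#' @param genome named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), file)
  invisible(file)
}

#' Pipeline configuration
#'
#' All stage parameters with their full-scale defaults: coverage floors
#' (> 6 global, >= 10 per strand, > 50 per element), deletion-index
#' threshold 0.3, run lengths 7 (DKO) / 5 (1KO), overlap gaps 50 (DKO) /
#' 200 (1KO) bp, fold-change threshold 2.5, fragment window [300, 600],
#' at most 20 alignment candidates, 3 mismatches in the leading 40 bases,
#' Phred budget 140.
#'
#' @param ... overrides for any default.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    fragment_window = c(300L, 600L),
    max_hits = 20L, max_mm = 3L, lead = 40L, phred_budget = 140L,
    seed_length = 18L,
    min_cov_global = 6L,       # combined coverage floor (strict >)
    min_cov_strand = 10L,      # per-strand floor for strand analyses
    min_cov_element = 50L,     # summed element coverage (strict >)
    di_threshold = 0.3,
    min_run_dko = 7L, min_run_1ko = 5L,
    gap_dko = 50L, gap_1ko = 200L,
    fc_threshold = 2.5,
    n_subgroups = 500L,
    promoter_halfwin = 500L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Load a YAML pipeline configuration
#'
#' @param file YAML file of overrides for [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  do.call(pipeline_config, yaml::read_yaml(file))
}

#' Run the methylome pipeline on simulated genotypes
#'
#' Simulates BS-seq reads for each requested genotype over one toy genome,
#' aligns them (or uses truth-table alignments), monoclonizes, calls
#' cytosines, and runs the strand and RRMR analyses. All stage outputs are
#' written as TSV under `outdir` together with a manifest of parameters
#' and record counts. Reruns with the same config are identical.
#'
#' @param genome named character vector of chromosome sequences.
#' @param annotations list (repeats, genes, islands).
#' @param genotypes character vector of genotypes to simulate.
#' @param lib a [library_params()].
#' @param config a [pipeline_config()].
#' @param outdir output directory (created), or NULL to skip writing.
#' @param use_aligner align reads with [align_pairs()]; if FALSE the
#'   simulator truth table stands in for a perfect aligner.
#' @param site_dispersion passed to [methylome_profile()].
#' @return list with per-genotype `sites` (combined CG tables), `summary`
#'   (dedup stats), `strand` stats, `rrmr` tables (DKO and 1KO vs WT when
#'   available), and the manifest.
#' @export
run_pipeline <- function(genome, annotations,
                         genotypes = c("WT", "KO1", "DKO"),
                         lib = library_params(),
                         config = pipeline_config(), outdir = NULL,
                         use_aligner = TRUE, site_dispersion = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  index <- if (use_aligner) build_index(genome, config$seed_length)
           else NULL
  sites <- list(); calls <- list(); summaries <- list()
  manifest <- list(config = unclass(config),
                   genotypes = genotypes, stages = list())
  for (gi in seq_along(genotypes)) {
    gt <- genotypes[gi]
    probs <- assign_methylome(
      genome, annotations,
      methylome_profile(gt, site_dispersion = site_dispersion),
      seed = config$seed + 101L * gi)
    sim <- simulate_bsseq_reads(genome, probs, lib,
                                seed = config$seed + 307L * gi)
    aln <- if (use_aligner)
      align_pairs(sim$pairs, index,
                  fragment_window = config$fragment_window,
                  max_mm = config$max_mm, lead = config$lead,
                  phred_budget = config$phred_budget,
                  max_hits = config$max_hits)
    else truth_alignments(sim)
    mono <- monoclonize(aln)
    cl <- pileup(mono$clones, genome)
    cg <- combine_cg_strands(cl, genome)
    calls[[gt]] <- cl; sites[[gt]] <- cg
    summaries[[gt]] <- mono$summary
    manifest$stages[[gt]] <- list(
      fragments = nrow(sim$truth), pairs = nrow(sim$pairs),
      aligned = nrow(aln), tags = mono$summary$tags,
      clones = mono$summary$clones, called_sites = nrow(cl),
      cg_sites = nrow(cg))
  }

  strand_stats <- lapply(sites, function(s) {
    pcc <- strand_correlation(s, config$min_cov_strand)
    bi <- bi_distribution(s, min_cov_per_strand = config$min_cov_strand)
    list(pcc = pcc$pcc, n_sites = pcc$n_sites,
         bi_fraction = bi$fraction_in_range)
  })

  rrmr <- list()
  if (all(c("WT", "DKO") %in% genotypes)) {
    r <- find_rrmrs(sites$WT, sites$DKO, min_run = config$min_run_dko,
                    di_threshold = config$di_threshold,
                    min_cov = config$min_cov_global)
    rrmr$DKO <- overlap_repeats(r, annotations$repeats,
                                gap = config$gap_dko)
  }
  if (all(c("WT", "KO1") %in% genotypes)) {
    r <- find_rrmrs(sites$WT, sites$KO1, min_run = config$min_run_1ko,
                    di_threshold = config$di_threshold,
                    min_cov = config$min_cov_global)
    rrmr$KO1 <- overlap_repeats(r, annotations$repeats,
                                gap = config$gap_1ko)
  }
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (gt in names(calls)) {
      write_cx_report(calls[[gt]],
                      file.path(outdir, paste0(gt, ".cx.tsv")),
                      bedgraph = file.path(outdir,
                                           paste0(gt, ".bedGraph")))
      data.table::fwrite(sites[[gt]],
                         file.path(outdir, paste0(gt, ".cg.tsv")),
                         sep = "\t")
    }
    for (nm in names(rrmr))
      data.table::fwrite(rrmr[[nm]],
                         file.path(outdir, paste0("rrmr_", nm, ".tsv")),
                         sep = "\t")
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }
  list(sites = sites, calls = calls, dedup = summaries,
       strand = strand_stats, rrmr = rrmr, manifest = manifest)
}
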