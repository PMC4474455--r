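## PCR-bias removal by monoclonization
##
## Sonication breaks chromosomes of different cells at effectively unique
## positions, so read pairs whose fragments share both end coordinates (and
## the bisulfite strand) are PCR copies of one molecule. They are collapsed
## to a single clone, keeping the best-scoring pair.

#' Collapse PCR duplicates to clones
#'
#' Groups resolved pairs by (chrom, fragment start, fragment end, fragment
#' strand) and keeps, per group, the pair with the best mapping score
#' (lowest summed Phred at mismatches); score ties break deterministically
#' on the lexicographically first read id.
#'
#' @param pairs alignment table with chrom, start, end, strand, score,
#'   read_id.
#' @return list with `clones` (deduplicated table) and `summary`
#'   (data.table: tags, clones, clone_fraction).
#' @export
monoclonize <- function(pairs) {
  pairs <- data.table::as.data.table(pairs)
  tags <- nrow(pairs)
  if (!tags)
    return(list(clones = pairs,
                summary = data.table::data.table(
                  tags = 0L, clones = 0L, clone_fraction = NA_real_)))
  stopifnot(all(pairs$start < pairs$end))
  ord <- order(pairs$chrom, pairs$start, pairs$end, pairs$strand,
               pairs$score, pairs$read_id)
  pairs <- pairs[ord]
  key <- paste(pairs$chrom, pairs$start, pairs$end, pairs$strand,
               sep = "\r")
  clones <- pairs[!duplicated(key)]
  list(clones = clones,
       summary = data.table::data.table(
         tags = tags, clones = nrow(clones),
         clone_fraction = nrow(clones) / tags))
}
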