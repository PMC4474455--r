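#' @import data.table
#' @importFrom stats rbinom runif rnorm median cor fisher.test rpois sd setNames
#' @importFrom utils write.table read.table head
#' @importFrom S4Vectors queryHits subjectHits
NULL

## A "genome" throughout this package is a named character vector of
## uppercase DNA strings (one element per chromosome). Annotation and
## fragment coordinates are 0-based half-open; R string indexing (1-based)
## is confined to the helpers below.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (length(x) == 1L) return(revcomp1(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## byte-level complement lookup; fast scalar reverse complement
.RC_TABLE <- local({
  tab <- as.raw(0:255)
  from <- charToRaw("ACGTNacgtn")
  to <- charToRaw("TGCANtgcan")
  tab[as.integer(from) + 1L] <- to
  tab
})

revcomp1 <- function(s) {
  rawToChar(.RC_TABLE[as.integer(rev(charToRaw(s))) + 1L])
}

## substring in 0-based half-open coordinates
seq_window <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

## character vector of single bases for a chromosome (cached upstream)
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

## raw-byte view used by the aligner for vectorised mismatch counting
seq_raw <- function(seq) charToRaw(seq)

## in-silico bisulfite conversions used for reads and genomes
c2t <- function(x) chartr("C", "T", x)
g2a <- function(x) chartr("G", "A", x)

## positions (0-based) of a single-character pattern in a string
base_positions <- function(seq, base) {
  r <- charToRaw(seq)
  which(r == charToRaw(base)) - 1L
}

## 0-based positions of "CG" dinucleotide starts (position of the + strand C)
cg_positions <- function(seq) {
  r <- charToRaw(seq)
  n <- length(r)
  if (n < 2L) return(integer(0))
  which(r[-n] == charToRaw("C") & r[-1L] == charToRaw("G")) - 1L
}

## deterministic RNG scope: run `expr` under `seed` without touching the
## caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
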