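#' @importFrom stats rbinom rnorm rpois runif median qt sd setNames
#' @importFrom utils write.table read.table head tail
#' @import data.table
NULL

DNA <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' @param n length in bases.
#' @param gc GC content as a fraction.
#' @return a single string of length `n`.
#' @export
random_dna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA, n, replace = TRUE, prob = p), collapse = "")
}

## substr() wrapper using 0-based half-open coordinates, the package-wide
## internal convention; conversions to 1-based happen only at I/O boundaries.
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

## mutate single bases in a vector of equal-length reads; pos is 1-based
## within the read. Used by the error model and variant planting.
mutate_base <- function(seqs, idx, pos) {
  for (j in seq_along(idx)) {
    i <- idx[j]
    old <- substr(seqs[i], pos[j], pos[j])
    substr(seqs[i], pos[j], pos[j]) <- sample(setdiff(DNA, old), 1L)
  }
  seqs
}

## apply i.i.d. substitution errors at `rate` to equal-width reads
apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  w <- nchar(seqs[1L])
  n_err <- rbinom(length(seqs), w, rate)
  hit <- which(n_err > 0L)
  if (length(hit) == 0L) return(seqs)
  idx <- rep(hit, n_err[hit])
  pos <- sample.int(w, length(idx), replace = TRUE)
  mutate_base(seqs, idx, pos)
}
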