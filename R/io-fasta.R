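#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] enforcing the
#' package's contracts: unique record names, no empty records, sequences
#' returned uppercase in file order.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences. Names are the FASTA headers
#'   truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop2("duplicate sequence name(s) in ", path, ": ",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(Biostrings::width(ss) == 0L)) stop2("empty record(s) in ", path)
  setNames(toupper(as.character(ss)), nm)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' Base qualities are not modelled anywhere in this package, so they are
#' dropped on input.
#'
#' @param path path to a FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Write reads to FASTQ with constant quality
#'
#' @param seqs named character vector of reads.
#' @param path output path.
#' @param qual quality character replicated across each read.
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    q <- vapply(nchar(seqs), function(n) strrep(qual, n), character(1))
    writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", q), con)
  }
  invisible(path)
}
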