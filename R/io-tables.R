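#' Write a minimal VCF v4.2 file
#'
#' Emits the CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns this package
#' uses for variant and insertion-call exchange. Positions are converted
#' from the internal 0-based convention to VCF 1-based.
#'
#' @param dt data.frame with columns `chrom`, `pos` (0-based), `id`, `ref`,
#'   `alt`, and optionally `info` (preformatted INFO string).
#' @param path output path.
#' @param info_header character vector of INFO header lines (without `##`).
#' @export
write_vcf <- function(dt, path, info_header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##", info_header),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(dt)) {
    info <- if ("info" %in% names(dt)) dt$info else "."
    id <- if ("id" %in% names(dt)) dt$id else "."
    writeLines(paste(dt$chrom, dt$pos + 1L, id, dt$ref, dt$alt,
                     ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read the minimal VCF subset written by [write_vcf()]
#' @param path VCF path.
#' @return data.table with 0-based `pos`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  rec <- lines[!startsWith(lines, "#")]
  if (!length(rec)) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  id = character(), ref = character(),
                                  alt = character(), info = character()))
  }
  f <- data.table::tstrsplit(rec, "\t", fixed = TRUE)
  data.table::data.table(chrom = f[[1]], pos = as.integer(f[[2]]) - 1L,
                         id = f[[3]], ref = f[[4]], alt = f[[5]],
                         info = f[[8]])
}

#' Write intervals to BED
#'
#' @param dt data.frame with `chrom`, `start`, `end` (already 0-based
#'   half-open, matching BED) and optionally `name`, `score`, `strand` for
#'   6-column output.
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(dt))) {
    cols <- c(cols, "name", "score", "strand")
  }
  write.table(as.data.frame(dt)[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read a TSV table
#' @param dt data.frame.
#' @param path file path.
#' @export
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) data.table::fread(path, sep = "\t")
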