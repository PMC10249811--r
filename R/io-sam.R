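## SAM flag bits used throughout
FLAG_PAIRED <- 1L
FLAG_PROPER <- 2L
FLAG_UNMAPPED <- 4L
FLAG_MUNMAPPED <- 8L
FLAG_REVERSE <- 16L
FLAG_MREVERSE <- 32L
FLAG_READ1 <- 64L
FLAG_READ2 <- 128L

## Parse CIGAR strings restricted to M/S/I/D (the DNA-read scope of this
## package; N/H/P and extended ops are rejected). Returns a data.table with
## one row per CIGAR: left_clip, right_clip, ref_span, read_len.
parse_cigars <- function(cigars) {
  uc <- unique(cigars)
  toks_all <- regmatches(uc, gregexpr("(\\d+)([A-Z=])", uc))
  parsed <- lapply(seq_along(uc), function(i) {
    toks <- toks_all[[i]]
    if (!length(toks) || paste(toks, collapse = "") != uc[i]) {
      stop2("malformed CIGAR: ", uc[i])
    }
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    bad <- setdiff(op, c("M", "S", "I", "D"))
    if (length(bad)) {
      stop2("unsupported CIGAR op(s) ", paste(bad, collapse = ""),
            " in ", uc[i], " (only M/S/I/D are handled)")
    }
    lc <- if (op[1] == "S") n[1] else 0L
    rc <- if (length(op) > 1L && op[length(op)] == "S") n[length(op)] else 0L
    if (sum(op == "S") > (lc > 0L) + (rc > 0L)) stop2("internal S op in ", uc[i])
    list(left_clip = lc, right_clip = rc,
         ref_span = sum(n[op %in% c("M", "D")]),
         read_len = sum(n[op %in% c("M", "S", "I")]))
  })
  dt <- data.table::rbindlist(parsed)
  dt[, cigar := uc]
  dt[match(cigars, uc)]
}

#' Read a SAM file into an alignment table
#'
#' Parses the plain-text SAM dialect this package emits and consumes:
#' coordinate fields, flags, CIGARs restricted to M/S/I/D, and mate
#' information. Positions are converted from SAM 1-based to the internal
#' 0-based half-open convention.
#'
#' @param path path to a SAM file.
#' @param sample_id sample label attached to every record (column `sample`).
#' @return a data.table with one row per alignment record: `qname`, `flag`,
#'   `chrom`, `pos` (0-based leftmost aligned base), `end` (0-based
#'   exclusive), `mapq`, `cigar`, `mchrom`, `mpos`, `tlen`, `seq`,
#'   `left_clip`, `right_clip`, plus decoded flag columns `paired`,
#'   `proper`, `unmapped`, `munmapped`, `reverse`, `first_in_pair` and
#'   `sample`.
#' @export
read_sam <- function(path, sample_id = "sample1") {
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  rec <- lines[!hdr]
  if (!length(rec)) {
    return(empty_alignments(sample_id))
  }
  f <- data.table::tstrsplit(rec, "\t", fixed = TRUE, keep = 1:11)
  dt <- data.table::data.table(
    qname = f[[1]], flag = as.integer(f[[2]]), chrom = f[[3]],
    pos = as.integer(f[[4]]) - 1L, mapq = as.integer(f[[5]]),
    cigar = f[[6]], mchrom = f[[7]], mpos = as.integer(f[[8]]) - 1L,
    tlen = as.integer(f[[9]]), seq = f[[10]])
  dt[mchrom == "=", mchrom := chrom]
  dt[, `:=`(paired = bitwAnd(flag, FLAG_PAIRED) > 0L,
            proper = bitwAnd(flag, FLAG_PROPER) > 0L,
            unmapped = bitwAnd(flag, FLAG_UNMAPPED) > 0L,
            munmapped = bitwAnd(flag, FLAG_MUNMAPPED) > 0L,
            reverse = bitwAnd(flag, FLAG_REVERSE) > 0L,
            first_in_pair = bitwAnd(flag, FLAG_READ1) > 0L)]
  cig <- parse_cigars(dt$cigar[!dt$unmapped])
  if (any(cig$read_len != nchar(dt$seq[!dt$unmapped]))) {
    stop2("CIGAR/sequence length mismatch in ", path)
  }
  dt[, `:=`(left_clip = 0L, right_clip = 0L, end = pos)]
  dt[!dt$unmapped, `:=`(left_clip = cig$left_clip,
                        right_clip = cig$right_clip,
                        end = pos + cig$ref_span)]
  dt[, sample := sample_id]
  dt[]
}

empty_alignments <- function(sample_id = "sample1") {
  data.table::data.table(
    qname = character(), flag = integer(), chrom = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    mchrom = character(), mpos = integer(), tlen = integer(),
    seq = character(), paired = logical(), proper = logical(),
    unmapped = logical(), munmapped = logical(), reverse = logical(),
    first_in_pair = logical(), left_clip = integer(),
    right_clip = integer(), end = integer(), sample = character())
}

#' Write an alignment table to SAM
#'
#' @param aln alignment data.table as produced by [read_sam()] or the read
#'   simulator.
#' @param seqlens named integer vector of reference sequence lengths for the
#'   header.
#' @param path output path.
#' @export
write_sam <- function(aln, seqlens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens), con)
  if (nrow(aln)) {
    aln <- aln[order(match(chrom, names(seqlens)), pos)]
    rnext <- ifelse(aln$mchrom == aln$chrom & aln$mchrom != "*", "=", aln$mchrom)
    writeLines(paste(aln$qname, aln$flag, aln$chrom, aln$pos + 1L, aln$mapq,
                     aln$cigar, rnext, aln$mpos + 1L, aln$tlen, aln$seq,
                     "*", sep = "\t"), con)
  }
  invisible(path)
}
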