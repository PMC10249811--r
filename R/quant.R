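## mean per-base depth of M-aligned bases over [start, end)
mean_depth <- function(aln, chrom, start, end) {
  ch <- chrom
  sub <- aln[chrom == ch & !unmapped & pos < end & end > start]
  if (nrow(sub) == 0L) return(0)
  ir <- IRanges::IRanges(start = sub$pos + 1L, end = sub$end)
  cov <- IRanges::coverage(ir, width = end)
  win <- IRanges::Views(cov, start = start + 1L, end = end)
  sum(IRanges::viewSums(win)) / (end - start)
}

#' Estimate copy number from relative read depth
#'
#' Copy number of an amplified segment is the mean aligned depth over the
#' region divided by genome-wide mean depth. A warning is issued for
#' regions under 1 kb, where the ratio is noisy.
#'
#' @param aln sample alignment table.
#' @param chrom,start,end region (0-based half-open).
#' @param genome_depth genome-wide mean depth (supplied, typically from a
#'   per-chromosome depth summary, rather than re-scanning all
#'   alignments).
#' @param sample_id label for the output row.
#' @return one-row data.table: `sample_id`, `chrom`, `start`, `end`,
#'   `region_mean_depth`, `genome_mean_depth`, `copy_number`.
#' @export
estimate_copy_number <- function(aln, chrom, start, end, genome_depth,
                                 sample_id = "sample1") {
  if (genome_depth <= 0) stop2("genome_depth must be positive")
  if (end - start < 1000L) {
    warning("region under 1 kb; depth-ratio copy number will be noisy")
  }
  d <- mean_depth(aln, chrom, start, end)
  data.table::data.table(sample_id = sample_id, chrom = chrom,
                         start = start, end = end,
                         region_mean_depth = d,
                         genome_mean_depth = genome_depth,
                         copy_number = d / genome_depth)
}

#' Genome-wide mean depth of an alignment table
#'
#' @param aln alignment table.
#' @param seqlens named vector of reference lengths.
#' @param exclude optional data.frame of regions (`chrom`, `start`, `end`)
#'   excluded from the average, e.g. amplified segments.
#' @export
genome_mean_depth <- function(aln, seqlens, exclude = NULL) {
  tot_bases <- 0
  tot_len <- 0
  for (ch in names(seqlens)) {
    sub <- aln[chrom == ch & !unmapped]
    mlen <- if (nrow(sub)) nchar(sub$seq) - sub$left_clip - sub$right_clip
            else integer(0)
    bases <- sum(as.numeric(mlen))
    len <- as.numeric(seqlens[[ch]])
    if (!is.null(exclude)) {
      exc <- exclude[exclude$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(exc))) {
        bases <- bases - mean_depth(sub, ch, exc$start[i], exc$end[i]) *
          (exc$end[i] - exc$start[i])
        len <- len - (exc$end[i] - exc$start[i])
      }
    }
    tot_bases <- tot_bases + bases
    tot_len <- tot_len + len
  }
  tot_bases / tot_len
}

#' Partition RNA-seq reads between parent gene and retrocopies
#'
#' Reads aligned to the N-masked transcript are assigned by the alleles
#' they show at the diagnostic positions they cover: all parent alleles
#' gives parent, all retrocopy alleles gives retrocopy, a conflict or no
#' covered site leaves the read unassigned. Mates of a pair vote jointly;
#' a between-mate conflict also gives unassigned.
#'
#' @param aln alignment table versus the masked transcript.
#' @param sites diagnostic-site table from [build_masked_transcript()].
#' @param sample_id label for the output row.
#' @return one-row data.table: `sample_id`, `parent_reads`, `retro_reads`,
#'   `unassigned_reads`, `retro_fraction` (= retro / (retro + parent)).
#' @export
partition_reads <- function(aln, sites, sample_id = "sample1") {
  if (nrow(sites) == 0L) stop2("diagnostic-site table is empty")
  sub <- aln[unmapped == FALSE]
  n <- nrow(sub)
  vote <- rep("none", n)
  if (n) {
    mlen <- nchar(sub$seq) - sub$left_clip - sub$right_clip
    for (i in seq_len(nrow(sites))) {
      p <- sites$tx_pos[i]
      cov <- which(sub$pos <= p & sub$pos + mlen > p)
      if (!length(cov)) next
      off <- p - sub$pos[cov] + sub$left_clip[cov] + 1L
      obs <- substr(sub$seq[cov], off, off)
      lab <- data.table::fcase(
        obs == sites$parent_allele[i], "parent",
        obs == sites$retro_allele[i], "retro",
        default = "other")
      ## bases matching neither allele are sequencing errors: no vote
      inf <- lab != "other"
      cv <- cov[inf]; lb <- lab[inf]
      vote[cv] <- ifelse(vote[cv] == "none" | vote[cv] == lb, lb, "conflict")
    }
  }
  dt <- data.table::data.table(qname = sub$qname, vote = vote)
  pair <- dt[, .(v = {
    u <- unique(vote[vote != "none"])
    u <- setdiff(u, "conflict")
    if (any(vote == "conflict")) "unassigned"
    else if (length(u) == 1L) u
    else if (length(u) == 0L) "unassigned"
    else "unassigned"
  }), by = qname]
  parent <- sum(pair$v == "parent")
  retro <- sum(pair$v == "retro")
  unass <- sum(pair$v == "unassigned")
  data.table::data.table(
    sample_id = sample_id, parent_reads = parent, retro_reads = retro,
    unassigned_reads = unass,
    retro_fraction = if (parent + retro > 0) retro / (parent + retro)
                     else NA_real_)
}

#' Transcripts-per-million from counts and effective lengths
#'
#' @param counts named numeric vector of read counts per transcript.
#' @param lengths named numeric vector of effective lengths (> 0).
#' @return named numeric vector of TPM values summing to 1e6 (all zero
#'   when every count is zero).
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(all(lengths > 0), length(counts) == length(lengths))
  lengths <- lengths[names(counts)]
  rate <- counts / lengths
  s <- sum(rate)
  if (s == 0) return(setNames(rep(0, length(counts)), names(counts)))
  1e6 * rate / s
}
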