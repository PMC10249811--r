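#' Construct a gene model
#'
#' A gene model holds the exon structure of one transcript of an annotated
#' gene. Coordinates are internal convention: 0-based half-open on the
#' genome. Exons are stored in transcript orientation (5' to 3'), i.e. in
#' decreasing genomic order for minus-strand genes.
#'
#' @param gene_id gene identifier.
#' @param transcript_id transcript identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with columns `start`, `end` (0-based half-open).
#'   May be given in any order; it is sorted into transcript orientation.
#' @param cds_start,cds_end optional CDS bounds in transcript coordinates
#'   (0-based half-open on the spliced transcript).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cds_start = NA_integer_, cds_end = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (any(exons$end <= exons$start)) stop2("gene ", gene_id, ": empty exon")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop2("gene ", gene_id, ": overlapping exons")
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s%s, %d exon(s), spliced length %d\n",
              x$gene_id, x$transcript_id, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x)))
  invisible(x)
}

#' Spliced transcript length of a gene model
#' @param gm a `gene_model`.
#' @export
transcript_length <- function(gm) sum(gm$exons$end - gm$exons$start)

## exons in ascending genomic order regardless of strand
exons_genomic <- function(gm) {
  e <- gm$exons
  e[order(e$start), , drop = FALSE]
}

#' Genomic footprint of a gene model
#' @param gm a [gene_model()].
#' @return named vector `c(start, end)`, 0-based half-open.
#' @export
gene_span <- function(gm) {
  c(start = min(gm$exons$start), end = max(gm$exons$end))
}

#' Read gene models from a GFF3 file
#'
#' Parsing is delegated to [rtracklayer::import()]; this function converts
#' the 1-based closed GFF3 coordinates to the internal 0-based half-open
#' convention, groups exons under their parent mRNA, and orders exons in
#' transcript orientation. CDS features, when present, are converted to
#' transcript coordinates.
#'
#' @param path GFF3 file with gene/mRNA/exon (and optionally CDS) features.
#' @param seqlens optional named integer vector of chromosome lengths used
#'   to reject out-of-bounds exons.
#' @return list of `gene_model` objects.
#' @export
read_gff3 <- function(path, seqlens = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(ex) && any(!ex$Parent %in% mrna$ID)) {
    bad <- setdiff(unique(ex$Parent), mrna$ID)
    stop2("orphan exon(s) with Parent not matching any mRNA: ",
          paste(bad, collapse = ", "))
  }
  lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    gid <- mrna$Parent[i]
    if (is.na(gid)) gid <- tid
    e <- ex[ex$Parent == tid, , drop = FALSE]
    if (nrow(e) == 0L) stop2("transcript ", tid, " has no exons")
    chrom <- as.character(e$seqnames[1])
    if (!is.null(seqlens)) {
      if (!chrom %in% names(seqlens)) stop2("unknown chromosome ", chrom)
      if (any(e$end > seqlens[[chrom]]) || any(e$start < 1L)) {
        stop2("exon outside chromosome bounds for transcript ", tid)
      }
    }
    strand <- as.character(mrna$strand[i])
    gm <- gene_model(gid, tid, chrom, strand,
                     data.frame(start = e$start - 1L, end = e$end))
    cc <- cds[cds$Parent == tid, , drop = FALSE]
    if (nrow(cc)) {
      b <- genome_to_tx(gm, c(min(cc$start) - 1L, max(cc$end) - 1L))
      gm$cds_start <- min(b)
      gm$cds_end <- max(b) + 1L
    }
    gm
  })
}

#' Map between genomic positions and transcript offsets
#'
#' `genome_to_tx` converts 0-based genomic positions to 0-based offsets on
#' the spliced transcript (NA outside exons); `tx_to_genome` is its
#' inverse. Both respect strand.
#'
#' @param gm a [gene_model()].
#' @param gpos,tpos integer vectors of positions/offsets.
#' @return integer/numeric vector of the converted coordinates.
#' @export
genome_to_tx <- function(gm, gpos) {
  e <- gm$exons
  lens <- e$end - e$start
  offs <- cumsum(c(0L, lens))[seq_len(nrow(e))]
  out <- vapply(gpos, function(p) {
    for (i in seq_len(nrow(e))) {
      if (p >= e$start[i] && p < e$end[i]) {
        return(if (gm$strand == "+") offs[i] + (p - e$start[i])
               else offs[i] + (e$end[i] - 1L - p))
      }
    }
    NA_real_
  }, numeric(1))
  as.integer(out)
}

#' @rdname genome_to_tx
#' @export
tx_to_genome <- function(gm, tpos) {
  e <- gm$exons
  lens <- e$end - e$start
  offs <- cumsum(c(0L, lens))
  vapply(tpos, function(t) {
    i <- findInterval(t, offs, rightmost.closed = FALSE)
    if (i < 1L || i > nrow(e)) return(NA_integer_)
    w <- t - offs[i]
    if (gm$strand == "+") e$start[i] + w else e$end[i] - 1L - w
  }, numeric(1))
}

#' Write gene models to GFF3
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in models) {
    eg <- exons_genomic(gm)
    g1 <- min(eg$start) + 1L
    g2 <- max(eg$end)
    writeLines(sprintf("%s\tretroscout\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       gm$chrom, g1, g2, gm$strand, gm$gene_id), con)
    writeLines(sprintf(
      "%s\tretroscout\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      gm$chrom, g1, g2, gm$strand, gm$transcript_id, gm$gene_id), con)
    for (i in seq_len(nrow(eg))) {
      writeLines(sprintf(
        "%s\tretroscout\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        gm$chrom, eg$start[i] + 1L, eg$end[i], gm$strand,
        gm$transcript_id, i, gm$transcript_id), con)
    }
    if (!is.na(gm$cds_start)) {
      gpos <- sort(tx_to_genome(gm, c(gm$cds_start, gm$cds_end - 1L)))
      keep <- eg[eg$end > gpos[1] & eg$start <= gpos[2], , drop = FALSE]
      keep$start <- pmax(keep$start, gpos[1])
      keep$end <- pmin(keep$end, gpos[2] + 1L)
      for (i in seq_len(nrow(keep))) {
        writeLines(sprintf(
          "%s\tretroscout\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
          gm$chrom, keep$start[i] + 1L, keep$end[i], gm$strand,
          gm$transcript_id, gm$transcript_id), con)
      }
    }
  }
  invisible(path)
}
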