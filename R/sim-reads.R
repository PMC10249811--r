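## Map one read span [s, e) on the sample genome to a reference alignment
## through the chromosome segment map. Emulates what a read aligner does on
## a reference lacking the implanted sequence: the portion falling in the
## single best ("anchor") segment is aligned as M, everything else is
## soft-clipped. Returns NULL for unalignable reads (pure poly(A)).
map_span <- function(sm, s, e) {
  idx <- which(sm$start < e & sm$end > s)
  ov <- pmin(sm$end[idx], e) - pmax(sm$start[idx], s)
  ok <- sm$type[idx] != "none"
  if (!any(ok)) return(NULL)
  anchor <- idx[ok][which.max(ov[ok])]
  a_s <- max(sm$start[anchor], s)
  a_e <- min(sm$end[anchor], e)
  lclip <- a_s - s
  rclip <- e - a_e
  dir <- sm$dir[anchor]
  ref_pos <- if (dir == 1L) {
    sm$ref_start[anchor] + (a_s - sm$start[anchor])
  } else {
    sm$ref_start[anchor] + (sm$end[anchor] - a_e)
  }
  list(chrom = sm$ref_chrom[anchor], pos = ref_pos, mlen = a_e - a_s,
       lclip = lclip, rclip = rclip, dir = dir,
       gene_id = sm$gene_id[anchor], type = sm$type[anchor])
}

cigar_of <- function(lclip, mlen, rclip) {
  paste0(if (lclip > 0L) paste0(lclip, "S") else "",
         mlen, "M",
         if (rclip > 0L) paste0(rclip, "S") else "")
}

#' Simulate paired-end WGS reads from a genome build
#'
#' Fragments are sampled uniformly from the sample genome; substitution
#' errors are applied i.i.d. per base. Alongside FASTQ-style read pairs, a
#' truth-guided SAM-style alignment table against the *reference* genome is
#' produced: reads straddling an implanted insertion breakpoint are
#' soft-clipped at the breakpoint, and reads falling inside an implanted
#' retrocopy are placed on the parent gene's exons — mimicking a real
#' aligner's behavior on a reference lacking the insertion.
#'
#' @param build a `genome_build`.
#' @param config a [sim_config()]; `coverage`, `read_length`,
#'   `insert_mean`, `insert_sd` and `error_rate` are used.
#' @param sample_id sample label carried into the alignment table.
#' @param emit_sam set FALSE to skip alignment emission when only raw reads
#'   are needed (the k-mer stage).
#' @param seed optional seed overriding `config$seed` so several samples
#'   can be drawn from one build.
#' @return list with `reads` (data.table: `qname`, `seq1`, `seq2`) and
#'   `aln` (alignment data.table as from [read_sam()], or NULL).
#' @export
simulate_reads <- function(build, config, sample_id = "sample1",
                           emit_sam = TRUE, seed = NULL) {
  stopifnot(inherits(build, "genome_build"), inherits(config, "sim_config"))
  set.seed(seed %||% config$seed)
  rl <- config$read_length
  if (rl > config$insert_mean) stop2("read_length exceeds mean insert size")
  chr_len <- vapply(build$seq, nchar, integer(1))
  total <- sum(chr_len)
  n_frag <- round(config$coverage * total / (2 * rl))
  chrom <- sample(names(chr_len), n_frag, replace = TRUE,
                  prob = chr_len / total)
  flen <- pmax(rl, pmin(round(rnorm(n_frag, config$insert_mean,
                                    config$insert_sd)),
                        chr_len[chrom]))
  start <- floor(runif(n_frag) * (chr_len[chrom] - flen + 1))

  qname <- sprintf("%s_f%07d", sample_id, seq_len(n_frag))
  seq1 <- character(n_frag)
  seq2 <- character(n_frag)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    g <- build$seq[[ch]]
    seq1[i] <- substr(rep(g, length(i)), start[i] + 1L, start[i] + rl)
    seq2[i] <- revcomp(substr(rep(g, length(i)),
                              start[i] + flen[i] - rl + 1L,
                              start[i] + flen[i]))
  }
  seq1 <- apply_errors(seq1, config$error_rate)
  seq2 <- apply_errors(seq2, config$error_rate)
  reads <- data.table::data.table(qname = qname, seq1 = seq1, seq2 = seq2)

  aln <- NULL
  if (emit_sam) {
    aln <- emit_alignments(build, config, qname, chrom, start, flen,
                           seq1, seq2, sample_id)
  }
  list(reads = reads, aln = aln)
}

## map one mate's source spans (sample coordinates) to reference
## alignments, vectorized; returns a data.table of mapping columns
map_mate <- function(build, chroms, s, rl) {
  n <- length(s)
  out <- data.table::data.table(
    chrom = NA_character_, pos = NA_integer_, mlen = 0L, lclip = 0L,
    rclip = 0L, dir = 1L, mapped = FALSE, idx = seq_len(n))
  e <- s + rl
  for (ch in unique(chroms)) {
    sm <- build$segmap[[ch]]
    i <- which(chroms == ch)
    r <- findInterval(s[i], sm$start)
    single <- e[i] <= sm$end[r]
    ## fast path: read entirely within one segment row
    fi <- i[single]; fr <- r[single]
    typ <- sm$type[fr]
    dir <- sm$dir[fr]
    pos <- data.table::fifelse(
      dir == 1L, sm$ref_start[fr] + (s[fi] - sm$start[fr]),
      sm$ref_start[fr] + (sm$end[fr] - e[fi]))
    data.table::set(out, fi, c("chrom", "pos", "mlen", "dir", "mapped"),
                    list(sm$ref_chrom[fr], as.integer(pos), rl, dir,
                         typ != "none"))
    ## slow path: boundary-straddling reads
    for (k in i[!single]) {
      m <- map_span(sm, s[k], e[k])
      if (is.null(m)) next
      data.table::set(out, k,
                      c("chrom", "pos", "mlen", "lclip", "rclip", "dir",
                        "mapped"),
                      list(m$chrom, as.integer(m$pos), m$mlen, m$lclip,
                           m$rclip, m$dir, TRUE))
    }
  }
  out
}

## core of truth-guided alignment emission; spans are sample coordinates
emit_alignments <- function(build, config, qname, chrom, start, flen,
                            seq1, seq2, sample_id) {
  rl <- config$read_length
  n <- length(qname)
  m1 <- map_mate(build, chrom, start, rl)
  m2 <- map_mate(build, chrom, start + flen - rl, rl)

  mk <- function(m, mm, raw, first) {
    ## mate 1 is forward on the sample genome, mate 2 reverse; SEQ must be
    ## reference-forward, so each is flipped when the anchor maps reverse
    neg <- m$dir == -1L
    sam_seq <- if (first) {
      s <- raw
      if (any(neg)) s[neg] <- revcomp(raw[neg])
      s
    } else {
      s <- raw
      if (any(!neg)) s[!neg] <- revcomp(raw[!neg])
      s
    }
    rev_flag <- if (first) neg else !neg
    lc <- data.table::fifelse(neg, m$rclip, m$lclip)
    rc <- data.table::fifelse(neg, m$lclip, m$rclip)
    cigar <- data.table::fifelse(
      m$mapped,
      paste0(data.table::fifelse(lc > 0L, paste0(lc, "S"), ""),
             m$mlen, "M",
             data.table::fifelse(rc > 0L, paste0(rc, "S"), "")),
      "*")
    max_frag <- config$insert_mean + 4 * config$insert_sd
    ## FR orientation: mate SAM strands are opposite exactly when the two
    ## anchor segments map in the same direction
    proper <- m$mapped & mm$mapped & m$chrom == mm$chrom &
      abs(mm$pos - m$pos) <= max_frag & m$dir == mm$dir
    proper[is.na(proper)] <- FALSE
    dt <- data.table::data.table(
      qname = qname, chrom = m$chrom, pos = m$pos, mapq = 60L,
      cigar = cigar, mchrom = mm$chrom, mpos = mm$pos, seq = sam_seq,
      paired = TRUE, proper = proper, unmapped = !m$mapped,
      munmapped = !mm$mapped, reverse = rev_flag & m$mapped,
      first_in_pair = first, left_clip = lc, right_clip = rc,
      end = m$pos + m$mlen)
    dt[unmapped == TRUE & munmapped == FALSE,
       `:=`(chrom = mchrom, pos = mpos, end = mpos, cigar = "*",
            left_clip = 0L, right_clip = 0L)]
    dt[munmapped == TRUE & unmapped == FALSE, `:=`(mchrom = chrom, mpos = pos)]
    dt[unmapped == TRUE & munmapped == TRUE,
       `:=`(chrom = "*", pos = -1L, mchrom = "*", mpos = -1L, end = -1L)]
    dt[, tlen := data.table::fifelse(proper, mpos - pos, 0L)]
    dt[, flag := FLAG_PAIRED +
         data.table::fifelse(proper, FLAG_PROPER, 0L) +
         data.table::fifelse(unmapped, FLAG_UNMAPPED, 0L) +
         data.table::fifelse(munmapped, FLAG_MUNMAPPED, 0L) +
         data.table::fifelse(reverse, FLAG_REVERSE, 0L) +
         data.table::fifelse(!munmapped &
                               (if (first) mm$dir == 1L else mm$dir == -1L),
                             FLAG_MREVERSE, 0L) +
         (if (first) FLAG_READ1 else FLAG_READ2)]
    dt
  }
  ## mate-2 raw reads are reverse-complements of the sample-forward span;
  ## sam_seq logic above therefore flips the complementary subset
  out <- data.table::rbindlist(list(mk(m1, m2, seq1, TRUE),
                                    mk(m2, m1, seq2, FALSE)))
  cols <- c("qname", "flag", "chrom", "pos", "mapq", "cigar", "mchrom",
            "mpos", "tlen", "seq", "paired", "proper", "unmapped",
            "munmapped", "reverse", "first_in_pair", "left_clip",
            "right_clip", "end")
  out <- out[, cols, with = FALSE]
  out[, sample := sample_id]
  out[order(chrom, pos)]
}

## single-row fast mapping (read fully inside segment row r)
row_map <- function(sm, r, s, rl) {
  type <- sm$type[r]
  if (type == "none") return(NULL)
  dir <- sm$dir[r]
  pos <- if (dir == 1L) sm$ref_start[r] + (s - sm$start[r])
         else sm$ref_start[r] + (sm$end[r] - (s + rl))
  list(chrom = sm$ref_chrom[r], pos = pos, mlen = rl, lclip = 0L,
       rclip = 0L, dir = dir, gene_id = sm$gene_id[r], type = type)
}

#' Simulate RNA-seq read pairs from a transcript pool
#'
#' Draws fragments from a pool of transcript variants (e.g. the parent
#' mRNA and the retrocopy-derived mRNA) at stated proportions and reports
#' truth-guided alignments against a designated target sequence (typically
#' the N-masked transcript), which must be coordinate-compatible with every
#' pool member (equal length; SNV differences only).
#'
#' @param pool named character vector of transcript sequences.
#' @param proportions named numeric vector over the pool, summing to 1.
#' @param n_pairs number of read pairs.
#' @param config a [sim_config()] (read length, insert size, error rate).
#' @param target target sequence name for the alignment records.
#' @param seed optional override of `config$seed`.
#' @return list with `reads`, `aln` (alignments to `target`) and `labels`
#'   (data.table `qname`, `source`).
#' @export
simulate_rnaseq <- function(pool, proportions, n_pairs, config,
                            target = "masked_tx", seed = NULL) {
  if (!length(pool)) stop2("empty transcript pool")
  if (abs(sum(proportions) - 1) > 1e-6) stop2("proportions must sum to 1")
  stopifnot(all(names(proportions) %in% names(pool)))
  set.seed(seed %||% config$seed)
  rl <- config$read_length
  src <- sample(names(proportions), n_pairs, replace = TRUE,
                prob = proportions)
  tlen <- nchar(pool[src])
  flen <- pmax(rl, pmin(round(rnorm(n_pairs, config$insert_mean,
                                    config$insert_sd)), tlen))
  start <- floor(runif(n_pairs) * (tlen - flen + 1))
  seq1 <- substr(pool[src], start + 1L, start + rl)
  seq2 <- revcomp(substr(pool[src], start + flen - rl + 1L, start + flen))
  seq1 <- apply_errors(seq1, config$error_rate)
  seq2 <- apply_errors(seq2, config$error_rate)
  qname <- sprintf("rna_f%07d", seq_len(n_pairs))
  reads <- data.table::data.table(qname = qname, seq1 = seq1, seq2 = seq2)
  labels <- data.table::data.table(qname = qname, source = src)

  mk <- function(mate) {
    first <- mate == 1L
    p <- if (first) start else start + flen - rl
    sq <- if (first) seq1 else revcomp(seq2)
    data.table::data.table(
      qname = qname,
      flag = FLAG_PAIRED + FLAG_PROPER +
        (if (first) 0L else FLAG_REVERSE) +
        (if (first) FLAG_MREVERSE else 0L) +
        (if (first) FLAG_READ1 else FLAG_READ2),
      chrom = target, pos = as.integer(p), mapq = 60L,
      cigar = paste0(rl, "M"), mchrom = target,
      mpos = as.integer(if (first) start + flen - rl else start),
      tlen = if (first) as.integer(flen) else -as.integer(flen),
      seq = sq, paired = TRUE, proper = TRUE, unmapped = FALSE,
      munmapped = FALSE, reverse = !first, first_in_pair = first,
      left_clip = 0L, right_clip = 0L, end = as.integer(p) + rl,
      sample = "rna")
  }
  aln <- data.table::rbindlist(list(mk(1L), mk(2L)))[order(pos)]
  list(reads = reads, aln = aln, labels = labels)
}
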