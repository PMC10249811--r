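#' Find discordant read pairs anchored at a parent gene
#'
#' Returns alignment records that overlap an exon of the parent gene while
#' their mate maps to another chromosome or farther than `d_max` away.
#' Properly paired reads are excluded, as are records whose only gene
#' overlap is intronic: retrocopies are intron-less, so intron-only mates
#' carry no retrocopy signal.
#'
#' @param aln alignment data.table (see [read_sam()]).
#' @param gm parent [gene_model()].
#' @param d_max discordance distance in bp (default 10 kb).
#' @return subset of `aln` with an added `mate_end` column.
#' @export
find_discordant_pairs <- function(aln, gm, d_max = 10000L) {
  eg <- exons_genomic(gm)
  cand <- aln[!unmapped & !munmapped & !proper & chrom == gm$chrom]
  if (nrow(cand) == 0L) return(cand[, mate_end := integer(0)][])
  ov <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(eg))) {
    ov <- ov | (cand$pos < eg$end[i] & cand$end > eg$start[i])
  }
  cand <- cand[ov]
  disc <- cand$mchrom != cand$chrom | abs(cand$mpos - cand$pos) > d_max
  cand <- cand[disc]
  rl <- nchar(cand$seq)
  cand[, mate_end := mpos + rl]
  cand[]
}

#' Cluster discordant mate positions
#'
#' Single-linkage clustering of mate positions per chromosome: consecutive
#' sorted positions at a gap of at most `cluster_window` join one cluster.
#' Clusters supported by fewer than `min_support` reads are dropped.
#'
#' @param candidates output of [find_discordant_pairs()].
#' @param gene_id parent gene id recorded on the clusters.
#' @param cluster_window maximum within-cluster gap in bp (default 500).
#' @param min_support minimum supporting reads (default 4).
#' @return data.table: `gene_id`, `chrom`, `start`, `end`, `support`,
#'   `samples` (comma-joined per-sample counts), plus a list column
#'   `qnames`.
#' @export
cluster_mates <- function(candidates, gene_id, cluster_window = 500L,
                          min_support = 4L) {
  empty <- data.table::data.table(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), support = integer(), samples = character(),
    qnames = list())
  if (nrow(candidates) == 0L) return(empty)
  out <- list()
  for (ch in unique(candidates$mchrom)) {
    cc <- candidates[mchrom == ch][order(mpos)]
    gap <- c(0L, diff(cc$mpos))
    cid <- cumsum(gap > cluster_window)
    for (g in unique(cid)) {
      rows <- cc[cid == g]
      if (nrow(rows) < min_support) next
      per_sample <- rows[, .N, by = sample]
      out[[length(out) + 1L]] <- data.table::data.table(
        gene_id = gene_id, chrom = ch, start = min(rows$mpos),
        end = max(rows$mate_end), support = nrow(rows),
        samples = paste(sprintf("%s:%d", per_sample$sample, per_sample$N),
                        collapse = ","),
        qnames = list(rows$qname))
    }
  }
  if (!length(out)) return(empty)
  data.table::rbindlist(out)
}

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  best <- as.integer(names(tab)[tab == tab[1L]])
  min(best)  # ties broken toward the leftmost coordinate
}

consensus_string <- function(seqs, lens = nchar(seqs)) {
  if (!length(seqs)) return("")
  w <- max(lens)
  cols <- vapply(seq_len(w), function(j) {
    ch <- substr(seqs, j, j)
    ch <- ch[nzchar(ch)]
    if (!length(ch)) return("")
    tab <- sort(table(ch), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
  paste(cols, collapse = "")
}

#' Resolve an insertion breakpoint and TSD from soft-clipped reads
#'
#' The left breakpoint is the modal right edge of alignments clipped on
#' the right (reads anchored in the left flank running into the inserted
#' sequence); the right breakpoint is the modal left edge of alignments
#' clipped on the left. When the left breakpoint lies beyond the right one,
#' the intervening reference bases were duplicated on both sides of the
#' insertion: the target-site duplication. Junction sequences are built
#' from flank consensus plus clipped-base consensus. Ties in breakpoint
#' support are broken toward higher clip support, then the leftmost
#' coordinate.
#'
#' @param cluster one row of [cluster_mates()] output.
#' @param aln alignment table covering the cluster region.
#' @param genome named character vector (reference sequences).
#' @param min_clip minimum soft-clip length for a read to vote (default 5).
#' @param flank junction flank length reported on each side (default 20).
#' @return a one-row data.table (an insertion call): `gene_id`, `chrom`,
#'   `start`, `end` (the duplicated target site, or the cluster interval
#'   when no clipped support exists), `tsd_seq`, `tsd_length`,
#'   `five_prime_junction`, `three_prime_junction`, `clip_support`,
#'   `discordant_support`, `samples`, `resolved`.
#' @export
resolve_breakpoints <- function(cluster, aln, genome, min_clip = 5L,
                                flank = 20L) {
  ch <- cluster$chrom
  pad <- 300L
  near <- aln[chrom == ch & !unmapped &
                pos < cluster$end + pad & end > cluster$start - pad]
  rclip <- near[right_clip >= min_clip]
  lclip <- near[left_clip >= min_clip]
  lowres <- function() data.table::data.table(
    gene_id = cluster$gene_id, chrom = ch, start = cluster$start,
    end = cluster$end, tsd_seq = NA_character_, tsd_length = NA_integer_,
    five_prime_junction = NA_character_, three_prime_junction = NA_character_,
    clip_support = 0L, discordant_support = cluster$support,
    samples = cluster$samples, resolved = FALSE)
  if (nrow(rclip) == 0L || nrow(lclip) == 0L) return(lowres())
  ## joint breakpoint choice: the left breakpoint (right edge of
  ## left-anchored clipped reads) and the right breakpoint (left edge of
  ## right-anchored ones) must bracket a plausible duplicated target site
  ## (TSD up to 50 bp, or a blunt/short-deletion junction). Among
  ## admissible pairs, the highest combined clip support wins; ties go to
  ## the leftmost coordinate.
  rc_tab <- table(rclip$end)
  lc_tab <- table(lclip$pos)
  le_cand <- as.integer(names(rc_tab))
  rs_cand <- as.integer(names(lc_tab))
  pairs <- expand.grid(le = le_cand, rs = rs_cand)
  pairs$score <- as.integer(rc_tab[as.character(pairs$le)]) +
    as.integer(lc_tab[as.character(pairs$rs)])
  ok <- pairs$le - pairs$rs >= -10L & pairs$le - pairs$rs <= 50L
  if (any(ok)) {
    pairs <- pairs[ok, , drop = FALSE]
    pairs <- pairs[order(-pairs$score, pairs$le, pairs$rs), , drop = FALSE]
    left_bp <- pairs$le[1L]
    right_bp <- pairs$rs[1L]
  } else {
    left_bp <- modal_value(rclip$end)
    right_bp <- modal_value(lclip$pos)
  }
  g <- genome[[ch]]

  l_sup <- rclip[end == left_bp]
  r_sup <- lclip[pos == right_bp]
  ## clipped bases on each side of the junction
  l_clipped <- substring(l_sup$seq, nchar(l_sup$seq) - l_sup$right_clip + 1L)
  r_clipped <- substring(r_sup$seq, 1L, r_sup$left_clip)
  l_cons <- consensus_string(substr(l_clipped, 1L, flank))
  ## right-side clipped bases end at the junction: align on their right edge
  r_trim <- substring(r_clipped, pmax(1L, nchar(r_clipped) - flank + 1L))
  r_cons <- consensus_string(
    vapply(r_trim, function(s) {
      paste0(strrep(" ", flank - nchar(s)), s)
    }, character(1), USE.NAMES = FALSE))
  r_cons <- gsub(" ", "", r_cons, fixed = TRUE)

  tsd_len <- left_bp - right_bp
  tsd <- if (tsd_len > 0L) subseq0(g, right_bp, left_bp) else NA_character_
  data.table::data.table(
    gene_id = cluster$gene_id, chrom = ch,
    start = min(left_bp, right_bp), end = max(left_bp, right_bp),
    tsd_seq = tsd, tsd_length = max(tsd_len, 0L),
    five_prime_junction = paste0(subseq0(g, left_bp - flank, left_bp), "|",
                                 l_cons),
    three_prime_junction = paste0(r_cons, "|",
                                  subseq0(g, right_bp, right_bp + flank)),
    clip_support = nrow(l_sup) + nrow(r_sup),
    discordant_support = cluster$support,
    samples = cluster$samples, resolved = TRUE)
}

#' Resolve all insertion calls for a set of parent genes
#'
#' Convenience driver: discordant-pair discovery, mate clustering and
#' breakpoint resolution across samples.
#'
#' @param aln_by_sample list of alignment tables (one per sample; the
#'   `sample` column distinguishes them after concatenation).
#' @param models list of parent [gene_model()]s to interrogate.
#' @param genome reference sequences.
#' @param d_max,cluster_window,min_support,min_clip tuning knobs, see the
#'   stage functions.
#' @return data.table of insertion calls (possibly zero rows).
#' @export
resolve_insertions <- function(aln_by_sample, models, genome,
                               d_max = 10000L, cluster_window = 500L,
                               min_support = 4L, min_clip = 5L) {
  aln <- data.table::rbindlist(aln_by_sample)
  calls <- list()
  for (gm in models) {
    cand <- find_discordant_pairs(aln, gm, d_max = d_max)
    cl <- cluster_mates(cand, gm$gene_id, cluster_window = cluster_window,
                        min_support = min_support)
    for (i in seq_len(nrow(cl))) {
      calls[[length(calls) + 1L]] <-
        resolve_breakpoints(cl[i], aln, genome, min_clip = min_clip)
    }
  }
  if (!length(calls)) {
    return(data.table::data.table(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), tsd_seq = character(), tsd_length = integer(),
      five_prime_junction = character(), three_prime_junction = character(),
      clip_support = integer(), discordant_support = integer(),
      samples = character(), resolved = logical()))
  }
  data.table::rbindlist(calls)
}

#' Count reads spanning exon-exon junctions
#'
#' For parent genes whose insertion site cannot be resolved, reads that
#' contain an exon-exon junction sequence contiguously are direct evidence
#' that an intron-less copy exists somewhere in the sample. Junction
#' windows are the last `j` bases of each exon joined to the first `j`
#' bases of the next, searched on both strands.
#'
#' @param genome reference sequences.
#' @param gm parent [gene_model()].
#' @param reads character vector of read sequences.
#' @param j flank length on each side of the junction (default 20).
#' @return integer: number of reads containing any junction window.
#' @export
detect_junction_reads <- function(genome, gm, reads, j = 20L) {
  if (!length(reads)) return(0L)
  rl <- min(nchar(reads))
  if (2L * j > rl) stop2("junction window (", 2L * j, ") longer than reads")
  tx <- extract_spliced_transcript(genome, gm)
  lens <- gm$exons$end - gm$exons$start
  offs <- cumsum(lens)
  if (length(lens) < 2L) return(0L)
  wins <- vapply(head(offs, -1L), function(o) {
    substr(tx, o - j + 1L, o + j)
  }, character(1))
  wins <- wins[nchar(wins) == 2L * j]
  if (!length(wins)) return(0L)
  wins <- unique(c(wins, revcomp(wins)))
  pd <- Biostrings::PDict(wins)
  hits <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(reads),
                                  collapse = 2L)
  sum(hits > 0L)
}

#' Test a reference retrocopy for deletion evidence
#'
#' Classifies an annotated reference retrocopy as present, heterozygously
#' absent, or homozygously absent in a sample, from the depth over the
#' interval relative to genome-wide depth and from read pairs straddling
#' the interval at a spacing consistent with its deletion.
#'
#' @param aln sample alignment table.
#' @param chrom,start,end the reference retrocopy interval (0-based
#'   half-open).
#' @param genome_depth genome-wide mean depth of the sample.
#' @param insert_mean,insert_sd fragment-size model used to judge
#'   straddling pairs.
#' @return list: `state` in `c("present","het_absent","hom_absent")`,
#'   `depth_ratio`, `straddling_pairs`.
#' @export
reference_retrocopy_absence <- function(aln, chrom, start, end,
                                        genome_depth,
                                        insert_mean = 300, insert_sd = 30) {
  if (genome_depth <= 0) stop2("genome_depth must be positive")
  ch <- chrom; s0 <- start; e0 <- end
  depth <- mean_depth(aln, ch, s0, e0)
  ratio <- depth / genome_depth
  ## pairs whose mates flank the interval with an apparent insert that only
  ## makes sense if the interval is absent from the sampled molecule
  fl <- aln[chrom == ch & !unmapped & !munmapped & mchrom == ch &
              end <= s0 & mpos >= e0]
  span <- fl$mpos - fl$end
  ilen <- e0 - s0
  straddle <- sum(span >= ilen - 4 * insert_sd &
                    span <= ilen + insert_mean + 4 * insert_sd)
  state <- if (ratio < 0.15) {
    "hom_absent"
  } else if (ratio <= 0.75 && straddle > 0L) {
    "het_absent"
  } else {
    "present"
  }
  list(state = state, depth_ratio = ratio, straddling_pairs = straddle)
}

#' Flag parent genes with male-only evidence
#'
#' Discordant or k-mer evidence present in several males and no females
#' suggests a Y-linked insertion site (unresolvable against a reference
#' lacking a Y assembly).
#'
#' @param evidence data.table with columns `gene_id`, `sample_id`,
#'   `has_evidence` (logical).
#' @param sexes data.table with `sample_id`, `sex` ("M"/"F").
#' @param m_min minimum number of males with evidence (default 2).
#' @return data.table `gene_id`, `males_with`, `females_with`, `flagged`.
#' @export
flag_sex_bias <- function(evidence, sexes, m_min = 2L) {
  ev <- data.table::as.data.table(evidence)
  sx <- data.table::as.data.table(sexes)
  unknown <- setdiff(ev$sample_id, sx$sample_id)
  if (length(unknown)) {
    warning("sample(s) without sex annotation excluded: ",
            paste(unknown, collapse = ", "))
    ev <- ev[!sample_id %in% unknown]
  }
  ev <- merge(ev, sx, by = "sample_id")
  if (length(unique(ev$sex)) < 2L) {
    warning("need at least one male and one female; nothing evaluable")
    return(data.table::data.table(gene_id = unique(ev$gene_id),
                                  males_with = NA_integer_,
                                  females_with = NA_integer_,
                                  flagged = FALSE))
  }
  out <- ev[, .(males_with = sum(has_evidence & sex == "M"),
                females_with = sum(has_evidence & sex == "F")),
            by = gene_id]
  out[, flagged := males_with >= m_min & females_with == 0L]
  out[]
}
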