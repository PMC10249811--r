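#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generator. The
#' defaults emulate the study conditions of a typical equid retroCNV
#' screen: ~20x paired-end Illumina-style coverage, 100 bp reads, 300 bp
#' fragments, and a low substitution error rate.
#'
#' @param seed integer seed; every stochastic output is a deterministic
#'   function of the config including this seed.
#' @param genome_length total reference length in bp.
#' @param n_genes number of multi-exon genes to place.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param gc_content GC fraction of the random background sequence.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment (insert) size mean and sd in bp.
#' @param coverage fold coverage of the sample genome.
#' @param error_rate per-base substitution error probability (< 0.05).
#' @param exon_size,intron_size ranges for exon and intron lengths in bp;
#'   introns are at least 200 bp so spliced transcripts are genuinely
#'   discontiguous on the genome.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 1e6L, n_genes = 10L,
                       exons_per_gene = c(4L, 6L), gc_content = 0.42,
                       read_length = 100L, insert_mean = 300L,
                       insert_sd = 30L, coverage = 20,
                       error_rate = 0.002,
                       exon_size = c(150L, 300L),
                       intron_size = c(200L, 500L)) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              gc_content = gc_content, read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              coverage = coverage, error_rate = error_rate,
              exon_size = as.integer(exon_size),
              intron_size = as.integer(intron_size))
  with(cfg, {
    stopifnot(genome_length > 0, n_genes >= 0, coverage > 0,
              read_length > 0, insert_mean >= read_length,
              all(exons_per_gene >= 2), gc_content > 0, gc_content < 1)
    if (error_rate < 0 || error_rate >= 0.05) {
      stop2("error_rate must be in [0, 0.05)")
    }
    if (any(intron_size < 200L)) stop2("introns must be at least 200 bp")
  })
  structure(cfg, class = "sim_config")
}

## A genome build pairs the reference (what reads are reported against)
## with the sample genome (what reads are drawn from) and a per-chromosome
## segment map from sample coordinates to reference coordinates.
##
## segmap columns (all 0-based half-open in sample coordinates):
##   start,end  - segment bounds on the sample genome
##   type       - "ref" (collinear with reference), "retro" (maps to parent
##                gene exons), "none" (poly(A) tail; unalignable)
##   ref_chrom, ref_start, dir - mapping; for dir == 1 sample x maps to
##                ref_start + (x - start); for dir == -1 to
##                ref_start + (end - 1 - x)
##   gene_id, event, copy      - provenance of retro segments
##   tx_start, tx_dir          - retro-transcript offset of the segment's
##                first base and its direction along the transcript
new_build <- function(ref) {
  segmap <- lapply(names(ref), function(ch) {
    data.table::data.table(start = 0L, end = nchar(ref[[ch]]), type = "ref",
                           ref_chrom = ch, ref_start = 0L, dir = 1L,
                           gene_id = NA_character_, event = NA_integer_,
                           copy = NA_integer_, tx_start = NA_integer_,
                           tx_dir = NA_integer_)
  })
  names(segmap) <- names(ref)
  structure(list(ref = ref, seq = ref, segmap = segmap,
                 truth = list(events = NULL, variants = NULL,
                              retro_tx = list())),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  ev <- if (is.null(x$truth$events)) 0L else nrow(x$truth$events)
  cat(sprintf("<genome_build> %d chromosome(s), ref %d bp, sample %d bp, %d implanted event(s)\n",
              length(x$ref), sum(nchar(x$ref)), sum(nchar(x$seq)), ev))
  invisible(x)
}

seg_template <- function(n) {
  data.table::data.table(start = integer(n), end = integer(n),
                         type = character(n), ref_chrom = NA_character_,
                         ref_start = NA_integer_, dir = NA_integer_,
                         gene_id = NA_character_, event = NA_integer_,
                         copy = NA_integer_, tx_start = NA_integer_,
                         tx_dir = NA_integer_)
}

#' Generate a toy annotated genome
#'
#' Places `n_genes` non-overlapping multi-exon genes on a single random
#' chromosome. Each gene gets a random strand, exon count drawn from
#' `exons_per_gene`, exon and intron sizes from the configured ranges, and
#' a CDS covering most of the spliced transcript. Deterministic for a fixed
#' config (the config seed is set internally).
#'
#' @param config a [sim_config()].
#' @return list with elements `build` (a `genome_build`), `models` (list of
#'   [gene_model()]) and `seqlens`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  seq <- random_dna(L, config$gc_content)
  ref <- c(chr1 = seq)
  n <- config$n_genes
  models <- list()
  if (n > 0L) {
    slot <- L %/% n
    ## draw from an inclusive integer range; safe for degenerate ranges
    ## (sample(4, 1) would draw from 1:4)
    rint <- function(lo, hi, n) lo + sample.int(hi - lo + 1L, n,
                                                replace = TRUE) - 1L
    models <- lapply(seq_len(n), function(i) {
      n_ex <- rint(config$exons_per_gene[1], config$exons_per_gene[2], 1L)
      ex_len <- rint(config$exon_size[1], config$exon_size[2], n_ex)
      in_len <- rint(config$intron_size[1], config$intron_size[2], n_ex - 1L)
      glen <- sum(ex_len) + sum(in_len)
      lo <- (i - 1L) * slot
      margin <- slot - glen - 100L
      if (margin <= 0L) {
        stop2("genome too small to place ", n, " genes of this size")
      }
      gstart <- lo + 50L + sample.int(margin, 1L)
      starts <- gstart + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ex <- data.frame(start = starts, end = starts + ex_len)
      strand <- sample(c("+", "-"), 1L)
      tx_len <- sum(ex_len)
      cds_start <- 9L
      cds_len <- ((tx_len - 30L) %/% 3L) * 3L
      gene_model(sprintf("gene%02d", i), sprintf("tx%02d", i), "chr1",
                 strand, ex, cds_start, cds_start + cds_len)
    })
  }
  list(build = new_build(ref), models = models,
       seqlens = c(chr1 = L))
}

## transcript blocks (len, ref_start, dir) of a gene model after optional
## exon skipping and 5' truncation, in transcript orientation
tx_blocks <- function(gm, skipped_exons = integer(), truncation = 0L) {
  e <- gm$exons
  keep <- setdiff(seq_len(nrow(e)), skipped_exons)
  if (!length(keep)) stop2("all exons skipped")
  blocks <- data.table::data.table(
    len = e$end[keep] - e$start[keep],
    ref_start = e$start[keep],
    dir = if (gm$strand == "+") 1L else -1L)
  if (truncation > 0L) {
    if (truncation >= sum(blocks$len)) {
      stop2("5' truncation (", truncation, ") >= transcript length")
    }
    while (truncation > 0L) {
      if (blocks$len[1L] <= truncation) {
        truncation <- truncation - blocks$len[1L]
        blocks <- blocks[-1L]
      } else {
        if (blocks$dir[1L] == 1L) {
          blocks[1L, ref_start := ref_start + truncation]
        }
        blocks[1L, len := len - truncation]
        truncation <- 0L
      }
    }
  }
  blocks
}

## sequence of transcript blocks from the reference
blocks_seq <- function(ref_seq, blocks) {
  parts <- vapply(seq_len(nrow(blocks)), function(i) {
    s <- subseq0(ref_seq, blocks$ref_start[i], blocks$ref_start[i] + blocks$len[i])
    if (blocks$dir[i] == -1L) revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

apply_tx_snvs <- function(seq, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(seq)
  for (i in seq_len(nrow(variants))) {
    p <- variants$tx_offset[i] + 1L
    if (p < 1L || p > nchar(seq)) stop2("variant offset out of transcript")
    have <- substr(seq, p, p)
    if (!is.na(variants$ref[i]) && nzchar(variants$ref[i]) &&
        have != variants$ref[i]) {
      stop2("variant ref mismatch at transcript offset ", variants$tx_offset[i],
            ": expected ", variants$ref[i], ", found ", have)
    }
    substr(seq, p, p) <- variants$alt[i]
  }
  seq
}

#' Implant a retrocopy into a genome build
#'
#' Splices the parent transcript (optionally skipping internal exons and
#' truncating the 5' end, as LINE-1-mediated insertions commonly are),
#' appends a poly(A) tail, and inserts the result at `site_pos` flanked by
#' a duplicated target site (TSD) of `tsd_length` bases taken from the
#' sequence immediately 5' of the insertion point. The segment map and
#' ground-truth tables are updated so reads drawn over the new allele can
#' be traced back to reference coordinates.
#'
#' @param build a `genome_build`.
#' @param gm parent [gene_model()].
#' @param site_chrom,site_pos insertion point (0-based, sample-genome
#'   coordinates; must fall in reference-collinear sequence outside the
#'   parent gene).
#' @param tsd_length TSD length; the observed range for LINE-1-mediated
#'   insertions is 10-31 bp and values outside it are rejected unless
#'   `allow_any_tsd`.
#' @param skipped_exons integer indices (1-based, transcript order) of
#'   internal exons absent from the retrocopy.
#' @param five_prime_truncation bases removed from the transcript 5' end.
#' @param polyA_length poly(A) tail length (default 30).
#' @param strand insertion orientation relative to the reference.
#' @param shared_variants optional data.frame (`tx_offset`, `ref`, `alt`)
#'   of substitutions carried by the retrocopy relative to the parent
#'   transcript.
#' @param allow_any_tsd lift the 10-31 bp TSD range check.
#' @return the modified `genome_build`; the new event id is
#'   `nrow(build$truth$events)`.
#' @export
insert_retrocopy <- function(build, gm, site_chrom, site_pos,
                             tsd_length = 17L, skipped_exons = integer(),
                             five_prime_truncation = 0L, polyA_length = 30L,
                             strand = "+", shared_variants = NULL,
                             allow_any_tsd = FALSE) {
  stopifnot(inherits(build, "genome_build"))
  if (!allow_any_tsd && (tsd_length < 10L || tsd_length > 31L)) {
    stop2("tsd_length ", tsd_length, " outside the observed 10-31 bp range ",
          "(use allow_any_tsd = TRUE to override)")
  }
  n_ex <- nrow(gm$exons)
  if (any(skipped_exons %in% c(1L, n_ex))) {
    stop2("cannot skip the first or last exon")
  }
  sm <- build$segmap[[site_chrom]]
  row <- which(sm$start <= site_pos & sm$end > site_pos)
  if (length(row) != 1L || sm$type[row] != "ref") {
    stop2("insertion site must fall in reference-collinear sequence")
  }
  if (site_pos - tsd_length < sm$start[row]) {
    stop2("not enough 5' flank for the TSD")
  }
  ref_ins <- sm$ref_start[row] + (site_pos - sm$start[row])
  if (sm$ref_chrom[row] == gm$chrom) {
    sp <- gene_span(gm)
    if (ref_ins >= sp["start"] && ref_ins < sp["end"]) {
      stop2("insertion site inside the parent gene")
    }
  }

  blocks <- tx_blocks(gm, skipped_exons, five_prime_truncation)
  tx_seq <- blocks_seq(build$ref[[gm$chrom]], blocks)
  tx_seq <- apply_tx_snvs(tx_seq, shared_variants)
  retro_len <- nchar(tx_seq)
  mrna <- paste0(tx_seq, strrep("A", polyA_length))

  ## local segment rows of the inserted sequence, in insertion orientation
  blk <- seg_template(nrow(blocks) + (polyA_length > 0L))
  off <- cumsum(c(0L, blocks$len))
  for (i in seq_len(nrow(blocks))) {
    data.table::set(blk, i, names(blk),
      list(off[i], off[i] + blocks$len[i], "retro", gm$chrom,
           blocks$ref_start[i], blocks$dir[i], gm$gene_id, NA_integer_,
           1L, off[i], 1L))
  }
  if (polyA_length > 0L) {
    i <- nrow(blk)
    data.table::set(blk, i, c("start", "end", "type"),
                    list(retro_len, retro_len + polyA_length, "none"))
  }
  ins_seq <- mrna
  if (strand == "-") {
    ins_seq <- revcomp(mrna)
    total <- nchar(mrna)
    blk <- blk[rev(seq_len(nrow(blk)))]
    ns <- total - blk$end
    blk[, `:=`(start = ns, end = ns + (end - start))]
    blk[type == "retro", `:=`(dir = -dir, tx_dir = -1L,
                              tx_start = tx_start + (end - start) - 1L)]
  }

  ev_id <- if (is.null(build$truth$events)) 1L else nrow(build$truth$events) + 1L
  data.table::set(blk, which(blk$type == "retro"), "event", ev_id)
  ins_len <- nchar(ins_seq)
  tsd_seq <- subseq0(build$seq[[site_chrom]], site_pos - tsd_length, site_pos)

  ## rebuild sequence and segment map
  old <- build$seq[[site_chrom]]
  build$seq[[site_chrom]] <- paste0(
    subseq0(old, 0L, site_pos), ins_seq, tsd_seq,
    subseq0(old, site_pos, nchar(old)))

  left <- if (row > 1L) sm[1:(row - 1L)] else sm[0L]
  mid_l <- data.table::copy(sm[row])[, end := site_pos]
  blk[, `:=`(start = start + site_pos, end = end + site_pos)]
  mid_r <- data.table::copy(sm[row])
  mid_r[, `:=`(start = site_pos + ins_len,
               end = end + ins_len + tsd_length,
               ref_start = ref_ins - tsd_length)]
  right <- if (row < nrow(sm)) sm[(row + 1L):nrow(sm)] else sm[0L]
  right[, `:=`(start = start + ins_len + tsd_length,
               end = end + ins_len + tsd_length)]
  build$segmap[[site_chrom]] <- data.table::rbindlist(
    list(left, mid_l, blk, mid_r, right))

  ev <- data.table::data.table(
    event = ev_id, gene_id = gm$gene_id, site_chrom = site_chrom,
    insertion_point = ref_ins, tsd_start = ref_ins - tsd_length,
    tsd_length = tsd_length, tsd_seq = tsd_seq, strand = strand,
    skipped = paste(skipped_exons, collapse = ","),
    truncation = five_prime_truncation, polyA_length = polyA_length,
    retro_len = retro_len, copy_count = 1L)
  build$truth$events <- data.table::rbindlist(list(build$truth$events, ev))
  if (!is.null(shared_variants) && nrow(shared_variants)) {
    sv <- data.table::as.data.table(shared_variants)
    sv[, `:=`(event = rep(ev_id, .N), copy = 0L)]
    build$truth$variants <- data.table::rbindlist(
      list(build$truth$variants, sv[, .(event, copy, tx_offset, ref, alt)]))
  }
  build$truth$retro_tx[[as.character(ev_id)]] <- tx_seq
  build
}

## write an SNV given in transcript coordinates into a local sample-genome
## string using the retro segment rows covering it
write_tx_snv <- function(local_seq, rows, local_offset, tx_offset, alt) {
  for (i in seq_len(nrow(rows))) {
    r <- rows[i]
    if (r$type != "retro") next
    o <- r$tx_start + r$tx_dir * (seq(r$start, r$end - 1L) - r$start)
    hit <- which(o == tx_offset)
    if (length(hit)) {
      p <- r$start + hit[1L] - 1L - local_offset + 1L
      base <- if (r$tx_dir == 1L) alt else revcomp(alt)
      substr(local_seq, p, p) <- base
      return(local_seq)
    }
  }
  stop2("transcript offset ", tx_offset, " not covered by retro segments")
}

#' Amplify a genomic segment into tandem copies
#'
#' Models a segmental duplication carrying a retrocopy: the interval
#' `[a, b)` (sample coordinates), which must contain exactly one implanted
#' retrocopy, is replaced by `copy_count` tandem copies. `shared_variants`
#' (transcript-offset SNVs) are written into every copy — these predate the
#' duplication — while private variants are drawn independently per copy at
#' `private_variant_rate` per transcript base, emulating post-duplication
#' divergence. All copies map back to the single original reference locus,
#' as a read aligner would place them.
#'
#' @param build a `genome_build`.
#' @param chrom chromosome.
#' @param a,b interval bounds, 0-based half-open sample coordinates.
#' @param copy_count total copies (>= 1; 1 leaves the sequence unchanged).
#' @param shared_variants optional data.frame (`tx_offset`, `ref`, `alt`).
#' @param private_variant_rate per-base substitution rate within the retro
#'   transcript, per copy.
#' @return modified `genome_build` with per-copy variant truth in
#'   `build$truth$variants`.
#' @export
amplify_segment <- function(build, chrom, a, b, copy_count,
                            shared_variants = NULL,
                            private_variant_rate = 0) {
  stopifnot(inherits(build, "genome_build"))
  if (copy_count < 1L) stop2("copy_count must be >= 1")
  sm <- build$segmap[[chrom]]
  inside <- sm[start < b & end > a]
  ev_ids <- unique(inside$event[!is.na(inside$event)])
  if (length(ev_ids) != 1L) {
    stop2("interval must contain exactly one implanted retrocopy")
  }
  ev <- ev_ids
  retro_rows <- inside[type == "retro" & event == ev]
  if (min(retro_rows$start) < a || max(retro_rows$end) > b) {
    stop2("interval truncates the retrocopy")
  }
  ## clip boundary rows to [a, b)
  unit <- data.table::copy(inside)
  unit[start < a, `:=`(ref_start = data.table::fifelse(dir == 1L,
                         ref_start + (a - start), ref_start),
                       tx_start = data.table::fifelse(type == "retro",
                         tx_start + tx_dir * (a - start), tx_start),
                       start = a)]
  unit[end > b & dir == -1L, ref_start := ref_start + (end - b)]
  unit[end > b, end := b]
  base_seq <- subseq0(build$seq[[chrom]], a, b)
  ulen <- b - a

  tx_seq <- build$truth$retro_tx[[as.character(ev)]]
  retro_len <- nchar(tx_seq)
  copies <- character(copy_count)
  var_rows <- list()
  if (!is.null(shared_variants) && nrow(shared_variants)) {
    sv <- data.table::as.data.table(shared_variants)
    var_rows[[length(var_rows) + 1L]] <-
      data.table::data.table(event = ev, copy = 0L, tx_offset = sv$tx_offset,
                             ref = sv$ref, alt = sv$alt)
  }
  for (j in seq_len(copy_count)) {
    s <- base_seq
    if (!is.null(shared_variants) && nrow(shared_variants)) {
      for (i in seq_len(nrow(shared_variants))) {
        s <- write_tx_snv(s, unit, a, shared_variants$tx_offset[i],
                          shared_variants$alt[i])
      }
    }
    if (private_variant_rate > 0) {
      n_priv <- rbinom(1L, retro_len, private_variant_rate)
      if (n_priv > 0L) {
        offs <- sort(sample.int(retro_len, n_priv) - 1L)
        refs <- substring(tx_seq, offs + 1L, offs + 1L)
        alts <- vapply(refs, function(r) sample(setdiff(DNA, r), 1L),
                       character(1), USE.NAMES = FALSE)
        for (i in seq_along(offs)) {
          s <- write_tx_snv(s, unit, a, offs[i], alts[i])
        }
        var_rows[[length(var_rows) + 1L]] <-
          data.table::data.table(event = ev, copy = j, tx_offset = offs,
                                 ref = refs, alt = alts)
      }
    }
    copies[j] <- s
  }

  ## assemble new sequence and segment map
  old <- build$seq[[chrom]]
  build$seq[[chrom]] <- paste0(subseq0(old, 0L, a),
                               paste(copies, collapse = ""),
                               subseq0(old, b, nchar(old)))
  shift_unit <- function(j) {
    u <- data.table::copy(unit)
    d <- (j - 1L) * ulen
    u[, `:=`(start = start + d, end = end + d)]
    u[type == "retro", copy := j]
    u
  }
  left <- sm[end <= a]
  lcut <- sm[start < a & end > a]
  if (nrow(lcut)) lcut[, end := a]
  rcut <- sm[start < b & end > b]
  if (nrow(rcut)) {
    rcut[, `:=`(ref_start = data.table::fifelse(dir == 1L,
                  ref_start + (b - start), ref_start),
                start = b)]
  }
  right <- data.table::rbindlist(list(rcut, sm[start >= b]))
  d_all <- (copy_count - 1L) * ulen
  right[, `:=`(start = start + d_all, end = end + d_all)]
  build$segmap[[chrom]] <- data.table::rbindlist(
    c(list(left, lcut), lapply(seq_len(copy_count), shift_unit), list(right)))

  n_copies <- as.integer(copy_count)
  build$truth$events[event == ev, copy_count := n_copies]
  if (length(var_rows)) {
    build$truth$variants <- data.table::rbindlist(
      c(list(build$truth$variants), var_rows))
  }
  build
}

#' Delete an interval from a sample genome
#'
#' Used to emulate haplotypes lacking a reference retrocopy.
#'
#' @param build a `genome_build`.
#' @param chrom chromosome.
#' @param a,b interval, 0-based half-open sample coordinates.
#' @export
delete_segment <- function(build, chrom, a, b) {
  old <- build$seq[[chrom]]
  build$seq[[chrom]] <- paste0(subseq0(old, 0L, a), subseq0(old, b, nchar(old)))
  sm <- build$segmap[[chrom]]
  left <- sm[end <= a]
  lcut <- sm[start < a & end > a & start < a]
  if (nrow(lcut)) lcut[, end := a]
  rcut <- sm[start < b & end > b]
  if (nrow(rcut)) {
    rcut[, `:=`(ref_start = data.table::fifelse(dir == 1L,
                  ref_start + (b - start), ref_start),
                start = b)]
  }
  right <- data.table::rbindlist(list(rcut, sm[start >= b]))
  d <- b - a
  right[, `:=`(start = start - d, end = end - d)]
  build$segmap[[chrom]] <- data.table::rbindlist(list(left, lcut, right))
  build
}

#' Pick intergenic insertion sites for a set of parent genes
#'
#' Chooses one insertion position per parent on the pristine reference:
#' outside every annotated gene (with `min_gene_dist` clearance) and at
#' least `min_parent_dist` from the parent itself, so that mates bridging
#' the insertion are unambiguously discordant. Positions are returned in
#' descending order: inserting in that order leaves each remaining site's
#' coordinates unshifted.
#'
#' @param models all gene models of the genome.
#' @param parents indices into `models` of the parents to implant.
#' @param genome_length reference length.
#' @param min_gene_dist,min_parent_dist clearances in bp.
#' @return data.table `parent` (model index), `site` (0-based position),
#'   sorted by descending site.
#' @export
pick_insertion_sites <- function(models, parents, genome_length,
                                 min_gene_dist = 2000L,
                                 min_parent_dist = 20000L) {
  spans <- do.call(rbind, lapply(models, function(m) gene_span(m)))
  ok_pos <- function(p, parent_span) {
    all(p < spans[, "start"] - min_gene_dist |
          p > spans[, "end"] + min_gene_dist) &&
      (p < parent_span["start"] - min_parent_dist ||
         p > parent_span["end"] + min_parent_dist)
  }
  sites <- integer(length(parents))
  for (i in seq_along(parents)) {
    psp <- gene_span(models[[parents[i]]])
    for (try in 1:1000) {
      p <- sample.int(genome_length - 4000L, 1L) + 2000L
      if (ok_pos(p, psp) && !p %in% sites) break
      p <- NA_integer_
    }
    if (is.na(p)) stop2("could not place insertion site for parent ", i)
    sites[i] <- p
  }
  data.table::data.table(parent = parents, site = sites)[order(-site)]
}

#' Plant a homozygous SNV in a sample genome
#'
#' Used to give individual samples parental polymorphisms. The position is
#' in sample coordinates (equal to reference coordinates while the region
#' is untouched by insertions).
#'
#' @param build a `genome_build`.
#' @param chrom chromosome.
#' @param pos 0-based position.
#' @param alt alternative base (random non-reference base when NULL).
#' @export
plant_snv <- function(build, chrom, pos, alt = NULL) {
  g <- build$seq[[chrom]]
  old <- substr(g, pos + 1L, pos + 1L)
  if (is.null(alt)) alt <- sample(setdiff(DNA, old), 1L)
  if (alt == old) stop2("alt equals the current base")
  substr(g, pos + 1L, pos + 1L) <- alt
  build$seq[[chrom]] <- g
  build
}

#' Lineage divergence specification
#'
#' @param target_age target divergence time in years.
#' @param mu substitution rate per site per generation.
#' @param g generation time in years.
#' @param k_lin lineage factor: 1 if all divergence is placed on one
#'   lineage, 2 if substitutions accumulate on both lineages.
#' @param length sequence length in bp (taken from the sequence when NULL).
#' @export
lineage_spec <- function(target_age, mu = 7.24e-9, g = 8, k_lin = 1L,
                         length = NULL) {
  stopifnot(mu > 0, g > 0, k_lin %in% c(1L, 2L), target_age >= 0)
  structure(list(target_age = target_age, mu = mu, g = g,
                 k_lin = as.integer(k_lin), length = length),
            class = "lineage_spec")
}

#' Simulate molecular-clock divergence on a sequence
#'
#' Draws a Poisson number of substitutions with mean
#' `L * mu * k_lin * target_age / g` and places them uniformly at distinct
#' positions, each to a random different base.
#'
#' @param spec a [lineage_spec()].
#' @param sequence the sequence to mutate.
#' @return list with `seq` (mutated copy) and `n_sub` (substitution count).
#' @export
simulate_lineage_divergence <- function(spec, sequence) {
  stopifnot(inherits(spec, "lineage_spec"))
  L <- nchar(sequence)
  mean_sub <- L * spec$mu * spec$k_lin * spec$target_age / spec$g
  if (mean_sub > L / 2) {
    stop2("expected substitutions (", round(mean_sub), ") exceed L/2; ",
          "divergence would be saturated")
  }
  n <- min(rpois(1L, mean_sub), L)
  if (n > 0L) {
    pos <- sample.int(L, n)
    for (p in pos) {
      old <- substr(sequence, p, p)
      substr(sequence, p, p) <- sample(setdiff(DNA, old), 1L)
    }
  }
  list(seq = sequence, n_sub = n)
}
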