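#' Pile up alleles over parent-gene exons
#'
#' Simple exact pileup of aligned M bases over the given exon intervals,
#' per sample, retaining sites where any sample shows a non-reference
#' base. Alt presence in a sample requires at least `r_min` alt reads, a
#' guard against sequencing error at typical 20x coverage.
#'
#' @param aln_by_sample named list of alignment tables, one per sample.
#' @param genome reference sequences.
#' @param gm parent [gene_model()]; only its exon intervals are piled up.
#' @param r_min minimum alt reads for presence (default 3).
#' @return a cohort allele table (data.table): `chrom`, `pos` (0-based),
#'   `ref`, `alt`, then per sample `<id>_frac` and `<id>_present`.
#' @export
pileup_alleles <- function(aln_by_sample, genome, gm, r_min = 3L) {
  eg <- exons_genomic(gm)
  g <- genome[[gm$chrom]]
  tally <- list()
  for (sid in names(aln_by_sample)) {
    aln <- aln_by_sample[[sid]]
    sub <- aln[chrom == gm$chrom & !unmapped]
    keep <- rep(FALSE, nrow(sub))
    for (i in seq_len(nrow(eg))) {
      keep <- keep | (sub$pos < eg$end[i] & sub$end > eg$start[i])
    }
    sub <- sub[keep]
    if (nrow(sub) == 0L) next
    ## expand M blocks (alignments here are M with optional terminal clips)
    mlen <- nchar(sub$seq) - sub$left_clip - sub$right_clip
    pos_list <- lapply(seq_len(nrow(sub)), function(i) {
      sub$pos[i] + 0:(mlen[i] - 1L)
    })
    base_list <- lapply(seq_len(nrow(sub)), function(i) {
      p1 <- sub$left_clip[i] + 1L
      strsplit(substr(sub$seq[i], p1, p1 + mlen[i] - 1L), "")[[1]]
    })
    dt <- data.table::data.table(pos = unlist(pos_list),
                                 base = unlist(base_list))
    dt <- dt[base %in% DNA]
    cnt <- dt[, .N, by = .(pos, base)]
    cnt[, sample := sid]
    tally[[sid]] <- cnt
  }
  empty <- data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character())
  if (!length(tally)) return(empty)
  cnt <- data.table::rbindlist(tally)
  ## keep exonic sites only
  ok <- rep(FALSE, nrow(cnt))
  for (i in seq_len(nrow(eg))) {
    ok <- ok | (cnt$pos >= eg$start[i] & cnt$pos < eg$end[i])
  }
  cnt <- cnt[ok]
  cnt[, ref := substring(g, pos + 1L, pos + 1L)]
  alt_cnt <- cnt[base != ref]
  if (nrow(alt_cnt) == 0L) return(empty)
  ## dominant alt per site across the cohort
  tot_alt <- alt_cnt[, .(n = sum(N)), by = .(pos, base)]
  best <- tot_alt[order(pos, -n, base)][, .SD[1L], by = pos]
  data.table::setnames(best, "base", "alt")
  site_tot <- cnt[, .(depth = sum(N)), by = .(pos, sample)]
  site_alt <- alt_cnt[, .(alt_n = sum(N)), by = .(pos, base, sample)]
  out <- best[, .(pos, alt)]
  out[, `:=`(chrom = gm$chrom, ref = substring(g, pos + 1L, pos + 1L))]
  for (sid in names(aln_by_sample)) {
    d <- site_tot[sample == sid][out, on = "pos"]
    a <- site_alt[sample == sid][out[, .(pos, base = alt)],
                                 on = c("pos", "base")]
    an <- data.table::fifelse(is.na(a$alt_n), 0L, a$alt_n)
    dp <- data.table::fifelse(is.na(d$depth), 0L, d$depth)
    frac <- data.table::fifelse(dp > 0L, an / dp, 0)
    out[, (paste0(sid, "_frac")) := frac]
    out[, (paste0(sid, "_present")) := an >= r_min]
  }
  ## require presence somewhere
  pres <- as.matrix(out[, paste0(names(aln_by_sample), "_present"),
                        with = FALSE])
  out <- out[rowSums(pres) > 0L]
  data.table::setcolorder(out, c("chrom", "pos", "ref", "alt"))
  out[order(pos)]
}

#' Attribute cohort variants to retrocopy or parent gene
#'
#' A variant seen only in retroCNV carriers is attributed to the
#' retrocopy (its reads pile onto the parent locus because the reference
#' lacks the insertion); a variant seen in any non-carrier must segregate
#' in the parent gene itself. Cohorts without both carriers and
#' non-carriers cannot separate the two hypotheses, so everything becomes
#' ambiguous.
#'
#' @param table cohort allele table from [pileup_alleles()].
#' @param carriers character vector of carrier sample ids.
#' @param non_carriers character vector of non-carrier sample ids.
#' @return the table with an `attribution` column in
#'   `c("retrocopy", "parental", "ambiguous")`.
#' @export
attribute_variants <- function(table, carriers, non_carriers) {
  out <- data.table::copy(data.table::as.data.table(table))
  if (nrow(out) == 0L) {
    out[, attribution := character(0)]
    return(out)
  }
  if (!length(carriers) || !length(non_carriers)) {
    warning("cohort lacks carriers or non-carriers; attributions ambiguous")
    out[, attribution := "ambiguous"]
    return(out[])
  }
  pc <- as.matrix(out[, paste0(carriers, "_present"), with = FALSE])
  pn <- as.matrix(out[, paste0(non_carriers, "_present"), with = FALSE])
  in_car <- rowSums(pc) > 0L
  in_non <- rowSums(pn) > 0L
  out[, attribution := data.table::fcase(
    in_non, "parental",
    in_car & !in_non, "retrocopy",
    default = "ambiguous")]
  out[in_car | in_non]
}

#' Classify the coding consequence of a variant
#'
#' Uses codon arithmetic against the gene model's CDS: the affected codon
#' is located from the transcript offset, mutated, and translated with the
#' standard genetic code. Indels are classified by length modulo 3.
#'
#' @param genome reference sequences.
#' @param gm [gene_model()] with CDS bounds set.
#' @param pos 0-based genomic position of the variant (first ref base for
#'   indels).
#' @param ref,alt alleles as VCF-style strings (SNV: single bases; indel:
#'   anchored, e.g. ref "CAAA" alt "C" for a 3 bp deletion).
#' @return list: `consequence` in synonymous/missense/nonsense/frameshift/
#'   inframe_indel/UTR/noncoding, plus `codons_changed` for inframe
#'   indels.
#' @export
classify_consequence <- function(genome, gm, pos, ref, alt) {
  tpos <- genome_to_tx(gm, pos)
  if (is.na(tpos)) return(list(consequence = "noncoding", codons_changed = NA))
  if (is.na(gm$cds_start)) return(list(consequence = "noncoding",
                                       codons_changed = NA))
  indel_len <- nchar(ref) - nchar(alt)
  if (indel_len != 0L) {
    in_cds <- tpos >= gm$cds_start && tpos < gm$cds_end
    if (!in_cds) return(list(consequence = "UTR", codons_changed = NA))
    if (abs(indel_len) %% 3L != 0L) {
      return(list(consequence = "frameshift", codons_changed = NA))
    }
    return(list(consequence = "inframe_indel",
                codons_changed = abs(indel_len) %/% 3L))
  }
  if (tpos < gm$cds_start || tpos >= gm$cds_end) {
    return(list(consequence = "UTR", codons_changed = NA))
  }
  tx <- extract_spliced_transcript(genome, gm)
  cds_off <- tpos - gm$cds_start
  codon_i <- cds_off %/% 3L
  within <- cds_off %% 3L
  codon_start <- gm$cds_start + codon_i * 3L
  codon <- substr(tx, codon_start + 1L, codon_start + 3L)
  ## the transcript carries the ref allele in transcript orientation
  tx_ref <- if (gm$strand == "+") ref else revcomp(ref)
  tx_alt <- if (gm$strand == "+") alt else revcomp(alt)
  if (substr(codon, within + 1L, within + 1L) != tx_ref) {
    stop2("ref allele mismatch at genomic pos ", pos)
  }
  new_codon <- codon
  substr(new_codon, within + 1L, within + 1L) <- tx_alt
  ## no.init.codon: a lone codon must not be read as an initiator
  aa_old <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                               no.init.codon = TRUE))
  aa_new <- as.character(Biostrings::translate(Biostrings::DNAString(new_codon),
                                               no.init.codon = TRUE))
  cons <- if (aa_new == aa_old) {
    "synonymous"
  } else if (aa_new == "*") {
    "nonsense"
  } else {
    "missense"
  }
  list(consequence = cons, codons_changed = NA)
}

#' Select variants fixed across all retrocopy copies
#'
#' When a retrocopy is amplified to CN copies, reads from all copies
#' mismap onto the two parental alleles, so a variant present in every
#' copy should show an alt fraction near CN/(CN+2) in each carrier. A
#' variant is selected as fixed when its alt fraction reaches
#' `tau_fixed * CN/(CN+2)` in every carrier.
#'
#' @param variants attributed table from [attribute_variants()] (only
#'   rows with attribution "retrocopy" are considered).
#' @param copy_number named numeric vector: copy-number estimate per
#'   carrier sample.
#' @param carriers carrier sample ids.
#' @param tau_fixed fraction of the expected alt fraction required
#'   (default 0.5).
#' @return the retrocopy-attributed subset with a logical `fixed` column.
#' @export
select_fixed_variants <- function(variants, copy_number, carriers,
                                  tau_fixed = 0.5) {
  v <- data.table::as.data.table(variants)[attribution == "retrocopy"]
  missing_cn <- setdiff(carriers, names(copy_number))
  if (length(missing_cn)) {
    warning("carrier(s) without copy-number estimate excluded from the ",
            "fixation test: ", paste(missing_cn, collapse = ", "))
    carriers <- setdiff(carriers, missing_cn)
  }
  if (!length(carriers)) stop2("no carriers with copy-number estimates")
  thr <- vapply(carriers, function(s) {
    cn <- copy_number[[s]]
    tau_fixed * cn / (cn + 2)
  }, numeric(1))
  fr <- as.matrix(v[, paste0(carriers, "_frac"), with = FALSE])
  v[, fixed := rowSums(sweep(fr, 2L, thr, `>=`)) == length(carriers)]
  v[]
}

#' Build an N-masked transcript for allele-specific alignment
#'
#' Replaces each fixed diagnostic SNV position with N so alignment is
#' unbiased between parent and retrocopy alleles; the diagnostic table
#' records which allele belongs to which source. Indels are recorded as
#' diagnostics but not masked (masking is positional).
#'
#' @param tx parent transcript sequence.
#' @param gm the parent [gene_model()] (to convert genomic variant
#'   positions to transcript offsets).
#' @param fixed_variants table from [select_fixed_variants()] with
#'   `fixed == TRUE` rows used.
#' @return list: `masked` (sequence), `sites` (data.table `tx_pos`
#'   0-based, `parent_allele`, `retro_allele`).
#' @export
build_masked_transcript <- function(tx, gm, fixed_variants) {
  v <- data.table::as.data.table(fixed_variants)
  v <- v[fixed == TRUE & nchar(ref) == 1L & nchar(alt) == 1L]
  if (nrow(v) == 0L) {
    return(list(masked = tx,
                sites = data.table::data.table(tx_pos = integer(),
                                               parent_allele = character(),
                                               retro_allele = character())))
  }
  tpos <- genome_to_tx(gm, v$pos)
  if (anyNA(tpos)) stop2("fixed variant outside the transcript")
  par_allele <- if (gm$strand == "+") v$ref else revcomp(v$ref)
  ret_allele <- if (gm$strand == "+") v$alt else revcomp(v$alt)
  sites <- data.table::data.table(tx_pos = as.integer(tpos),
                                  parent_allele = par_allele,
                                  retro_allele = ret_allele)
  if (anyDuplicated(sites$tx_pos)) {
    dup <- sites[duplicated(tx_pos) | duplicated(tx_pos, fromLast = TRUE)]
    if (any(duplicated(dup$tx_pos) &
            !duplicated(dup[, .(tx_pos, retro_allele)]))) {
      stop2("conflicting alt alleles at one transcript position")
    }
    sites <- unique(sites, by = "tx_pos")
  }
  masked <- tx
  for (i in seq_len(nrow(sites))) {
    p <- sites$tx_pos[i] + 1L
    if (substr(masked, p, p) != sites$parent_allele[i]) {
      stop2("parent allele mismatch at transcript position ", p - 1L)
    }
    substr(masked, p, p) <- "N"
  }
  list(masked = masked, sites = sites[order(tx_pos)])
}

#' Undo masking using the diagnostic-site table
#' @param masked masked transcript from [build_masked_transcript()].
#' @param sites its `sites` table.
#' @export
unmask_transcript <- function(masked, sites) {
  for (i in seq_len(nrow(sites))) {
    p <- sites$tx_pos[i] + 1L
    substr(masked, p, p) <- sites$parent_allele[i]
  }
  masked
}
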