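#' Extract the spliced transcript of a gene model
#'
#' Concatenates exon sequences in transcript orientation;
#' minus-strand transcripts are reverse-complemented.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gm a [gene_model()].
#' @return transcript sequence (character scalar).
#' @export
extract_spliced_transcript <- function(genome, gm) {
  g <- genome[[gm$chrom]]
  if (is.null(g)) stop2("chromosome ", gm$chrom, " not in genome")
  if (max(gm$exons$end) > nchar(g) || min(gm$exons$start) < 0L) {
    stop2("exon out of chromosome bounds for ", gm$gene_id)
  }
  eg <- exons_genomic(gm)
  s <- paste(substring(g, eg$start + 1L, eg$end), collapse = "")
  if (gm$strand == "-") revcomp(s) else s
}

## all k-mers of a string as a character vector (empty if too short)
string_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

#' Canonicalize k-mers
#'
#' The canonical form is the lexicographic minimum of a k-mer and its
#' reverse complement; reads are unstranded, so inventories and scans both
#' work on canonical k-mers.
#'
#' @param kmers character vector.
#' @export
canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(character(0))
  rc <- revcomp(kmers)
  pmin(kmers, rc)
}

## positions where each pattern occurs exactly in any genome sequence,
## either strand; returns logical "present" per pattern
genome_has_exact <- function(patterns, genome_ss) {
  if (!length(patterns)) return(logical(0))
  pd <- Biostrings::PDict(patterns)
  pd_rc <- Biostrings::PDict(revcomp(patterns))
  hit <- rep(FALSE, length(patterns))
  for (i in seq_along(genome_ss)) {
    hit <- hit | Biostrings::countPDict(pd, genome_ss[[i]]) > 0L |
      Biostrings::countPDict(pd_rc, genome_ss[[i]]) > 0L
  }
  hit
}

## does any genomic window match `pat` within Hamming distance <= maxmm?
## Pigeonhole seed-and-verify: split the k-mer into maxmm+1 segments; any
## window within maxmm substitutions matches at least one segment exactly.
genome_has_hamming <- function(patterns, genome_ss, maxmm) {
  if (!length(patterns)) return(logical(0))
  k <- nchar(patterns[1L])
  nseg <- maxmm + 1L
  bounds <- round(seq(0L, k, length.out = nseg + 1L))
  hit <- rep(FALSE, length(patterns))
  for (ori in 1:2) {
    pats <- if (ori == 1L) patterns else revcomp(patterns)
    pss <- Biostrings::DNAStringSet(pats)
    for (s in seq_len(nseg)) {
      b1 <- bounds[s] + 1L
      b2 <- bounds[s + 1L]
      segs <- Biostrings::subseq(pss, b1, b2)
      pd <- Biostrings::PDict(segs)
      for (ci in seq_along(genome_ss)) {
        subj <- genome_ss[[ci]]
        slen <- length(subj)
        ml <- Biostrings::matchPDict(pd, subj)
        cnt <- vapply(ml, length, integer(1))
        todo <- which(cnt > 0L & !hit)
        for (p in todo) {
          starts <- Biostrings::start(ml[[p]]) - (b1 - 1L)
          starts <- starts[starts >= 1L & starts + k - 1L <= slen]
          if (!length(starts)) next
          nm <- Biostrings::neditStartingAt(Biostrings::DNAString(pats[p]),
                                            subj, starting.at = starts,
                                            with.indels = FALSE)
          if (any(nm <= maxmm)) hit[p] <- TRUE
        }
      }
    }
  }
  hit
}

#' Build mRNA-specific k-mer inventories
#'
#' For each gene, enumerates all k-mers of its spliced transcript(s),
#' canonicalizes them, and removes (a) every k-mer with an exact occurrence
#' anywhere in the genome on either strand and (b) every k-mer with a
#' genomic occurrence within Hamming distance `max_mismatch` — the latter
#' guards against sequencing errors turning a near-genomic k-mer into a
#' false retrocopy signal. Surviving k-mers necessarily straddle exon-exon
#' junctions, the sequence configuration unique to spliced mRNA (and to
#' retrocopies derived from it). Multiple transcripts of one gene pool
#' their inventories under the gene id. k-mers containing N are skipped.
#'
#' @param genome named character vector of chromosome sequences.
#' @param models list of [gene_model()] objects.
#' @param k k-mer length (default 30, as used with ~2.7 Gb genomes; toy
#'   genomes should use a smaller k such as 12).
#' @param max_mismatch maximum Hamming distance to the genome for removal
#'   (default 2; substitutions only).
#' @return named list of inventories, one per gene: list with `gene_id`,
#'   `k`, `kmers` (canonical character vector), `total_count`.
#' @export
build_specific_kmers <- function(genome, models, k = 30L, max_mismatch = 2L) {
  if (k < 8L) stop2("k < 8 gives degenerate specificity")
  stopifnot(max_mismatch >= 0L)
  genome_ss <- Biostrings::DNAStringSet(unlist(genome))
  per_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  cand <- lapply(per_gene, function(ms) {
    km <- unlist(lapply(ms, function(gm) {
      tx <- extract_spliced_transcript(genome, gm)
      string_kmers(tx, k)
    }))
    km <- unique(km[!grepl("N", km, fixed = TRUE)])
    unique(canonical_kmers(km))
  })
  ## filter the pooled candidate set in one pass; per-pattern dictionary
  ## construction dominates otherwise
  pool <- unique(unlist(cand, use.names = FALSE))
  keep <- pool
  if (length(keep)) keep <- keep[!genome_has_exact(keep, genome_ss)]
  if (length(keep) && max_mismatch > 0L) {
    keep <- keep[!genome_has_hamming(keep, genome_ss, max_mismatch)]
  }
  lapply(cand, function(km) {
    km <- sort(intersect(km, keep))
    list(gene_id = NULL, k = as.integer(k), kmers = km,
         total_count = length(km))
  }) -> invs
  for (g in names(invs)) invs[[g]]$gene_id <- g
  invs
}

#' Scan reads for inventory k-mers
#'
#' A k-mer counts as observed if it (in canonical form) occurs in any read
#' on either strand; `specific_hits` is the number of *distinct* inventory
#' k-mers observed, not total occurrences.
#'
#' @param inventories output of [build_specific_kmers()].
#' @param reads character vector of read sequences (e.g. from
#'   [read_fastq()], or `c(rbind(seq1, seq2))` of a simulated pair table).
#' @return data.table: `gene_id`, `specific_hits`, `total_count`.
#' @export
scan_reads <- function(inventories, reads) {
  res <- data.table::data.table(
    gene_id = vapply(inventories, `[[`, character(1), "gene_id"),
    specific_hits = 0L,
    total_count = vapply(inventories, `[[`, integer(1), "total_count"))
  all_km <- unlist(lapply(inventories, `[[`, "kmers"), use.names = FALSE)
  if (!length(all_km) || !length(reads)) return(res)
  gene_of <- rep(res$gene_id, res$total_count)
  ## concatenate reads with an N separator: inventory k-mers are ACGT-only,
  ## so no match can span a read boundary, and one subject scan replaces
  ## hundreds of thousands of per-read scans
  subject <- Biostrings::DNAString(paste(reads, collapse = "N"))
  pd <- Biostrings::PDict(all_km)
  pd_rc <- Biostrings::PDict(revcomp(all_km))
  cnt <- Biostrings::countPDict(pd, subject) +
    Biostrings::countPDict(pd_rc, subject)
  seen <- cnt > 0L
  hits <- tapply(seen, gene_of, sum)
  res[match(names(hits), gene_id), specific_hits := as.integer(hits)]
  res[]
}

#' Call putative retroCNV parent genes
#'
#' A gene is called when a sample's reads contain more than `t_min`
#' distinct mRNA-specific k-mers of that gene and those hits cover at least
#' `f_min` of the gene's inventory.
#'
#' @param counts data.table from [scan_reads()].
#' @param t_min minimum distinct specific k-mers, strict inequality
#'   (default 5).
#' @param f_min minimum fraction of the inventory observed (default 0.10).
#' @param sample_id sample label for the output.
#' @return data.table: `sample_id`, `gene_id`, `specific_hits`,
#'   `total_count`, `fraction`, `called`. Genes with empty inventories are
#'   excluded with a warning.
#' @export
call_parent_genes <- function(counts, t_min = 5L, f_min = 0.10,
                              sample_id = "sample1") {
  counts <- data.table::as.data.table(counts)
  if (any(counts$total_count == 0L)) {
    warning(sum(counts$total_count == 0L),
            " gene(s) with empty k-mer inventory excluded")
    counts <- counts[total_count > 0L]
  }
  counts[, `:=`(sample_id = sample_id,
                fraction = specific_hits / total_count)]
  counts[, called := specific_hits > t_min & fraction >= f_min]
  counts[, .(sample_id, gene_id, specific_hits, total_count, fraction,
             called)]
}

#' Persist / load a k-mer inventory as TSV
#' @param inventories output of [build_specific_kmers()].
#' @param path file path (gzip applied when the name ends in .gz).
#' @export
write_kmer_inventory <- function(inventories, path) {
  dt <- data.table::rbindlist(lapply(inventories, function(inv) {
    if (!inv$total_count) {
      return(data.table::data.table(gene_id = character(), k = integer(),
                                    kmer = character()))
    }
    data.table::data.table(gene_id = inv$gene_id, k = inv$k,
                           kmer = inv$kmers)
  }))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_kmer_inventory
#' @export
read_kmer_inventory <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  lapply(split(dt, dt$gene_id), function(d) {
    list(gene_id = d$gene_id[1], k = d$k[1], kmers = sort(d$kmer),
         total_count = nrow(d))
  })
}
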