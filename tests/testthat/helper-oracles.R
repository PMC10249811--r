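## Independent oracles used across tests. These deliberately use naive
## algorithms (exhaustive scans, full translation, direct gap counting) so
## they share no code path with the implementation they check.

## minimum Hamming distance from each k-mer to any genomic window on
## either strand, by exhaustive window-by-window comparison
brute_min_hamming <- function(kmers, genome) {
  k <- nchar(kmers[1])
  wins <- character(0)
  for (g in genome) {
    n <- nchar(g)
    if (n >= k) wins <- c(wins, substring(g, 1:(n - k + 1), k:n))
  }
  wins <- c(wins, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(wins))))
  wmat <- matrix(unlist(strsplit(wins, "")), nrow = k)
  vapply(kmers, function(km) {
    kc <- strsplit(km, "")[[1]]
    min(colSums(wmat != kc))
  }, numeric(1))
}

## brute-force inventory: all transcript k-mers (canonical) whose minimum
## genomic Hamming distance exceeds max_mismatch
brute_inventory <- function(genome, gm, k, max_mismatch = 2) {
  tx <- extract_spliced_transcript(genome, gm)
  km <- unique(substring(tx, 1:(nchar(tx) - k + 1), k:nchar(tx)))
  km <- unique(canonical_kmers(km))
  d <- brute_min_hamming(km, genome)
  sort(km[d > max_mismatch])
}

## consequence oracle: apply the variant to the CDS, translate both CDS
## versions completely, and compare the proteins
translate_oracle <- function(genome, gm, pos, ref, alt) {
  tx <- extract_spliced_transcript(genome, gm)
  cds <- substr(tx, gm$cds_start + 1, gm$cds_end)
  tpos <- retroscout:::genome_to_tx(gm, pos)
  if (is.na(tpos) || tpos < gm$cds_start || tpos >= gm$cds_end) {
    return("not_cds")
  }
  off <- tpos - gm$cds_start
  tx_alt <- if (gm$strand == "+") alt else revcomp(alt)
  mut <- cds
  substr(mut, off + 1, off + 1) <- tx_alt
  ## straight genetic-code translation, no initiator-codon special case
  p0 <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                           no.init.codon = TRUE))
  if (p1 == p0) return("synonymous")
  aa <- substr(p1, off %/% 3 + 1, off %/% 3 + 1)
  if (aa == "*") "nonsense" else "missense"
}

## single-linkage clustering oracle on sorted positions: cluster ids by
## cutting at gaps larger than the window
single_linkage_oracle <- function(positions, window) {
  o <- order(positions)
  p <- positions[o]
  cid <- cumsum(c(0, diff(p) > window))
  cid[order(o)]
}

## -- fixture builders -------------------------------------------------

## small annotated genome with optional implanted retrocopies
make_fixture <- function(seed = 1, genome_length = 1e5, n_genes = 3,
                         coverage = 20, error_rate = 0.002, ...) {
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    n_genes = n_genes, coverage = coverage,
                    error_rate = error_rate, ...)
  gen <- generate_genome(cfg)
  list(cfg = cfg, gen = gen)
}

## cohort of carriers and non-carriers of one retrocopy, with optional
## retro-borne and parental SNVs; returns per-sample alignments
make_cohort <- function(seed, n_carriers = 3, n_non = 5,
                        genome_length = 6e4, retro_variants = NULL,
                        parental_pos = NULL, coverage = 20) {
  fx <- make_fixture(seed = seed, genome_length = genome_length,
                     n_genes = 2, coverage = coverage)
  gm <- fx$gen$models[[1]]
  site <- pick_insertion_sites(fx$gen$models, 1L, genome_length,
                               min_parent_dist = 15000L)$site
  samples <- sprintf("s%02d", seq_len(n_carriers + n_non))
  carriers <- samples[seq_len(n_carriers)]
  alns <- list()
  for (i in seq_along(samples)) {
    b <- fx$gen$build
    if (!is.null(parental_pos) && i %% 2 == 0) {
      ## parental polymorphism in alternating samples (both groups);
      ## planted before the insertion so positions are reference coords.
      ## The alt base is a fixed function of the reference base so every
      ## sample shares the same allele.
      for (p in parental_pos) {
        ref <- substr(fx$gen$build$ref[["chr1"]], p + 1, p + 1)
        alt <- c(A = "C", C = "G", G = "T", T = "A")[[ref]]
        b <- plant_snv(b, "chr1", p, alt = alt)
      }
    }
    if (samples[i] %in% carriers) {
      b <- insert_retrocopy(b, gm, "chr1", site, tsd_length = 17L,
                            shared_variants = retro_variants)
    }
    rr <- simulate_reads(b, fx$cfg, sample_id = samples[i],
                         seed = seed * 100 + i)
    alns[[samples[i]]] <- rr$aln
  }
  list(fx = fx, gm = gm, site = site, samples = samples,
       carriers = carriers, non_carriers = setdiff(samples, carriers),
       alns = alns)
}
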