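## minimal alignment-record builder for hand-constructed cases
mk_aln <- function(pos, mpos, mchrom = "chr1", chrom = "chr1", proper = FALSE,
                   cigar = "100M", seq = strrep("A", 100), qname = NULL,
                   sample = "s1") {
  n <- length(pos)
  lc <- ifelse(grepl("^\\d+S", cigar), as.integer(sub("S.*", "", cigar)), 0L)
  rc <- ifelse(grepl("\\d+S$", cigar),
               as.integer(sub(".*[MS](\\d+)S$", "\\1", cigar)), 0L)
  mlen <- nchar(seq) - lc - rc
  mate_end <- as.integer(mpos) + 100L
  data.table::data.table(
    mate_end = mate_end,
    qname = qname %||% sprintf("r%03d", seq_len(n)), flag = 0L,
    chrom = chrom, pos = as.integer(pos), mapq = 60L, cigar = cigar,
    mchrom = mchrom, mpos = as.integer(mpos), tlen = 0L, seq = seq,
    paired = TRUE, proper = proper, unmapped = FALSE, munmapped = FALSE,
    reverse = FALSE, first_in_pair = TRUE, left_clip = lc, right_clip = rc,
    end = as.integer(pos) + mlen, sample = sample)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("discordant-pair discovery keeps exon-anchored distant mates only", {
  gm <- gene_model("g1", "t1", "chr1", "+",
                   data.frame(start = c(1000, 2000), end = c(1500, 2500)))
  aln <- rbind(
    mk_aln(1100, 5e6, mchrom = "chr2"),            # exon + other chrom: keep
    mk_aln(1200, 90000),                           # exon + >d_max away: keep
    mk_aln(1300, 1500, proper = TRUE),             # proper pair: drop
    mk_aln(1600, 5e6, mchrom = "chr2"),            # intron only: drop
    mk_aln(1100, 1400))                            # exon + nearby mate: drop
  got <- find_discordant_pairs(aln, gm, d_max = 10000)
  expect_equal(nrow(got), 2)
  expect_setequal(got$pos, c(1100, 1200))
  expect_equal(got$mate_end, got$mpos + 100L)
})

test_that("mate clustering is single-linkage with a support floor", {
  within <- mk_aln(rep(1100, 8), 50000 + seq(0, 280, by = 40))
  one <- cluster_mates(within, "g1", cluster_window = 500, min_support = 4)
  expect_equal(nrow(one), 1)
  expect_equal(one$support, 8)
  expect_equal(one$start, 50000)

  few <- cluster_mates(within[1:3], "g1", min_support = 4)
  expect_equal(nrow(few), 0)

  two_grp <- mk_aln(rep(1100, 10), c(50000 + seq(0, 160, 40),
                                     60000 + seq(0, 160, 40)))
  two <- cluster_mates(two_grp, "g1", cluster_window = 500, min_support = 4)
  expect_equal(nrow(two), 2)

  ## randomized agreement with a direct single-linkage oracle
  set.seed(5)
  for (rep in 1:5) {
    mpos <- sort(sample.int(1e5, 40))
    cand <- mk_aln(rep(1100, 40), mpos)
    oracle <- single_linkage_oracle(mpos, 500)
    got <- cluster_mates(cand, "g1", cluster_window = 500, min_support = 1)
    expect_equal(nrow(got), length(unique(oracle)))
    expect_equal(sort(got$support), as.vector(sort(table(oracle))))
  }
})

test_that("breakpoints use modal clip edges and recover the TSD", {
  fx <- make_fixture(seed = 51, genome_length = 1e5, n_genes = 2,
                     error_rate = 0.001)
  gm <- fx$gen$models[[1]]
  site <- pick_insertion_sites(fx$gen$models, 1L, 1e5)$site
  b <- insert_retrocopy(fx$gen$build, gm, "chr1", site, tsd_length = 17L)
  rr <- simulate_reads(b, fx$cfg)
  calls <- resolve_insertions(list(s1 = rr$aln), list(gm), fx$gen$build$ref)
  ev <- b$truth$events
  expect_equal(nrow(calls), 1)
  expect_true(calls$resolved)
  expect_equal(calls$start, ev$tsd_start)
  expect_equal(calls$end, ev$insertion_point)
  expect_identical(calls$tsd_seq, ev$tsd_seq)
  expect_equal(calls$tsd_length, 17L)
  ## TSD self-consistency: reported sequence equals the reference bases of
  ## the reported interval
  expect_identical(calls$tsd_seq,
                   substr(fx$gen$build$ref[["chr1"]], calls$start + 1,
                          calls$end))
  ## junction sequences carry flank and insert bases
  expect_match(calls$five_prime_junction, "\\|")
  expect_match(calls$three_prime_junction, "\\|")
})

test_that("breakpoint votes follow the majority and degenerate cases", {
  expect_equal(retroscout:::modal_value(c(rep(120L, 6), rep(130L, 2))), 120)
  ## exact tie broken toward the leftmost coordinate
  expect_equal(retroscout:::modal_value(c(rep(130L, 3), rep(120L, 3))), 120)
})

test_that("genomes without insertions produce no insertion calls", {
  fx <- make_fixture(seed = 52, genome_length = 1e5, n_genes = 3)
  rr <- simulate_reads(fx$gen$build, fx$cfg)
  calls <- resolve_insertions(list(s1 = rr$aln), fx$gen$models,
                              fx$gen$build$ref)
  expect_equal(nrow(calls), 0)
})

test_that("discordant support grows with tandem copy number", {
  supports <- vapply(c(1L, 5L, 25L), function(N) {
    fx <- make_fixture(seed = 53, genome_length = 1e5, n_genes = 2)
    gm <- fx$gen$models[[1]]
    site <- pick_insertion_sites(fx$gen$models, 1L, 1e5)$site
    b <- insert_retrocopy(fx$gen$build, gm, "chr1", site, tsd_length = 17L)
    ev <- b$truth$events
    ins_len <- ev$retro_len + ev$polyA_length + ev$tsd_length
    if (N > 1L) {
      b <- amplify_segment(b, "chr1", site - 500L, site + ins_len + 500L, N)
    }
    rr <- simulate_reads(b, fx$cfg)
    calls <- resolve_insertions(list(s1 = rr$aln), list(gm),
                                fx$gen$build$ref)
    expect_equal(nrow(calls), 1)  # one locus regardless of copy number
    calls$discordant_support
  }, integer(1))
  expect_true(all(diff(supports) > 0))
})

test_that("junction-spanning reads are detected exactly", {
  fx <- make_fixture(seed = 54, genome_length = 4e4, n_genes = 1,
                     error_rate = 0)
  gm <- fx$gen$models[[1]]
  genome <- fx$gen$build$ref
  tx <- extract_spliced_transcript(genome, gm)
  lens <- gm$exons$end - gm$exons$start
  o <- lens[1]
  jread <- substr(tx, o - 30 + 1, o + 30)          # spans junction 1
  iread <- substr(genome[["chr1"]], gm$exons$start[1] + 1,
                  gm$exons$start[1] + 60)           # collinear genomic read
  expect_equal(detect_junction_reads(genome, gm, c(jread, iread)), 1)
  expect_equal(detect_junction_reads(genome, gm, revcomp(jread)), 1)
  ## error-free reads from a retrocopy-free genome carry no junctions
  rr <- simulate_reads(fx$gen$build, fx$cfg, emit_sam = FALSE)
  expect_equal(
    detect_junction_reads(genome, gm, c(rr$reads$seq1, rr$reads$seq2)), 0)
  expect_error(detect_junction_reads(genome, gm, "ACGT", j = 20),
               "longer than")
})

test_that("reference retrocopy absence is classified from depth and pairs", {
  fx <- make_fixture(seed = 55, genome_length = 6e4, n_genes = 1,
                     coverage = 30)
  ## treat an arbitrary 1.5 kb interval as the annotated reference retrocopy
  a <- 30000L; z <- 31500L
  b_del <- delete_segment(fx$gen$build, "chr1", a, z)

  rr_pres <- simulate_reads(fx$gen$build, fx$cfg)
  gd <- genome_mean_depth(rr_pres$aln, fx$gen$seqlens)
  pres <- reference_retrocopy_absence(rr_pres$aln, "chr1", a, z, gd)
  expect_equal(pres$state, "present")
  expect_gt(pres$depth_ratio, 0.8)

  rr_hom <- simulate_reads(b_del, fx$cfg)
  hom <- reference_retrocopy_absence(rr_hom$aln, "chr1", a, z, gd)
  expect_equal(hom$state, "hom_absent")
  expect_gt(hom$straddling_pairs, 0)

  ## heterozygous deletion: half the reads from each haplotype
  half <- sim_config(seed = 56, genome_length = 6e4, n_genes = 1,
                     coverage = 15)
  r1 <- simulate_reads(fx$gen$build, half, sample_id = "h1")
  r2 <- simulate_reads(b_del, half, sample_id = "h1", seed = 57)
  aln_het <- rbind(r1$aln, r2$aln)
  het <- reference_retrocopy_absence(aln_het, "chr1", a, z, gd)
  expect_equal(het$state, "het_absent")

  expect_error(reference_retrocopy_absence(rr_pres$aln, "chr1", a, z, 0),
               "positive")
})

test_that("sex-bias flagging requires males-only evidence", {
  sexes <- data.table::data.table(
    sample_id = sprintf("s%02d", 1:10),
    sex = rep(c("M", "F"), c(4, 6)))
  ev <- function(gene, with) data.table::data.table(
    gene_id = gene, sample_id = sprintf("s%02d", 1:10),
    has_evidence = sprintf("s%02d", 1:10) %in% with)
  flag <- flag_sex_bias(rbind(ev("gA", sprintf("s%02d", 1:4)),
                              ev("gB", sprintf("s%02d", c(1:3, 5)))),
                        sexes)
  expect_true(flag[gene_id == "gA"]$flagged)   # 4/4 males, 0 females
  expect_false(flag[gene_id == "gB"]$flagged)  # 3 males + 1 female
  ## a cohort without females is not evaluable
  expect_warning(
    res <- flag_sex_bias(ev("gA", "s01"),
                         data.table::data.table(sample_id = sprintf("s%02d", 1:10),
                                                sex = "M")),
    "male")
  expect_false(any(res$flagged))
})
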