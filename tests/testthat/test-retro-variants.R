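## tiny deterministic pileup fixture: reads of 20 bp over one exon
mk_pileup_aln <- function(n_ref, n_alt, pos_var = 110L, alt = "T",
                          sample = "s1", genome) {
  ref20 <- substr(genome, 101, 120)
  alt20 <- ref20
  substr(alt20, pos_var - 100 + 1, pos_var - 100 + 1) <- alt
  seqs <- c(rep(ref20, n_ref), rep(alt20, n_alt))
  n <- length(seqs)
  data.table::data.table(
    qname = sprintf("r%03d", seq_len(n)), flag = 0L, chrom = "chr1",
    pos = 100L, mapq = 60L, cigar = "20M", mchrom = "chr1", mpos = 400L,
    tlen = 0L, seq = seqs, paired = TRUE, proper = TRUE, unmapped = FALSE,
    munmapped = FALSE, reverse = FALSE, first_in_pair = TRUE,
    left_clip = 0L, right_clip = 0L, end = 120L, sample = sample)
}

test_that("pileup counts alleles over exons with the r_min presence rule", {
  set.seed(61)
  g <- random_dna(500)
  ref_base <- substr(g, 111, 111)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  gm <- gene_model("g1", "t1", "chr1", "+",
                   data.frame(start = 100, end = 120))
  genome <- c(chr1 = g)

  ## ref-only coverage yields no rows
  tab0 <- pileup_alleles(list(s1 = mk_pileup_aln(30, 0, genome = g)),
                         genome, gm)
  expect_equal(nrow(tab0), 0)

  ## 10 ref + 5 alt: fraction 1/3, present at r_min = 3
  tab <- pileup_alleles(list(s1 = mk_pileup_aln(10, 5, alt = alt,
                                                genome = g)),
                        genome, gm)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pos, 110)
  expect_equal(tab$ref, ref_base)
  expect_equal(tab$alt, alt)
  expect_equal(tab$s1_frac, 5 / 15, tolerance = 1e-12)
  expect_true(tab$s1_present)

  ## 2 alt reads stay below the presence threshold
  two <- pileup_alleles(list(s1 = mk_pileup_aln(20, 2, alt = alt,
                                                genome = g),
                             s2 = mk_pileup_aln(10, 5, alt = alt,
                                                genome = g, sample = "s2")),
                        genome, gm)
  expect_false(two$s1_present)
  expect_true(two$s2_present)
})

test_that("variant attribution conditions on carrier status", {
  tab <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A", alt = "T",
    c1_frac = c(0.3, 0.3, 0), c2_frac = c(0.35, 0, 0),
    c3_frac = c(0.31, 0, 0),
    n1_frac = c(0, 0.5, 0), n2_frac = 0,
    c1_present = c(TRUE, TRUE, FALSE), c2_present = c(TRUE, FALSE, FALSE),
    c3_present = c(TRUE, FALSE, FALSE),
    n1_present = c(FALSE, TRUE, FALSE), n2_present = FALSE)
  att <- attribute_variants(tab, c("c1", "c2", "c3"), c("n1", "n2"))
  ## carriers-only variant -> retrocopy; any non-carrier -> parental;
  ## nobody -> dropped
  expect_equal(att[pos == 10]$attribution, "retrocopy")
  expect_equal(att[pos == 20]$attribution, "parental")
  expect_false(30 %in% att$pos)
  expect_warning(amb <- attribute_variants(tab, c("c1", "c2", "c3"),
                                           character(0)),
                 "ambiguous")
  expect_true(all(amb$attribution == "ambiguous"))
})

test_that("consequence classification matches codon arithmetic cases", {
  ## hand-built gene: 1 exon, CDS from offset 0, known codons
  cds <- "ATGCAACCCGGGTAA"  # M Q P G *
  genome <- c(chr1 = paste0("GGGG", cds, "GGGGGGG"))
  gm <- gene_model("g1", "t1", "chr1", "+",
                   data.frame(start = 4, end = 4 + nchar(cds)),
                   cds_start = 0, cds_end = nchar(cds))
  ## CAA -> TAA at codon-1 position: nonsense
  expect_equal(classify_consequence(genome, gm, 7L, "C", "T")$consequence,
               "nonsense")
  ## CCC -> CCG: synonymous (both proline)
  expect_equal(classify_consequence(genome, gm, 12L, "C", "G")$consequence,
               "synonymous")
  ## GGG -> GAG: missense
  expect_equal(classify_consequence(genome, gm, 14L, "G", "A")$consequence,
               "missense")
  ## 1 bp insertion: frameshift; 33 bp in-frame deletion: 11 codons
  expect_equal(classify_consequence(genome, gm, 7L, "C", "CT")$consequence,
               "frameshift")
  del33 <- classify_consequence(genome, gm, 7L, strrep("C", 34), "C")
  expect_equal(del33$consequence, "inframe_indel")
  expect_equal(del33$codons_changed, 11)
  ## outside any exon: noncoding
  expect_equal(classify_consequence(genome, gm, 1L, "G", "A")$consequence,
               "noncoding")
})

test_that("the classifier agrees with a translate-and-compare oracle", {
  fx <- make_fixture(seed = 62, genome_length = 3e4, n_genes = 2)
  genome <- fx$gen$build$ref
  set.seed(62)
  checked <- 0
  for (gm in fx$gen$models) {
    cds_pos <- retroscout:::tx_to_genome(
      gm, seq(gm$cds_start, gm$cds_end - 1L))
    pos <- sample(cds_pos, 500, replace = TRUE)
    for (p in pos) {
      ref <- substr(genome[["chr1"]], p + 1, p + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- classify_consequence(genome, gm, as.integer(p), ref, alt)
      want <- translate_oracle(genome, gm, as.integer(p), ref, alt)
      expect_equal(got$consequence, want)
      checked <- checked + 1
    }
  }
  expect_equal(checked, 1000)
})

test_that("fixation selection applies the CN-scaled fraction rule", {
  tab <- data.table::data.table(
    chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "T",
    attribution = "retrocopy",
    c1_frac = c(0.93, 0.04), c2_frac = c(0.95, 0.5),
    c1_present = TRUE, c2_present = TRUE)
  cn <- c(c1 = 25, c2 = 25)
  sel <- select_fixed_variants(tab, cn, c("c1", "c2"))
  ## threshold 0.5 * 25/27 = 0.463: site 1 fixed, site 2 fails in c1
  expect_true(sel[pos == 1]$fixed)
  expect_false(sel[pos == 2]$fixed)
  expect_warning(select_fixed_variants(tab, c(c1 = 25), c("c1", "c2")),
                 "copy-number")
})

test_that("masking is positional, involutive, and conflict-checked", {
  set.seed(63)
  fx <- make_fixture(seed = 63, genome_length = 3e4, n_genes = 1)
  gm <- fx$gen$models[[1]]
  genome <- fx$gen$build$ref
  tx <- extract_spliced_transcript(genome, gm)
  exonic <- retroscout:::tx_to_genome(gm, seq(0, transcript_length(gm) - 1))
  pos <- sort(sample(exonic, 15))
  mkrow <- function(p) {
    ref <- substr(genome[["chr1"]], p + 1, p + 1)
    data.table::data.table(chrom = "chr1", pos = as.integer(p), ref = ref,
                           alt = setdiff(c("A", "C", "G", "T"), ref)[1],
                           attribution = "retrocopy", fixed = TRUE)
  }
  fixed <- data.table::rbindlist(lapply(pos, mkrow))
  res <- build_masked_transcript(tx, gm, fixed)
  d <- which(strsplit(res$masked, "")[[1]] != strsplit(tx, "")[[1]])
  expect_equal(length(d), 15)
  expect_true(all(strsplit(res$masked, "")[[1]][d] == "N"))
  expect_equal(nrow(res$sites), 15)
  ## involution: unmasking restores the original transcript exactly
  expect_identical(unmask_transcript(res$masked, res$sites), tx)

  ## no fixed variants: identity
  none <- build_masked_transcript(tx, gm, fixed[0])
  expect_identical(none$masked, tx)

  ## conflicting alleles at one position
  clash <- rbind(fixed[1], fixed[1])
  clash$alt[2] <- setdiff(c("A", "C", "G", "T"),
                          c(clash$ref[1], clash$alt[1]))[1]
  expect_error(build_masked_transcript(tx, gm, clash), "conflict")
})

test_that("attribution is sound end-to-end on a simulated cohort", {
  ## one retro-borne SNV and one parental polymorphism; 2 carriers + 3
  ## non-carriers
  co <- make_cohort(seed = 71, n_carriers = 2, n_non = 3,
                    genome_length = 5e4,
                    retro_variants = NULL, parental_pos = NULL)
  gm <- co$gm
  tx_len <- transcript_length(gm)
  rv <- data.frame(tx_offset = 150L, ref = NA, alt = NA)
  tx <- extract_spliced_transcript(co$fx$gen$build$ref, gm)
  rv$ref <- substr(tx, 151, 151)
  rv$alt <- c(A = "C", C = "G", G = "T", T = "A")[[rv$ref]]
  par_pos <- retroscout:::tx_to_genome(gm, 300L)
  co <- make_cohort(seed = 71, n_carriers = 2, n_non = 3,
                    genome_length = 5e4, retro_variants = rv,
                    parental_pos = par_pos)
  tab <- pileup_alleles(co$alns, co$fx$gen$build$ref, gm)
  att <- attribute_variants(tab, co$carriers, co$non_carriers)
  rv_gpos <- retroscout:::tx_to_genome(gm, 150L)
  expect_equal(att[pos == rv_gpos]$attribution, "retrocopy")
  expect_equal(att[pos == par_pos]$attribution, "parental")
})
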