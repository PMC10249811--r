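test_that("genome generation is deterministic and respects the config", {
  cfg <- sim_config(seed = 3, genome_length = 3e4, n_genes = 3,
                    exons_per_gene = c(4, 4))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$build$ref, g2$build$ref)
  expect_identical(lapply(g1$models, `[[`, "exons"),
                   lapply(g2$models, `[[`, "exons"))
  expect_equal(sum(vapply(g1$models, function(m) nrow(m$exons), 1L)), 12)
  expect_error(generate_genome(sim_config(seed = 1, genome_length = 1000,
                                          n_genes = 50)),
               "too small")
})

test_that("config validation rejects out-of-range settings", {
  expect_error(sim_config(error_rate = 0.1), "error_rate")
  expect_error(sim_config(coverage = -1))
  expect_error(sim_config(intron_size = c(50, 100)), "intron")
})

test_that("retrocopy insertion obeys TSD, conservation, and anatomy rules", {
  fx <- make_fixture(seed = 21, genome_length = 5e4, n_genes = 2)
  gm <- fx$gen$models[[1]]
  site <- pick_insertion_sites(fx$gen$models, 1L, 5e4)$site
  b0 <- fx$gen$build
  tx <- extract_spliced_transcript(b0$ref, gm)

  ## identity case: no skipping, no truncation, no poly(A)
  b <- insert_retrocopy(b0, gm, "chr1", site, tsd_length = 10L,
                        polyA_length = 0L)
  ev <- b$truth$events
  g <- b$seq[["chr1"]]
  ins <- substr(g, site + 1, site + ev$retro_len)
  expect_identical(ins, tx)
  ## TSD: bases 5' of the insertion repeat right after the insert
  expect_identical(substr(g, site - 10 + 1, site),
                   substr(g, site + ev$retro_len + 1,
                          site + ev$retro_len + 10))
  expect_identical(ev$tsd_seq, substr(g, site - 10 + 1, site))
  ## length conservation
  expect_equal(nchar(g), nchar(b0$seq[["chr1"]]) + ev$retro_len + 10)

  ## exon skipping and poly(A) arithmetic
  lens <- gm$exons$end - gm$exons$start
  b2 <- insert_retrocopy(b0, gm, "chr1", site, tsd_length = 17L,
                         skipped_exons = 2L, polyA_length = 30L)
  ev2 <- b2$truth$events
  expect_equal(ev2$retro_len, sum(lens[-2]))
  expect_equal(nchar(b2$seq[["chr1"]]),
               nchar(b0$seq[["chr1"]]) + sum(lens[-2]) + 30 + 17)

  ## contract violations
  expect_error(insert_retrocopy(b0, gm, "chr1", site, tsd_length = 5L),
               "10-31")
  expect_error(insert_retrocopy(b0, gm, "chr1", site,
                                five_prime_truncation = sum(lens)),
               "truncation")
  expect_error(insert_retrocopy(b0, gm, "chr1", site,
                                skipped_exons = 1L),
               "first or last")
  inside <- gm$exons$start[1] + 5L
  expect_error(insert_retrocopy(b0, gm, "chr1", inside), "inside the parent")
})

test_that("minus-strand insertions carry the reverse-complement transcript", {
  fx <- make_fixture(seed = 22, genome_length = 5e4, n_genes = 2)
  gm <- fx$gen$models[[1]]
  site <- pick_insertion_sites(fx$gen$models, 1L, 5e4)$site
  tx <- extract_spliced_transcript(fx$gen$build$ref, gm)
  b <- insert_retrocopy(fx$gen$build, gm, "chr1", site, tsd_length = 12L,
                        polyA_length = 5L, strand = "-")
  ev <- b$truth$events
  ins <- substr(b$seq[["chr1"]], site + 1, site + ev$retro_len + 5)
  expect_identical(ins, revcomp(paste0(tx, strrep("A", 5))))
})

test_that("segment amplification writes shared and private variants per copy", {
  fx <- make_fixture(seed = 23, genome_length = 5e4, n_genes = 2)
  gm <- fx$gen$models[[1]]
  site <- pick_insertion_sites(fx$gen$models, 1L, 5e4)$site
  b <- insert_retrocopy(fx$gen$build, gm, "chr1", site, tsd_length = 17L)
  ev <- b$truth$events
  ins_len <- ev$retro_len + ev$polyA_length + ev$tsd_length
  a <- site - 500L
  z <- site + ins_len + 500L

  ## copy_count = 1 leaves the sequence unchanged
  b1 <- amplify_segment(b, "chr1", a, z, 1L)
  expect_identical(b1$seq, b$seq)
  expect_error(amplify_segment(b, "chr1", a, z, 0L), ">= 1")

  ## a shared variant appears in all 25 copies
  tx <- b$truth$retro_tx[["1"]]
  off <- 100L
  refb <- substr(tx, off + 1, off + 1)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  sv <- data.frame(tx_offset = off, ref = refb, alt = altb)
  set.seed(77)
  b25 <- amplify_segment(b, "chr1", a, z, 25L, shared_variants = sv,
                         private_variant_rate = 0.002)
  expect_equal(b25$truth$events$copy_count, 25)
  unit_len <- z - a
  for (j in 0:24) {
    p <- a + j * unit_len + (site - a) + off
    expect_identical(substr(b25$seq[["chr1"]], p + 1, p + 1), altb)
  }
  expect_equal(nchar(b25$seq[["chr1"]]),
               nchar(b$seq[["chr1"]]) + 24L * unit_len)
  priv <- b25$truth$variants[copy > 0]
  expect_true(all(priv$copy %in% 1:25))

  ## private variants reproducible under a fixed seed
  set.seed(77)
  b25b <- amplify_segment(b, "chr1", a, z, 25L, shared_variants = sv,
                          private_variant_rate = 0.002)
  expect_identical(b25$truth$variants, b25b$truth$variants)
  expect_identical(b25$seq, b25b$seq)
})

test_that("lineage divergence follows the molecular-clock Poisson model", {
  set.seed(1)
  s <- random_dna(2000)
  expect_equal(simulate_lineage_divergence(lineage_spec(0), s)$n_sub, 0)

  ## Poisson mean for the target age that gives d = 0.0145 on one lineage:
  ## 2000 * 7.24e-9 * 16022099 / 8 = 29.0
  spec <- lineage_spec(target_age = 16022099, mu = 7.24e-9, g = 8, k_lin = 1)
  expect_equal(2000 * 7.24e-9 * 1 * 16022099 / 8, 29.0, tolerance = 1e-4)
  n <- 4000
  subs <- vapply(seq_len(n), function(i) {
    simulate_lineage_divergence(spec, s)$n_sub
  }, numeric(1))
  se <- sqrt(29.0 / n)
  expect_lt(abs(mean(subs) - 29.0), 3 * se)
  ## substitutions land at distinct positions, each to a different base
  one <- simulate_lineage_divergence(spec, s)
  diffs <- which(strsplit(one$seq, "")[[1]] != strsplit(s, "")[[1]])
  expect_equal(length(diffs), one$n_sub)

  expect_error(
    simulate_lineage_divergence(lineage_spec(1e12), s), "saturated")
})

test_that("read simulation yields the configured coverage and exact bases", {
  cfg <- sim_config(seed = 4, genome_length = 1e5, n_genes = 0,
                    coverage = 20, error_rate = 0)
  gen <- generate_genome(cfg)
  rr <- simulate_reads(gen$build, cfg, emit_sam = FALSE)
  ## fragment count = coverage * length / (2 * read_length)
  expect_equal(nrow(rr$reads), round(20 * 1e5 / (2 * 100)))
  ## with zero error rate every base matches its source
  g <- gen$build$seq[["chr1"]]
  aln <- simulate_reads(gen$build, cfg)$aln
  sub <- aln[!unmapped & left_clip == 0 & right_clip == 0][1:200]
  ## SEQ is reference-forward, so it must equal the genome substring
  expect_identical(unname(substring(g, sub$pos + 1, sub$end)), sub$seq)
})

test_that("mates inside an implanted retrocopy map to parent exons, discordant", {
  fx <- make_fixture(seed = 31, genome_length = 1e5, n_genes = 2,
                     error_rate = 0)
  gm <- fx$gen$models[[1]]
  site <- pick_insertion_sites(fx$gen$models, 1L, 1e5)$site
  b <- insert_retrocopy(fx$gen$build, gm, "chr1", site, tsd_length = 17L)
  rr <- simulate_reads(b, fx$cfg)
  ev <- b$truth$events
  sp <- range(c(gm$exons$start, gm$exons$end))
  ## reads near the insertion whose mates are at the parent gene
  near <- rr$aln[!unmapped & !munmapped &
                   pos < ev$insertion_point + 500 &
                   end > ev$insertion_point - 500 &
                   abs(mpos - pos) > 10000]
  expect_gt(nrow(near), 0)
  expect_true(all(near$mpos >= sp[1] - 200 & near$mpos <= sp[2] + 200))
  expect_true(all(!near$proper))
})

test_that("simulated read pairs are byte-identical under a fixed seed", {
  fx <- make_fixture(seed = 6, genome_length = 2e4, n_genes = 1,
                     coverage = 5)
  r1 <- simulate_reads(fx$gen$build, fx$cfg)
  r2 <- simulate_reads(fx$gen$build, fx$cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$aln, r2$aln)
  r3 <- simulate_reads(fx$gen$build, fx$cfg, seed = 999)
  expect_false(identical(r1$reads, r3$reads))
})

test_that("RNA-seq simulation honours pool proportions and truth labels", {
  cfg <- sim_config(seed = 8, read_length = 75, insert_mean = 200,
                    insert_sd = 20, error_rate = 0)
  set.seed(8)
  parent <- random_dna(1500)
  retro <- parent
  substr(retro, 700, 700) <- if (substr(parent, 700, 700) == "A") "C" else "A"
  pool <- c(parent = parent, retro = retro)

  one <- simulate_rnaseq(pool, c(parent = 1.0), 500, cfg)
  expect_true(all(one$labels$source == "parent"))

  mix <- simulate_rnaseq(pool, c(parent = 0.2, retro = 0.8), 10000, cfg)
  frac <- mean(mix$labels$source == "retro")
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(frac - 0.8), 3 * se)

  expect_error(simulate_rnaseq(pool, c(parent = 0.5, retro = 0.4), 10, cfg),
               "sum to 1")
  expect_error(simulate_rnaseq(character(0), numeric(0), 10, cfg), "empty")
})
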