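#' Validate a pipeline configuration
#'
#' The configuration is a named list with components:
#' \describe{
#'   \item{out_dir}{artifact directory.}
#'   \item{seed}{integer master seed.}
#'   \item{samples}{character vector of sample ids.}
#'   \item{sim}{arguments for [sim_config()].}
#'   \item{events}{list of [insert_retrocopy()] argument lists, keyed by
#'     `gene` (index into the generated models) plus the insertion
#'     parameters.}
#'   \item{params}{thresholds: `k`, `max_mismatch`, `t_min`, `f_min`,
#'     `d_max`, `cluster_window`, `min_support`, `r_min`, `tau_fixed`,
#'     `mu`, `g`, `k_lin`.}
#' }
#' Unknown parameter names and invalid values are rejected.
#'
#' @param config configuration list.
#' @return the config with defaults filled in.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  config$seed <- as.integer(config$seed %||% 1L)
  config$samples <- config$samples %||% c("sample1", "sample2")
  defaults <- list(k = 30L, max_mismatch = 2L, t_min = 5L, f_min = 0.10,
                   d_max = 10000L, cluster_window = 500L, min_support = 4L,
                   r_min = 3L, tau_fixed = 0.5, mu = 7.24e-9, g = 8,
                   k_lin = 1L)
  p <- config$params %||% list()
  bad <- setdiff(names(p), names(defaults))
  if (length(bad)) stop2("unknown parameter(s): ", paste(bad, collapse = ", "))
  config$params <- utils::modifyList(defaults, p)
  if (config$params$f_min < 0 || config$params$f_min > 1) {
    stop2("f_min must be a fraction")
  }
  sim_args <- config$sim %||% list()
  sim_args$seed <- sim_args$seed %||% config$seed
  config$sim_config <- do.call(sim_config, sim_args)  # validates
  config
}

stage_done <- function(manifest, stage) {
  !is.null(manifest$stages[[stage]]) &&
    all(file.exists(manifest$stages[[stage]]$outputs))
}

#' Run the retroCNV pipeline end to end on a simulated cohort
#'
#' Stages run in dependency order: genome simulation, k-mer inventory,
#' read scan, parent-gene calling, insertion resolution, variant
#' attribution, and cohort summary. Every artifact is recorded in a
#' manifest (`manifest.json`) with the parameters and seed that produced
#' it; re-running with an up-to-date manifest skips completed stages.
#'
#' @param config see [validate_config()].
#' @return invisible list with the in-memory results (`calls`,
#'   `insertions`, `summary`, `truth`) and the artifact directory.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else {
    list(version = as.character(utils::packageVersion("retroscout")),
         seed = config$seed, params = config$params, stages = list())
  }
  p <- config$params
  record <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(outputs = outputs,
                                      time = format(Sys.time()))
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  }

  ## stage: simulate ---------------------------------------------------
  paths <- list(fasta = file.path(out, "ref.fa"),
                gff = file.path(out, "genes.gff3"),
                truth = file.path(out, "truth.tsv"))
  set.seed(config$seed)
  gen <- generate_genome(config$sim_config)
  builds <- list()
  for (s in config$samples) builds[[s]] <- gen$build
  events <- config$events %||% list()
  ## fill in unspecified insertion sites with safe intergenic positions;
  ## descending site order keeps remaining coordinates unshifted as the
  ## insertions are applied
  need <- which(vapply(events, function(e) is.null(e$site_pos), logical(1)))
  if (length(need)) {
    picked <- pick_insertion_sites(
      gen$models, vapply(events[need], `[[`, integer(1), "gene"),
      config$sim_config$genome_length)
    for (j in seq_along(need)) {
      events[[need[j]]]$site_pos <- picked[parent == events[[need[j]]]$gene]$site[1]
    }
  }
  events <- events[order(-vapply(events, `[[`, numeric(1), "site_pos"))]
  for (ev in events) {
    gm <- gen$models[[ev$gene]]
    carriers <- ev$carriers %||% config$samples
    for (s in intersect(carriers, config$samples)) {
      builds[[s]] <- insert_retrocopy(
        builds[[s]], gm, ev$site_chrom %||% gm$chrom, ev$site_pos,
        tsd_length = ev$tsd_length %||% 17L,
        skipped_exons = ev$skipped_exons %||% integer(),
        polyA_length = ev$polyA_length %||% 30L,
        strand = ev$strand %||% "+")
    }
  }
  if (!stage_done(manifest, "simulate")) {
    write_fasta(gen$build$ref, paths$fasta)
    write_gff3(gen$models, paths$gff)
    tdt <- data.table::rbindlist(lapply(names(builds), function(s) {
      ev <- builds[[s]]$truth$events
      if (is.null(ev)) return(NULL)
      cbind(sample_id = s, ev)
    }), fill = TRUE)
    write_tsv(tdt %||% data.table::data.table(), paths$truth)
    record("simulate", unlist(paths))
  }

  reads <- list(); alns <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[i]
    rr <- simulate_reads(builds[[s]], config$sim_config, sample_id = s,
                         seed = config$seed * 1000L + i)
    reads[[s]] <- rr$reads
    alns[[s]] <- rr$aln
  }

  ## stage: kmers ------------------------------------------------------
  inv_path <- file.path(out, "kmer_inventory.tsv")
  if (stage_done(manifest, "kmers")) {
    inv <- read_kmer_inventory(inv_path)
  } else {
    inv <- build_specific_kmers(gen$build$ref, gen$models, k = p$k,
                                max_mismatch = p$max_mismatch)
    write_kmer_inventory(inv, inv_path)
    record("kmers", inv_path)
  }

  ## stage: scan + call ------------------------------------------------
  calls_path <- file.path(out, "parent_calls.tsv")
  calls <- data.table::rbindlist(lapply(config$samples, function(s) {
    cnt <- scan_reads(inv, c(reads[[s]]$seq1, reads[[s]]$seq2))
    call_parent_genes(cnt, t_min = p$t_min, f_min = p$f_min, sample_id = s)
  }))
  if (!stage_done(manifest, "call")) {
    write_tsv(calls, calls_path)
    record("call", calls_path)
  }

  ## stage: resolve ----------------------------------------------------
  ins_path <- file.path(out, "insertions.tsv")
  called_genes <- unique(calls[called == TRUE]$gene_id)
  called_models <- Filter(function(m) m$gene_id %in% called_genes,
                          gen$models)
  insertions <- resolve_insertions(alns, called_models, gen$build$ref,
                                   d_max = p$d_max,
                                   cluster_window = p$cluster_window,
                                   min_support = p$min_support)
  if (!stage_done(manifest, "resolve")) {
    write_tsv(insertions, ins_path)
    bed <- insertions[resolved == TRUE,
                      .(chrom, start, end, name = gene_id,
                        score = discordant_support, strand = "+")]
    write_bed(bed, file.path(out, "insertions.bed"))
    vcf <- insertions[resolved == TRUE,
                      .(chrom, pos = start, id = gene_id, ref = "N",
                        alt = "<INS>",
                        info = sprintf("TSD=%s;TSDLEN=%d;SUPPORT=%d",
                                       tsd_seq, tsd_length,
                                       discordant_support))]
    write_vcf(vcf, file.path(out, "insertions.vcf"),
              info_header = c(
                "INFO=<ID=TSD,Number=1,Type=String,Description=\"TSD sequence\">",
                "INFO=<ID=TSDLEN,Number=1,Type=Integer,Description=\"TSD length\">",
                "INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Discordant support\">"))
    record("resolve", ins_path)
  }

  ## stage: attribute --------------------------------------------------
  var_path <- file.path(out, "variants.tsv")
  variants <- list()
  for (gm in called_models) {
    carr <- calls[gene_id == gm$gene_id & called == TRUE]$sample_id
    nonc <- setdiff(config$samples, carr)
    tab <- pileup_alleles(alns, gen$build$ref, gm, r_min = p$r_min)
    if (nrow(tab) == 0L) next
    att <- suppressWarnings(attribute_variants(tab, carr, nonc))
    att[, gene_id := gm$gene_id]
    variants[[gm$gene_id]] <- att
  }
  variants <- if (length(variants)) {
    data.table::rbindlist(variants, fill = TRUE)
  } else {
    data.table::data.table(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           attribution = character(), gene_id = character())
  }
  if (!stage_done(manifest, "attribute")) {
    write_tsv(variants, var_path)
    record("attribute", var_path)
  }

  ## stage: summarize --------------------------------------------------
  sum_path <- file.path(out, "cohort_summary.tsv")
  carriers <- calls[called == TRUE, .(retrocnv = gene_id,
                                      sample_id = sample_id)]
  pops <- config$populations %||%
    setNames(rep("cohort", length(config$samples)), config$samples)
  summary <- summarize_cohort(carriers, pops)
  if (!stage_done(manifest, "summarize")) {
    write_tsv(summary$per_retrocnv, sum_path)
    record("summarize", sum_path)
  }

  invisible(list(dir = out, calls = calls, insertions = insertions,
                 variants = variants, summary = summary,
                 truth = lapply(builds, function(b) b$truth$events)))
}

#' Summarize retroCNV carriers across a cohort
#'
#' Set algebra over carrier lists: per-sample counts, per-retroCNV
#' carrier frequency, and counts of retroCNVs exclusive to each
#' population.
#'
#' @param carriers data.table with `retrocnv`, `sample_id` (one row per
#'   carried retroCNV).
#' @param populations named character vector: population label per sample
#'   id.
#' @return list of data.tables: `per_sample`, `per_retrocnv`,
#'   `exclusivity` (per population: retroCNVs found in it and nowhere
#'   else).
#' @export
summarize_cohort <- function(carriers, populations) {
  carriers <- data.table::as.data.table(carriers)
  bad <- setdiff(carriers$sample_id, names(populations))
  if (length(bad)) stop2("unknown sample(s): ", paste(bad, collapse = ", "))
  all_samples <- names(populations)
  per_sample <- carriers[, .(n_retrocnv = .N), by = sample_id]
  missing <- setdiff(all_samples, per_sample$sample_id)
  if (length(missing)) {
    per_sample <- data.table::rbindlist(list(
      per_sample, data.table::data.table(sample_id = missing,
                                         n_retrocnv = 0L)))
  }
  per_sample[, population := populations[sample_id]]
  n_samp <- length(all_samples)
  per_retrocnv <- carriers[, .(
    carriers = paste(sort(sample_id), collapse = ","),
    n_carriers = .N,
    carrier_frequency = .N / n_samp,
    populations = paste(sort(unique(populations[sample_id])),
                        collapse = ",")), by = retrocnv]
  excl <- per_retrocnv[!grepl(",", populations),
                       .(n_exclusive = .N), by = populations]
  data.table::setnames(excl, "populations", "population")
  all_pops <- unique(populations)
  mp <- setdiff(all_pops, excl$population)
  if (length(mp)) {
    excl <- data.table::rbindlist(list(
      excl, data.table::data.table(population = mp, n_exclusive = 0L)))
  }
  list(per_sample = per_sample[order(sample_id)],
       per_retrocnv = per_retrocnv[order(retrocnv)],
       exclusivity = excl[order(population)])
}
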