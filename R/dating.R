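#' Count substitutions between a retrocopy and its parent transcript
#'
#' Accepts either two unaligned sequences — globally aligned here with
#' Needleman-Wunsch scoring (match 1, mismatch -1, gap -2), suitable for
#' the near-identical pairs this package dates — or a precomputed pairwise
#' alignment as two equal-length gapped strings. Substitutions are counted
#' over ungapped columns only; gap columns contribute to neither the count
#' nor the aligned length.
#'
#' @param seq_a,seq_b the two sequences (retrocopy and parent transcript;
#'   the count is symmetric).
#' @param aligned logical; TRUE when `seq_a`/`seq_b` are already gapped
#'   alignment rows.
#' @return data.table: `substitutions`, `aligned_length`, `divergence`.
#' @export
count_divergence <- function(seq_a, seq_b, aligned = FALSE) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop2("empty sequence")
  if (!aligned) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 0, gapExtension = 2)
    seq_a <- as.character(Biostrings::alignedPattern(al))
    seq_b <- as.character(Biostrings::alignedSubject(al))
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    stop2("aligned rows differ in length")
  }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  ungapped <- a != "-" & b != "-"
  L <- sum(ungapped)
  if (L == 0L) stop2("alignment has no ungapped columns")
  S <- sum(a[ungapped] != b[ungapped])
  data.table::data.table(substitutions = S, aligned_length = L,
                         divergence = S / L)
}

#' Convert divergence to an age under a molecular clock
#'
#' `age_years = (S / L) / (k_lin * mu) * g`, with `mu` in substitutions
#' per site per generation and `g` in years per generation. `k_lin = 1`
#' attributes all divergence to one lineage (the default, matching the
#' arithmetic used for retrocopy-parent pairs where the parent is assumed
#' conserved); `k_lin = 2` halves the age by spreading substitutions over
#' both lineages.
#'
#' @param divergence a row from [count_divergence()].
#' @param mu substitution rate per site per generation (default 7.24e-9,
#'   the rate estimated for horses).
#' @param g generation time in years (default 8).
#' @param k_lin lineage factor, 1 or 2.
#' @return data.table extending the divergence record with `mu`, `g`,
#'   `k_lin`, `age_years`.
#' @export
estimate_age <- function(divergence, mu = 7.24e-9, g = 8, k_lin = 1L) {
  stopifnot(mu > 0, g > 0, k_lin %in% c(1L, 2L))
  d <- data.table::as.data.table(divergence)
  if (any(d$aligned_length == 0L)) stop2("aligned_length must be positive")
  d[, `:=`(mu = mu, g = g, k_lin = as.integer(k_lin),
           age_years = (substitutions / aligned_length) / (k_lin * mu) * g)]
  d[]
}

#' Aggregate per-haplotype age estimates
#'
#' @param ages numeric vector of age estimates (years).
#' @return list: `mean`, `ci` (95 percent Student-t interval, NULL when
#'   n < 2), `range`, `n`.
#' @export
aggregate_ages <- function(ages) {
  n <- length(ages)
  if (n == 0L) stop2("no age estimates")
  m <- mean(ages)
  ci <- NULL
  if (n >= 2L) {
    se <- sd(ages) / sqrt(n)
    tq <- qt(0.975, n - 1L)
    ci <- c(m - tq * se, m + tq * se)
  }
  list(mean = m, ci = ci, range = range(ages), n = n)
}

## leaf bipartitions (as sorted label sets) of an hclust tree
tree_clades <- function(hc, labels) {
  n <- length(labels)
  members <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(j) if (j < 0) labels[-j] else members[[j]]
    members[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
    out[[i]] <- members[[i]]
  }
  out
}

#' Cluster variant profiles with bootstrap support
#'
#' Hierarchical clustering (Euclidean distance, average linkage) of a
#' binary variant-presence matrix, with node support computed as the
#' fraction of bootstrap replicates — columns resampled with replacement —
#' whose tree contains the same leaf set under some node. Deterministic
#' for a fixed seed.
#'
#' @param mat numeric/binary matrix, rows = sequences, columns = variant
#'   sites.
#' @param n_bootstrap bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return list: `hclust`, `phylo` (an [ape::phylo] with node support as
#'   labels), `support` (data.table `clade`, `support`).
#' @export
cluster_profiles <- function(mat, n_bootstrap = 1000L, seed = 1L) {
  stopifnot(nrow(mat) >= 3L)
  if (n_bootstrap < 100L) stop2("n_bootstrap must be >= 100")
  if (all(stats::dist(mat) == 0)) stop2("constant matrix: all distances zero")
  set.seed(seed)
  labels <- rownames(mat) %||% paste0("row", seq_len(nrow(mat)))
  rownames(mat) <- labels
  hc <- stats::hclust(stats::dist(mat), method = "average")
  ref_clades <- tree_clades(hc, labels)
  keys <- vapply(ref_clades, paste, character(1), collapse = "\r")
  hits <- integer(length(keys))
  for (b in seq_len(n_bootstrap)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    mb <- mat[, cols, drop = FALSE]
    db <- stats::dist(mb)
    if (all(db == 0)) next
    hb <- stats::hclust(db, method = "average")
    kb <- vapply(tree_clades(hb, labels), paste, character(1),
                 collapse = "\r")
    hits <- hits + (keys %in% kb)
  }
  support <- hits / n_bootstrap
  phy <- ape::as.phylo(hc)
  ## ape internal node order: match clades by their tip sets
  phy_clades <- lapply(seq_len(phy$Nnode) + length(labels), function(nd) {
    sort(ape::extract.clade(phy, nd)$tip.label)
  })
  phy_keys <- vapply(phy_clades, paste, character(1), collapse = "\r")
  phy$node.label <- as.character(round(support[match(phy_keys, keys)], 3))
  list(hclust = hc, phylo = phy,
       support = data.table::data.table(
         clade = vapply(ref_clades, paste, character(1), collapse = ","),
         support = support))
}

#' Write a clustered profile tree as Newick with support values
#' @param clust result of [cluster_profiles()].
#' @param path output path.
#' @export
write_profile_tree <- function(clust, path) {
  ape::write.tree(clust$phylo, file = path)
  invisible(path)
}
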