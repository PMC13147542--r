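#' Specification of a synthetic biparental haploid cross
#'
#' Emulates a segregant library from a cross of two parents. Markers come
#' in tight clusters in perfect linkage (all markers of a cluster report
#' the same haplotype -- these clusters are the haplotype blocks the
#' mapping collapses to), while recombination between adjacent clusters is
#' close to free, so the blocks are nearly independent mapping units. Each
#' strain's chromosome is a two-state Markov chain over the clusters, one
#' cluster carries a planted quantitative trait locus, and a fraction of
#' calls is masked as missing.
#'
#' The default geometry (2 chromosomes x 4 clusters x 25 markers = 200
#' markers collapsing to 8 blocks) keeps the block count below the
#' `n_perm > n_blocks / alpha` attainability bound of [min_permutations()]
#' for permutation nulls of a few hundred draws.
#'
#' @param n_strains number of segregants (default 100).
#' @param n_chrom number of chromosomes (default 2).
#' @param blocks_per_chrom marker clusters (haplotype blocks) per
#'   chromosome (default 4).
#' @param markers_per_block markers per cluster, in perfect linkage
#'   (default 25).
#' @param marker_spacing genomic distance between adjacent markers of the
#'   same cluster in bp (default 1000; markers of a block are physically
#'   close).
#' @param block_gap genomic gap between adjacent clusters in bp (default
#'   50000, much larger than the within-cluster span, so the nearest
#'   called marker of any masked call lies within its own cluster).
#' @param recomb recombination probability between adjacent clusters
#'   (default 0.45, near-free recombination; within clusters it is 0).
#' @param qtl_chrom,qtl_block chromosome and cluster index of the planted
#'   QTL (defaults 1 and 2).
#' @param effect phenotype shift of the `P2` QTL allele, in units of the
#'   residual standard deviation (default 2).
#' @param noise_sd residual phenotype standard deviation (default 1).
#' @param missing_rate fraction of genotype calls masked (default 0.05).
#' @param seed integer seed.
#' @return An object of class `cross_spec`.
#' @export
cross_spec <- function(n_strains = 100, n_chrom = 2, blocks_per_chrom = 4,
                       markers_per_block = 25, marker_spacing = 1000,
                       block_gap = 50000, recomb = 0.45, qtl_chrom = 1,
                       qtl_block = 2, effect = 2, noise_sd = 1,
                       missing_rate = 0.05, seed = 1) {
  stopifnot(n_strains >= 2, recomb >= 0, recomb <= 1,
            missing_rate >= 0, missing_rate < 1, is.finite(effect),
            qtl_chrom <= n_chrom, qtl_block <= blocks_per_chrom,
            blocks_per_chrom >= 1, markers_per_block >= 1)
  structure(list(n_strains = n_strains, n_chrom = n_chrom,
                 blocks_per_chrom = blocks_per_chrom,
                 markers_per_block = markers_per_block,
                 marker_spacing = marker_spacing, block_gap = block_gap,
                 recomb = recomb,
                 qtl_chrom = qtl_chrom, qtl_block = qtl_block,
                 effect = effect, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = seed),
            class = "cross_spec")
}

#' Simulate a segregant cross with one planted QTL
#'
#' @param spec a [cross_spec()].
#' @return list with `genotypes` (a [genotype_matrix()] carrying the
#'   missing calls), `phenotype` (named numeric, one value per strain) and
#'   `truth`: `qtl_chrom`, `qtl_pos` (position of the QTL cluster's first
#'   marker), `qtl_index` (column index of that marker),
#'   `breakpoint_blocks` (number of haplotype blocks implied by the
#'   simulated recombination events) and `full_geno` (the unmasked
#'   [genotype_matrix()]).
#' @export
simulate_cross <- function(spec) {
  stopifnot(inherits(spec, "cross_spec"))
  mpb <- spec$markers_per_block
  bpc <- spec$blocks_per_chrom
  m <- mpb * bpc  # markers per chromosome
  chrom_pos <- as.vector(vapply(seq_len(bpc), function(b) {
    (b - 1) * ((mpb - 1) * spec$marker_spacing + spec$block_gap) +
      seq_len(mpb) * spec$marker_spacing
  }, numeric(mpb)))
  markers <- data.frame(
    chrom = rep(paste0("chr", seq_len(spec$n_chrom)), each = m),
    pos = rep(chrom_pos, spec$n_chrom)
  )
  out <- withr::with_seed(spec$seed, {
    geno <- matrix(NA_character_, spec$n_strains, nrow(markers))
    for (ch in seq_len(spec$n_chrom)) {
      start <- rbinom(spec$n_strains, 1, 0.5)
      switches <- matrix(rbinom(spec$n_strains * (bpc - 1), 1, spec$recomb),
                         spec$n_strains, bpc - 1)
      states <- (start + cbind(0, t(apply(switches, 1, cumsum)))) %% 2
      block_geno <- ifelse(states == 1, "P2", "P1")
      cols <- (ch - 1) * m + seq_len(m)
      geno[, cols] <- block_geno[, rep(seq_len(bpc), each = mpb)]
    }
    qtl_index <- (spec$qtl_chrom - 1) * m +
      (spec$qtl_block - 1) * mpb + 1L
    phenotype <- spec$effect * (geno[, qtl_index] == "P2") +
      rnorm(spec$n_strains, 0, spec$noise_sd)
    full <- geno
    if (spec$missing_rate > 0) {
      mask <- runif(length(geno)) < spec$missing_rate
      geno[mask] <- NA_character_
    }
    list(geno = geno, full = full, phenotype = phenotype,
         qtl_index = qtl_index)
  })
  # block boundaries implied by the simulated recombination events: adjacent
  # markers merge iff no strain differs between them
  boundaries <- 0L
  for (ch in seq_len(spec$n_chrom)) {
    cols <- (ch - 1) * m + seq_len(m)
    g <- out$full[, cols, drop = FALSE]
    boundaries <- boundaries +
      sum(vapply(seq_len(m - 1), function(j) any(g[, j] != g[, j + 1]),
                 logical(1)))
  }
  rownames(out$geno) <- paste0("S", seq_len(spec$n_strains))
  rownames(out$full) <- rownames(out$geno)
  list(
    genotypes = genotype_matrix(out$geno, markers),
    phenotype = setNames(out$phenotype, rownames(out$geno)),
    truth = list(
      qtl_chrom = paste0("chr", spec$qtl_chrom),
      qtl_pos = markers$pos[out$qtl_index],
      qtl_index = out$qtl_index,
      breakpoint_blocks = spec$n_chrom + boundaries,
      full_geno = genotype_matrix(out$full, markers)
    )
  )
}
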