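#' Collapse markers into haplotype blocks
#'
#' Adjacent markers whose genotype columns are identical across all strains
#' (including the missingness pattern) carry no independent information and
#' are merged into a single haplotype block; the reduced matrix has one
#' column per block. Blocks never span chromosomes.
#'
#' @param gm a [genotype_matrix()] (imputed with [impute_flanked()] first,
#'   ideally).
#' @return list with `blocks` (data.frame: `block`, `chrom`, `pos`
#'   (representative = median member position), `start`, `end`,
#'   `n_markers`), `geno` (strains x blocks character matrix) and `mapping`
#'   (block index of each original marker).
#' @export
collapse_blocks <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  geno <- gm$geno
  keys <- apply(geno, 2, function(col) paste(ifelse(is.na(col), ".", col),
                                             collapse = ""))
  n_markers <- length(keys)
  block_of <- integer(n_markers)
  b <- 0L
  for (j in seq_len(n_markers)) {
    new_block <- j == 1L ||
      gm$markers$chrom[j] != gm$markers$chrom[j - 1L] ||
      keys[j] != keys[j - 1L]
    if (new_block) b <- b + 1L
    block_of[j] <- b
  }
  blocks <- do.call(rbind, lapply(split(seq_len(n_markers), block_of),
                                  function(j) {
    data.frame(block = block_of[j[1]],
               chrom = gm$markers$chrom[j[1]],
               pos = median(gm$markers$pos[j]),
               start = min(gm$markers$pos[j]),
               end = max(gm$markers$pos[j]),
               n_markers = length(j))
  }))
  rownames(blocks) <- NULL
  reduced <- geno[, !duplicated(block_of), drop = FALSE]
  colnames(reduced) <- paste0("B", blocks$block)
  list(blocks = blocks, geno = reduced, mapping = block_of)
}

# numeric 0/1 coding of a haplotype matrix; residual missing values are
# filled with the column's majority label
.code_genotypes <- function(geno) {
  X <- matrix(0, nrow(geno), ncol(geno))
  for (j in seq_len(ncol(geno))) {
    col <- geno[, j]
    if (anyNA(col)) {
      tab <- table(col)
      col[is.na(col)] <- names(tab)[which.max(tab)]
    }
    X[, j] <- as.numeric(col == "P2")
  }
  X
}

#' Random-forest selection frequency of haplotype blocks
#'
#' Trains `n_forests` independent regression forests of `n_trees` trees
#' each (bootstrap rows, `mtry` random candidate features per split, binary
#' haplotype splits) and scores every block by its *selection frequency*:
#' the fraction of all trees in which the block is chosen for at least one
#' split. Because candidate features compete within each node, a block's
#' frequency reflects its explanatory power relative to the rest of the
#' genome, and tree structure lets linked and epistatic blocks share
#' splits.
#'
#' @param geno strains x blocks character matrix of `"P1"`/`"P2"` codes
#'   (residual `NA`s are filled with the column majority), or the list
#'   returned by [collapse_blocks()].
#' @param phenotype numeric phenotype, one value per strain.
#' @param n_forests,n_trees forest ensemble size (defaults 100 x 100).
#' @param mtry candidate features per split; default `ceiling(sqrt(p))`.
#' @param min_leaf minimum rows per child node (default 5).
#' @param root_only count only root splits instead of all splits
#'   (default `FALSE`).
#' @param seed optional integer seed.
#' @return object of class `importance_profile`: `frequency` (named numeric
#'   in `[0, 1]`), `n_forests`, `n_trees`, `seed`, `constant_phenotype`.
#' @export
selection_frequency <- function(geno, phenotype, n_forests = 100,
                                n_trees = 100, mtry = NULL, min_leaf = 5,
                                root_only = FALSE, seed = NULL) {
  if (is.list(geno) && !is.null(geno$geno)) geno <- geno$geno
  stopifnot(is.matrix(geno), nrow(geno) == length(phenotype),
            all(is.finite(phenotype)))
  if (nrow(geno) < 10) stop("need at least 10 strains")
  if (n_trees < 1) stop("n_trees must be >= 1")
  constant <- sd(phenotype) == 0
  if (constant)
    warning("phenotype is constant; selection frequencies are meaningless")
  X <- .code_genotypes(geno)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X)))
  run <- function() {
    .forest_selection_frequency(X, as.numeric(phenotype),
                                as.integer(n_forests), as.integer(n_trees),
                                as.integer(mtry), as.integer(min_leaf),
                                isTRUE(root_only))
  }
  freq <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  names(freq) <- colnames(geno)
  structure(list(frequency = freq, n_forests = n_forests, n_trees = n_trees,
                 seed = seed, constant_phenotype = constant),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("<importance_profile: %d blocks, %d forests x %d trees; top block %s (%.3f)>\n",
              length(x$frequency), x$n_forests, x$n_trees,
              names(which.max(x$frequency)), max(x$frequency)))
  invisible(x)
}

#' Permutation null distribution of selection frequencies
#'
#' Destroys the genotype-phenotype link by shuffling the phenotype values
#' across strains and recomputing the selection frequencies, once per
#' permutation, with the same forest configuration as the observed profile.
#'
#' @inheritParams selection_frequency
#' @param n_perm number of phenotype permutations (>= 1).
#' @return numeric matrix, `n_perm` rows x blocks columns, of null
#'   selection frequencies.
#' @export
permutation_null <- function(geno, phenotype, n_perm, n_forests = 100,
                             n_trees = 100, mtry = NULL, min_leaf = 5,
                             seed = NULL) {
  if (is.list(geno) && !is.null(geno$geno)) geno <- geno$geno
  stopifnot(n_perm >= 1)
  run <- function() {
    t(vapply(seq_len(n_perm), function(i) {
      yp <- sample(phenotype)
      suppressWarnings(
        selection_frequency(geno, yp, n_forests, n_trees, mtry,
                            min_leaf)$frequency)
    }, numeric(ncol(geno))))
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(null) <- colnames(geno)
  null
}

#' Permutation p-values and genome-wide significance for QTL blocks
#'
#' Per block, `p = (1 + #\{null >= observed\}) / (1 + n_perm)`; genome-wide
#' significance applies a Bonferroni correction over the number of blocks
#' tested. Note the smallest achievable corrected p-value is
#' `n_blocks / (1 + n_perm)`: use [min_permutations()] to size the null.
#'
#' @param observed an `importance_profile` (or bare numeric vector) of
#'   observed selection frequencies.
#' @param null matrix from [permutation_null()] (permutations x blocks).
#' @param n_blocks number of tests for the Bonferroni correction
#'   (default: number of blocks scored).
#' @param alpha genome-wide significance level (default 0.05).
#' @return data.frame with one row per block: `block`, `importance`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
qtl_pvalues <- function(observed, null, n_blocks = NULL, alpha = 0.05) {
  obs <- if (inherits(observed, "importance_profile")) {
    observed$frequency
  } else {
    observed
  }
  null <- as.matrix(null)
  stopifnot(ncol(null) == length(obs), nrow(null) >= 1)
  if (is.null(n_blocks)) n_blocks <- length(obs)
  n_perm <- nrow(null)
  p <- vapply(seq_along(obs), function(j) {
    (1 + sum(null[, j] >= obs[j])) / (1 + n_perm)
  }, numeric(1))
  p_bonf <- pmin(1, n_blocks * p)
  data.frame(block = names(obs) %||% seq_along(obs),
             importance = unname(obs), p = p, p_bonferroni = p_bonf,
             significant = p_bonf < alpha)
}

#' Minimum permutations for genome-wide significance
#'
#' With a Bonferroni correction over `n_blocks` haplotype blocks, a block
#' can only reach corrected significance `alpha` when the permutation count
#' exceeds `n_blocks / alpha` (the smallest raw permutation p-value is
#' about `1 / n_perm`). For 803 blocks at alpha 0.05 this is 16,060.
#'
#' @param n_blocks number of haplotype blocks (>= 1).
#' @param alpha genome-wide significance threshold, in (0, 1).
#' @return the count that `n_perm` must exceed.
#' @export
min_permutations <- function(n_blocks, alpha) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  stopifnot(n_blocks >= 1)
  n_blocks / alpha
}

#' Map QTL with a random-forest selection-frequency scan
#'
#' Full pipeline: flank-impute the genotype matrix, fill residual missing
#' calls from the nearest called marker, collapse markers into
#' haplotype blocks, score observed selection frequencies, build a
#' permutation null, and report Bonferroni-corrected per-block p-values.
#'
#' @param gm a [genotype_matrix()].
#' @param phenotype numeric phenotype, one value per strain.
#' @param n_forests,n_trees forest configuration (defaults 100 x 100).
#' @param n_perm permutations for the null (default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed optional integer seed covering the observed scan and the
#'   null.
#' @return data.frame: per block `chrom`, `pos`, `start`, `end`,
#'   `n_markers`, `importance`, `p`, `p_bonferroni`, `significant`.
#' @export
map_qtl <- function(gm, phenotype, n_forests = 100, n_trees = 100,
                    n_perm = 1000, alpha = 0.05, seed = NULL) {
  collapsed <- collapse_blocks(fill_nearest_haplotype(impute_flanked(gm)))
  run <- function() {
    obs <- selection_frequency(collapsed$geno, phenotype, n_forests, n_trees)
    null <- permutation_null(collapsed$geno, phenotype, n_perm, n_forests,
                             n_trees)
    qtl_pvalues(obs, null, alpha = alpha)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  cbind(collapsed$blocks[c("chrom", "pos", "start", "end", "n_markers")],
        res[c("importance", "p", "p_bonferroni", "significant")])
}
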