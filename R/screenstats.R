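#' Strong-adhesion call
#'
#' A strain shows a strong adhesion phenotype when its wash ratio (density
#' after washing over density before) exceeds 0.2 -- i.e. more than 20% of
#' the colony stayed on the agar.
#'
#' @param ratio adhesion ratio(s), >= 0.
#' @param cutoff strict cutoff (default 0.2).
#' @return logical: `ratio > cutoff`.
#' @export
strong_adhesion_call <- function(ratio, cutoff = 0.2) {
  stopifnot(all(ratio >= 0, na.rm = TRUE))
  ratio > cutoff
}

#' Screen-positive threshold at a percentile
#'
#' The q-th percentile of the screen's adhesion values under linear
#' interpolation (the type-7 convention); strains strictly above it are
#' screen-positive. With q = 95 this is the "top 5th percentile" rule.
#'
#' @param values numeric vector (NAs dropped), at least 2 finite values.
#' @param q percentile in (0, 100), default 95.
#' @return the threshold value.
#' @export
percentile_threshold <- function(values, q = 95) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  unname(quantile(values, q / 100, type = 7))
}

#' Elbow threshold on a sorted curve
#'
#' Sorts the values in decreasing order and returns the value at the point
#' of maximum perpendicular distance to the chord joining the first and
#' last points of the sorted curve (the "kneedle" construction). Degenerate
#' inputs without curvature (all equal, or an exactly linear ramp) yield a
#' warning and the midpoint value of the sorted curve.
#'
#' @param values numeric vector, length >= 3.
#' @return the threshold value at the elbow.
#' @export
elbow_threshold <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  y <- sort(values, decreasing = TRUE)
  x <- seq_len(n)
  # distance from (x_i, y_i) to the chord (1, y_1) -- (n, y_n)
  dx <- n - 1; dy <- y[n] - y[1]
  dist <- abs(dy * (x - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  if (max(dist) < sqrt(.Machine$double.eps) * max(1, abs(y[1]))) {
    warning("no elbow: sorted values are linear; returning the midpoint value")
    return(y[ceiling(n / 2)])
  }
  y[which.max(dist)]
}

#' Confirm screen hits from replicate measurements
#'
#' A replicate is *valid* when it allowed robust quantification: prewash
#' density > `pre_min` and postwash density > `post_min`. A strain is a hit
#' when it has at least `min_repeats` valid replicates and its adhesion
#' ratio over the valid replicates exceeds `ratio_min`. By default the
#' *mean* ratio over valid replicates must pass (`rule = "mean"`); with
#' `rule = "each"` every valid replicate must pass individually.
#'
#' @param table data.frame with columns `strain`, `pre`, `post`, `ratio`
#'   (one row per replicate).
#' @param min_repeats minimum number of valid replicates (default 5).
#' @param pre_min,post_min validity thresholds (defaults 0.1 and 0.05).
#' @param ratio_min adhesion cutoff; the screen's 95th-percentile value is
#'   the conventional choice (0.086 in the original deletion screen).
#' @param rule `"mean"` or `"each"` (see above).
#' @return data.frame with one row per strain: `strain`, `n_valid`,
#'   `mean_ratio`, `hit`.
#' @export
confirm_hits <- function(table, min_repeats = 5, pre_min = 0.1,
                         post_min = 0.05, ratio_min,
                         rule = c("mean", "each")) {
  rule <- match.arg(rule)
  stopifnot(nrow(table) > 0, min_repeats >= 1,
            all(c("strain", "pre", "post", "ratio") %in% names(table)))
  out <- do.call(rbind, lapply(split(table, table$strain), function(d) {
    valid <- d$pre > pre_min & d$post > post_min
    mr <- if (any(valid)) mean(d$ratio[valid]) else NA_real_
    passed <- if (rule == "mean") {
      !is.na(mr) && mr > ratio_min
    } else {
      any(valid) && all(d$ratio[valid] > ratio_min)
    }
    data.frame(strain = d$strain[1], n_valid = sum(valid), mean_ratio = mr,
               hit = sum(valid) >= min_repeats && passed)
  }))
  rownames(out) <- NULL
  out[order(out$strain), ]
}

#' Permutation T-test on the difference of means
#'
#' Tests a difference in location between two samples by relabeling the
#' pooled observations. The statistic is `mean(x) - mean(y)` (a monotone
#' proxy for the t statistic at fixed group sizes, chosen for determinism).
#' When the number of distinct splits `choose(nx+ny, nx)` does not exceed
#' `n_perm`, all splits are enumerated exhaustively; otherwise `n_perm`
#' random relabelings are drawn. The p-value uses the add-one convention
#' `p = (1 + #extreme) / (1 + #draws)`, which is exact for sampled nulls and
#' slightly conservative for exhaustive ones.
#'
#' @param x,y numeric samples, each with >= 2 observations.
#' @param n_perm maximum number of permutations (default 10000).
#' @param alternative `"two.sided"`, `"greater"` (mean(x) > mean(y)) or
#'   `"less"`.
#' @param seed optional integer seed for the sampled mode.
#' @return list of class `perm_test`: `statistic`, `p`, `n_permutations`
#'   (number of null draws), `alternative`, `exhaustive`.
#' @export
permutation_t_test <- function(x, y, n_perm = 10000,
                               alternative = c("two.sided", "greater", "less"),
                               seed = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  obs <- mean(x) - mean(y)
  total <- sum(pooled)
  # mean(x') - mean(y') is affine in sum(x'): enough to track group-x sums
  stat_from_sum <- function(sx) sx / nx - (total - sx) / (n - nx)
  n_exact <- choose(n, nx)
  if (is.finite(n_exact) && n_exact <= n_perm) {
    idx <- utils::combn(n, nx)
    null_stats <- stat_from_sum(colSums(matrix(pooled[idx], nrow = nx)))
    exhaustive <- TRUE
  } else {
    draw <- function() stat_from_sum(sum(pooled[sample.int(n, nx)]))
    null_stats <- if (is.null(seed)) {
      vapply(seq_len(n_perm), function(i) draw(), numeric(1))
    } else {
      withr::with_seed(seed,
        vapply(seq_len(n_perm), function(i) draw(), numeric(1)))
    }
    exhaustive <- FALSE
  }
  eps <- sqrt(.Machine$double.eps) * (1 + abs(obs))
  extreme <- switch(alternative,
    greater = sum(null_stats >= obs - eps),
    less = sum(null_stats <= obs + eps),
    two.sided = sum(abs(null_stats) >= abs(obs) - eps)
  )
  structure(list(statistic = obs,
                 p = (1 + extreme) / (1 + length(null_stats)),
                 n_permutations = length(null_stats),
                 alternative = alternative,
                 exhaustive = exhaustive),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation T-test (%s%s): mean difference %.4g, p = %.4g (%d draws)\n",
    x$alternative, if (x$exhaustive) ", exhaustive" else "",
    x$statistic, x$p, x$n_permutations))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "bonferroni")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p vector of p-values in (0, 1].
#' @return step-up q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Median-of-ratios size factors for count normalization
#'
#' The classical median-of-ratios construction: a pseudo-reference sample is
#' formed as the per-gene geometric mean across samples, and each sample's
#' size factor is the median (over genes expressed in every sample) of its
#' counts divided by the pseudo-reference. Dividing a sample's counts by its
#' factor makes libraries comparable without being driven by a few highly
#' expressed genes.
#'
#' @param counts non-negative matrix, genes x samples.
#' @return numeric vector of per-sample size factors.
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene has nonzero counts in all samples")
  factors <- apply(counts, 2, function(cnt) {
    exp(median(log(cnt[use]) - log_geo[use]))
  })
  unname(factors)
}

#' Correlate gene expression with a phenotype across strains
#'
#' For each gene, correlates its expression across strains with a phenotype
#' vector (e.g. a flocculation score), then controls the false discovery
#' rate across genes with Benjamini-Hochberg. The default correlation is
#' rank-based (Spearman), robust to the nonlinear relation between
#' adhesion and flocculation readouts; Pearson is available. Genes with
#' zero variance get a missing correlation and are excluded from the FDR.
#'
#' @param expression numeric matrix, genes x strains (column names are
#'   strain ids when `phenotype` is named).
#' @param phenotype numeric vector of per-strain phenotype values, named by
#'   strain when `expression` has column names.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param fdr_level significance level on the q-values (default 0.05).
#' @return data.frame with one row per gene: `gene`, `r`, `p`, `q`,
#'   `significant`.
#' @export
correlate_phenotype <- function(expression, phenotype,
                                method = c("spearman", "pearson"),
                                fdr_level = 0.05) {
  method <- match.arg(method)
  expression <- as.matrix(expression)
  if (!is.null(names(phenotype)) && !is.null(colnames(expression))) {
    shared <- intersect(colnames(expression), names(phenotype))
    if (length(shared) < 3) stop("fewer than 3 shared strains")
    expression <- expression[, shared, drop = FALSE]
    phenotype <- phenotype[shared]
  } else if (ncol(expression) != length(phenotype) ||
             length(phenotype) < 3) {
    stop("phenotype length must match columns (>= 3 strains)")
  }
  genes <- rownames(expression)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(expression)))
  res <- t(apply(expression, 1, function(e) {
    if (sd(e) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(e, phenotype, method = method))
    c(unname(ct$estimate), ct$p.value)
  }))
  out <- data.frame(gene = genes, r = res[, 1], p = res[, 2],
                    q = NA_real_, significant = NA)
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out$significant[ok] <- out$q[ok] < fdr_level
  rownames(out) <- NULL
  out
}
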