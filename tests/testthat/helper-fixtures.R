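# shared fixture builders for the test suite

# a small measured plate pair: render, build+fit layout, measure both grids
measure_pair <- function(spec, offset = c(0, 0), max_shift = 20) {
  pp <- render_plate_pair(spec, offset = offset)
  filled <- render_filled_plate(spec)
  layout <- build_reference_layout(filled)
  fitted <- fit_layout(layout, pp$pre, max_shift)
  controls <- which(spec$densities == 0, arr.ind = TRUE)
  list(
    pair = pp,
    fitted = fitted,
    pre = measure_grid(pp$pre, fitted, controls),
    post = measure_grid(pp$post, fitted, controls)
  )
}

# merge adhesion records with planted truth
records_vs_truth <- function(spec, offset = c(0, 0)) {
  mp <- measure_pair(spec, offset)
  rec <- adhesion_from_pair(mp$pre, mp$post)
  m <- merge(rec, mp$pair$truth, by = c("row", "col"),
             suffixes = c("_measured", "_planted"))
  m$offset_err <- max(abs(attr(mp$fitted, "offset") - offset))
  m
}

# a toy single-exon plus-strand gene: ATG AAA TGC TGG TAA on a padded chrom
toy_gene_fixture <- function() {
  cds <- "ATGAAATGCTGGTAA"
  chrom <- paste0(strrep("C", 10), cds, strrep("G", 10))
  list(genome = c(chr1 = chrom),
       gene = gene_model("toy", "chr1", "+", cbind(11, 10 + nchar(cds))),
       cds = cds)
}

# brute-force flank-agreement imputation oracle: two nested loops, no
# shared code with impute_flanked
impute_oracle <- function(geno, chrom) {
  out <- geno
  for (i in seq_len(nrow(geno))) {
    for (j in seq_len(ncol(geno))) {
      if (!is.na(geno[i, j])) next
      same <- which(chrom == chrom[j])
      left <- same[same < j & !is.na(geno[i, same])]
      right <- same[same > j & !is.na(geno[i, same])]
      if (length(left) && length(right)) {
        l <- geno[i, max(left)]
        r <- geno[i, min(right)]
        if (l == r) out[i, j] <- l
      }
    }
  }
  out
}

# random genotype matrix with missing calls
random_genotype_matrix <- function(n_strains = 8, n_markers = 30,
                                   missing = 0.2) {
  geno <- matrix(sample(c("P1", "P2"), n_strains * n_markers, TRUE),
                 n_strains, n_markers)
  geno[matrix(runif(length(geno)) < missing, n_strains, n_markers)] <- NA
  chrom <- rep(c("chr1", "chr2"), each = ceiling(n_markers / 2))[1:n_markers]
  markers <- data.frame(chrom = sort(chrom),
                        pos = ave(seq_len(n_markers), sort(chrom),
                                  FUN = seq_along) * 100)
  genotype_matrix(geno, markers)
}
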