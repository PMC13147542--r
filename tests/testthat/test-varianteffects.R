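test_that("spliced CDS extraction is strand- and exon-aware", {
  fx <- toy_gene_fixture()
  expect_equal(spliced_cds(fx$genome, fx$gene), fx$cds)

  # minus strand: independent reverse-complement oracle via chartr
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  minus_chrom <- paste0("AAAA", rc(fx$cds), "TTTT")
  g <- gene_model("m", "chr1", "-", cbind(5, 4 + nchar(fx$cds)))
  expect_equal(spliced_cds(c(chr1 = minus_chrom), g), fx$cds)

  # two-exon gene from the generator round-trips through splicing
  tg <- toy_genome(seed = 3, n_variants = 6)
  two_exon <- Filter(function(g) nrow(g$cds_intervals) == 2, tg$genes)
  expect_gt(length(two_exon), 0)
  for (g in two_exon[1:2]) {
    cds <- spliced_cds(tg$genome, g)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
  }

  out_of_bounds <- gene_model("b", "chr1", "+", cbind(1, 1e6))
  expect_error(spliced_cds(fx$genome, out_of_bounds), "bounds")
})

test_that("variant classification covers the canonical constructed cases", {
  fx <- toy_gene_fixture()  # ATG AAA TGC TGG TAA at chr1:11
  # nonsense: codon 2 AAA -> TAA
  v <- list(chrom = "chr1", pos = 14, ref = "A", alt = "T")
  call <- classify_variant(fx$genome, fx$gene, v)
  expect_equal(call$category, "nonsense")
  expect_equal(call$protein_length_ref, 4)
  expect_equal(call$protein_length_alt, 1)
  expect_true(call$premature_stop)

  # synonymous: TGC -> TGT (both Cys)
  v <- list(chrom = "chr1", pos = 19, ref = "C", alt = "T")
  call <- classify_variant(fx$genome, fx$gene, v)
  expect_equal(call$category, "synonymous")
  expect_equal(call$protein_length_alt, call$protein_length_ref)
  expect_false(call$premature_stop)

  # missense: AAA -> ACA (Lys -> Thr)
  v <- list(chrom = "chr1", pos = 15, ref = "A", alt = "C")
  expect_equal(classify_variant(fx$genome, fx$gene, v)$category, "missense")

  # 3-bp anchored deletion on a codon boundary: in-frame
  v <- list(chrom = "chr1", pos = 13, ref = "GAAA", alt = "G")
  call <- classify_variant(fx$genome, fx$gene, v)
  expect_equal(call$category, "inframe_indel")
  expect_false(call$premature_stop)

  # 1-bp deletion: frameshift
  v <- list(chrom = "chr1", pos = 13, ref = "GA", alt = "G")
  expect_equal(classify_variant(fx$genome, fx$gene, v)$category, "frameshift")

  # upstream SNP: non-coding
  v <- list(chrom = "chr1", pos = 3, ref = "C", alt = "A")
  expect_equal(classify_variant(fx$genome, fx$gene, v)$category, "non_coding")

  # data-integrity check on the reference allele
  v <- list(chrom = "chr1", pos = 14, ref = "G", alt = "T")
  expect_error(classify_variant(fx$genome, fx$gene, v), "mismatch")
})

test_that("indel frame rule: frameshift iff length change is not a multiple of 3", {
  tg <- toy_genome(seed = 4, n_variants = 60)
  indels <- tg$truth[nchar(tg$truth$ref) != nchar(tg$truth$alt), ]
  expect_gt(nrow(indels), 5)
  calls <- classify_variants(indels, tg$genes, tg$genome)
  delta <- abs(nchar(calls$ref) - nchar(calls$alt))
  expect_equal(calls$category == "frameshift", delta %% 3 != 0)
})

test_that("the truncation scan returns exactly the truncating constructions", {
  tg <- toy_genome(seed = 5, n_variants = 120)
  trunc <- scan_for_truncations(tg$variants, tg$genes, tg$genome)
  expect_true(all(trunc$category %in% c("frameshift", "nonsense")))
  expect_equal(nrow(trunc),
               sum(tg$truth$category %in% c("frameshift", "nonsense")))
  expect_equal(nrow(scan_for_truncations(tg$variants[0, ], tg$genes,
                                         tg$genome)), 0)
  syn <- tg$variants[tg$truth$category == "synonymous", ]
  expect_equal(nrow(scan_for_truncations(syn, tg$genes, tg$genome)), 0)
})

test_that("the synthetic cyclin-C-style worked example truncates 228 aa to 77", {
  ex <- synthetic_srb11_example()
  call <- classify_variant(ex$genome, ex$gene, ex$variant)
  expect_equal(call$category, "frameshift")
  expect_equal(call$protein_length_ref, 228)
  expect_equal(call$protein_length_alt, 77)
  expect_true(call$premature_stop)
})

test_that("heterozygous calls are dropped and homozygous calls kept verbatim", {
  calls <- data.frame(chrom = "I", pos = 1:10, zygosity =
                        c(rep("hom", 7), rep("het", 3)))
  kept <- drop_heterozygous(calls)
  expect_equal(nrow(kept), 7)
  expect_equal(kept$pos, 1:7)
  expect_equal(nrow(drop_heterozygous(calls[calls$zygosity == "hom", ])), 7)
  expect_equal(nrow(drop_heterozygous(calls[calls$zygosity == "het", ])), 0)
})

test_that("flank-agreement imputation fills only agreeing flanks", {
  markers <- data.frame(chrom = "chr1", pos = c(100, 200, 300))
  gm <- genotype_matrix(rbind(c("P1", NA, "P1"),
                              c("P1", NA, "P2"),
                              c(NA, "P2", "P2")), markers)
  out <- impute_flanked(gm)
  expect_equal(out$geno[1, ], c("P1", "P1", "P1"))
  expect_true(is.na(out$geno[2, 2]))       # disagreeing flanks stay missing
  expect_true(is.na(out$geno[3, 1]))       # chromosome ends never imputed
})

test_that("imputation matches a brute-force oracle and is idempotent", {
  for (s in 1:25) {
    gm <- withr::with_seed(s, random_genotype_matrix())
    out <- impute_flanked(gm)
    expect_identical(out$geno, impute_oracle(gm$geno, gm$markers$chrom))
    expect_identical(impute_flanked(out)$geno, out$geno)
    expect_gte(sum(!is.na(out$geno)), sum(!is.na(gm$geno)))
    called <- !is.na(gm$geno)
    expect_identical(out$geno[called], gm$geno[called])
  }
})

test_that("nearest-haplotype filling completes the matrix without touching calls", {
  gm <- withr::with_seed(7, random_genotype_matrix(missing = 0.3))
  out <- fill_nearest_haplotype(gm)
  expect_false(anyNA(out$geno))
  called <- !is.na(gm$geno)
  expect_identical(out$geno[called], gm$geno[called])
})

test_that("generated genome files round-trip through the standard readers", {
  tg <- toy_genome(seed = 6, n_variants = 40)
  dir <- withr::local_tempdir()
  expect_no_warning(write_toy_genome(tg, dir))
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_equal(genome, tg$genome)
  genes <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_setequal(names(genes), names(tg$genes))
  g0 <- tg$genes[[5]]; g1 <- genes[[g0$gene_id]]
  expect_equal(g1$cds_intervals, g0$cds_intervals)
  expect_equal(g1$strand, g0$strand)
  variants <- read_variant_table(file.path(dir, "variants.tsv"))
  calls <- classify_variants(variants, genes, genome)
  expect_equal(calls$category, tg$truth$category)
  # genotype matrix CSV round trip
  gm <- withr::with_seed(8, random_genotype_matrix())
  f <- file.path(dir, "geno.csv")
  write_genotype_csv(gm, f)
  back <- read_genotype_csv(f)
  expect_equal(unname(back$geno), unname(gm$geno))
  expect_equal(back$markers, gm$markers)
})
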