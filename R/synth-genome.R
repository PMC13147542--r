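# Toy-genome generator: emits a small genome, gene annotation and a variant
# table whose coding consequences are known at construction time. The
# generator carries its own codon table and does all editing/translation in
# CDS coordinate space, independently of the genomic-space consequence
# caller it serves as an oracle for.

.BASES <- c("A", "C", "G", "T")

# standard nuclear code, codon order (T, C, A, G) x 3 positions
.CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

.STOPS <- names(.CODON_TABLE)[.CODON_TABLE == "*"]
.SENSE <- setdiff(names(.CODON_TABLE), .STOPS)

.comp <- c(A = "T", C = "G", G = "C", T = "A")

.rc_local <- function(s) {
  paste(rev(.comp[strsplit(s, "")[[1]]]), collapse = "")
}

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

# translate with the local table up to the first stop codon
.local_translate <- function(cds) {
  n3 <- nchar(cds) %/% 3
  if (n3 == 0) return(list(protein = "", stopped = FALSE))
  codons <- substring(cds, 3 * seq_len(n3) - 2, 3 * seq_len(n3))
  aa <- .CODON_TABLE[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    list(protein = paste(aa[seq_len(stop_at[1] - 1)], collapse = ""),
         stopped = TRUE)
  } else {
    list(protein = paste(aa, collapse = ""), stopped = FALSE)
  }
}

# one random gene: CDS string plus exon split
.make_gene_cds <- function(n_codons) {
  internal <- sample(.SENSE, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(internal, collapse = ""), sample(.STOPS, 1))
}

# genomic layout of one gene starting at position `at` (1-based): returns
# the locus sequence, CDS intervals and the cds-index -> genomic-pos map
.place_gene <- function(cds, strand, at, two_exon, intron_len) {
  len <- nchar(cds)
  if (two_exon) {
    split_at <- 3 * sample(seq(2, len / 3 - 2), 1)  # codon-boundary split
    e1 <- substr(cds, 1, split_at)
    e2 <- substr(cds, split_at + 1, len)
    intron <- .rand_dna(intron_len)
    if (strand == "+") {
      locus <- paste0(e1, intron, e2)
      iv <- rbind(c(at, at + nchar(e1) - 1),
                  c(at + nchar(e1) + intron_len,
                    at + len + intron_len - 1))
    } else {
      locus <- paste0(.rc_local(e2), intron, .rc_local(e1))
      iv <- rbind(c(at, at + nchar(e2) - 1),
                  c(at + nchar(e2) + intron_len,
                    at + len + intron_len - 1))
    }
  } else {
    locus <- if (strand == "+") cds else .rc_local(cds)
    iv <- rbind(c(at, at + len - 1))
  }
  map <- unlist(lapply(seq_len(nrow(iv)), function(k) iv[k, 1]:iv[k, 2]))
  if (strand == "-") map <- rev(map)
  list(locus = locus, iv = iv, map = map)
}

# apply a CDS-space edit and return the generator's own consequence label
.label_edit <- function(cds, edit) {
  new_cds <- switch(edit$kind,
    snp = paste0(substr(cds, 1, edit$i - 1), edit$base,
                 substr(cds, edit$i + 1, nchar(cds))),
    del = paste0(substr(cds, 1, edit$i - 1),
                 substr(cds, edit$i + edit$len, nchar(cds))),
    ins = paste0(substr(cds, 1, edit$i), edit$seq,
                 substr(cds, edit$i + 1, nchar(cds)))
  )
  ref_tr <- .local_translate(cds)
  alt_tr <- .local_translate(new_cds)
  delta <- nchar(new_cds) - nchar(cds)
  category <- if (edit$kind == "snp") {
    if (identical(alt_tr$protein, ref_tr$protein)) "synonymous"
    else if (nchar(alt_tr$protein) < nchar(ref_tr$protein) && alt_tr$stopped)
      "nonsense"
    else "missense"
  } else if (abs(delta) %% 3 != 0) "frameshift" else "inframe_indel"
  len_ref <- nchar(ref_tr$protein)
  len_alt <- nchar(alt_tr$protein)
  expected <- if (category == "inframe_indel") len_ref + delta %/% 3 else len_ref
  list(category = category,
       protein_length_ref = len_ref,
       protein_length_alt = len_alt,
       premature_stop = alt_tr$stopped && len_alt < min(len_ref, expected))
}

#' Generate a toy genome with consequence-labelled variants
#'
#' Builds a small genome of random sequence carrying `n_genes` genes on
#' both strands (a mix of single- and two-exon models) and `n_variants`
#' short variants whose coding consequences -- synonymous, missense,
#' nonsense, frameshift, in-frame indel or non-coding -- are assigned at
#' construction time by editing and translating the coding sequence
#' directly in CDS coordinate space with the generator's own codon table.
#' The labels therefore provide a fully independent oracle for the
#' genomic-space consequence caller ([classify_variant()]).
#'
#' @param seed integer seed.
#' @param n_genes number of genes, >= 10 (default 12).
#' @param n_variants number of variants, >= 200 (default 220).
#' @return list of class `toy_genome`: `genome` (named character vector),
#'   `genes` (list of [gene_model()]s), `variants` (data.frame `chrom`,
#'   `pos`, `ref`, `alt`), `truth` (the variants plus `gene_id`,
#'   `category`, `protein_length_ref`, `protein_length_alt`,
#'   `premature_stop`).
#' @export
toy_genome <- function(seed = 1, n_genes = 12, n_variants = 220) {
  stopifnot(n_genes >= 10, n_variants >= 1)
  withr::with_seed(seed, .build_toy_genome(n_genes, n_variants))
}

.build_toy_genome <- function(n_genes, n_variants) {
  chrom_names <- c("chrI", "chrII")
  chrom_seq <- setNames(character(2), chrom_names)
  coding_mask <- list()  # per chrom: logical, TRUE where inside a CDS exon
  genes <- list()
  gene_info <- list()    # cds string + map, for variant construction

  for (ci in 1:2) {
    seq_parts <- character(0)
    cursor <- 1L
    mask <- logical(0)
    for (gi in seq_len(ceiling(n_genes / 2))) {
      gap <- sample(100:300, 1)
      seq_parts <- c(seq_parts, .rand_dna(gap))
      mask <- c(mask, rep(FALSE, gap))
      cursor <- cursor + gap
      id <- sprintf("g%d", (ci - 1) * ceiling(n_genes / 2) + gi)
      strand <- if (gi %% 2 == 0) "-" else "+"
      two_exon <- gi %% 3 == 0
      cds <- .make_gene_cds(sample(60:120, 1))
      placed <- .place_gene(cds, strand, cursor, two_exon,
                            intron_len = sample(50:120, 1))
      seq_parts <- c(seq_parts, placed$locus)
      locus_mask <- rep(FALSE, nchar(placed$locus))
      locus_mask[placed$map - cursor + 1L] <- TRUE
      mask <- c(mask, locus_mask)
      cursor <- cursor + nchar(placed$locus)
      genes[[id]] <- gene_model(id, chrom_names[ci], strand, placed$iv)
      gene_info[[id]] <- list(cds = cds, map = placed$map, strand = strand,
                              chrom = chrom_names[ci])
    }
    tail_gap <- sample(200:400, 1)
    seq_parts <- c(seq_parts, .rand_dna(tail_gap))
    mask <- c(mask, rep(FALSE, tail_gap))
    chrom_seq[ci] <- paste(seq_parts, collapse = "")
    coding_mask[[chrom_names[ci]]] <- mask
  }
  genes <- genes[seq_len(n_genes)]
  gene_info <- gene_info[names(genes)]

  types <- sample(rep(c("synonymous", "missense", "nonsense", "frameshift",
                        "inframe_indel", "non_coding"),
                      length.out = n_variants))
  used_pos <- list(chrI = integer(0), chrII = integer(0))
  rows <- vector("list", n_variants)
  for (vi in seq_len(n_variants)) {
    rows[[vi]] <- .make_labelled_variant(types[vi], gene_info, chrom_seq,
                                         coding_mask, used_pos)
    used_pos[[rows[[vi]]$chrom]] <- c(used_pos[[rows[[vi]]$chrom]],
                                      seq(rows[[vi]]$pos,
                                          rows[[vi]]$pos + nchar(rows[[vi]]$ref)))
  }
  truth <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(truth) <- NULL
  structure(list(
    genome = chrom_seq,
    genes = genes,
    variants = truth[c("chrom", "pos", "ref", "alt")],
    truth = truth
  ), class = "toy_genome")
}

# draw one variant of the requested labelled type; retries across random
# choices until the construction constraints are met
.make_labelled_variant <- function(type, gene_info, chrom_seq, coding_mask,
                                   used_pos, max_tries = 500) {
  for (try in seq_len(max_tries)) {
    if (type == "non_coding") {
      chrom <- sample(names(chrom_seq), 1)
      pos <- sample(2:(nchar(chrom_seq[[chrom]]) - 2), 1)
      if (coding_mask[[chrom]][pos] || pos %in% used_pos[[chrom]]) next
      ref <- substr(chrom_seq[[chrom]], pos, pos)
      alt <- sample(setdiff(.BASES, ref), 1)
      return(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  gene_id = NA_character_, category = "non_coding",
                  protein_length_ref = NA_integer_,
                  protein_length_alt = NA_integer_,
                  premature_stop = FALSE))
    }
    gid <- sample(names(gene_info), 1)
    g <- gene_info[[gid]]
    cds <- g$cds
    len <- nchar(cds)
    edit <- NULL
    if (type %in% c("synonymous", "missense", "nonsense")) {
      k <- sample(2:(len / 3 - 1), 1)      # internal codon
      codon <- substr(cds, 3 * k - 2, 3 * k)
      within <- sample(1:3, 1)
      old <- substr(codon, within, within)
      cands <- setdiff(.BASES, old)
      new_codons <- vapply(cands, function(b) {
        cd <- codon
        substr(cd, within, within) <- b
        cd
      }, character(1))
      target_ok <- switch(type,
        synonymous = .CODON_TABLE[new_codons] == .CODON_TABLE[codon],
        missense = .CODON_TABLE[new_codons] != .CODON_TABLE[codon] &
          .CODON_TABLE[new_codons] != "*",
        nonsense = .CODON_TABLE[new_codons] == "*"
      )
      if (!any(target_ok)) next
      ok <- which(target_ok)
      base <- cands[ok[sample.int(length(ok), 1)]]
      edit <- list(kind = "snp", i = 3 * (k - 1) + within, base = base)
    } else if (type == "frameshift") {
      ind_len <- sample(1:2, 1)
      if (runif(1) < 0.5) {
        i <- sample(4:(len - 6 - ind_len), 1)
        edit <- list(kind = "del", i = i, len = ind_len)
      } else {
        i <- sample(4:(len - 6), 1)
        edit <- list(kind = "ins", i = i, seq = .rand_dna(ind_len))
      }
    } else {  # inframe_indel
      if (runif(1) < 0.5) {
        i <- sample(4:(len - 9), 1)
        edit <- list(kind = "del", i = i, len = 3L)
      } else {
        i <- sample(4:(len - 6), 1)
        edit <- list(kind = "ins", i = i, seq = .rand_dna(3))
      }
    }
    v <- .edit_to_genomic(edit, g, chrom_seq[[g$chrom]])
    if (is.null(v)) next
    span <- seq(v$pos, v$pos + nchar(v$ref))
    if (any(span %in% used_pos[[g$chrom]])) next
    lab <- .label_edit(cds, edit)
    if (lab$category != type) next
    return(c(list(chrom = g$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                  gene_id = gid), lab))
  }
  stop("could not construct a variant of type ", type)
}

# translate a CDS-space edit into an anchored genomic variant; NULL when the
# edit cannot be represented within a single exon
.edit_to_genomic <- function(edit, g, chrom) {
  map <- g$map
  minus <- g$strand == "-"
  base_at <- function(pos) substr(chrom, pos, pos)
  if (edit$kind == "snp") {
    pos <- map[edit$i]
    ref <- base_at(pos)
    alt <- if (minus) .comp[[edit$base]] else edit$base
    if (ref == alt) return(NULL)
    return(list(pos = pos, ref = ref, alt = alt))
  }
  if (edit$kind == "del") {
    gpos <- sort(map[edit$i:(edit$i + edit$len - 1)])
    if (any(diff(gpos) != 1)) return(NULL)  # spans an intron
    anchor <- gpos[1] - 1
    if (anchor < 1) return(NULL)
    return(list(pos = anchor,
                ref = substr(chrom, anchor, gpos[length(gpos)]),
                alt = base_at(anchor)))
  }
  # insertion after cds index i
  gl <- map[edit$i]; gr <- map[edit$i + 1]
  if (abs(gr - gl) != 1) return(NULL)  # exon junction
  anchor <- min(gl, gr)
  ins <- if (minus) .rc_local(edit$seq) else edit$seq
  list(pos = anchor, ref = base_at(anchor),
       alt = paste0(base_at(anchor), ins))
}

#' Write a toy genome to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `variants.tsv` and `truth.tsv` in the
#' formats the analysis readers consume.
#'
#' @param tg a [toy_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_genome <- function(tg, dir) {
  stopifnot(inherits(tg, "toy_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- unlist(lapply(names(tg$genome), function(ch) {
    c(paste0(">", ch),
      substring(tg$genome[[ch]],
                seq(1, nchar(tg$genome[[ch]]), 70),
                pmin(seq(1, nchar(tg$genome[[ch]]), 70) + 69,
                     nchar(tg$genome[[ch]]))))
  }))
  writeLines(fa, file.path(dir, "genome.fa"))
  gff <- "##gff-version 3"
  for (g in tg$genes) {
    iv <- g$cds_intervals
    span <- c(min(iv[, 1]), max(iv[, 2]))
    gff <- c(gff,
      sprintf("%s\tmlpquant\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chromosome, span[1], span[2], g$strand, g$gene_id),
      sprintf("%s\tmlpquant\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$chromosome, span[1], span[2], g$strand, g$gene_id,
              g$gene_id),
      sprintf("%s\tmlpquant\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              g$chromosome, iv[, 1], iv[, 2], g$strand, g$gene_id,
              g$gene_id))
  }
  writeLines(gff, file.path(dir, "genes.gff3"))
  v <- tg$variants
  names(v) <- toupper(names(v))
  write.table(v, file.path(dir, "variants.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(tg$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Synthetic frameshift worked example
#'
#' A synthetic stand-in for the classic cyclin-C truncation case: a
#' single-exon gene encoding a 228-amino-acid protein, engineered so that
#' an anchored `TA > T` single-base deletion shifts the reading frame after
#' codon 77 straight into a stop codon, truncating the product to 77 of
#' 228 amino acids. The gene and chromosome are generated sequence, not the
#' public reference; only the construction pattern mirrors the real case.
#'
#' @param seed integer seed for the surrounding sequence.
#' @return list with `genome`, `gene` (a [gene_model()]) and `variant`
#'   (list with `chrom`, `pos`, `ref`, `alt`).
#' @export
synthetic_srb11_example <- function(seed = 1) {
  withr::with_seed(seed, {
    n_codons <- 229  # 228 aa + stop
    codons <- c("ATG", sample(.SENSE, n_codons - 2, replace = TRUE),
                "TAA")
    # codon 77 ends in T (anchor), codon 78 = ATA, codon 79 starts with A:
    # deleting the A at codon 78 position 1 makes the new codon 78 read TAA
    codons[77] <- "CAT"
    codons[78] <- "ATA"
    codons[79] <- paste0("A", substr(codons[79], 2, 3))
    cds <- paste(codons, collapse = "")
    pad5 <- .rand_dna(200)
    pad3 <- .rand_dna(200)
    chrom <- paste0(pad5, cds, pad3)
    gene <- gene_model("srb11_synthetic", "II", "+",
                       cbind(201, 200 + nchar(cds)))
    variant <- list(chrom = "II", pos = 200 + 231, ref = "TA", alt = "T")
    list(genome = c(II = chrom), gene = gene, variant = variant)
  })
}
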