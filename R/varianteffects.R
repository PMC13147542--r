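#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of uppercase chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) stop("duplicated chromosome names")
  out
}

#' Gene model: an ordered set of CDS intervals
#'
#' Coordinates follow the GFF3 convention: 1-based, inclusive, sorted by
#' genomic position regardless of strand.
#'
#' @param gene_id gene label.
#' @param chromosome chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals 2-column matrix of (start, end), 1-based inclusive,
#'   non-overlapping, sorted by start.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, cds_intervals) {
  cds_intervals <- matrix(as.integer(cds_intervals), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))
  stopifnot(strand %in% c("+", "-"),
            all(cds_intervals[, 2] >= cds_intervals[, 1]))
  cds_intervals <- cds_intervals[order(cds_intervals[, 1]), , drop = FALSE]
  if (nrow(cds_intervals) > 1 &&
      any(cds_intervals[-1, 1] <= cds_intervals[-nrow(cds_intervals), 2]))
    stop("overlapping CDS intervals in gene ", gene_id)
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 strand = strand, cds_intervals = cds_intervals),
            class = "gene_model")
}

#' Read gene models from a GFF3 annotation
#'
#' Collects CDS features grouped by their parent transcript; when a gene has
#' several annotated transcripts, the one with the longest total CDS is
#' kept.
#'
#' @param path GFF3 path.
#' @return named list of [gene_model()]s.
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gff)
  type <- as.character(meta$type)
  first_parent <- function(p) {
    vapply(p, function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }
  tx <- which(type %in% c("mRNA", "transcript"))
  tx2gene <- setNames(first_parent(meta$Parent[tx]),
                      as.character(meta$ID[tx]))
  cds <- which(type == "CDS")
  if (!length(cds)) stop("no CDS features in ", path)
  cds_parent <- first_parent(meta$Parent[cds])
  models <- list()
  for (p in unique(cds_parent)) {
    i <- cds[cds_parent == p]
    gid <- if (p %in% names(tx2gene)) tx2gene[[p]] else p
    gm <- gene_model(
      gene_id = gid,
      chromosome = as.character(GenomeInfoDb::seqnames(gff[i[1]])),
      strand = as.character(BiocGenerics::strand(gff[i[1]])),
      cds_intervals = cbind(BiocGenerics::start(gff[i]),
                            BiocGenerics::end(gff[i]))
    )
    len <- sum(gm$cds_intervals[, 2] - gm$cds_intervals[, 1] + 1)
    if (is.null(models[[gid]]) || len > attr(models[[gid]], "cds_len")) {
      attr(gm, "cds_len") <- len
      models[[gid]] <- gm
    }
  }
  models
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the CDS intervals in transcription order;
#' reverse-complemented for minus-strand genes.
#'
#' @param genome named character vector from [read_genome_fasta()].
#' @param gene a [gene_model()].
#' @return DNA string of the coding sequence.
#' @export
spliced_cds <- function(genome, gene) {
  chrom <- genome[[gene$chromosome]]
  if (is.null(chrom)) stop("chromosome ", gene$chromosome, " not in genome")
  iv <- gene$cds_intervals
  if (any(iv[, 1] < 1) || any(iv[, 2] > nchar(chrom)))
    stop("CDS interval out of chromosome bounds for gene ", gene$gene_id)
  s <- paste(substring(chrom, iv[, 1], iv[, 2]), collapse = "")
  if (gene$strand == "-") s <- .revcomp(s)
  s
}

# translate up to (not including) the first stop codon; trailing partial
# codons are dropped. Returns the protein string and whether a stop was hit.
.translate_to_stop <- function(cds) {
  n3 <- (nchar(cds) %/% 3) * 3
  if (n3 == 0) return(list(protein = "", stopped = FALSE))
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, n3)),
    if.fuzzy.codon = "X", no.init.codon = TRUE)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    list(protein = substr(aa, 1, stop_at - 1), stopped = TRUE)
  } else {
    list(protein = aa, stopped = FALSE)
  }
}

# which CDS interval (if any) fully contains genomic positions from..to
.containing_interval <- function(iv, from, to) {
  hit <- which(iv[, 1] <= from & iv[, 2] >= to)
  if (length(hit) == 1) hit else NA_integer_
}

.overlaps_cds <- function(iv, from, to) {
  any(iv[, 1] <= to & iv[, 2] >= from)
}

#' Classify the coding consequence of one variant on one gene
#'
#' Applies the edit to the chromosome, rebuilds the gene's spliced CDS with
#' strand awareness, translates reference and edited CDS up to the first
#' stop codon, and assigns a category:
#' \itemize{
#'   \item `synonymous` / `missense` / `nonsense` for length-preserving
#'     substitutions (nonsense = the edited protein is truncated by a new
#'     stop codon);
#'   \item `frameshift` for CDS-internal indels whose length difference is
#'     not divisible by 3, `inframe_indel` otherwise;
#'   \item `non_coding` when the changed bases fall outside every CDS
#'     interval (variants straddling a CDS boundary are conservatively
#'     called `non_coding` with a warning).
#' }
#' Protein lengths count amino acids excluding the stop codon.
#'
#' @param genome named character vector from [read_genome_fasta()].
#' @param gene a [gene_model()].
#' @param variant list or one-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt` (VCF style: indels carry a shared anchor base).
#' @return data.frame of class `consequence_call` with columns `gene_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `category`, `protein_length_ref`,
#'   `protein_length_alt`, `premature_stop`.
#' @export
classify_variant <- function(genome, gene, variant) {
  chrom_seq <- genome[[variant$chrom]]
  if (is.null(chrom_seq)) stop("chromosome ", variant$chrom, " not in genome")
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  pos <- as.integer(variant$pos)
  if (ref == alt) stop("ref and alt alleles are identical")
  genomic_ref <- substring(chrom_seq, pos, pos + nchar(ref) - 1)
  if (genomic_ref != ref)
    stop(sprintf("ref allele mismatch at %s:%d: genome has %s, variant says %s",
                 variant$chrom, pos, genomic_ref, ref))

  ref_cds <- spliced_cds(genome, gene)
  ref_tr <- .translate_to_stop(ref_cds)
  len_ref <- nchar(ref_tr$protein)
  # premature_stop: translation terminates at a stop codon earlier than the
  # edit alone accounts for (an in-frame deletion shortening the protein by
  # its own length is not a premature stop)
  call <- function(category, len_alt, stopped = TRUE) {
    expected <- if (category == "inframe_indel") {
      len_ref + (nchar(alt) - nchar(ref)) %/% 3L
    } else {
      len_ref
    }
    structure(data.frame(
      gene_id = gene$gene_id, chrom = variant$chrom, pos = pos,
      ref = ref, alt = alt, category = category,
      protein_length_ref = len_ref, protein_length_alt = len_alt,
      premature_stop = stopped && len_alt < min(len_ref, expected),
      stringsAsFactors = FALSE), class = c("consequence_call", "data.frame"))
  }

  iv <- gene$cds_intervals
  delta <- nchar(alt) - nchar(ref)
  same_chrom <- identical(gene$chromosome, variant$chrom)

  if (delta == 0L && nchar(ref) == nchar(alt)) {
    from <- pos; to <- pos + nchar(ref) - 1
    if (!same_chrom || !.overlaps_cds(iv, from, to))
      return(call("non_coding", len_ref))
    if (is.na(.containing_interval(iv, from, to))) {
      warning("substitution straddles a CDS boundary; calling non_coding")
      return(call("non_coding", len_ref))
    }
    new_iv <- iv
  } else if (delta < 0L) {
    # deletion: the bases after the shared anchor are removed
    from <- pos + nchar(alt); to <- pos + nchar(ref) - 1
    if (!same_chrom || !.overlaps_cds(iv, from, to))
      return(call("non_coding", len_ref))
    k <- .containing_interval(iv, from, to)
    if (is.na(k)) {
      warning("deletion straddles a CDS boundary; calling non_coding")
      return(call("non_coding", len_ref))
    }
    new_iv <- iv
    new_iv[k, 2] <- new_iv[k, 2] + delta
    after <- new_iv[, 1] > to
    new_iv[after, ] <- new_iv[after, , drop = FALSE] + delta
  } else {
    # insertion between the anchor base and the next position
    at <- pos + nchar(ref) - 1
    inside <- same_chrom && any(iv[, 1] <= at & iv[, 2] > at)
    if (!inside) return(call("non_coding", len_ref))
    k <- which(iv[, 1] <= at & iv[, 2] > at)
    new_iv <- iv
    new_iv[k, 2] <- new_iv[k, 2] + delta
    after <- new_iv[, 1] > at
    new_iv[after, ] <- new_iv[after, , drop = FALSE] + delta
  }

  edited_chrom <- paste0(substring(chrom_seq, 1, pos - 1), alt,
                         substring(chrom_seq, pos + nchar(ref)))
  edited_genome <- genome
  edited_genome[[gene$chromosome]] <- edited_chrom
  edited_gene <- gene_model(gene$gene_id, gene$chromosome, gene$strand,
                            new_iv)
  alt_cds <- spliced_cds(edited_genome, edited_gene)
  alt_tr <- .translate_to_stop(alt_cds)
  len_alt <- nchar(alt_tr$protein)

  if (delta != 0L) {
    category <- if (abs(delta) %% 3L != 0L) "frameshift" else "inframe_indel"
    return(call(category, len_alt, alt_tr$stopped))
  }
  if (identical(alt_tr$protein, ref_tr$protein))
    return(call("synonymous", len_alt))
  if (len_alt < len_ref && alt_tr$stopped)
    return(call("nonsense", len_alt))
  call("missense", len_alt, alt_tr$stopped)
}

#' Classify a table of variants against a set of gene models
#'
#' Each variant is classified against every gene on its chromosome whose
#' CDS span it touches; variants touching no gene are reported once as
#' `non_coding`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (VCF-style; columns named `CHROM`, `POS`, `REF`, `ALT` are accepted).
#' @param genes list of [gene_model()]s.
#' @param genome named character vector from [read_genome_fasta()].
#' @return data.frame of consequence calls, one row per variant-gene pair.
#' @export
classify_variants <- function(variants, genes, genome) {
  names(variants) <- tolower(names(variants))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), category = character(0),
                      protein_length_ref = integer(0),
                      protein_length_alt = integer(0),
                      premature_stop = logical(0))
  if (nrow(variants) == 0) return(empty)
  spans <- do.call(rbind, lapply(genes, function(g) {
    data.frame(chrom = g$chromosome,
               from = min(g$cds_intervals[, 1]),
               to = max(g$cds_intervals[, 2]))
  }))
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    touch <- which(spans$chrom == v$chrom & spans$from <= v$pos + nchar(v$ref) &
                     spans$to >= v$pos)
    if (!length(touch)) {
      return(data.frame(gene_id = NA_character_, chrom = v$chrom,
                        pos = as.integer(v$pos), ref = toupper(v$ref),
                        alt = toupper(v$alt), category = "non_coding",
                        protein_length_ref = NA_integer_,
                        protein_length_alt = NA_integer_,
                        premature_stop = FALSE, stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(touch, function(k) {
      as.data.frame(classify_variant(genome, genes[[k]], v))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a variant set for truncating consequences
#'
#' Classifies every variant and keeps the calls that create a frameshift or
#' a premature stop codon (nonsense) -- the classes expected to disrupt
#' protein function outright.
#'
#' @inheritParams classify_variants
#' @return data.frame of calls with `category` in
#'   `{"frameshift", "nonsense"}`.
#' @export
scan_for_truncations <- function(variants, genes, genome) {
  calls <- classify_variants(variants, genes, genome)
  out <- calls[calls$category %in% c("frameshift", "nonsense"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a variant table
#'
#' TSV with columns `CHROM`, `POS`, `REF`, `ALT` (case-insensitive; extra
#' columns such as `zygosity` are carried through).
#'
#' @param path TSV path.
#' @return data.frame with lower-cased standard column names.
#' @export
read_variant_table <- function(path) {
  v <- read.delim(path, stringsAsFactors = FALSE)
  names(v) <- tolower(names(v))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(v)))
  v$pos <- as.integer(v$pos)
  v
}

#' Drop heterozygous genotype calls
#'
#' Haploid samples genotyped under a diploid model should never be called
#' heterozygous; heterozygous calls therefore flag unreliable sites and are
#' discarded as a quality filter.
#'
#' @param calls data.frame with a `zygosity` column (`"hom"`/`"het"`,
#'   case-insensitive; `"heterozygous"` also recognized).
#' @return the calls with heterozygous rows removed.
#' @export
drop_heterozygous <- function(calls) {
  stopifnot("zygosity" %in% names(calls))
  z <- tolower(calls$zygosity)
  out <- calls[!(z %in% c("het", "heterozygous")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segregant genotype matrix
#'
#' @param geno character matrix, strains x markers, values `"P1"`, `"P2"`
#'   or `NA` (parental haplotype of origin).
#' @param markers data.frame with columns `chrom` and `pos`, one row per
#'   marker, strictly increasing position within chromosome.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, markers) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == nrow(markers),
            all(c("chrom", "pos") %in% names(markers)))
  ok <- geno %in% c("P1", "P2") | is.na(geno)
  if (!all(ok)) stop("genotype values must be P1, P2 or NA")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within ", ch)
  }
  structure(list(geno = geno, markers = markers), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix %d strains x %d markers (%d chromosomes), %.1f%% missing>\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$markers$chrom)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Read / write a genotype matrix CSV
#'
#' The CSV has one row per strain and one column per marker; column names
#' encode the marker as `chrom:pos`, the first column holds strain ids,
#' and cells are `P1`, `P2` or `NA`.
#'
#' @param path CSV path.
#' @return A [genotype_matrix()].
#' @export
read_genotype_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  strains <- d[[1]]
  geno <- as.matrix(d[, -1, drop = FALSE])
  rownames(geno) <- strains
  parts <- strsplit(colnames(geno), ":", fixed = TRUE)
  markers <- data.frame(chrom = vapply(parts, `[`, "", 1),
                        pos = as.integer(vapply(parts, `[`, "", 2)))
  genotype_matrix(geno, markers)
}

#' @rdname read_genotype_csv
#' @param gm a [genotype_matrix()].
#' @export
write_genotype_csv <- function(gm, path) {
  d <- as.data.frame(gm$geno)
  colnames(d) <- paste0(gm$markers$chrom, ":", gm$markers$pos)
  d <- cbind(strain = rownames(gm$geno) %||% paste0("S", seq_len(nrow(d))), d)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# last observation carried forward (NA-preserving), vector version
.locf <- function(v) {
  pos <- which(!is.na(v))
  if (!length(pos)) return(v)
  idx <- findInterval(seq_along(v), pos)
  out <- rep(NA_character_, length(v))
  out[idx > 0] <- v[pos[idx[idx > 0]]]
  out
}

#' Fill residual missing genotypes from the nearest called marker
#'
#' After [impute_flanked()], missing calls remain at chromosome ends and
#' where the flanking haplotypes disagree. For mapping, each such call is
#' filled per strain with the haplotype of the nearest called marker on the
#' same chromosome (ties go to the preceding marker). This preserves the
#' strain's haplotype-block structure, whereas a column-majority fill would
#' fabricate block boundaries out of missingness patterns.
#'
#' @param gm a [genotype_matrix()].
#' @return a complete [genotype_matrix()] (strains with no calls at all on
#'   a chromosome keep their `NA`s).
#' @export
fill_nearest_haplotype <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  geno <- gm$geno
  for (ch in unique(gm$markers$chrom)) {
    j <- which(gm$markers$chrom == ch)
    pos <- gm$markers$pos[j]
    for (i in seq_len(nrow(geno))) {
      v <- geno[i, j]
      if (!anyNA(v) || all(is.na(v))) next
      fwd <- .locf(v)
      bwd <- rev(.locf(rev(v)))
      called <- which(!is.na(v))
      fill <- ifelse(is.na(fwd), bwd, fwd)
      miss <- is.na(v)
      # prefer the genuinely nearest flank where both exist
      for (k in which(miss & !is.na(fwd) & !is.na(bwd))) {
        left <- max(called[called < k])
        right <- min(called[called > k])
        fill[k] <- if (pos[k] - pos[left] <= pos[right] - pos[k]) {
          v[left]
        } else {
          v[right]
        }
      }
      v[miss] <- fill[miss]
      geno[i, j] <- v
    }
  }
  genotype_matrix(geno, gm$markers)
}

#' Impute missing genotypes flanked by agreeing haplotypes
#'
#' For each strain and each uncalled marker, when the nearest called markers
#' on *both* sides (same chromosome) carry the same parental haplotype, the
#' missing call is filled with that haplotype: a recombination event inside
#' a run of agreeing flanks would require two crossovers in a short
#' interval. Disagreeing flanks and chromosome ends are left missing;
#' called genotypes are never changed. The operation is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @return the imputed [genotype_matrix()].
#' @export
impute_flanked <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  geno <- gm$geno
  for (ch in unique(gm$markers$chrom)) {
    j <- which(gm$markers$chrom == ch)
    for (i in seq_len(nrow(geno))) {
      v <- geno[i, j]
      if (!anyNA(v)) next
      fwd <- .locf(v)
      bwd <- rev(.locf(rev(v)))
      fill <- is.na(v) & !is.na(fwd) & !is.na(bwd) & fwd == bwd
      v[fill] <- fwd[fill]
      geno[i, j] <- v
    }
  }
  genotype_matrix(geno, gm$markers)
}
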