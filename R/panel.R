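#' Genotype panel container
#'
#' Holds an ordered SNP map, sample metadata and a samples-by-loci genotype
#' matrix. Genotypes are coded as copies of allele B: 0 = homozygous A,
#' 1 = heterozygous, 2 = homozygous B, -1 = missing. Loci must be sorted by
#' (chromosome, position) with strictly increasing positions per chromosome.
#'
#' @param loci data.frame with columns `chrom`, `pos_bp`, `allele_a`,
#'   `allele_b` (alleles may be `NA` for toy panels).
#' @param samples data.frame with columns `id`, `flock`, `status`; `status`
#'   is one of `"affected"`, `"carrier"`, `"unaffected"`, `"unknown"`.
#' @param genotypes Integer matrix, one row per sample (rownames = sample
#'   ids), one column per locus, codes in \{-1, 0, 1, 2\}.
#' @param planted Optional data.frame describing planted ancestral segments
#'   (columns `chrom`, `start_index`, `end_index`, `n_snps`, `start_bp`,
#'   `end_bp`; indices are 1-based within the chromosome's locus list).
#' @param causal_copies Optional named integer vector: per-sample copy number
#'   (0/1/2) of the causal haplotype.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(loci, samples, genotypes,
                           planted = NULL, causal_copies = NULL) {
  loci$chrom <- as.character(loci$chrom)
  samples$id <- as.character(samples$id)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes))) rownames(genotypes) <- samples$id
  obj <- structure(list(loci = loci, samples = samples,
                        genotypes = genotypes, planted = planted,
                        causal_copies = causal_copies),
                   class = "genotype_panel")
  validate_genotype_panel(obj)
}

validate_genotype_panel <- function(p) {
  stopifnot(inherits(p, "genotype_panel"))
  if (!all(c("chrom", "pos_bp") %in% names(p$loci)))
    stop("loci need columns chrom and pos_bp", call. = FALSE)
  if (!all(c("id", "flock", "status") %in% names(p$samples)))
    stop("samples need columns id, flock and status", call. = FALSE)
  if (nrow(p$genotypes) != nrow(p$samples) ||
      ncol(p$genotypes) != nrow(p$loci))
    stop("genotype matrix dimensions do not match samples x loci",
         call. = FALSE)
  bad <- !p$genotypes %in% c(-1L, 0L, 1L, 2L)
  if (any(bad))
    stop("genotype codes must be in {-1, 0, 1, 2}", call. = FALSE)
  if (anyDuplicated(p$samples$id))
    stop("duplicate sample ids", call. = FALSE)
  # per-chromosome strictly increasing positions, chromosomes contiguous
  idx <- split(seq_len(nrow(p$loci)), p$loci$chrom)
  for (ii in idx) {
    if (any(diff(ii) != 1L))
      stop("loci of one chromosome must be contiguous in the map",
           call. = FALSE)
    if (is.unsorted(p$loci$pos_bp[ii], strictly = TRUE))
      stop("positions must be strictly increasing within a chromosome",
           call. = FALSE)
  }
  p
}

# global locus indices of one chromosome, in map order
chrom_loci <- function(panel, chrom) {
  which(panel$loci$chrom == as.character(chrom))
}

panel_chroms <- function(panel) unique(panel$loci$chrom)

sample_index <- function(panel, ids) {
  i <- match(as.character(ids), panel$samples$id)
  if (anyNA(i))
    stop("unknown sample id(s): ",
         paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' @exportS3Method base::print
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$samples), " samples x ", nrow(x$loci),
      " loci on ", length(panel_chroms(x)), " chromosome(s)\n", sep = "")
  tab <- table(x$samples$flock, x$samples$status)
  print(tab)
  if (!is.null(x$planted) && nrow(x$planted))
    cat("planted segments: ",
        paste(sprintf("chr%s[%d..%d] (%d SNPs)", x$planted$chrom,
                      x$planted$start_index, x$planted$end_index,
                      x$planted$n_snps), collapse = ", "), "\n", sep = "")
  invisible(x)
}
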