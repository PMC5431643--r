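# File interchange. Genotype panels travel either as PLINK-style text
# (.ped/.map) or as a single TSV dialect:
#   header lines  "#sample<TAB>id<TAB>flock<TAB>status" (one per animal)
#   column header "chrom pos_bp allele_a allele_b <sample ids...>"
#   one row per locus, genotype codes -1/0/1/2.

#' Write / read a genotype panel as the package's TSV dialect
#'
#' @param panel A [genotype_panel()].
#' @param path Output file.
#' @return `write_genotype_tsv`: `path`, invisibly. `read_genotype_tsv`:
#'   a [genotype_panel()].
#' @export
write_genotype_tsv <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample\t%s\t%s\t%s", panel$samples$id,
                     panel$samples$flock, panel$samples$status), con)
  tab <- cbind(panel$loci[, c("chrom", "pos_bp", "allele_a", "allele_b")],
               as.data.frame(t(panel$genotypes)))
  names(tab) <- c("chrom", "pos_bp", "allele_a", "allele_b",
                  panel$samples$id)
  writeLines(paste(names(tab), collapse = "\t"), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#sample")]
  parts <- strsplit(meta, "\t", fixed = TRUE)
  samples <- data.frame(id = vapply(parts, `[`, "", 2L),
                        flock = vapply(parts, `[`, "", 3L),
                        status = vapply(parts, `[`, "", 4L),
                        stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  loci <- data.frame(chrom = tab$chrom, pos_bp = as.integer(tab$pos_bp),
                     allele_a = tab$allele_a, allele_b = tab$allele_b,
                     stringsAsFactors = FALSE)
  G <- vapply(seq_len(nrow(tab)), function(i) {
    as.integer(unlist(tab[i, samples$id]))
  }, integer(nrow(samples)))  # samples x loci
  rownames(G) <- samples$id
  genotype_panel(loci, samples, G)
}

#' Write / read a genotype panel as PLINK-style .ped/.map text
#'
#' The `.map` file has columns chrom, snp id, genetic distance (0) and bp
#' position; the `.ped` file has family/individual ids, zeroed parental
#' ids and sex, an affection code (2 = affected, 1 = otherwise) and two
#' allele columns per locus (`0 0` for missing). Reading back recovers
#' hom/het/missing structure; the allele that plays "allele B" at a locus is
#' taken from the `.map`-order allele pair written alongside, so codes
#' round-trip exactly.
#'
#' @param panel A [genotype_panel()].
#' @param prefix Path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return `write_plink`: `prefix`, invisibly; `read_plink`: a
#'   [genotype_panel()].
#' @export
write_plink <- function(panel, prefix) {
  map <- data.frame(chrom = panel$loci$chrom,
                    id = sprintf("snp%06d", seq_len(nrow(panel$loci))),
                    cm = 0L, pos = panel$loci$pos_bp,
                    allele_a = panel$loci$allele_a,
                    allele_b = panel$loci$allele_b)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  a <- panel$loci$allele_a
  b <- panel$loci$allele_b
  ped_rows <- vapply(seq_len(nrow(panel$samples)), function(i) {
    g <- panel$genotypes[i, ]
    a1 <- ifelse(g == -1L, "0", ifelse(g >= 1L, b, a))
    a2 <- ifelse(g == -1L, "0", ifelse(g == 2L, b, a))
    paste(c(panel$samples$flock[i], panel$samples$id[i], "0", "0", "0",
            if (panel$samples$status[i] == "affected") "2" else "1",
            rbind(a1, a2)), collapse = " ")
  }, character(1))
  writeLines(ped_rows, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), sep = "\t",
                    colClasses = "character")
  names(map) <- c("chrom", "id", "cm", "pos", "allele_a", "allele_b")
  loci <- data.frame(chrom = map$chrom, pos_bp = as.integer(map$pos),
                     allele_a = map$allele_a, allele_b = map$allele_b,
                     stringsAsFactors = FALSE)
  ped <- strsplit(readLines(paste0(prefix, ".ped")), " ", fixed = TRUE)
  n_loci <- nrow(loci)
  samples <- data.frame(
    id = vapply(ped, `[`, "", 2L),
    flock = vapply(ped, `[`, "", 1L),
    status = ifelse(vapply(ped, `[`, "", 6L) == "2", "affected", "unknown"),
    stringsAsFactors = FALSE)
  G <- t(vapply(ped, function(p) {
    al <- p[-(1:6)]
    a1 <- al[c(TRUE, FALSE)]
    a2 <- al[c(FALSE, TRUE)]
    ifelse(a1 == "0" | a2 == "0", -1L,
           (a1 == loci$allele_b) + (a2 == loci$allele_b))
  }, integer(n_loci)))
  rownames(G) <- samples$id
  genotype_panel(loci, samples, G)
}

#' Write shared regions as BED plus a TSV report
#'
#' BED intervals are 0-based half-open (internal coordinates are 1-based
#' inclusive); the TSV report carries the SNP counts and the IBD /
#' carrier-fixation flags.
#'
#' @param regions Regions from [shared_concordant_regions()].
#' @param bed_path,tsv_path Output files (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = regions$chrom,
                      start = regions$start_bp - 1L,
                      end = regions$end_bp,
                      name = sprintf("region_%d", seq_len(nrow(regions))))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    write.table(regions, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Write RFLP templates (FASTA) and primers (TSV)
#'
#' @param fixture An `rflp_fixture` from [gen_rflp_templates()].
#' @param fasta_path FASTA output for the two allele templates.
#' @param primers_path Optional TSV with the primer pair.
#' @return Invisibly, the FASTA path.
#' @export
write_rflp_fasta <- function(fixture, fasta_path, primers_path = NULL) {
  seqs <- Biostrings::DNAStringSet(c(wild_type = fixture$wild,
                                     mutant = fixture$mutant))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(primers_path))
    write.table(data.frame(name = c("fwd", "rev"),
                           sequence = c(fixture$primers$fwd,
                                        fixture$primers$rev)),
                primers_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Write / read a variant set as VCF v4.2
#'
#' Writes a minimal VCF v4.2 with GT genotypes and the generator's truth
#' class (when present) in the INFO field; reads back via the vcfR parser.
#'
#' @param vs A [variant_set()].
#' @param path VCF path (uncompressed).
#' @return `write_variant_vcf`: `path`, invisibly; `read_variant_vcf`: a
#'   [variant_set()].
#' @export
write_variant_vcf <- function(vs, path) {
  G <- variant_genotypes(vs)
  gt_str <- matrix(c(`-1` = "./.", `0` = "0/0", `1` = "0/1",
                     `2` = "1/1")[as.character(G)], nrow(G))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ciliomap",
    "##INFO=<ID=TRUTH,Number=1,Type=String,Description=\"Simulated truth class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t"))
  info <- if ("class_truth" %in% names(vs))
    paste0("TRUTH=", vs$class_truth) else rep(".", nrow(vs))
  body <- vapply(seq_len(nrow(vs)), function(k) {
    paste(c(vs$chrom[k], vs$pos_bp[k], vs$id[k], vs$ref[k], vs$alt[k], ".",
            "PASS", info[k], "GT", gt_str[, k]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_variant_vcf
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  code <- matrix(-1L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  recs <- data.frame(id = fix$ID, chrom = fix$CHROM,
                     pos_bp = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  truth <- vcfR::extract.info(v, "TRUTH")
  if (!all(is.na(truth))) recs$class_truth <- truth
  variant_set(recs, t(code))
}

#' Write a grade table or cilia sample as TSV
#'
#' @param x A `grade_table` or `cilia_sample`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pheno_tsv <- function(x, path) {
  if (inherits(x, "grade_table")) {
    df <- data.frame(condition = rownames(x), unclass(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a grade table written by [write_pheno_tsv()]
#' @param path TSV path.
#' @return A `grade_table` matrix.
#' @export
read_grade_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  tab <- as.matrix(df[, -1, drop = FALSE])
  rownames(tab) <- df$condition
  storage.mode(tab) <- "integer"
  class(tab) <- c("grade_table", class(tab))
  tab
}
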