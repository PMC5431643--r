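#' Approximate ovine autosome lengths
#'
#' Lengths (bp) of the 26 sheep autosomes used to place simulated SNP-chip
#' markers. Values approximate the ovine reference assembly at megabase
#' resolution; the mapper is purely positional, so only relative sizes and a
#' realistic marker density matter.
#'
#' @return Named numeric vector, names `"1"`..`"26"`, values in bp.
#' @export
ovine_chrom_lengths <- function() {
  mb <- c(275, 249, 224, 119, 108, 117, 100, 91, 95, 86, 62, 79, 83,
          63, 81, 71, 72, 68, 61, 51, 50, 51, 62, 42, 45, 44)
  setNames(mb * 1e6, as.character(seq_along(mb)))
}

#' Configuration for the synthetic flock generator
#'
#' Bundles every knob of the SNP-panel simulator. The defaults reproduce the
#' study design this package models: a ~54k-marker ovine SNP chip, two
#' carrier-bred flocks (6 and 14 affected lambs respectively, plus carriers
#' and unaffected controls), a shared ancestral haplotype planted on two
#' chromosomes as segments of 26 and 8 consecutive markers, and reduced
#' penetrance of 0.482 for homozygous-mutant lambs (4 x 37/307, the affected
#' fraction observed over ten years of carrier-by-carrier matings).
#'
#' @param n_snps Total marker count on the simulated chip (default 54,241).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param maf_range Lower/upper bounds in (0, 0.5] for the allele-B frequency
#'   of background markers, drawn uniformly per locus.
#' @param flock_sizes Named list; each element is a named integer vector with
#'   entries `affected`, `carrier`, `unaffected` giving the ascertained
#'   composition of that flock (see [gen_snp_panel()]).
#' @param penetrance Probability that a homozygous-mutant lamb expresses (and
#'   is labelled with) the phenotype; used by [sim_carrier_matings()].
#' @param genotyping_error_rate Per-call probability that a genotype is
#'   replaced by one of the two other (non-missing) codes.
#' @param planted_segments data.frame with columns `chrom` and `n_snps`: the
#'   chromosome and marker length of each planted ancestral segment. All
#'   segments co-segregate as one causal haplotype.
#' @param seed Integer RNG seed; identical seeds give identical panels.
#'
#' @return An object of class `sim_config`.
#' @seealso [gen_snp_panel()], [sim_carrier_matings()]
#' @export
sim_config <- function(n_snps = 54241L,
                       chrom_lengths = ovine_chrom_lengths(),
                       maf_range = c(0.05, 0.5),
                       flock_sizes = list(
                         A = c(affected = 6L, carrier = 2L, unaffected = 2L),
                         B = c(affected = 14L, carrier = 4L, unaffected = 4L)
                       ),
                       penetrance = 0.482,
                       genotyping_error_rate = 0,
                       planted_segments = data.frame(
                         chrom = c("9", "11"),
                         n_snps = c(26L, 8L),
                         stringsAsFactors = FALSE
                       ),
                       seed = NULL) {
  cfg <- structure(
    list(n_snps = as.integer(n_snps),
         chrom_lengths = chrom_lengths,
         maf_range = as.numeric(maf_range),
         flock_sizes = flock_sizes,
         penetrance = as.numeric(penetrance),
         genotyping_error_rate = as.numeric(genotyping_error_rate),
         planted_segments = planted_segments,
         seed = seed),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is_count(cfg$n_snps) || cfg$n_snps < 1)
    stop("`n_snps` must be a positive integer", call. = FALSE)
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths < 1))
    stop("`chrom_lengths` must be a named vector of positive lengths",
         call. = FALSE)
  if (length(cfg$maf_range) != 2L ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("`maf_range` bounds must lie in (0, 0.5] and be ordered",
         call. = FALSE)
  if (!(cfg$penetrance > 0 && cfg$penetrance <= 1))
    stop("`penetrance` must lie in (0, 1]", call. = FALSE)
  if (!(cfg$genotyping_error_rate >= 0 && cfg$genotyping_error_rate < 1))
    stop("`genotyping_error_rate` must lie in [0, 1)", call. = FALSE)
  for (fl in names(cfg$flock_sizes)) {
    fs <- cfg$flock_sizes[[fl]]
    if (!all(c("affected", "carrier", "unaffected") %in% names(fs)) ||
        any(fs < 0))
      stop("each flock needs non-negative affected/carrier/unaffected counts",
           call. = FALSE)
  }
  ps <- cfg$planted_segments
  if (!is.null(ps) && nrow(ps)) {
    if (!all(c("chrom", "n_snps") %in% names(ps)))
      stop("`planted_segments` needs columns chrom and n_snps", call. = FALSE)
    if (any(ps$n_snps < 1))
      stop("planted segment SNP counts must be >= 1", call. = FALSE)
    if (!all(ps$chrom %in% names(cfg$chrom_lengths)))
      stop("planted segment chromosome not in `chrom_lengths`", call. = FALSE)
  }
  cfg
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  markers:", x$n_snps, "on", length(x$chrom_lengths), "chromosomes\n")
  cat("  flocks:", paste(sprintf(
    "%s (%d aff / %d car / %d unaff)", names(x$flock_sizes),
    vapply(x$flock_sizes, `[[`, 1L, "affected"),
    vapply(x$flock_sizes, `[[`, 1L, "carrier"),
    vapply(x$flock_sizes, `[[`, 1L, "unaffected")), collapse = ", "), "\n")
  cat("  planted segments:", paste(sprintf(
    "chr%s (%d SNPs)", x$planted_segments$chrom,
    x$planted_segments$n_snps), collapse = ", "), "\n")
  cat("  penetrance:", x$penetrance,
      " genotyping error:", x$genotyping_error_rate, "\n")
  invisible(x)
}
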