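#' Keep variants inside candidate regions
#'
#' Retains variants whose position falls inside any supplied region
#' (1-based inclusive interval test on the same chromosome); all others are
#' rejected with reason `outside_region`.
#'
#' @param vs A [variant_set()].
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp`
#'   (non-overlapping).
#' @return The variant set with verdicts updated.
#' @export
filter_by_region <- function(vs, regions) {
  stopifnot(inherits(vs, "variant_set"))
  inside <- vapply(seq_len(nrow(vs)), function(k) {
    any(regions$chrom == vs$chrom[k] &
          regions$start_bp <= vs$pos_bp[k] &
          regions$end_bp >= vs$pos_bp[k])
  }, logical(1))
  reject(vs, !inside, "outside_region")
}

#' Segregation filter for a fully penetrant recessive variant
#'
#' Keeps variants whose genotypes follow the expected recessive segregation
#' pattern: homozygous-alt in every affected animal, heterozygous in every
#' known carrier, and never homozygous-alt in an unaffected control. Missing
#' genotypes are non-disqualifying but are counted; variants missing in more
#' than 20% of affected animals are flagged `low_confidence`.
#'
#' @param vs A [variant_set()] whose genotype rownames appear in `panel`.
#' @param panel A [genotype_panel()] supplying per-sample status labels.
#' @return The variant set with verdicts updated and columns
#'   `n_missing_affected` and `low_confidence` added.
#' @export
segregation_filter <- function(vs, panel) {
  stopifnot(inherits(vs, "variant_set"))
  G <- variant_genotypes(vs)
  st <- panel$samples$status[match(rownames(G), panel$samples$id)]
  if (anyNA(st))
    stop("variant genotypes include samples absent from the panel",
         call. = FALSE)
  aff <- st == "affected"
  car <- st == "carrier"
  una <- st == "unaffected"
  fail_aff <- logical(nrow(vs))
  fail_car <- logical(nrow(vs))
  fail_ctl <- logical(nrow(vs))
  n_miss_aff <- integer(nrow(vs))
  for (k in seq_len(nrow(vs))) {
    g <- G[, k]
    n_miss_aff[k] <- sum(g[aff] == -1L)
    fail_aff[k] <- any(g[aff] != 2L & g[aff] != -1L)
    fail_car[k] <- any(g[car] != 1L & g[car] != -1L)
    fail_ctl[k] <- any(g[una] == 2L)
  }
  vs <- reject(vs, fail_aff, "not_hom_in_affected")
  vs <- reject(vs, fail_car, "not_het_in_carrier")
  vs <- reject(vs, fail_ctl, "present_in_controls")
  vs$n_missing_affected <- n_miss_aff
  vs$low_confidence <- sum(aff) > 0 & n_miss_aff > 0.2 * sum(aff)
  vs
}

#' Annotate coding consequence against a transcript model
#'
#' Maps each variant to the transcript's coding sequence, derives the cDNA
#' position, codon number (`ceiling(cdna/3)`), reference and alternate amino
#' acids (standard genetic code, strand-aware), the consequence class
#' (`missense`, `synonymous`, `stop_gained`, or `noncoding` for positions
#' outside the CDS), and the Grantham distance of the substitution. A coding
#' variant whose stated reference base disagrees with the transcript
#' sequence raises a reference-mismatch error.
#'
#' @param vs A [variant_set()] (or any data.frame with `chrom`, `pos_bp`,
#'   `ref`, `alt`).
#' @param transcript A placed [transcript_fixture()]; defaults to the
#'   `"transcript"` attribute of `vs`.
#' @return The variant set with columns `cdna_pos`, `codon_number`,
#'   `ref_aa`, `alt_aa`, `consequence`, `grantham` added.
#' @export
annotate_consequence <- function(vs, transcript = attr(vs, "transcript")) {
  if (is.null(transcript))
    stop("no transcript model supplied", call. = FALSE)
  fx <- transcript
  n <- nrow(vs)
  cdna <- rep(NA_integer_, n)
  on_chr <- vs$chrom == fx$chrom
  cdna[on_chr] <- genomic_to_cdna(fx, vs$pos_bp[on_chr])
  codon_no <- ifelse(is.na(cdna), NA_integer_, as.integer(ceiling(cdna / 3)))
  ref_aa <- alt_aa <- rep(NA_character_, n)
  consequence <- ifelse(is.na(cdna), "noncoding", NA_character_)
  grantham <- rep(NA_real_, n)
  minus <- fx$strand == "-"
  for (k in which(!is.na(cdna))) {
    cn <- codon_no[k]
    cod <- substr(fx$cds, 3L * cn - 2L, 3L * cn)
    off <- cdna[k] - (3L * cn - 3L)
    ref_tx <- substr(cod, off, off)
    ref_in <- if (minus) dna_complement(vs$ref[k]) else vs$ref[k]
    alt_in <- if (minus) dna_complement(vs$alt[k]) else vs$alt[k]
    if (ref_tx != ref_in)
      stop("reference mismatch for variant ", vs$id[k] %||% k, ": transcript has ",
           ref_tx, ", variant states ", ref_in, call. = FALSE)
    alt_cod <- cod
    substr(alt_cod, off, off) <- alt_in
    ref_aa[k] <- translate_codon(cod)
    alt_aa[k] <- translate_codon(alt_cod)
    consequence[k] <-
      if (alt_aa[k] == ref_aa[k]) "synonymous"
      else if (alt_aa[k] == "*") "stop_gained"
      else "missense"
    grantham[k] <- if (alt_aa[k] == "*") NA_real_ else
      grantham_distance(ref_aa[k], alt_aa[k])
  }
  vs$cdna_pos <- cdna
  vs$codon_number <- codon_no
  vs$ref_aa <- ref_aa
  vs$alt_aa <- alt_aa
  vs$consequence <- consequence
  vs$grantham <- grantham
  vs
}

dna_complement <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[toupper(b)]]
}

#' Classify annotated variants as deleterious candidates
#'
#' Decision proxy for pathogenicity prediction: a variant is a `candidate`
#' iff it is missense, its Grantham distance reaches `grantham_min` and the
#' ortholog-alignment conservation of its reference residue reaches
#' `conservation_min`. Non-missense variants are rejected regardless of
#' scores; missense variants failing a gate get reasons `low_grantham`,
#' `low_conservation`, or `conservation_undefined` when the residue is not
#' covered by the alignment.
#'
#' @param vs An annotated [variant_set()] (see [annotate_consequence()]).
#' @param alignment An [ortholog_alignment()].
#' @param grantham_min Minimum Grantham distance (default 100, the
#'   conventional "radical substitution" cut).
#' @param conservation_min Minimum conservation fraction (default 0.8).
#' @return The variant set with verdicts updated and a `conservation`
#'   column added.
#' @export
classify_deleterious <- function(vs, alignment = ortholog_alignment(),
                                 grantham_min = 100,
                                 conservation_min = 0.8) {
  if (is.null(vs$consequence))
    stop("variants are not annotated; run annotate_consequence()",
         call. = FALSE)
  cons <- vapply(seq_len(nrow(vs)), function(k) {
    if (is.na(vs$codon_number[k])) return(NA_real_)
    conservation_score(alignment, vs$codon_number[k])
  }, numeric(1))
  vs$conservation <- cons
  vs <- reject(vs, vs$consequence != "missense", "not_missense")
  vs <- reject(vs, vs$consequence == "missense" &
                 !is.na(vs$grantham) & vs$grantham < grantham_min,
               "low_grantham")
  vs <- reject(vs, vs$consequence == "missense" & is.na(cons),
               "conservation_undefined")
  vs <- reject(vs, vs$consequence == "missense" & !is.na(cons) &
                 cons < conservation_min, "low_conservation")
  vs
}

#' Run the full candidate-variant filter chain
#'
#' Applies, in order: region filter, segregation filter, consequence
#' annotation and deleteriousness classification. Region and segregation
#' filters commute (both test independent per-variant predicates), so the
#' surviving set does not depend on their order.
#'
#' @inheritParams filter_by_region
#' @inheritParams segregation_filter
#' @inheritParams classify_deleterious
#' @param transcript A placed [transcript_fixture()].
#' @return The fully annotated variant set; survivors via [candidates()].
#' @export
filter_candidate_variants <- function(vs, regions, panel,
                                      transcript = attr(vs, "transcript"),
                                      alignment = ortholog_alignment(),
                                      grantham_min = 100,
                                      conservation_min = 0.8) {
  vs <- filter_by_region(vs, regions)
  vs <- segregation_filter(vs, panel)
  vs <- annotate_consequence(vs, transcript)
  classify_deleterious(vs, alignment, grantham_min, conservation_min)
}
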