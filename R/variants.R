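#' Variant set container
#'
#' A data.frame of variant records plus a per-sample genotype matrix kept in
#' the `"genotypes"` attribute (samples x variants, same codes as
#' [genotype_panel()]). Filters annotate `verdict`/`reason` columns in place
#' rather than dropping rows, so every rejection is auditable.
#'
#' @param records data.frame with at least `id`, `chrom`, `pos_bp`, `ref`,
#'   `alt`.
#' @param genotypes Integer matrix, rows = samples (rownames required),
#'   columns = variants (colnames = variant ids).
#' @return Object of class `variant_set` (a data.frame subclass).
#' @export
variant_set <- function(records, genotypes) {
  stopifnot(all(c("id", "chrom", "pos_bp", "ref", "alt") %in% names(records)))
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(!is.null(rownames(genotypes)),
            ncol(genotypes) == nrow(records))
  colnames(genotypes) <- records$id
  if (!"verdict" %in% names(records)) records$verdict <- "candidate"
  if (!"reason" %in% names(records)) records$reason <- NA_character_
  structure(records, genotypes = genotypes,
            class = c("variant_set", "data.frame"))
}

#' Extract the per-sample genotype matrix of a variant set
#' @param vs A [variant_set()].
#' @return Integer matrix, samples x variants.
#' @export
variant_genotypes <- function(vs) attr(vs, "genotypes")

reject <- function(vs, which, reason) {
  hit <- which & vs$verdict == "candidate"
  vs$verdict[hit] <- "rejected"
  vs$reason[hit] <- reason
  vs
}

#' Surviving candidates of a filtered variant set
#' @param vs A [variant_set()].
#' @return The subset of rows still carrying verdict `"candidate"`.
#' @export
candidates <- function(vs) vs[vs$verdict == "candidate", , drop = FALSE]

#' Generate variant calls with recorded truth labels
#'
#' Emits the fixture's two causal variants with per-sample genotypes
#' perfectly correlated with the planted haplotype (homozygous-mutant
#' animals are hom-alt, carriers het, others hom-ref), plus `n_decoys`
#' background variants cycling through four truth classes: `synonymous`
#' (in-region, perfect segregation, silent), `intergenic` (in-region but
#' outside the transcript), `missense_outside_region`, and
#' `missense_nonsegregating` (in-region missense that is heterozygous in one
#' affected animal). Truth labels are recorded in `class_truth` so the
#' filter chain can be scored against the generator.
#'
#' @param panel A [gen_snp_panel()] panel with planted segments.
#' @param fixture A placed [transcript_fixture()] (see [place_transcript()]);
#'   an unplaced fixture is placed into the panel's first planted segment.
#' @param n_decoys Number of decoy variants.
#' @param seed Optional RNG seed.
#' @return A [variant_set()]; its `"transcript"` attribute holds the placed
#'   fixture.
#' @export
gen_variant_calls <- function(panel, fixture = transcript_fixture(),
                              n_decoys = 0L, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), is_count(n_decoys))
  if (is.null(panel$planted) || !nrow(panel$planted))
    stop("panel has no planted segments; the fixture gene must lie inside one",
         call. = FALSE)
  if (is.null(fixture$tx_start)) fixture <- place_transcript(fixture, panel)
  seg <- panel$planted[panel$planted$chrom == fixture$chrom, , drop = FALSE]
  span <- transcript_genomic_span(fixture)
  inside <- nrow(seg) && any(fixture$tx_start >= seg$start_bp &
                               fixture$tx_start + span - 1L <= seg$end_bp)
  if (!inside)
    stop("fixture gene lies outside every planted segment", call. = FALSE)

  copies <- panel$causal_copies
  if (is.null(copies))
    stop("panel records no causal copy numbers", call. = FALSE)
  samples <- panel$samples$id
  causal_gt <- matrix(rep(as.integer(copies[samples]), 2L),
                      ncol = 2L, dimnames = list(samples, NULL))

  with_seed(seed, {
    recs <- data.frame(
      id = c("causal_1", "causal_2"),
      chrom = fixture$chrom,
      pos_bp = cdna_to_genomic(fixture, fixture$causal$cdna_pos),
      ref = fixture$causal$ref, alt = fixture$causal$alt,
      class_truth = "causal", stringsAsFactors = FALSE)
    G <- causal_gt

    if (n_decoys > 0L) {
      classes <- rep(c("synonymous", "intergenic", "missense_outside_region",
                       "missense_nonsegregating"),
                     length.out = n_decoys)
      dec <- lapply(seq_len(n_decoys), function(k) {
        make_decoy(classes[k], panel, fixture, copies[samples], k)
      })
      recs <- rbind(recs, do.call(rbind, lapply(dec, `[[`, "rec")))
      G <- cbind(G, do.call(cbind, lapply(dec, `[[`, "gt")))
    }
    o <- order(recs$chrom, recs$pos_bp)
    variant_set_with_transcript(recs[o, , drop = FALSE],
                                G[, o, drop = FALSE], fixture)
  })
}

variant_set_with_transcript <- function(recs, G, fixture) {
  vs <- variant_set(recs, G)
  attr(vs, "transcript") <- fixture
  vs
}

# build one decoy variant of the requested truth class
make_decoy <- function(class, panel, fixture, copies, k) {
  samples <- names(copies)
  seg_gt <- as.integer(copies)  # perfect-segregation genotype vector
  ex <- transcript_exons_genomic(fixture)
  seg <- panel$planted[panel$planted$chrom == fixture$chrom, ][1L, ]
  bases <- c("A", "C", "G", "T")
  if (class == "synonymous") {
    # third position of a codon whose 3rd-base change is silent (fourfold
    # degenerate family, e.g. CTx Leu); search the CDS for one
    pos_c <- pick_synonymous_site(fixture, k)
    gpos <- cdna_to_genomic(fixture, pos_c$cdna)
    rec <- data.frame(id = sprintf("decoy%03d", k), chrom = fixture$chrom,
                      pos_bp = gpos, ref = pos_c$ref, alt = pos_c$alt,
                      class_truth = class, stringsAsFactors = FALSE)
    gt <- seg_gt
  } else if (class == "intergenic") {
    # in the planted region but outside the transcript
    gpos <- sample(seq(seg$start_bp, fixture$tx_start - 10L), 1L)
    ref <- sample(bases, 1L)
    rec <- data.frame(id = sprintf("decoy%03d", k), chrom = fixture$chrom,
                      pos_bp = as.integer(gpos), ref = ref,
                      alt = sample(setdiff(bases, ref), 1L),
                      class_truth = class, stringsAsFactors = FALSE)
    gt <- seg_gt
  } else if (class == "missense_outside_region") {
    other <- setdiff(panel_chroms(panel),
                     unique(panel$planted$chrom))
    ch <- if (length(other)) sample(other, 1L) else panel$planted$chrom[1L]
    gidx <- chrom_loci(panel, ch)
    gpos <- sample(panel$loci$pos_bp[range(gidx)][1L]:
                     panel$loci$pos_bp[range(gidx)][2L], 1L)
    ref <- sample(bases, 1L)
    rec <- data.frame(id = sprintf("decoy%03d", k), chrom = ch,
                      pos_bp = as.integer(gpos), ref = ref,
                      alt = sample(setdiff(bases, ref), 1L),
                      class_truth = class, stringsAsFactors = FALSE)
    gt <- seg_gt
  } else {  # missense_nonsegregating
    pos_c <- pick_missense_site(fixture, k)
    gpos <- cdna_to_genomic(fixture, pos_c$cdna)
    rec <- data.frame(id = sprintf("decoy%03d", k), chrom = fixture$chrom,
                      pos_bp = gpos, ref = pos_c$ref, alt = pos_c$alt,
                      class_truth = class, stringsAsFactors = FALSE)
    gt <- seg_gt
    aff <- which(gt == 2L)
    if (length(aff)) gt[aff[1L]] <- 1L  # het in one affected: fails the rule
  }
  list(rec = rec,
       gt = matrix(gt, ncol = 1L, dimnames = list(samples, rec$id)))
}

# deterministic search for a synonymous third-position change, offset by k
pick_synonymous_site <- function(fx, k) {
  n_codons <- nchar(fx$cds) %/% 3L
  forbidden <- c(1L, fx$causal$residue, 611L, 612L, 680L, 682L, n_codons)
  cods <- seq(2L, n_codons - 1L)
  cods <- setdiff(cods, forbidden)
  cods <- cods[(seq_along(cods) + 17L * k) %% length(cods) < 25L]
  for (cn in cods) {
    cod <- substr(fx$cds, 3L * cn - 2L, 3L * cn)
    ref <- substr(cod, 3L, 3L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      alt_cod <- paste0(substr(cod, 1L, 2L), alt)
      if (translate_codon(alt_cod) == translate_codon(cod))
        return(list(cdna = 3L * cn, ref = ref, alt = alt))
    }
  }
  stop("no synonymous site found")  # unreachable for a realistic CDS
}

pick_missense_site <- function(fx, k) {
  n_codons <- nchar(fx$cds) %/% 3L
  forbidden <- c(1L, fx$causal$residue, 611L, 612L, 680L, 682L, n_codons)
  cods <- setdiff(seq(2L, n_codons - 1L), forbidden)
  cods <- cods[(seq_along(cods) + 31L * k) %% length(cods) < 25L]
  for (cn in cods) {
    cod <- substr(fx$cds, 3L * cn - 2L, 3L * cn)
    ref <- substr(cod, 1L, 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      alt_cod <- paste0(alt, substr(cod, 2L, 3L))
      aa <- translate_codon(alt_cod)
      if (aa != translate_codon(cod) && aa != "*")
        return(list(cdna = 3L * cn - 2L, ref = ref, alt = alt))
    }
  }
  stop("no missense site found")
}
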