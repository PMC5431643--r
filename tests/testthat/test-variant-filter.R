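toy_variants <- function(pos, chrom = "9", ref = "T", alt = "A",
                         gt = matrix(2L, 1, length(pos),
                                     dimnames = list("a", NULL))) {
  variant_set(data.frame(id = sprintf("v%d", seq_along(pos)),
                         chrom = chrom, pos_bp = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE), gt)
}

test_that("region filter is 1-based inclusive on both boundaries", {
  regions <- data.frame(chrom = "9", start_bp = 100L, end_bp = 200L)
  vs <- toy_variants(c(100L, 200L, 201L, 99L),
                     gt = matrix(2L, 1, 4, dimnames = list("a", NULL)))
  out <- filter_by_region(vs, regions)
  expect_equal(out$verdict, c("candidate", "candidate", "rejected",
                              "rejected"))
  expect_equal(out$reason[3:4], rep("outside_region", 2))
})

test_that("segregation filter enforces the recessive pattern per rule", {
  p <- make_toy_panel(list(aff = rep(0L, 4), car = rep(0L, 4),
                           una = rep(0L, 4)),
                      status = c("affected", "carrier", "unaffected"))
  gt <- cbind(c(2L, 1L, 0L),   # perfect segregation
              c(1L, 1L, 0L),   # het in an affected
              c(2L, 2L, 0L),   # hom in a carrier
              c(2L, 1L, 2L),   # hom-alt in a control
              c(-1L, 1L, 0L))  # missing in the affected: not disqualifying
  rownames(gt) <- c("aff", "car", "una")
  vs <- variant_set(data.frame(id = paste0("v", 1:5), chrom = "1",
                               pos_bp = 1:5 * 10L, ref = "T", alt = "A",
                               stringsAsFactors = FALSE), gt)
  out <- segregation_filter(vs, p)
  expect_equal(out$verdict,
               c("candidate", "rejected", "rejected", "rejected",
                 "candidate"))
  expect_equal(out$reason[2:4],
               c("not_hom_in_affected", "not_het_in_carrier",
                 "present_in_controls"))
  # the all-missing-in-affected variant is flagged low confidence
  expect_true(out$low_confidence[5])
  expect_false(out$low_confidence[1])
})

test_that("consequence annotation recovers the two causal substitutions", {
  p <- gen_snp_panel(small_sim_config(seed = 4))
  vs <- gen_variant_calls(p, n_decoys = 0, seed = 1)
  ann <- annotate_consequence(vs)
  expect_equal(ann$consequence, rep("missense", 2))
  expect_equal(ann$codon_number, c(681L, 687L))
  expect_equal(ann$ref_aa, c("I", "I"))
  expect_equal(ann$alt_aa, c("N", "S"))
  expect_equal(ann$grantham, c(149, 142))
})

test_that("third-position degeneracy yields synonymous annotations", {
  fx <- transcript_fixture()
  fx$tx_start <- 1000L
  # find a fourfold-degenerate codon and perturb its third base
  aa_of <- function(cod) Biostrings::GENETIC_CODE[[cod]]
  hit <- NULL
  for (cn in 5:100) {
    cod <- substr(fx$cds, 3 * cn - 2, 3 * cn)
    for (alt in setdiff(c("A", "C", "G", "T"), substr(cod, 3, 3))) {
      if (aa_of(paste0(substr(cod, 1, 2), alt)) == aa_of(cod)) {
        hit <- list(cn = cn, ref = substr(cod, 3, 3), alt = alt)
        break
      }
    }
    if (!is.null(hit)) break
  }
  pos <- cdna_pos <- 3L * hit$cn
  gpos <- ciliomap:::cdna_to_genomic(fx, cdna_pos)
  vs <- toy_variants(gpos, ref = hit$ref, alt = hit$alt)
  ann <- annotate_consequence(vs, fx)
  expect_equal(ann$consequence, "synonymous")
  expect_equal(ann$grantham, 0)
})

test_that("a reference mismatch in the CDS is an error", {
  fx <- transcript_fixture()
  fx$tx_start <- 1000L
  gpos <- ciliomap:::cdna_to_genomic(fx, 2042L)
  vs <- toy_variants(gpos, ref = "G", alt = "A")  # transcript has T here
  expect_error(annotate_consequence(vs, fx), "reference mismatch")
})

test_that("annotation is strand-aware", {
  fx <- transcript_fixture()
  fx$tx_start <- 1000L
  fx$strand <- "-"
  # on the minus strand the variant is reported in plus-strand alleles;
  # the causal T>A in the transcript reads A>T on the genome
  ex <- ciliomap:::transcript_exons_genomic(fx)
  gpos <- ex$end[2] - (2042L - ex$cdna_start[2])
  vs <- toy_variants(gpos, ref = "A", alt = "T")
  ann <- annotate_consequence(vs, fx)
  expect_equal(ann$consequence, "missense")
  expect_equal(ann$codon_number, 681L)
  expect_equal(ann$alt_aa, "N")
})

test_that("Grantham distances match the published matrix oracle", {
  expect_equal(grantham_distance("A", "A"), 0)
  # symmetry and identity across all residue pairs
  aa <- rownames(ciliomap:::GRANTHAM_PROPERTIES)
  for (i in 1:10) {
    pair <- sample(aa, 2)
    expect_equal(grantham_distance(pair[1], pair[2]),
                 grantham_distance(pair[2], pair[1]))
  }
  expect_true(all(grantham_distance(aa, aa) == 0))
  # frozen published entries: exact for the two causal substitutions and
  # within the 1-unit printing rounding of the published matrix overall
  got <- grantham_distance(grantham_published$a, grantham_published$b)
  expect_equal(got[1:2], c(149, 142))  # I681N, I687S
  expect_true(all(abs(got - grantham_published$d) <= 1))
  expect_gte(mean(abs(got - grantham_published$d) == 0), 0.8)
  expect_error(grantham_distance("I", "B"), "unknown residue")
})

test_that("conservation scores count matching non-gap rows", {
  m <- matrix("I", nrow = 11, ncol = 3,
              dimnames = list(paste0("sp", 1:11), NULL))
  m[7:10, 2] <- c("V", "L", "V", "T")  # 6 of 10 non-gap rows match ref
  m[11, 2] <- "-"
  m[2:11, 3] <- "-"
  aln <- ortholog_alignment(m, start_residue = 10L)
  expect_equal(conservation_score(aln, 10L), 1.0)
  expect_equal(conservation_score(aln, 11L), 0.6)
  # a residue outside the alignment is undefined, not zero
  expect_true(is.na(conservation_score(aln, 99L)))
  # default fixture: causal columns conserved in 9 of 11 species
  d <- ortholog_alignment()
  expect_equal(conservation_score(d, 681L), 9 / 11)
  expect_equal(conservation_score(d, 687L), 9 / 11)
})

test_that("deleteriousness classification applies both gates", {
  p <- gen_snp_panel(small_sim_config(seed = 6))
  vs <- gen_variant_calls(p, n_decoys = 8, seed = 2)
  ann <- annotate_consequence(vs)
  out <- classify_deleterious(ann)
  cand <- candidates(out)
  expect_setequal(cand$class_truth, "causal")
  # synonymous variants rejected regardless of scores
  syn <- out[out$class_truth == "synonymous", ]
  expect_true(all(syn$verdict == "rejected"))
  # low conservation rejects a missense variant
  out2 <- classify_deleterious(ann, conservation_min = 0.99)
  expect_true(all(out2$verdict == "rejected"))
  expect_true(any(out2$reason == "low_conservation"))
})

test_that("the filter chain recovers exactly the causal pair across seeds", {
  for (s in 1:100) {
    p <- gen_snp_panel(small_sim_config(seed = 1000 + s, n_snps = 600))
    aff <- p$samples$id[p$samples$status == "affected"]
    regions <- shared_concordant_regions(p, aff, mapping_config())
    vs <- gen_variant_calls(p, n_decoys = 12, seed = s)
    out <- filter_candidate_variants(vs, regions, p)
    cand <- candidates(out)
    # precision and recall 1.0 for the planted causal variants
    expect_identical(sort(cand$id), c("causal_1", "causal_2"))
    expect_true(all(cand$class_truth == "causal"))
  }
})

test_that("region and segregation filters commute", {
  p <- gen_snp_panel(small_sim_config(seed = 77))
  aff <- p$samples$id[p$samples$status == "affected"]
  regions <- shared_concordant_regions(p, aff, mapping_config())
  vs <- gen_variant_calls(p, n_decoys = 30, seed = 5)
  ab <- segregation_filter(filter_by_region(vs, regions), p)
  ba <- filter_by_region(segregation_filter(vs, p), regions)
  expect_identical(candidates(ab)$id, candidates(ba)$id)
})
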