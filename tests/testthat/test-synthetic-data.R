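test_that("panel generation is deterministic and respects the chip layout", {
  cfg <- small_sim_config(seed = 11)
  p1 <- gen_snp_panel(cfg)
  p2 <- gen_snp_panel(cfg)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$loci, p2$loci)
  expect_equal(nrow(p1$loci), 1200L)
  # markers sorted, strictly increasing per chromosome
  for (ch in unique(p1$loci$chrom)) {
    pos <- p1$loci$pos_bp[p1$loci$chrom == ch]
    expect_false(is.unsorted(pos, strictly = TRUE))
  }
  # planted segments recorded with the configured sizes
  expect_equal(sort(p1$planted$n_snps), c(8L, 26L))
})

test_that("a planted segment larger than its chromosome is a config error", {
  cfg <- sim_config(n_snps = 30L, chrom_lengths = c("9" = 1e6, "11" = 1e6),
                    planted_segments = data.frame(chrom = "9", n_snps = 40L),
                    seed = 1)
  expect_error(gen_snp_panel(cfg), "larger than its chromosome")
})

test_that("affected animals are homozygous across every planted segment SNP", {
  p <- gen_snp_panel(small_sim_config(seed = 3))
  aff <- p$samples$id[p$samples$status == "affected"]
  for (k in seq_len(nrow(p$planted))) {
    gidx <- which(p$loci$chrom == p$planted$chrom[k])
    span <- gidx[p$planted$start_index[k]:p$planted$end_index[k]]
    G <- p$genotypes[aff, span, drop = FALSE]
    expect_true(all(G %in% c(0L, 2L)))
    # IBD: one shared allele per SNP
    expect_true(all(apply(G, 2, function(x) length(unique(x)) == 1L)))
  }
})

test_that("carrier matings follow Mendelian 1:2:1 segregation", {
  m <- sim_carrier_matings(10000, penetrance = 1, seed = 21)
  tab <- table(factor(m$genotype, levels = 0:2))
  gof <- suppressWarnings(chisq.test(tab, p = c(0.25, 0.5, 0.25)))
  expect_gt(gof$p.value, 0.01)
  # with full penetrance, hom-mutant lambs are all labelled affected
  aff_frac <- mean(m$status == "affected")
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(aff_frac - 0.25), 3 * se)
})

test_that("reduced penetrance scales the affected fraction", {
  m <- sim_carrier_matings(10000, penetrance = 0.482, seed = 22)
  target <- 0.25 * 0.482  # ~0.1205, the observed 37/307
  se <- sqrt(target * (1 - target) / 10000)
  expect_lt(abs(mean(m$status == "affected") - target), 3 * se)
  # non-penetrant homozygotes are labelled unaffected, not dropped
  hom <- m[m$genotype == 2L, ]
  expect_true(all(hom$status %in% c("affected", "unaffected")))
  expect_gt(sum(hom$status == "unaffected"), 0)
})

test_that("genotyping errors perturb calls at the configured rate", {
  cfg0 <- small_sim_config(seed = 5)
  cfg1 <- small_sim_config(seed = 5, error_rate = 0.02)
  g0 <- gen_snp_panel(cfg0)$genotypes
  g1 <- gen_snp_panel(cfg1)$genotypes
  rate <- mean(g0 != g1)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.03)
})

test_that("the transcript fixture is internally consistent", {
  fx <- transcript_fixture()
  expect_equal(nchar(fx$cds) %% 3, 0)
  expect_equal(diff(fx$causal$cdna_pos), 18L)
  expect_equal(diff(fx$causal$residue), 6L)
  expect_identical(fx$causal$ref_aa, c("I", "I"))
  expect_identical(fx$causal$alt_aa, c("N", "S"))
  expect_identical(fx$causal$residue, c(681L, 687L))
  # fixture is a package constant
  expect_identical(fx$cds, transcript_fixture()$cds)
})

test_that("variant generation encodes the causal segregation pattern", {
  p <- gen_snp_panel(small_sim_config(seed = 9))
  vs <- gen_variant_calls(p, n_decoys = 0, seed = 1)
  expect_equal(nrow(vs), 2L)
  G <- variant_genotypes(vs)
  aff <- p$samples$id[p$samples$status == "affected"]
  car <- p$samples$id[p$samples$status == "carrier"]
  una <- p$samples$id[p$samples$status == "unaffected"]
  expect_true(all(G[aff, ] == 2L))
  expect_true(all(G[car, ] == 1L))
  expect_true(all(G[una, ] == 0L))
})

test_that("variants are emitted even for a panel without affected animals", {
  cfg <- small_sim_config(seed = 13,
                          flock_sizes = list(A = c(affected = 0L,
                                                   carrier = 3L,
                                                   unaffected = 3L)))
  p <- gen_snp_panel(cfg)
  vs <- gen_variant_calls(p, n_decoys = 0, seed = 1)
  expect_equal(nrow(vs), 2L)
})

test_that("a transcript outside every planted segment is rejected", {
  p <- gen_snp_panel(small_sim_config(seed = 2))
  fx <- transcript_fixture()
  fx$tx_start <- 1L  # far outside the planted segments
  expect_error(gen_variant_calls(p, fx), "outside every planted segment")
})

test_that("grade tables are deterministic multinomials with exact row sums", {
  params <- grade_params(n_embryos = c(0L, 100L, 100L, 100L))
  t1 <- gen_embryo_grades(params, seed = 4)
  t2 <- gen_embryo_grades(params, seed = 4)
  expect_identical(t1, t2)
  expect_equal(unname(rowSums(t1)), c(0L, 100L, 100L, 100L))
  expect_equal(sum(t1["uninjected", ]), 0L)
})

test_that("cilia generator hits its calibrated mean and handles edge cases", {
  # degenerate Bernoulli: every cell ciliated
  pp <- cilia_params(conditions = "affected", n_cells = 10L)
  pp$incidence <- 1
  x <- gen_cilia_measurements(pp, seed = 1)
  expect_equal(sum(x$ciliated), 10L)
  expect_equal(sum(!is.na(x$length_um)), 10L)
  # incidence 0: no lengths, summary still defined
  pp$incidence <- 0
  x0 <- gen_cilia_measurements(pp, seed = 1)
  expect_equal(sum(x0$ciliated), 0L)
  s0 <- cilia_summary(x0)
  expect_equal(s0$n_ciliated, 0L)
  expect_true(is.na(s0$mean_length_um))
  # law of large numbers: sample mean within 2 SEM of the generator target
  pp50 <- cilia_params(conditions = "affected", n_cells = 50L)
  pp50$incidence <- 1
  xs <- gen_cilia_measurements(pp50, seed = 42)
  s <- cilia_summary(xs)
  expect_lt(abs(s$mean_length_um - pp50$target_mean_um), 2 * s$sem_length_um)
})
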