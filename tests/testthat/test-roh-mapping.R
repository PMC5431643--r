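test_that("homozygosity runs follow the scan definition on worked examples", {
  cfg3 <- mapping_config(min_snps = 3)
  # an all-heterozygous animal has no runs
  p <- make_toy_panel(list(a = rep(1L, 10)))
  expect_equal(nrow(call_homozygosity_runs(p, "a", mapping_config())), 0L)
  # eight consecutive homozygous calls meet the 8-SNP threshold exactly
  p8 <- make_toy_panel(list(a = rep(0L, 8)))
  r8 <- call_homozygosity_runs(p8, "a", mapping_config(min_snps = 8))
  expect_equal(nrow(r8), 1L)
  expect_equal(r8$n_snps, 8L)
  # mixed vector under both missing policies (1-based indices)
  codes <- c(0L, 0L, 2L, 1L, 2L, 2L, 2L, -1L, 2L, 2L)
  pm <- make_toy_panel(list(a = codes))
  rn <- call_homozygosity_runs(pm, "a", cfg3)
  expect_equal(rn[, c("start_index", "end_index")],
               data.frame(start_index = c(1L, 5L), end_index = c(3L, 10L)),
               ignore_attr = TRUE)
  rb <- call_homozygosity_runs(
    pm, "a", mapping_config(min_snps = 3, missing_policy = "break"))
  expect_equal(rb[, c("start_index", "end_index")],
               data.frame(start_index = c(1L, 5L), end_index = c(3L, 7L)),
               ignore_attr = TRUE)
  # unknown sample id
  expect_error(call_homozygosity_runs(p8, "nope"), "unknown sample")
})

test_that("runs never span chromosomes", {
  p <- make_toy_panel(list(a = rep(0L, 8)),
                      chrom = rep(c("1", "2"), each = 4))
  r <- call_homozygosity_runs(p, "a", mapping_config(min_snps = 2))
  expect_equal(nrow(r), 2L)
  expect_equal(r$n_snps, c(4L, 4L))
})

test_that("shared regions handle the worked interval examples", {
  # a 9-SNP shared stretch broken in the middle for one animal: both halves
  # are 4 SNPs, so nothing survives an 8-SNP threshold
  a <- rep(0L, 9)
  b <- rep(0L, 9); b[5] <- 1L
  p <- make_toy_panel(list(a = a, b = b))
  expect_equal(nrow(shared_concordant_regions(p, c("a", "b"),
                                              mapping_config(min_snps = 8))),
               0L)
  # concordant homozygosity with opposite alleles is shared but not IBD
  g1 <- rep(0L, 12)
  g2 <- rep(0L, 12); g2[6] <- 2L
  g3 <- rep(0L, 12)
  p3 <- make_toy_panel(list(s1 = g1, s2 = g2, s3 = g3))
  reg <- shared_concordant_regions(p3, c("s1", "s2", "s3"),
                                   mapping_config(min_snps = 8))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_snps, 12L)
  expect_false(reg$ibd_identical)
  expect_error(shared_concordant_regions(p3, character()), "empty")
})

test_that("strict shared regions equal the brute-force interval oracle", {
  set.seed(7031)
  n_panels <- 10000
  for (i in seq_len(n_panels)) {
    L <- sample(3:12, 1)
    A <- sample(2:4, 1)
    min_snps <- sample(2:3, 1)
    policy <- sample(c("neutral", "break"), 1)
    max_miss <- sample(0:2, 1)
    G <- matrix(sample(c(-1L, 0L, 1L, 2L), L * A, replace = TRUE,
                       prob = c(0.08, 0.40, 0.12, 0.40)), nrow = A)
    codes <- lapply(seq_len(A), function(k) G[k, ])
    names(codes) <- sprintf("s%d", seq_len(A))
    p <- make_toy_panel(codes)
    cfg <- mapping_config(min_snps = min_snps, missing_policy = policy,
                          max_consecutive_missing = max_miss)
    got <- shared_concordant_regions(p, names(codes), cfg)
    want <- oracle_shared_regions(G, min_snps, policy, max_miss)
    if (!isTRUE(all.equal(got$start_index, want$start)) ||
        !isTRUE(all.equal(got$end_index, want$end))) {
      fail(sprintf("oracle mismatch at panel %d", i))
      break
    }
    # emitted regions are sorted and non-overlapping
    if (nrow(got) > 1L)
      expect_true(all(got$start_index[-1] > got$end_index[-nrow(got)]))
  }
  succeed()
})

test_that("planted segments are recovered exactly at error rate zero", {
  hits <- 0L
  for (s in 1:100) {
    p <- gen_snp_panel(small_sim_config(seed = s))
    aff <- p$samples$id[p$samples$status == "affected"]
    reg <- shared_concordant_regions(p, aff, mapping_config())
    reg <- reg[order(reg$chrom), ]
    pl <- p$planted[order(p$planted$chrom), ]
    ok <- nrow(reg) == nrow(pl) &&
      all(reg$chrom == pl$chrom) &&
      all(reg$start_index == pl$start_index) &&
      all(reg$end_index == pl$end_index) &&
      all(reg$ibd_identical)
    hits <- hits + ok
  }
  expect_equal(hits, 100L)
})

test_that("raising min_snps never adds a region", {
  set.seed(88)
  for (i in 1:50) {
    G <- matrix(sample(c(-1L, 0L, 1L, 2L), 36, replace = TRUE,
                       prob = c(0.05, 0.45, 0.1, 0.4)), nrow = 3)
    codes <- setNames(lapply(1:3, function(k) G[k, ]), c("a", "b", "c"))
    p <- make_toy_panel(codes)
    lo <- shared_concordant_regions(p, names(codes),
                                    mapping_config(min_snps = 2))
    hi <- shared_concordant_regions(p, names(codes),
                                    mapping_config(min_snps = 4))
    expect_lte(nrow(hi), nrow(lo))
    # every high-threshold region exists at the lower threshold too
    if (nrow(hi))
      expect_true(all(paste(hi$start_index, hi$end_index) %in%
                        paste(lo$start_index, lo$end_index)))
  }
})

test_that("sliding-window concordance reports exact window fractions", {
  # fully concordant stretch: every window 1.0
  p <- make_toy_panel(list(a = rep(2L, 16), b = rep(2L, 16)))
  sw <- sliding_window_concordance(p, c("a", "b"), mapping_config())
  expect_true(all(sw$track[["1"]] == 1))
  # one discordant SNP: covering windows drop to 7/8
  b <- rep(2L, 16); b[9] <- 1L
  pd <- make_toy_panel(list(a = rep(2L, 16), b = b))
  swd <- sliding_window_concordance(pd, c("a", "b"), mapping_config())
  tr <- swd$track[["1"]]
  expect_equal(sort(unique(tr)), c(0.875, 1))
  expect_equal(tr[2:9], rep(0.875, 8))
  # window larger than the chromosome: skipped with a warning
  tiny <- make_toy_panel(list(a = rep(0L, 4), b = rep(0L, 4)))
  expect_warning(sliding_window_concordance(tiny, c("a", "b"),
                                            mapping_config()),
                 "fewer loci")
})

test_that("relaxed windows bridge an isolated bad call that breaks strict runs", {
  # 26-SNP concordant segment with one mid-segment heterozygous call,
  # flanked by heterozygous background
  seg <- rep(2L, 26)
  mk <- function(bad) c(1L, 1L, if (is.null(bad)) seg else
    replace(seg, bad, 1L), 1L, 1L)
  p <- make_toy_panel(list(a = mk(NULL), b = mk(13L), c = mk(NULL)))
  strict <- shared_concordant_regions(p, c("a", "b", "c"),
                                      mapping_config(min_snps = 8))
  # strict mode fragments the segment around the bad call
  expect_equal(nrow(strict), 2L)
  expect_true(all(strict$n_snps < 26))
  # a threshold tolerating one bad call per 8-SNP window recovers a single
  # region covering the whole segment (plus at most one flanking SNP per
  # side, since edge windows may also carry a single discordant flank)
  relaxed <- sliding_window_concordance(
    p, c("a", "b", "c"),
    mapping_config(window_concordance_min = 0.85))$regions
  expect_equal(nrow(relaxed), 1L)
  expect_lte(relaxed$start_index, 3L)
  expect_gte(relaxed$end_index, 28L)
})

test_that("lowering the window threshold never shrinks relaxed coverage", {
  set.seed(19)
  for (i in 1:25) {
    G <- matrix(sample(c(0L, 1L, 2L), 80, replace = TRUE,
                       prob = c(0.35, 0.15, 0.5)), nrow = 2)
    codes <- setNames(lapply(1:2, function(k) G[k, ]), c("a", "b"))
    p <- make_toy_panel(codes)
    cover <- function(th) {
      r <- sliding_window_concordance(
        p, names(codes), mapping_config(window_concordance_min = th))$regions
      unlist(lapply(seq_len(nrow(r)), function(k)
        r$start_index[k]:r$end_index[k]))
    }
    hi <- cover(0.9)
    lo <- cover(0.7)
    expect_true(all(hi %in% lo))
  }
})

test_that("carrier fixation splits candidate regions as defined", {
  aff <- list(a1 = rep(2L, 10), a2 = rep(2L, 10))
  # carrier heterozygous at one region SNP: region retained
  p1 <- make_toy_panel(c(aff, list(car = c(rep(2L, 4), 1L, rep(2L, 5)))),
                       status = c("affected", "affected", "carrier"))
  reg <- shared_concordant_regions(p1, c("a1", "a2"), mapping_config())
  out <- carrier_fixation_filter(reg, p1, "car")
  expect_equal(nrow(out$kept), 1L)
  expect_false(out$kept$carrier_fixed)
  # carrier homozygous across the region: flagged and excluded
  p2 <- make_toy_panel(c(aff, list(car = rep(0L, 10))),
                       status = c("affected", "affected", "carrier"))
  reg2 <- shared_concordant_regions(p2, c("a1", "a2"), mapping_config())
  out2 <- carrier_fixation_filter(reg2, p2, "car")
  expect_equal(nrow(out2$kept), 0L)
  expect_equal(nrow(out2$excluded), 1L)
  expect_true(out2$excluded$carrier_fixed)
  # all-missing carrier: no evidence, retained with a warning
  p3 <- make_toy_panel(c(aff, list(car = rep(-1L, 10))),
                       status = c("affected", "affected", "carrier"))
  reg3 <- shared_concordant_regions(p3, c("a1", "a2"), mapping_config())
  expect_warning(out3 <- carrier_fixation_filter(reg3, p3, "car"),
                 "missing")
  expect_equal(nrow(out3$kept), 1L)
  expect_true(is.na(out3$kept$carrier_fixed))
  # empty carrier list: unchanged with a warning
  expect_warning(out4 <- carrier_fixation_filter(reg, p1, character()),
                 "no carriers")
  expect_equal(nrow(out4$kept), nrow(reg))
})

test_that("cross-flock intersection keeps shared regions, reports private ones", {
  regA <- data.frame(chrom = c("9", "11"),
                     start_bp = c(100L, 500L), end_bp = c(200L, 600L),
                     stringsAsFactors = FALSE)
  regB <- data.frame(chrom = c("4", "9", "11"),
                     start_bp = c(10L, 150L, 480L),
                     end_bp = c(90L, 260L, 560L), stringsAsFactors = FALSE)
  x <- cross_flock_intersection(list(A = regA, B = regB))
  expect_setequal(x$candidates$chrom, c("9", "11"))
  expect_equal(x$candidates$start_bp[x$candidates$chrom == "9"], 150L)
  expect_equal(x$candidates$end_bp[x$candidates$chrom == "9"], 200L)
  expect_equal(x$excluded$chrom, "4")
  expect_equal(x$excluded$flock, "B")
  # a single flock passes through unchanged
  one <- cross_flock_intersection(list(A = regA))
  expect_identical(one$candidates, regA)
  # disjoint regions intersect to nothing
  regC <- data.frame(chrom = "9", start_bp = 900L, end_bp = 950L,
                     stringsAsFactors = FALSE)
  none <- cross_flock_intersection(list(A = regA, C = regC))
  expect_equal(nrow(none$candidates), 0L)
})
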