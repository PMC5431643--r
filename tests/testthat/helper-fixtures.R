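# Shared fixtures and independent oracles for the test suite.

# Build a toy genotype panel from a list of per-sample genotype code vectors
# (all on one chromosome unless `chrom` gives a per-locus vector).
make_toy_panel <- function(codes, status = NULL, flock = "A", chrom = "1") {
  codes <- lapply(codes, as.integer)
  n_loci <- length(codes[[1]])
  ids <- names(codes) %||% sprintf("s%02d", seq_along(codes))
  if (is.null(status)) status <- rep("affected", length(codes))
  chrom <- rep_len(chrom, n_loci)
  # positions strictly increasing within each chromosome
  pos <- stats::ave(seq_len(n_loci), chrom, FUN = seq_along) * 1000L
  loci <- data.frame(chrom = chrom, pos_bp = pos,
                     allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)
  o <- order(loci$chrom, loci$pos_bp)
  G <- do.call(rbind, codes)[, o, drop = FALSE]
  rownames(G) <- ids
  genotype_panel(loci[o, ], data.frame(id = ids,
                                       flock = rep_len(flock, length(ids)),
                                       status = status,
                                       stringsAsFactors = FALSE), G)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small simulation configuration used where the full 54k chip is unnecessary
small_sim_config <- function(seed, n_snps = 1200L,
                             error_rate = 0,
                             flock_sizes = list(
                               A = c(affected = 6L, carrier = 2L,
                                     unaffected = 2L))) {
  sim_config(n_snps = n_snps,
             chrom_lengths = c("9" = 90e6, "11" = 60e6),
             flock_sizes = flock_sizes,
             genotyping_error_rate = error_rate,
             seed = seed)
}

# ---- independent oracle: shared concordant regions by interval enumeration

# per-locus qualification, computed by explicit neighbour counting (not rle)
oracle_qualifies <- function(g, policy, max_miss) {
  n <- length(g)
  vapply(seq_len(n), function(k) {
    if (g[k] %in% c(0L, 2L)) return(TRUE)
    if (g[k] == 1L) return(FALSE)
    if (policy == "break") return(FALSE)
    # length of the consecutive-missing stretch containing k
    lo <- k
    while (lo > 1L && g[lo - 1L] == -1L) lo <- lo - 1L
    hi <- k
    while (hi < n && g[hi + 1L] == -1L) hi <- hi + 1L
    (hi - lo + 1L) <= max_miss
  }, logical(1))
}

# every maximal interval (length >= min_snps) where all animals qualify at
# all loci; returns start/end indices within the vector
oracle_shared_regions <- function(G, min_snps, policy, max_miss) {
  ok <- Reduce(`&`, lapply(seq_len(nrow(G)), function(a) {
    oracle_qualifies(G[a, ], policy, max_miss)
  }))
  n <- length(ok)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < min_snps) next
      if (!all(ok[i:j])) next
      left_max <- i == 1L || !ok[i - 1L]
      right_max <- j == n || !ok[j + 1L]
      if (left_max && right_max) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# ---- independent oracle: IUPAC pattern positions by exhaustive offsets

iupac_expand <- function(pattern) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  sets <- codes[strsplit(pattern, "")[[1]]]
  apply(do.call(expand.grid, rev(sets)), 1L,
        function(r) paste(rev(r), collapse = ""))
}

oracle_pattern_positions <- function(seq, pattern) {
  variants <- iupac_expand(pattern)
  w <- nchar(pattern)
  n <- nchar(seq)
  if (n < w) return(integer())
  offs <- seq_len(n - w + 1L)
  words <- substring(seq, offs, offs + w - 1L)
  offs[words %in% variants]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# frozen subset of the published Grantham (1974) distance matrix used as the
# test oracle (see package docs for the rounding caveat on 4 entries)
grantham_published <- data.frame(
  a   = c("I", "I", "L", "W", "F", "K", "D", "S", "I", "G", "A", "M", "Q",
          "D", "H", "Y", "P", "C", "M", "V", "R", "A", "T", "C", "H"),
  b   = c("N", "S", "I", "C", "Y", "R", "E", "T", "V", "W", "G", "L", "E",
          "N", "Q", "W", "S", "S", "I", "L", "W", "P", "M", "Y", "R"),
  d   = c(149, 142, 5, 215, 22, 26, 45, 58, 29, 184, 60, 15, 29,
          23, 24, 37, 74, 112, 10, 32, 101, 27, 81, 194, 29),
  stringsAsFactors = FALSE)
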