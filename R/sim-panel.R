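#' Simulate a flock SNP-chip genotype panel with a planted IBD haplotype
#'
#' Generates the genotype data the homozygosity mapper consumes. Markers are
#' placed uniformly at random (then sorted) along each chromosome, with
#' per-chromosome counts proportional to chromosome length. Each background
#' locus gets an allele-B frequency drawn from `maf_range`, and genotypes are
#' drawn independently per animal (background markers are unlinked; the
#' mapper is positional and needs runs, not LD structure). Each planted
#' segment carries one fixed ancestral haplotype; all segments co-segregate
#' as a single causal haplotype, and its boundaries are pinned: the locus on
#' either side of a segment is heterozygous in at least one affected animal
#' of every flock, representing the recombination breakpoints that delimit
#' the shared ancestral segment. Animals in the `affected` slot of a flock
#' carry two copies and are therefore homozygous for the ancestral allele at
#' every segment SNP; `carrier` animals carry one copy; `unaffected` animals
#' none. Genotyping errors, if enabled, replace a call with one of the two
#' other codes independently per call.
#'
#' The flock composition is interpreted as an *ascertained* study cohort:
#' the affected slot holds homozygous-mutant animals that were observed to
#' express the phenotype. The Mendelian segregation and reduced-penetrance
#' machinery of the underlying breeding programme is exposed separately in
#' [sim_carrier_matings()].
#'
#' @param config A [sim_config()] object.
#' @return A [genotype_panel()] with `planted` segment coordinates and
#'   per-sample `causal_copies` recorded for downstream truth checks.
#' @export
gen_snp_panel <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  with_seed(cfg$seed, {
    chroms <- names(cfg$chrom_lengths)
    counts <- allocate_markers(cfg$n_snps, cfg$chrom_lengths)

    # check planted segments fit before any drawing
    ps <- cfg$planted_segments
    if (!is.null(ps) && nrow(ps)) {
      too_big <- ps$n_snps > counts[ps$chrom]
      if (any(too_big))
        stop("planted segment larger than its chromosome's marker count: chr",
             paste(ps$chrom[too_big], collapse = ", "), call. = FALSE)
    }

    pos <- unlist(lapply(chroms, function(ch) {
      sort(sample.int(as.integer(cfg$chrom_lengths[[ch]]), counts[[ch]]))
    }), use.names = FALSE)
    ref_alt <- replicate(cfg$n_snps, sample(c("A", "C", "G", "T"), 2L))
    loci <- data.frame(chrom = rep(chroms, counts[chroms]),
                       pos_bp = pos,
                       allele_a = ref_alt[1L, ],
                       allele_b = ref_alt[2L, ],
                       stringsAsFactors = FALSE)
    freq_b <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])

    # planted segments: centred on their chromosome; ancestral allele per SNP
    planted <- NULL
    anc <- vector("list", if (is.null(ps)) 0L else nrow(ps))
    seg_idx <- vector("list", length(anc))
    if (length(anc)) {
      planted <- data.frame(chrom = ps$chrom, start_index = NA_integer_,
                            end_index = NA_integer_, n_snps = ps$n_snps,
                            start_bp = NA_integer_, end_bp = NA_integer_,
                            stringsAsFactors = FALSE)
      first <- cumsum(c(1L, unname(counts[chroms])))[seq_along(chroms)]
      names(first) <- chroms
      for (k in seq_len(nrow(ps))) {
        ch <- ps$chrom[k]
        n_seg <- ps$n_snps[k]
        local_start <- (counts[[ch]] - n_seg) %/% 2L + 1L
        gidx <- first[[ch]] + local_start - 1L + seq_len(n_seg) - 1L
        seg_idx[[k]] <- gidx
        anc[[k]] <- rbinom(n_seg, 1L, freq_b[gidx])
        planted$start_index[k] <- local_start
        planted$end_index[k] <- local_start + n_seg - 1L
        planted$start_bp[k] <- loci$pos_bp[gidx[1L]]
        planted$end_bp[k] <- loci$pos_bp[gidx[n_seg]]
      }
    }

    samples <- do.call(rbind, lapply(names(cfg$flock_sizes), function(fl) {
      fs <- cfg$flock_sizes[[fl]]
      status <- rep(c("affected", "carrier", "unaffected"),
                    fs[c("affected", "carrier", "unaffected")])
      if (!length(status)) return(NULL)
      data.frame(id = sprintf("%s_%s%02d", fl,
                              substr(status, 1L, 3L),
                              unlist(lapply(fs[c("affected", "carrier",
                                                 "unaffected")], seq_len))),
                 flock = fl, status = status, stringsAsFactors = FALSE)
    }))
    if (is.null(samples) || !nrow(samples))
      stop("flock sizes produced no animals", call. = FALSE)
    copies <- c(affected = 2L, carrier = 1L, unaffected = 0L)[samples$status]
    names(copies) <- samples$id

    G <- matrix(0L, nrow(samples), cfg$n_snps,
                dimnames = list(samples$id, NULL))
    for (i in seq_len(nrow(samples))) {
      g <- rbinom(cfg$n_snps, 2L, freq_b)
      nc <- copies[[i]]
      if (nc > 0L) for (k in seq_along(seg_idx)) {
        gi <- seg_idx[[k]]
        extra <- if (nc == 2L) 0L else rbinom(length(gi), 1L, freq_b[gi])
        g[gi] <- nc * anc[[k]] + extra
      }
      G[i, ] <- g
    }

    # pin segment boundaries: the locus on either side of a planted segment
    # is forced heterozygous in one affected animal per flock, marking the
    # recombination breakpoints that delimit the shared ancestral segment;
    # without this, chance background homozygosity across all affected
    # animals would stochastically extend the designed run
    if (length(seg_idx)) {
      for (fl in unique(samples$flock)) {
        pin <- which(samples$flock == fl & copies == 2L)[1L]
        if (is.na(pin)) next
        for (k in seq_along(seg_idx)) {
          gi <- seg_idx[[k]]
          ch_span <- range(chrom_span(loci, loci$chrom[gi[1L]]))
          for (b in c(gi[1L] - 1L, gi[length(gi)] + 1L))
            if (b >= ch_span[1L] && b <= ch_span[2L]) G[pin, b] <- 1L
        }
      }
    }

    if (cfg$genotyping_error_rate > 0) {
      err <- which(matrix(runif(length(G)) < cfg$genotyping_error_rate,
                          nrow(G)))
      if (length(err)) {
        shift <- sample(1:2, length(err), replace = TRUE)
        G[err] <- (G[err] + shift) %% 3L
      }
    }

    genotype_panel(loci, samples, G, planted = planted,
                   causal_copies = copies)
  })
}

chrom_span <- function(loci, chrom) which(loci$chrom == chrom)

# proportional allocation of markers to chromosomes, largest remainder rule
allocate_markers <- function(n, lengths) {
  w <- lengths / sum(lengths)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * w - base
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  out <- as.integer(base)
  names(out) <- names(lengths)
  out
}

#' Simulate causal genotypes and phenotype labels from carrier matings
#'
#' Draws lambs from carrier-by-carrier matings: the causal-haplotype copy
#' number follows the Mendelian 1:2:1 distribution, and homozygous-mutant
#' lambs are labelled `affected` with probability `penetrance` (otherwise
#' `unaffected`, modelling reduced penetrance). Heterozygous lambs are
#' labelled `carrier` and homozygous wild-type lambs `unaffected`. With the
#' default penetrance 0.482 the expected affected fraction is
#' 0.25 x 0.482 = 0.1205, matching the 37/307 affected lambs the breeding
#' programme this simulator emulates produced.
#'
#' @param n_lambs Number of offspring to draw.
#' @param penetrance Probability a homozygous-mutant lamb is labelled
#'   affected; in (0, 1].
#' @param seed Optional RNG seed.
#' @return data.frame with columns `id`, `genotype` (0/1/2 copies of the
#'   causal haplotype) and `status`.
#' @export
sim_carrier_matings <- function(n_lambs, penetrance = 0.482, seed = NULL) {
  stopifnot(is_count(n_lambs), penetrance > 0, penetrance <= 1)
  with_seed(seed, {
    g <- rbinom(n_lambs, 2L, 0.5)  # one allele from each carrier parent
    status <- ifelse(g == 2L,
                     ifelse(runif(n_lambs) < penetrance,
                            "affected", "unaffected"),
                     ifelse(g == 1L, "carrier", "unaffected"))
    data.frame(id = sprintf("lamb%05d", seq_len(n_lambs)),
               genotype = g, status = status, stringsAsFactors = FALSE)
  })
}
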