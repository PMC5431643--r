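#' Configuration for homozygosity mapping
#'
#' @param min_snps Minimum number of consecutive qualifying SNPs for a run or
#'   shared region to be reported (default 8, the threshold used to define a
#'   candidate consecutive homozygous region).
#' @param window_size Sliding-window length in SNPs for the error-tolerant
#'   concordance track (default 8, mirroring `min_snps`).
#' @param window_concordance_min Minimum fraction of concordant SNPs for a
#'   window to seed a relaxed candidate region (default 0.9). Note that at
#'   the default window of 8 SNPs, a single discordant call scores
#'   7/8 = 0.875, so tolerating one bad call per window requires a threshold
#'   of 0.875 or below.
#' @param missing_policy How missing calls are treated: `"neutral"` (a
#'   missing call neither proves nor breaks homozygosity, up to
#'   `max_consecutive_missing` in a row) or `"break"` (a missing call
#'   terminates a run).
#' @param max_consecutive_missing Longest stretch of consecutive missing
#'   calls tolerated under the neutral policy (default 1).
#' @return Object of class `mapping_config`.
#' @export
mapping_config <- function(min_snps = 8L, window_size = 8L,
                           window_concordance_min = 0.9,
                           missing_policy = c("neutral", "break"),
                           max_consecutive_missing = 1L) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is_count(min_snps), min_snps >= 2,
            is_count(window_size), window_size >= 2,
            window_concordance_min > 0, window_concordance_min <= 1,
            is_count(max_consecutive_missing))
  structure(list(min_snps = as.integer(min_snps),
                 window_size = as.integer(window_size),
                 window_concordance_min = window_concordance_min,
                 missing_policy = missing_policy,
                 max_consecutive_missing = as.integer(max_consecutive_missing)),
            class = "mapping_config")
}

# per-locus homozygosity compatibility for one genotype vector:
# hom (0/2) -> TRUE; het -> FALSE; missing -> policy-dependent
hom_compatible <- function(g, policy, max_miss) {
  ok <- g == 0L | g == 2L
  miss <- g == -1L
  if (any(miss)) {
    if (policy == "neutral") {
      r <- rle(miss)
      short <- rep(r$values & r$lengths <= max_miss, r$lengths)
      ok[miss] <- short[miss]
    } else {
      ok[miss] <- FALSE
    }
  }
  ok
}

#' Call runs of homozygosity for one animal
#'
#' Scans each chromosome for maximal runs of consecutive loci whose
#' non-missing genotypes are homozygous, with missing calls handled per the
#' configured policy. Runs shorter than `min_snps` are discarded; runs never
#' span chromosomes.
#'
#' @param panel A [genotype_panel()].
#' @param sample_id Animal to scan.
#' @param config A [mapping_config()].
#' @return data.frame with one row per run: `sample_id`, `chrom`,
#'   `start_index`, `end_index` (1-based inclusive indices into that
#'   chromosome's locus list), `n_snps`, `start_bp`, `end_bp`.
#' @export
call_homozygosity_runs <- function(panel, sample_id,
                                   config = mapping_config()) {
  i <- sample_index(panel, sample_id)
  out <- lapply(panel_chroms(panel), function(ch) {
    gidx <- chrom_loci(panel, ch)
    ok <- hom_compatible(panel$genotypes[i, gidx],
                         config$missing_policy,
                         config$max_consecutive_missing)
    runs <- true_runs(ok)
    runs <- runs[runs$end - runs$start + 1L >= config$min_snps, ,
                 drop = FALSE]
    if (!nrow(runs)) return(NULL)
    data.frame(sample_id = as.character(sample_id), chrom = ch,
               start_index = runs$start, end_index = runs$end,
               n_snps = runs$end - runs$start + 1L,
               start_bp = panel$loci$pos_bp[gidx[runs$start]],
               end_bp = panel$loci$pos_bp[gidx[runs$end]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = character(),
                      start_index = integer(), end_index = integer(),
                      n_snps = integer(), start_bp = integer(),
                      end_bp = integer(), stringsAsFactors = FALSE)
  out
}

empty_regions <- function() {
  data.frame(chrom = character(), start_index = integer(),
             end_index = integer(), n_snps = integer(),
             start_bp = integer(), end_bp = integer(),
             ibd_identical = logical(), carrier_fixed = logical(),
             mean_concordance = numeric(), stringsAsFactors = FALSE)
}

#' Shared concordant homozygous (candidate IBD) regions across affected animals
#'
#' Finds maximal intervals where every affected animal is homozygous (per
#' the missing policy) at every SNP, of length at least `min_snps`. Each
#' region carries an `ibd_identical` flag: TRUE when at every SNP all
#' affected animals share the same homozygous allele (allowing missing
#' calls), the signature of a segment inherited identical by descent from a
#' common ancestor. `mean_concordance` summarises the region's
#' allele-concordance windows (window size from `config`).
#'
#' @param panel A [genotype_panel()].
#' @param affected_ids Character vector of affected animals (at least 2 for
#'   a meaningful shared analysis).
#' @param config A [mapping_config()].
#' @return data.frame of regions, sorted by (chrom, start), non-overlapping;
#'   `carrier_fixed` is `NA` until [carrier_fixation_filter()] is applied.
#' @export
shared_concordant_regions <- function(panel, affected_ids,
                                      config = mapping_config()) {
  if (length(affected_ids) < 1L)
    stop("affected set is empty", call. = FALSE)
  rows <- sample_index(panel, affected_ids)
  out <- lapply(panel_chroms(panel), function(ch) {
    gidx <- chrom_loci(panel, ch)
    ok_all <- Reduce(`&`, lapply(rows, function(r) {
      hom_compatible(panel$genotypes[r, gidx],
                     config$missing_policy,
                     config$max_consecutive_missing)
    }))
    runs <- true_runs(ok_all)
    runs <- runs[runs$end - runs$start + 1L >= config$min_snps, ,
                 drop = FALSE]
    if (!nrow(runs)) return(NULL)
    G <- panel$genotypes[rows, gidx, drop = FALSE]
    conc <- site_allele_concordant(G, config$missing_policy)
    data.frame(chrom = ch, start_index = runs$start, end_index = runs$end,
               n_snps = runs$end - runs$start + 1L,
               start_bp = panel$loci$pos_bp[gidx[runs$start]],
               end_bp = panel$loci$pos_bp[gidx[runs$end]],
               ibd_identical = vapply(seq_len(nrow(runs)), function(k) {
                 all(conc[runs$start[k]:runs$end[k]])
               }, logical(1)),
               carrier_fixed = NA,
               mean_concordance = vapply(seq_len(nrow(runs)), function(k) {
                 region_mean_concordance(conc[runs$start[k]:runs$end[k]],
                                         config$window_size)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_regions())
  out[order(out$chrom, out$start_index), , drop = FALSE]
}

# per-site allele concordance across the affected matrix (animals x loci):
# TRUE when all non-missing genotypes are homozygous and identical
# (break policy: any missing call disqualifies the site)
site_allele_concordant <- function(G, policy) {
  vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    miss <- g == -1L
    if (policy == "break" && any(miss)) return(FALSE)
    v <- g[!miss]
    if (!length(v)) return(TRUE)  # no evidence against concordance
    all(v %in% c(0L, 2L)) && length(unique(v)) == 1L
  }, logical(1))
}

region_mean_concordance <- function(conc, window) {
  n <- length(conc)
  w <- min(window, n)
  cs <- cumsum(conc)
  frac <- (cs[w:n] - c(0, cs)[(w:n) - w + 1L]) / w
  mean(frac)
}

#' Sliding-window concordance track and relaxed candidate regions
#'
#' For each window start on a chromosome, reports the fraction of the
#' window's SNPs at which all affected animals are homozygous for the same
#' allele. Windows whose fraction reaches `window_concordance_min` are
#' merged (union of their footprints) into relaxed candidate regions,
#' providing tolerance to occasional genotyping or map errors that fragment
#' strict runs. Chromosomes shorter than the window are skipped with a
#' warning.
#'
#' @inheritParams shared_concordant_regions
#' @return List with `track` (named list per chromosome of window-start
#'   fractions) and `regions` (data.frame of merged relaxed regions with SNP
#'   index and bp extents).
#' @export
sliding_window_concordance <- function(panel, affected_ids,
                                       config = mapping_config()) {
  if (length(affected_ids) < 1L)
    stop("affected set is empty", call. = FALSE)
  rows <- sample_index(panel, affected_ids)
  w <- config$window_size
  track <- list()
  regions <- list()
  for (ch in panel_chroms(panel)) {
    gidx <- chrom_loci(panel, ch)
    n <- length(gidx)
    if (n < w) {
      warning("chromosome ", ch, " has fewer loci (", n,
              ") than the window (", w, "); skipped", call. = FALSE)
      next
    }
    G <- panel$genotypes[rows, gidx, drop = FALSE]
    conc <- site_allele_concordant(G, config$missing_policy)
    cs <- cumsum(conc)
    frac <- (cs[w:n] - c(0L, cs)[(w:n) - w + 1L]) / w
    track[[ch]] <- frac
    pass <- which(frac >= config$window_concordance_min)
    if (length(pass)) {
      cov <- logical(n)
      for (s in pass) cov[s:(s + w - 1L)] <- TRUE
      runs <- true_runs(cov)
      regions[[ch]] <- data.frame(
        chrom = ch, start_index = runs$start, end_index = runs$end,
        n_snps = runs$end - runs$start + 1L,
        start_bp = panel$loci$pos_bp[gidx[runs$start]],
        end_bp = panel$loci$pos_bp[gidx[runs$end]],
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    empty_regions()[, c("chrom", "start_index", "end_index", "n_snps",
                        "start_bp", "end_bp")]
  rownames(regions) <- NULL
  list(track = track, regions = regions)
}

#' Exclude regions fixed in a known carrier
#'
#' A region that is homozygous across a known (obligate heterozygote)
#' carrier cannot be the recessive locus: it is simply fixed in the
#' population. This sets `carrier_fixed = TRUE` on regions where any
#' designated carrier is homozygous at every region SNP and splits those
#' regions off the candidate list. A carrier with all-missing genotypes in
#' a region provides no evidence; the region is retained with
#' `carrier_fixed = NA` and a warning.
#'
#' @param regions Regions from [shared_concordant_regions()].
#' @param panel The [genotype_panel()].
#' @param carrier_ids Character vector of known carriers.
#' @return List with `kept` (candidate regions) and `excluded`
#'   (carrier-fixed regions).
#' @export
carrier_fixation_filter <- function(regions, panel, carrier_ids) {
  if (!nrow(regions)) return(list(kept = regions, excluded = regions))
  if (!length(carrier_ids)) {
    warning("no carriers supplied; regions returned unchanged",
            call. = FALSE)
    return(list(kept = regions, excluded = regions[0, , drop = FALSE]))
  }
  rows <- sample_index(panel, carrier_ids)
  fixed <- rep(NA, nrow(regions))
  for (k in seq_len(nrow(regions))) {
    gidx <- chrom_loci(panel, regions$chrom[k])
    span <- gidx[regions$start_index[k]:regions$end_index[k]]
    verdicts <- vapply(rows, function(r) {
      g <- panel$genotypes[r, span]
      nm <- g[g != -1L]
      if (!length(nm)) return(NA)  # no evidence
      all(nm %in% c(0L, 2L))
    }, logical(1))
    if (all(is.na(verdicts))) {
      warning("carrier genotypes all missing in region ", k,
              "; fixation undetermined", call. = FALSE)
      fixed[k] <- NA
    } else {
      fixed[k] <- any(verdicts, na.rm = TRUE)
    }
  }
  regions$carrier_fixed <- fixed
  list(kept = regions[!fixed %in% TRUE, , drop = FALSE],
       excluded = regions[fixed %in% TRUE, , drop = FALSE])
}

#' Intersect candidate regions across flocks
#'
#' A causal region segregating from a shared ancestor must appear in every
#' affected flock; regions private to one flock are mapping noise or
#' flock-specific autozygosity. Returns the base-pair intersections of
#' regions present (overlapping by at least one base) in every flock, and
#' the flock-private regions separately.
#'
#' @param regions_by_flock Named list of region data.frames, one per flock.
#' @param panel Optional [genotype_panel()]; when given, SNP counts of the
#'   intersections are recomputed from its map.
#' @return List with `candidates` (chrom/start_bp/end_bp of cross-flock
#'   intersections, plus `n_snps` when `panel` is given) and `excluded`
#'   (flock-private regions with a `flock` column).
#' @export
cross_flock_intersection <- function(regions_by_flock, panel = NULL) {
  stopifnot(is.list(regions_by_flock), length(regions_by_flock) >= 1L)
  flocks <- names(regions_by_flock) %||%
    as.character(seq_along(regions_by_flock))
  names(regions_by_flock) <- flocks
  if (length(regions_by_flock) == 1L) {
    return(list(candidates = regions_by_flock[[1L]],
                excluded = cbind(regions_by_flock[[1L]][0, , drop = FALSE],
                                 flock = character())))
  }
  chroms <- unique(unlist(lapply(regions_by_flock, function(r) r$chrom)))
  cand <- list()
  for (ch in chroms) {
    per_flock <- lapply(regions_by_flock, function(r) {
      rr <- r[r$chrom == ch, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(start = rr$start_bp,
                                       end = rr$end_bp))
    })
    inter <- Reduce(IRanges::intersect, per_flock)
    if (length(inter)) {
      cand[[ch]] <- data.frame(chrom = ch,
                               start_bp = IRanges::start(inter),
                               end_bp = IRanges::end(inter),
                               stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(chrom = character(), start_bp = integer(),
               end_bp = integer(), stringsAsFactors = FALSE)
  rownames(cand) <- NULL
  if (!is.null(panel) && nrow(cand)) {
    cand$n_snps <- vapply(seq_len(nrow(cand)), function(k) {
      sum(panel$loci$chrom == cand$chrom[k] &
            panel$loci$pos_bp >= cand$start_bp[k] &
            panel$loci$pos_bp <= cand$end_bp[k])
    }, integer(1))
  }

  excl <- list()
  for (fl in flocks) {
    r <- regions_by_flock[[fl]]
    if (!nrow(r)) next
    others <- regions_by_flock[setdiff(flocks, fl)]
    private <- vapply(seq_len(nrow(r)), function(k) {
      !all(vapply(others, function(o) {
        oo <- o[o$chrom == r$chrom[k], , drop = FALSE]
        any(oo$start_bp <= r$end_bp[k] & oo$end_bp >= r$start_bp[k])
      }, logical(1)))
    }, logical(1))
    if (any(private))
      excl[[fl]] <- cbind(r[private, , drop = FALSE], flock = fl)
  }
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(chrom = character(), start_bp = integer(),
               end_bp = integer(), flock = character(),
               stringsAsFactors = FALSE)
  rownames(excl) <- NULL
  list(candidates = cand, excluded = excl)
}
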