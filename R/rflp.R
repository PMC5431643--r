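#' Restriction enzyme definitions
#'
#' Small built-in table of enzymes, each defined by an IUPAC recognition
#' pattern and a top-strand cut offset: `cut_offset = k` cuts after the k-th
#' base of the pattern. ApoI is `R^AATTY` (R = A/G, Y = C/T), a degenerate
#' palindrome: its reverse complement is the same pattern, so a single
#' top-strand scan finds every site.
#'
#' @param name Enzyme name; one of the built-ins (`"ApoI"`, `"EcoRI"`,
#'   `"HindIII"`, `"TaqI"`) or use `site`/`cut_offset` to define a custom
#'   enzyme.
#' @param site IUPAC recognition pattern (overrides the built-in).
#' @param cut_offset Bases from pattern start after which the top strand is
#'   cut (overrides the built-in).
#' @return Object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name = "ApoI", site = NULL, cut_offset = NULL) {
  builtin <- list(
    ApoI    = list(site = "RAATTY", cut_offset = 1L),
    EcoRI   = list(site = "GAATTC", cut_offset = 1L),
    HindIII = list(site = "AAGCTT", cut_offset = 1L),
    TaqI    = list(site = "TCGA",   cut_offset = 1L))
  if (is.null(site)) {
    if (!name %in% names(builtin))
      stop("unknown enzyme '", name, "'; supply `site` and `cut_offset`",
           call. = FALSE)
    site <- builtin[[name]]$site
    cut_offset <- builtin[[name]]$cut_offset
  }
  site <- toupper(site)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site))
    stop("recognition site must be IUPAC nucleotide codes", call. = FALSE)
  cut_offset <- as.integer(cut_offset %||% 1L)
  if (cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie within the pattern", call. = FALSE)
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' In-silico PCR with exact primer matching
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the template and returns the inclusive amplicon (primers
#' included). Exactly one product must form; zero or multiple products raise
#' an assay-design error listing all primer hits. Primer matching is exact
#' (no mismatch model).
#'
#' @param template Template sequence (character).
#' @param primers List with elements `fwd` and `rev` (5'->3' sequences, each
#'   at least 15 nt).
#' @return Object of class `amplicon`: list with `seq`, `start`, `end`
#'   (1-based inclusive template coordinates) and `length`.
#' @export
in_silico_pcr <- function(template, primers) {
  stopifnot(is.character(template), length(template) == 1L)
  fwd <- toupper(primers$fwd)
  rev <- toupper(primers$rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  subj <- Biostrings::DNAString(toupper(template))
  f_hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(fwd), subj))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  r_hits <- Biostrings::end(Biostrings::matchPattern(
    Biostrings::DNAString(rc), subj))
  # a product forms for every fwd hit with a rev-site end downstream of it
  prod <- expand.grid(f = as.integer(f_hits), r = as.integer(r_hits))
  prod <- prod[prod$r >= prod$f + nchar(fwd), , drop = FALSE]
  if (nrow(prod) != 1L)
    stop(sprintf(
      "in-silico PCR requires exactly one product, found %d (forward hits: %s; reverse-site ends: %s)",
      nrow(prod),
      paste(f_hits, collapse = ",") %||% "",
      paste(r_hits, collapse = ",") %||% ""), call. = FALSE)
  start <- prod$f[1L]
  end <- prod$r[1L]
  structure(list(seq = substr(template, start, end),
                 start = start, end = end, length = end - start + 1L),
            class = "amplicon")
}

#' Digest an amplicon with a restriction enzyme
#'
#' Scans the top strand for every IUPAC match of the recognition pattern,
#' cuts after `cut_offset` bases of each match, and returns the fragment
#' lengths in descending order. Fragment lengths always sum to the amplicon
#' length. For palindromic patterns such as ApoI's `RAATTY` the top-strand
#' scan covers both strands; for non-palindromic patterns both strands are
#' scanned.
#'
#' @param amplicon An [in_silico_pcr()] product, or a plain sequence string.
#' @param enzyme A [restriction_enzyme()].
#' @return Object of class `digest_profile`: list with `fragment_lengths`
#'   (descending), `cut_positions` (cut after these 1-based positions) and
#'   `amplicon_length`.
#' @export
digest <- function(amplicon, enzyme = restriction_enzyme("ApoI")) {
  seq <- if (inherits(amplicon, "amplicon")) amplicon$seq else
    as.character(amplicon)
  stopifnot(nchar(seq) > 0L)
  subj <- Biostrings::DNAString(toupper(seq))
  pat <- Biostrings::DNAString(enzyme$site)
  hits <- Biostrings::start(Biostrings::matchPattern(pat, subj,
                                                     fixed = FALSE))
  cuts <- as.integer(hits) + enzyme$cut_offset - 1L
  rc_pat <- Biostrings::reverseComplement(pat)
  if (as.character(rc_pat) != as.character(pat)) {
    # non-palindromic site: bottom-strand matches cut the duplex too
    hits2 <- Biostrings::start(Biostrings::matchPattern(rc_pat, subj,
                                                        fixed = FALSE))
    cuts2 <- as.integer(hits2) + (nchar(enzyme$site) - enzyme$cut_offset) - 1L
    cuts <- c(cuts, cuts2)
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < nchar(seq)]))
  frags <- diff(c(0L, cuts, nchar(seq)))
  structure(list(fragment_lengths = sort(frags, decreasing = TRUE),
                 cut_positions = cuts,
                 amplicon_length = nchar(seq)),
            class = "digest_profile")
}

#' Call a genotype from an observed restriction band pattern
#'
#' Matches the observed set of band lengths against the three reference
#' patterns: the unaffected (wild-type) digest, the affected (mutant) digest
#' and their union (carrier). Anything else is a failed call. Band matching
#' is exact by default; `tolerance` (bp) allows gel-resolution slack when
#' parsing real gel tables.
#'
#' @param observed Integer vector of observed band lengths.
#' @param patterns List with elements `U` and `A`: reference band sets for
#'   the two homozygous genotypes; the carrier pattern is their union.
#'   Defaults to the fixture assay's 140/208/264 and 140/472 patterns.
#' @param tolerance Band-length matching tolerance in bp (default 0).
#' @return One of `"U"`, `"C"`, `"A"`, `"fail"`.
#' @export
genotype_from_bands <- function(observed,
                                patterns = list(U = c(140L, 208L, 264L),
                                                A = c(140L, 472L)),
                                tolerance = 0) {
  obs <- sort(unique(as.integer(observed)))
  refs <- list(U = sort(unique(patterns$U)),
               A = sort(unique(patterns$A)),
               C = sort(unique(c(patterns$U, patterns$A))))
  match_set <- function(ref) {
    length(obs) == length(ref) && all(abs(obs - ref) <= tolerance)
  }
  # carrier first: with tolerance 0 the three sets are distinct; with slack
  # the richest pattern is the most specific match
  if (match_set(refs$C)) return("C")
  if (match_set(refs$U)) return("U")
  if (match_set(refs$A)) return("A")
  "fail"
}

#' Build wild-type and mutant RFLP templates and primers from the fixture
#'
#' Returns two PCR templates identical except at the site-destroying base
#' (the fixture's first causal variant): the wild-type amplicon between the
#' primers is exactly 612 bp with ApoI cut sites after 140 bp and 348 bp
#' (fragments 264/208/140), while the mutant allele destroys the internal
#' site (fragments 472/140). The second causal variant lies in cis on the
#' mutant haplotype but touches no ApoI site, so the assay reads out the
#' whole causal haplotype through variant 1 alone; the templates therefore
#' differ at exactly one base.
#'
#' @param fixture A [transcript_fixture()].
#' @return Object of class `rflp_fixture`: list with `wild`, `mutant`
#'   (template sequences), `primers` (list `fwd`, `rev`), `amplicon_length`
#'   (612) and `patterns` (expected band sets `U` and `A`).
#' @export
gen_rflp_templates <- function(fixture = transcript_fixture()) {
  stopifnot(inherits(fixture, "transcript_fixture"))
  cds <- fixture$cds
  v1 <- fixture$causal[1L, ]
  # template = the exon holding the amplicon (both variants are exonic)
  exon2_start <- FIXTURE_EXON1_LEN + 1L
  wild <- substr(cds, exon2_start, nchar(cds))
  mut <- wild
  at <- v1$cdna_pos - exon2_start + 1L
  stopifnot(substr(mut, at, at) == v1$ref)
  substr(mut, at, at) <- v1$alt

  amp_from <- FIXTURE_AMPLICON_START - exon2_start + 1L
  amp_to <- FIXTURE_AMPLICON_END - exon2_start + 1L
  amplicon <- substr(wild, amp_from, amp_to)
  stopifnot(nchar(amplicon) == 612L)
  fwd <- substr(amplicon, 1L, 20L)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amplicon, 612L - 19L, 612L))))

  out <- structure(list(wild = wild, mutant = mut,
                        primers = list(fwd = fwd, rev = rev),
                        amplicon_length = 612L,
                        patterns = list(U = c(140L, 208L, 264L),
                                        A = c(140L, 472L))),
                   class = "rflp_fixture")
  # construction invariants: unique product on each allele, expected digests
  wt_prof <- digest(in_silico_pcr(wild, out$primers))
  mt_prof <- digest(in_silico_pcr(mut, out$primers))
  stopifnot(identical(wt_prof$fragment_lengths, c(264L, 208L, 140L)),
            identical(mt_prof$fragment_lengths, c(472L, 140L)))
  out
}

#' Genotype a cohort by simulated PCR-RFLP
#'
#' For every animal, builds the two allele templates implied by its causal
#' genotype (0, 1 or 2 mutant alleles), amplifies and digests each allele,
#' unions the band sets, calls the genotype from the band pattern and
#' reports concordance of the calls against the true genotypes and, when
#' available, against phenotype labels. A PCR failure on any allele is
#' recorded as `call = "fail"`; failed calls stay in the denominator of the
#' concordance summary.
#'
#' @param genotypes Named integer vector (0/1/2) of true causal genotypes
#'   per animal, or a [gen_snp_panel()] panel (its `causal_copies` are
#'   used).
#' @param fixture A [transcript_fixture()] (templates are rebuilt from it),
#'   or an `rflp_fixture` from [gen_rflp_templates()].
#' @param enzyme A [restriction_enzyme()].
#' @param status Optional named character vector of phenotype labels for
#'   call-vs-phenotype concordance.
#' @param template_overrides Optional named list: per-animal list with
#'   elements `allele1`/`allele2` replacing that animal's templates (used to
#'   model assay failures such as primer-site mutations).
#' @return Object of class `rflp_cohort`: list with `calls` (data.frame:
#'   `sample_id`, `true_genotype`, `bands`, `call`, `called_genotype`,
#'   `concordant`) and `concordance` (list with `n`, `n_concordant`,
#'   `n_fail`, and phenotype concordance when `status` is given).
#' @export
genotype_cohort <- function(genotypes, fixture = transcript_fixture(),
                            enzyme = restriction_enzyme("ApoI"),
                            status = NULL, template_overrides = NULL) {
  if (inherits(genotypes, "genotype_panel")) {
    panel <- genotypes
    if (is.null(panel$causal_copies))
      stop("panel records no causal genotypes", call. = FALSE)
    genotypes <- panel$causal_copies
    if (is.null(status))
      status <- setNames(panel$samples$status, panel$samples$id)
  }
  stopifnot(all(genotypes %in% 0:2), !is.null(names(genotypes)))
  fx <- if (inherits(fixture, "rflp_fixture")) fixture else
    gen_rflp_templates(fixture)

  allele_bands <- function(template) {
    prof <- digest(in_silico_pcr(template, fx$primers), enzyme)
    prof$fragment_lengths
  }
  calls <- lapply(names(genotypes), function(id) {
    g <- genotypes[[id]]
    tmpl <- list(allele1 = if (g >= 1L) fx$mutant else fx$wild,
                 allele2 = if (g == 2L) fx$mutant else fx$wild)
    ov <- template_overrides[[id]]
    if (!is.null(ov)) tmpl[names(ov)] <- ov
    bands <- tryCatch(
      sort(unique(c(allele_bands(tmpl$allele1), allele_bands(tmpl$allele2)))),
      error = function(e) NULL)
    call <- if (is.null(bands)) "fail" else
      genotype_from_bands(bands, fx$patterns)
    data.frame(sample_id = id, true_genotype = g,
               bands = if (is.null(bands)) NA_character_ else
                 paste(sort(bands, decreasing = TRUE), collapse = "+"),
               call = call, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  calls$called_genotype <- c(U = 0L, C = 1L, A = 2L,
                             fail = NA_integer_)[calls$call]
  calls$concordant <- !is.na(calls$called_genotype) &
    calls$called_genotype == calls$true_genotype

  conc <- list(n = nrow(calls),
               n_concordant = sum(calls$concordant),
               n_fail = sum(calls$call == "fail"))
  if (!is.null(status)) {
    st <- status[calls$sample_id]
    # under full penetrance, affected <=> homozygous-mutant call "A";
    # non-penetrant homozygotes surface here as listed discordances
    expected_call <- ifelse(st == "affected", "A",
                            ifelse(st == "carrier", "C", "U"))
    calls$status <- unname(st)
    calls$phenotype_concordant <- calls$call == expected_call
    conc$n_phenotype_concordant <- sum(calls$phenotype_concordant,
                                       na.rm = TRUE)
    conc$phenotype_discordant <-
      calls$sample_id[!calls$phenotype_concordant %in% TRUE]
  }
  structure(list(calls = calls, concordance = conc), class = "rflp_cohort")
}

#' @exportS3Method base::print
print.rflp_cohort <- function(x, ...) {
  cat("<rflp_cohort> ", x$concordance$n, " animals, ",
      x$concordance$n_concordant, " call-genotype concordant, ",
      x$concordance$n_fail, " failed\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.digest_profile <- function(x, ...) {
  cat("<digest_profile> fragments:",
      paste(x$fragment_lengths, collapse = " + "),
      "=", x$amplicon_length, "bp\n")
  invisible(x)
}
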