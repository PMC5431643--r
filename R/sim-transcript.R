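# Transcript fixture layout (all coordinates 1-based in the coding sequence):
#
#   CDS: 2958 nt = 986 codons (ATG ... TAA), deterministic sequence
#   codon 681 = ATT (Ile) -> c.2042 T>A -> AAT (Asn)   "variant 1"
#   codon 687 = ATT (Ile) -> c.2060 T>G -> AGT (Ser)   "variant 2"
#   (18 nt apart; residues 6 codons apart)
#
#   Amplicon: cds[1692..2303], 612 bp, both primers included.
#   ApoI (R^AATTY) sites in the wild-type amplicon:
#     site 1: planted "GAATTC" at cds 1831..1836  -> cut after amplicon 140
#     site 2: "GAATTT" spanning codons 680-682    -> cut after amplicon 348
#   Variant 1 (c.2042 T>A) lies at position 4 of site 2 and destroys it;
#   site 1 is untouched by either variant.
#
#   Exons: exon 1 = cds 1..600, 500-bp intron, exon 2 = cds 601..2958, so the
#   amplicon and both variants lie in a single exon, as in an exonic
#   PCR-RFLP assay.

FIXTURE_AMPLICON_START <- 1692L
FIXTURE_AMPLICON_END <- 2303L
FIXTURE_SITE1_START <- 1831L
FIXTURE_SITE2_START <- 2039L
FIXTURE_EXON1_LEN <- 600L
FIXTURE_INTRON_LEN <- 500L

#' Deterministic transcript fixture carrying the two causal missense variants
#'
#' Builds a self-consistent coding model of the candidate gene: a 2958-nt CDS
#' whose codons 681 and 687 are isoleucines, with the two causal variants
#' c.2042T>A (p.I681N) and c.2068-equivalent c.2060T>G (p.I687S) 18 nt apart,
#' and a restriction-site layout such that the wild-type allele's PCR
#' amplicon carries two ApoI sites while variant 1 destroys the internal one.
#' The fixture uses its own internally consistent cDNA/residue numbering
#' rather than any external transcript's.
#'
#' @param gene_id Gene label.
#' @param chrom Chromosome label the gene is placed on.
#' @param tx_start Genomic start of the transcript, or `NULL` if not yet
#'   placed (see [place_transcript()]).
#' @return Object of class `transcript_fixture` with fields `gene_id`,
#'   `chrom`, `strand`, `tx_start`, `exons` (cDNA extents + genomic extents
#'   once placed), `cds` (character), `causal` (data.frame of the two causal
#'   variants with expected amino-acid consequences).
#' @export
transcript_fixture <- function(gene_id = "TMEM67", chrom = "9",
                               tx_start = NULL) {
  cds <- build_fixture_cds()
  causal <- data.frame(
    cdna_pos = c(2042L, 2060L),
    ref = c("T", "T"), alt = c("A", "G"),
    ref_aa = c("I", "I"), alt_aa = c("N", "S"),
    residue = c(681L, 687L),
    stringsAsFactors = FALSE)
  fx <- structure(
    list(gene_id = gene_id, chrom = as.character(chrom), strand = "+",
         tx_start = tx_start,
         exons = data.frame(cdna_start = c(1L, FIXTURE_EXON1_LEN + 1L),
                            cdna_end = c(FIXTURE_EXON1_LEN, nchar(cds))),
         cds = cds, causal = causal),
    class = "transcript_fixture")
  validate_transcript_fixture(fx)
}

validate_transcript_fixture <- function(fx) {
  stopifnot(inherits(fx, "transcript_fixture"))
  n <- nchar(fx$cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3", call. = FALSE)
  for (i in seq_len(nrow(fx$causal))) {
    v <- fx$causal[i, ]
    codon_no <- ceiling(v$cdna_pos / 3)
    cod <- substr(fx$cds, 3L * codon_no - 2L, 3L * codon_no)
    if (substr(fx$cds, v$cdna_pos, v$cdna_pos) != v$ref)
      stop("fixture ref base mismatch at c.", v$cdna_pos, call. = FALSE)
    off <- v$cdna_pos - (3L * codon_no - 3L)
    alt_cod <- cod
    substr(alt_cod, off, off) <- v$alt
    if (translate_codon(cod) != v$ref_aa ||
        translate_codon(alt_cod) != v$alt_aa ||
        codon_no != v$residue)
      stop("fixture causal variant ", i,
           " does not translate to the expected substitution", call. = FALSE)
  }
  fx
}

# deterministic CDS construction; internal fixed seed makes the fixture a
# constant of the package
build_fixture_cds <- function() {
  n_codons <- 986L
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0))
  sense <- setdiff(all_codons, stops)
  codons <- with_seed(20050901, sample(sense, n_codons, replace = TRUE))
  codons[1L] <- "ATG"
  codons[n_codons] <- "TAA"
  codons[611L] <- "GAA"  # ApoI site 1: GAA|TTC at cds 1831..1836
  codons[612L] <- "TTC"
  codons[680L] <- "GGA"  # ApoI site 2: ..G|GA ATT T.. -> GAATTT at 2039..2044
  codons[681L] <- "ATT"  # Ile; c.2042 T>A -> AAT (Asn), destroys site 2
  codons[682L] <- "TAC"
  codons[687L] <- "ATT"  # Ile; c.2060 T>G -> AGT (Ser)
  cds <- paste(codons, collapse = "")

  # remove every other ApoI match; substituting C can neither complete
  # R AATT Y nor create a stop codon (no stop contains C)
  protected <- c(FIXTURE_SITE1_START:(FIXTURE_SITE1_START + 5L),
                 2038L:2046L, 2059L:2061L, 1L:3L,
                 (3L * n_codons - 2L):(3L * n_codons))
  repeat {
    hits <- apoi_sites(cds)
    extra <- setdiff(hits, c(FIXTURE_SITE1_START, FIXTURE_SITE2_START))
    if (!length(extra)) break
    for (s in extra) {
      at <- setdiff(s + 0:4, protected)[1L]
      if (is.na(at)) stop("cannot scrub fixture ApoI site at ", s)
      substr(cds, at, at) <- "C"
    }
  }
  stopifnot(identical(apoi_sites(cds),
                      c(FIXTURE_SITE1_START, FIXTURE_SITE2_START)))
  cds
}

# start positions of R AATT Y matches (top strand; the pattern is its own
# reverse complement so one scan covers both strands)
apoi_sites <- function(seq) {
  m <- Biostrings::matchPattern(
    Biostrings::DNAString("RAATTY"), Biostrings::DNAString(seq),
    fixed = FALSE)
  as.integer(Biostrings::start(m))
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[toupper(codon)]])
}

#' Place a transcript fixture inside a planted panel segment
#'
#' Assigns genomic coordinates to the fixture so that the whole transcript
#' (exons plus intron) lies inside one of the panel's planted IBD segments,
#' as required before variant calls against the panel can be generated.
#'
#' @param fixture A [transcript_fixture()].
#' @param panel A [gen_snp_panel()] output with planted segments.
#' @param segment Index of the planted segment to use (default 1).
#' @return The fixture with `tx_start` and genomic exon coordinates set.
#' @export
place_transcript <- function(fixture, panel, segment = 1L) {
  stopifnot(inherits(fixture, "transcript_fixture"),
            inherits(panel, "genotype_panel"))
  if (is.null(panel$planted) || nrow(panel$planted) < segment)
    stop("panel has no planted segment ", segment, call. = FALSE)
  seg <- panel$planted[segment, ]
  span <- transcript_genomic_span(fixture)
  width <- seg$end_bp - seg$start_bp + 1L
  if (width <= span)
    stop("planted segment too narrow for the transcript", call. = FALSE)
  fixture$chrom <- seg$chrom
  fixture$tx_start <- as.integer(seg$start_bp + (width - span) %/% 2L)
  fixture
}

transcript_genomic_span <- function(fx) {
  nchar(fx$cds) + FIXTURE_INTRON_LEN
}

# genomic coordinates of the fixture's exons (plus strand layout)
transcript_exons_genomic <- function(fx) {
  if (is.null(fx$tx_start))
    stop("transcript has no genomic placement; see place_transcript()",
         call. = FALSE)
  t0 <- fx$tx_start
  e1 <- c(t0, t0 + FIXTURE_EXON1_LEN - 1L)
  e2_start <- t0 + FIXTURE_EXON1_LEN + FIXTURE_INTRON_LEN
  e2 <- c(e2_start, e2_start + (nchar(fx$cds) - FIXTURE_EXON1_LEN) - 1L)
  data.frame(start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
             cdna_start = fx$exons$cdna_start, cdna_end = fx$exons$cdna_end)
}

# map a genomic position to a cDNA position (NA if intronic/intergenic)
genomic_to_cdna <- function(fx, pos) {
  ex <- transcript_exons_genomic(fx)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    inside <- !is.na(pos) & pos >= ex$start[i] & pos <= ex$end[i]
    if (fx$strand == "+") {
      out[inside] <- ex$cdna_start[i] + (pos[inside] - ex$start[i])
    } else {
      out[inside] <- ex$cdna_start[i] + (ex$end[i] - pos[inside])
    }
  }
  out
}

cdna_to_genomic <- function(fx, cdna) {
  ex <- transcript_exons_genomic(fx)
  out <- rep(NA_integer_, length(cdna))
  for (i in seq_len(nrow(ex))) {
    inside <- !is.na(cdna) & cdna >= ex$cdna_start[i] & cdna <= ex$cdna_end[i]
    if (fx$strand == "+") {
      out[inside] <- ex$start[i] + (cdna[inside] - ex$cdna_start[i])
    } else {
      out[inside] <- ex$end[i] - (cdna[inside] - ex$cdna_start[i])
    }
  }
  out
}

#' @exportS3Method base::print
print.transcript_fixture <- function(x, ...) {
  cat("<transcript_fixture> ", x$gene_id, " on chr", x$chrom, " (", x$strand,
      "), CDS ", nchar(x$cds), " nt, ",
      if (is.null(x$tx_start)) "unplaced" else paste0("tx_start ", x$tx_start),
      "\n", sep = "")
  print(x$causal)
  invisible(x)
}
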