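#' Ortholog alignment for residue conservation scoring
#'
#' An aligned residue matrix (rows = species, columns = alignment columns;
#' `-` marks gaps) plus the map from non-gap columns of the reference row to
#' residue numbers of the reference protein. With no arguments, builds the
#' package's default 11-species fixture around residues 661-700 of the
#' candidate protein: the reference (sheep) row plus eight further
#' vertebrates conserving the isoleucines at residues 681 and 687, and two
#' invertebrate rows (fly, worm) that do not — the conservation signature
#' motivating the conservation gate of [classify_deleterious()].
#'
#' @param mat Character matrix of aligned residues with species rownames;
#'   the first row is the reference.
#' @param start_residue Residue number of the first non-gap reference
#'   column.
#' @param fixture A [transcript_fixture()] supplying the reference protein
#'   for the default alignment.
#' @return Object of class `ortholog_alignment`: list with `mat`, `species`
#'   and `residue_of_column` (NA for reference-gap columns).
#' @export
ortholog_alignment <- function(mat = NULL, start_residue = 661L,
                               fixture = transcript_fixture()) {
  if (is.null(mat)) {
    mat <- default_alignment_matrix(fixture, start_residue)
  }
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (any(nchar(mat) != 1L))
    stop("alignment cells must be single residue characters", call. = FALSE)
  ref <- mat[1L, ]
  residue_of_column <- rep(NA_integer_, ncol(mat))
  non_gap <- ref != "-"
  residue_of_column[non_gap] <- start_residue + seq_len(sum(non_gap)) - 1L
  structure(list(mat = mat, species = rownames(mat),
                 residue_of_column = residue_of_column),
            class = "ortholog_alignment")
}

# Deterministic default: vertebrates conserve the block; fly and worm
# diverge at scattered positions including both causal isoleucines.
default_alignment_matrix <- function(fixture, start_residue) {
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(fixture$cds))), "")[[1L]]
  block <- aa[start_residue:(start_residue + 39L)]
  species <- c("sheep", "human", "cattle", "dog", "rat", "mouse",
               "chicken", "lamprey", "zebrafish", "fly", "worm")
  m <- matrix(rep(block, length(species)), nrow = length(species),
              byrow = TRUE, dimnames = list(species, NULL))
  # benign vertebrate divergence away from the causal columns
  i681 <- 681L - start_residue + 1L
  i687 <- 687L - start_residue + 1L
  benign <- setdiff(c(3L, 11L, 24L, 33L, 38L), c(i681, i687))
  subs <- c("S", "T", "A", "V", "N")
  for (j in seq_along(benign)) {
    sp <- c("chicken", "lamprey", "zebrafish", "rat", "dog")[j]
    m[sp, benign[j]] <- subs[j]
  }
  # invertebrates: divergent across the block, including the causal columns
  fly <- block
  worm <- block
  alt <- c("V", "L", "A", "T", "S", "G", "M", "F")
  idx <- seq(1L, 40L, by = 5L)
  fly[idx] <- alt[seq_along(idx)]
  worm[rev(idx)] <- alt[seq_along(idx)]
  fly[c(i681, i687)] <- c("V", "A")
  worm[c(i681, i687)] <- c("L", "T")
  worm[c(6L, 7L)] <- "-"  # a short indel
  m["fly", ] <- fly
  m["worm", ] <- worm
  m
}

#' Conservation of a reference residue across an ortholog alignment
#'
#' Returns the fraction of non-gap rows whose residue matches the reference
#' residue at the alignment column mapped to `residue_number`. Columns not
#' covered by the alignment (or columns that are entirely gaps) yield `NA`,
#' an undefined score — deliberately distinct from 0.
#'
#' @param alignment An [ortholog_alignment()].
#' @param residue_number Residue number in the reference protein.
#' @return Fraction in `[0, 1]`, or `NA` when undefined.
#' @export
conservation_score <- function(alignment, residue_number) {
  stopifnot(inherits(alignment, "ortholog_alignment"))
  col <- match(residue_number, alignment$residue_of_column)
  if (is.na(col)) return(NA_real_)
  column <- alignment$mat[, col]
  non_gap <- column != "-"
  if (!any(non_gap)) return(NA_real_)
  ref <- alignment$mat[1L, col]
  mean(column[non_gap] == ref)
}

#' @exportS3Method base::print
print.ortholog_alignment <- function(x, ...) {
  cat("<ortholog_alignment> ", nrow(x$mat), " species x ", ncol(x$mat),
      " columns (residues ", min(x$residue_of_column, na.rm = TRUE), "-",
      max(x$residue_of_column, na.rm = TRUE), ")\n", sep = "")
  invisible(x)
}
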