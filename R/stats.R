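#' Collapse a grade table to a 2x2 normal-vs-morphant contingency table
#'
#' Embryos of grades 1-4 are combined as morphologically defective
#' ("morphant") — grade 4 includes embryos that died at or shortly after the
#' scoring stage — against the grade-0 (normal) column, for a chosen pair of
#' injection conditions.
#'
#' @param table A `grade_table` from [gen_embryo_grades()] (or any matrix
#'   with a `normal` column and grade columns, conditions as rownames).
#' @param condition_pair Character vector of two condition names.
#' @return 2x2 integer matrix, rows = conditions, columns =
#'   `c("normal", "morphant")`.
#' @export
collapse_grades <- function(table, condition_pair) {
  stopifnot(length(condition_pair) == 2L)
  missing <- setdiff(condition_pair, rownames(table))
  if (length(missing))
    stop("condition(s) absent from grade table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  grade_cols <- setdiff(colnames(table), "normal")
  out <- cbind(normal = table[condition_pair, "normal"],
               morphant = rowSums(table[condition_pair, grade_cols,
                                        drop = FALSE]))
  storage.mode(out) <- "integer"
  out
}

#' Two-tailed Fisher exact test by hypergeometric enumeration
#'
#' Computes the exact two-sided p-value of a 2x2 table by enumerating every
#' table with the observed margins under the hypergeometric null and
#' summing the probabilities of all tables whose point probability does not
#' exceed that of the observed table (the "small-p" two-tail rule), with a
#' relative tie tolerance of 1e-7. A table with a zero row or column margin
#' carries no information; by convention it returns p = 1 with a warning.
#'
#' @param t A 2x2 matrix of non-negative integer counts (or a vector
#'   `c(a, b, c, d)` filled by row).
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_two_tailed <- function(t) {
  m <- matrix(as.numeric(t), 2L, 2L, byrow = !is.matrix(t))
  if (any(m < 0) || any(m != floor(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    warning("zero row or column margin; p = 1 by convention", call. = FALSE)
    return(1)
  }
  # hypergeometric over the top-left cell x: x ~ Hyper(m = cs[1], n = cs[2],
  # k = rs[1]); support is [max(0, rs1 - cs2), min(rs1, cs1)]
  supp <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  probs <- dhyper(supp, cs[1], cs[2], rs[1])
  p_obs <- dhyper(m[1, 1], cs[1], cs[2], rs[1])
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Rescue-assay contrasts: morpholino alone versus each co-injection
#'
#' Collapses the grade table and tests the two rescue contrasts —
#' morpholino alone (`MO`) versus wild-type mRNA co-injection (`MO+WT`) and
#' versus mutant mRNA co-injection (`MO+MT`) — each with the exact
#' two-tailed Fisher test, reporting the 2x2 tables, p-values, significance
#' verdicts at `alpha` and per-condition morphant fractions.
#'
#' @param table A `grade_table` containing at least the `MO` row.
#' @param alpha Significance level for the verdicts (default 0.05).
#' @return Object of class `rescue_report`: list with `contrasts` (named
#'   list, each with `table`, `p_value`, `significant`) and
#'   `morphant_fraction` (named vector over conditions present).
#' @export
rescue_comparison <- function(table, alpha = 0.05) {
  if (!"MO" %in% rownames(table))
    stop("grade table has no MO condition", call. = FALSE)
  grade_cols <- setdiff(colnames(table), "normal")
  frac <- rowSums(table[, grade_cols, drop = FALSE]) / rowSums(table)
  contrasts <- list()
  for (other in intersect(c("MO+WT", "MO+MT"), rownames(table))) {
    t2 <- collapse_grades(table, c("MO", other))
    p <- fisher_exact_two_tailed(t2)
    contrasts[[paste0("MO_vs_", sub("MO\\+", "", other))]] <-
      list(table = t2, p_value = p, significant = p < alpha)
  }
  structure(list(contrasts = contrasts, morphant_fraction = frac,
                 alpha = alpha),
            class = "rescue_report")
}

#' @exportS3Method base::print
print.rescue_report <- function(x, ...) {
  cat("<rescue_report> morphant fractions:\n")
  print(round(x$morphant_fraction, 3))
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("  %s: p = %.4g (%s at alpha = %g)\n", nm, ct$p_value,
                if (ct$significant) "significant" else "not significant",
                x$alpha))
  }
  invisible(x)
}

#' Summarise a cilia sample: incidence and length
#'
#' Ciliation incidence is the fraction of ciliated cells (as a percentage),
#' with a standard error computed across fields of view (the sampling unit
#' of the imaging). Cilium length is summarised as mean +/- SEM over
#' ciliated cells. An empty sample (or a condition with no ciliated cells)
#' yields a defined n = 0 / NA row rather than an error.
#'
#' @param sample A `cilia_sample` from [gen_cilia_measurements()].
#' @param condition Optional condition to restrict to; by default one
#'   summary row per condition present.
#' @return data.frame with columns `condition`, `n_cells`, `n_ciliated`,
#'   `incidence_pct`, `incidence_sem_pct`, `mean_length_um`,
#'   `sem_length_um`.
#' @export
cilia_summary <- function(sample, condition = NULL) {
  if (!is.null(condition)) sample <- sample[sample$condition %in% condition, ]
  conds <- unique(sample$condition)
  if (!length(conds))
    return(data.frame(condition = condition %||% NA_character_,
                      n_cells = 0L, n_ciliated = 0L,
                      incidence_pct = NA_real_, incidence_sem_pct = NA_real_,
                      mean_length_um = NA_real_, sem_length_um = NA_real_,
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(conds, function(cd) {
    s <- sample[sample$condition == cd, ]
    lens <- s$length_um[s$ciliated]
    by_field <- tapply(s$ciliated, s$field_id, mean)
    data.frame(condition = cd, n_cells = nrow(s),
               n_ciliated = sum(s$ciliated),
               incidence_pct = 100 * mean(s$ciliated),
               incidence_sem_pct = if (length(by_field) > 1L)
                 100 * sd(by_field) / sqrt(length(by_field)) else NA_real_,
               mean_length_um = if (length(lens)) mean(lens) else NA_real_,
               sem_length_um = if (length(lens) > 1L)
                 sd(lens) / sqrt(length(lens)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Two-sample comparison of cilium lengths
#'
#' Compares cilium lengths between two samples. The default is a Welch
#' unequal-variance t-test on log lengths (lengths are positive and
#' right-skewed, so the log scale is the natural one); a rank-based
#' alternative (Wilcoxon-Mann-Whitney, normal approximation without
#' continuity correction) is selectable. Two-sided in both modes.
#'
#' @param affected,unaffected `cilia_sample` data.frames (or numeric length
#'   vectors); each must contribute at least 2 lengths.
#' @param method `"welch"` (default) or `"rank"`.
#' @return List with `p_value`, `method`, `estimate` (mean lengths), `n`.
#' @export
cilia_length_test <- function(affected, unaffected,
                              method = c("welch", "rank")) {
  method <- match.arg(method)
  pull <- function(x) {
    if (is.data.frame(x)) x$length_um[x$ciliated] else as.numeric(x)
  }
  a <- pull(affected)
  u <- pull(unaffected)
  a <- a[!is.na(a)]
  u <- u[!is.na(u)]
  if (length(a) < 2L || length(u) < 2L)
    stop("each group needs at least 2 cilium lengths", call. = FALSE)
  p <- if (method == "welch") {
    t.test(log(a), log(u))$p.value
  } else {
    suppressWarnings(wilcox.test(a, u, exact = FALSE,
                                 correct = FALSE)$p.value)
  }
  list(p_value = p, method = method,
       estimate = c(mean_affected = mean(a), mean_unaffected = mean(u)),
       n = c(n_affected = length(a), n_unaffected = length(u)))
}
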