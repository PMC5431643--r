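#' Default grade-probability vectors for the rescue-assay generator
#'
#' Per-condition probabilities over the five phenotype grades (normal,
#' grade1..grade4) of the morphant severity scale. These vectors are
#' simulator fixtures, not measured values: they are chosen by a power
#' calculation so that at 100 embryos per condition the morpholino-alone
#' versus wild-type-rescue contrast reaches a two-tailed Fisher
#' p < 0.0001 with >= 90% power, while morpholino-alone versus
#' mutant-rescue stays non-significant (p > 0.05) with >= 80% probability —
#' the qualitative outcome of the rescue experiment they emulate (morphant
#' fractions 0.75, 0.35 and 0.70 for MO, MO+WT and MO+MT; see the methods
#' vignette for the calculation).
#'
#' @param conditions Conditions to include.
#' @param n_embryos Embryos injected per condition (recycled).
#' @return data.frame of class `grade_params` with a `condition` column,
#'   `n_embryos`, and probability columns `normal`, `grade1`..`grade4`.
#' @export
grade_params <- function(conditions = c("uninjected", "MO", "MO+WT",
                                        "MO+MT"),
                         n_embryos = 100L) {
  probs <- rbind(
    "uninjected" = c(0.96, 0.02, 0.01, 0.005, 0.005),
    "MO"         = c(0.25, 0.25, 0.20, 0.15, 0.15),
    "MO+WT"      = c(0.65, 0.12, 0.10, 0.07, 0.06),
    "MO+MT"      = c(0.30, 0.24, 0.20, 0.14, 0.12))
  colnames(probs) <- c("normal", "grade1", "grade2", "grade3", "grade4")
  unknown <- setdiff(conditions, rownames(probs))
  if (length(unknown))
    stop("no default grade probabilities for: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- data.frame(condition = conditions,
                    n_embryos = as.integer(rep_len(n_embryos,
                                                   length(conditions))),
                    probs[conditions, , drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("grade_params", "data.frame")
  validate_grade_params(out)
}

validate_grade_params <- function(p) {
  pr <- as.matrix(p[, c("normal", "grade1", "grade2", "grade3", "grade4")])
  if (any(pr < 0) || any(abs(rowSums(pr) - 1) > 1e-8))
    stop("grade probabilities must be non-negative and sum to 1",
         call. = FALSE)
  if (any(p$n_embryos < 0))
    stop("n_embryos must be non-negative", call. = FALSE)
  p
}

#' Simulate an embryo grade table
#'
#' One multinomial draw per injection condition over the five severity
#' grades. Row sums equal the number of embryos injected; a zero-embryo
#' condition yields an all-zero row.
#'
#' @param params A [grade_params()] data.frame.
#' @param seed Optional RNG seed.
#' @return A `grade_table`: integer matrix, rows = conditions, columns =
#'   `normal`, `grade1`..`grade4`.
#' @export
gen_embryo_grades <- function(params = grade_params(), seed = NULL) {
  params <- validate_grade_params(params)
  pr <- as.matrix(params[, c("normal", "grade1", "grade2", "grade3",
                             "grade4")])
  with_seed(seed, {
    tab <- t(vapply(seq_len(nrow(params)), function(i) {
      if (params$n_embryos[i] == 0L) return(integer(5L))
      as.integer(rmultinom(1L, params$n_embryos[i], pr[i, ]))
    }, integer(5L)))
    dimnames(tab) <- list(params$condition, colnames(pr))
    class(tab) <- c("grade_table", class(tab))
    tab
  })
}

#' Default cilia-measurement generator parameters
#'
#' Per-condition parameters of the cilium morphometry generator. Ciliation
#' incidence defaults follow the reported per-condition incidences (49%
#' affected, 45% unaffected). Cilium lengths are lognormal — lengths are
#' positive and right-skewed, with affected cilia ranging from very short
#' fragments to extremely long axonemes — with scale parameters
#' moment-matched so that the length mean and its standard error at n = 50
#' measured cilia reproduce the reported 15.1 +/- 1.8 um (affected) and
#' 8.3 +/- 1.0 um (unaffected): the implied length standard deviation is
#' SEM * sqrt(50).
#'
#' @param conditions Conditions to include.
#' @param n_cells Cells examined per condition (default 110, enough for
#'   ~50 ciliated cells at the default incidences).
#' @param n_fields Fields of view per condition (default 31); cells are
#'   assigned to fields round-robin.
#' @return data.frame of class `cilia_params` with columns `condition`,
#'   `n_cells`, `incidence`, `meanlog`, `sdlog`, `target_mean_um`,
#'   `n_fields`.
#' @export
cilia_params <- function(conditions = c("affected", "unaffected"),
                         n_cells = 110L, n_fields = 31L) {
  defaults <- data.frame(
    condition = c("affected", "unaffected"),
    incidence = c(0.49, 0.45),
    target_mean_um = c(15.1, 8.3),
    target_sd_um = c(1.8 * sqrt(50), 1.0 * sqrt(50)),
    stringsAsFactors = FALSE)
  unknown <- setdiff(conditions, defaults$condition)
  if (length(unknown))
    stop("no default cilia parameters for: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  d <- defaults[match(conditions, defaults$condition), ]
  scale <- lnorm_from_mean_sd(d$target_mean_um, d$target_sd_um)
  out <- data.frame(condition = d$condition,
                    n_cells = as.integer(rep_len(n_cells, nrow(d))),
                    incidence = d$incidence,
                    meanlog = scale$meanlog, sdlog = scale$sdlog,
                    target_mean_um = d$target_mean_um,
                    n_fields = as.integer(rep_len(n_fields, nrow(d))),
                    stringsAsFactors = FALSE)
  class(out) <- c("cilia_params", "data.frame")
  out
}

# lognormal scale parameters matching an arithmetic mean and SD
lnorm_from_mean_sd <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate per-cell cilium measurements
#'
#' For every cell: a Bernoulli(incidence) ciliated flag, and for ciliated
#' cells a lognormal cilium length; field-of-view labels are assigned
#' round-robin.
#'
#' @param params A [cilia_params()] data.frame.
#' @param seed Optional RNG seed.
#' @return A `cilia_sample` data.frame: `condition`, `cell_id`, `field_id`,
#'   `ciliated`, `length_um` (`NA` for unciliated cells).
#' @export
gen_cilia_measurements <- function(params = cilia_params(), seed = NULL) {
  stopifnot(inherits(params, "data.frame"),
            all(params$incidence >= 0 & params$incidence <= 1),
            all(params$sdlog > 0), all(params$n_cells >= 0))
  with_seed(seed, {
    out <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      n <- p$n_cells
      if (n == 0L) return(NULL)
      ciliated <- runif(n) < p$incidence
      len <- rep(NA_real_, n)
      len[ciliated] <- rlnorm(sum(ciliated), p$meanlog, p$sdlog)
      data.frame(condition = p$condition,
                 cell_id = sprintf("%s_cell%03d", p$condition, seq_len(n)),
                 field_id = rep_len(seq_len(p$n_fields), n),
                 ciliated = ciliated, length_um = len,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(condition = character(), cell_id = character(),
                        field_id = integer(), ciliated = logical(),
                        length_um = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("cilia_sample", "data.frame")
    out
  })
}
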