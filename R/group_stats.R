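# Two-group comparison of morphometry tables: Welch's unequal-variance
# two-tailed t-test, computable either from raw per-cell values or from
# summary statistics (mean, SD, n) alone.

#' Welch's t-test from summary statistics
#'
#' Two-tailed Welch (unequal-variance) t-test computed from group means,
#' standard deviations and sizes:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with the
#' Welch-Satterthwaite degrees of freedom. All arguments are vectorized.
#'
#' @param mean_a,sd_a,n_a summary statistics of group a (`n_a >= 2`).
#' @param mean_b,sd_b,n_b summary statistics of group b.
#' @return List with `t`, `df` and two-tailed `p` (vectors).
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (any(n_a < 2L) || any(n_b < 2L))
    stop("group sizes must be >= 2", call. = FALSE)
  if (any(sd_a < 0) || any(sd_b < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[mean_a == mean_b & sd_a == sd_b & n_a == n_b] <- 1
  list(t = t, df = df, p = p)
}

#' Compare two morphometry cohorts parameter by parameter
#'
#' For every shared numeric parameter column, computes group means and SDs
#' (sample SD over cells), the Welch two-tailed p-value, and a significance
#' flag at `p <= alpha`. No multiple-testing correction is applied.
#'
#' @param table_a,table_b data frames of per-cell parameters (e.g. from
#'   [morphometry_table()]); must share the same parameter columns.
#' @param alpha significance threshold (default 0.05, flagged at
#'   `p <= alpha`).
#' @param labels group labels for the output column names.
#' @return `data.frame` with one row per parameter: means, SDs, ns, `t`,
#'   `df`, `p`, `significant`.
#' @export
compare_groups <- function(table_a, table_b, alpha = 0.05,
                           labels = c("a", "b")) {
  if (nrow(table_a) == 0L || nrow(table_b) == 0L)
    stop("both tables must be non-empty", call. = FALSE)
  meta <- c("cell_id", "viability", "truncated")
  num_a <- setdiff(names(table_a)[vapply(table_a, is.numeric, logical(1))], meta)
  num_b <- setdiff(names(table_b)[vapply(table_b, is.numeric, logical(1))], meta)
  if (!setequal(num_a, num_b))
    stop("column mismatch between the two tables", call. = FALSE)
  cols <- num_a
  res <- lapply(cols, function(cl) {
    a <- table_a[[cl]]; b <- table_b[[cl]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(parameter = cl, mean_a = NA_real_, sd_a = NA_real_,
                        n_a = length(a), mean_b = NA_real_, sd_b = NA_real_,
                        n_b = length(b), t = NA_real_, df = NA_real_,
                        p = NA_real_, significant = NA))
    w <- welch_from_summary(mean(a), stats::sd(a), length(a),
                            mean(b), stats::sd(b), length(b))
    data.frame(parameter = cl, mean_a = mean(a), sd_a = stats::sd(a),
               n_a = length(a), mean_b = mean(b), sd_b = stats::sd(b),
               n_b = length(b), t = w$t, df = w$df, p = w$p,
               significant = w$p <= alpha)
  })
  out <- do.call(rbind, res)
  names(out) <- sub("_a$", paste0("_", labels[1]), names(out))
  names(out) <- sub("_b$", paste0("_", labels[2]), names(out))
  out
}

#' Reference cohort summary statistics
#'
#' Bundled summary table (mean, SD, n and two-tailed p per parameter) for a
#' reference cohort of 101 viable and 105 apoptotic doxorubicin-treated
#' MCF-7 cells, used to cross-check the Welch machinery and as the
#' generating distribution of [sample_morphometry_cohort()]. The
#' `consistent` column marks rows whose printed summary statistics and
#' p-value are mutually consistent under a t-test recomputation; the grid
#' perimeter row of the mitochondria block is internally inconsistent
#' (its summaries imply p of order 1e-17) and the mitochondrion-to-cell
#' volume ratio row is printed with too few significant digits to pin its p
#' down.
#'
#' @return `data.frame` with one row per parameter.
#' @export
reference_cohort_stats <- function() {
  path <- system.file("extdata", "mcf7_cohort_stats.csv", package = "voxmorph",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
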