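#' Pearson chi-square test on a 2x2 contingency table
#'
#' Computes the uncorrected Pearson statistic (no Yates continuity
#' correction) with expected counts from the row/column margins, df = 1.
#' The uncorrected form is the one whose values match classical reports of
#' 2x2 comparisons between species-level trait counts.
#'
#' @param table 2x2 numeric matrix, or a length-4 vector \code{c(a, b, c, d)}
#'   filled row-wise (rows = condition, columns = trait present/absent).
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
#' @examples
#' chi2_2x2(c(31, 499, 168, 308))  # intact transposase, maize vs rice
chi2_2x2 <- function(table) {
  m <- if (is.matrix(table)) table else matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (any(dim(m) != c(2, 2))) stop("need a 2x2 table")
  if (any(m < 0)) stop("negative counts")
  n <- sum(m)
  if (n <= 0) stop("empty table")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in 2x2 table")
  e <- outer(rs, cs) / n
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sample t-test
#'
#' Welch's t-test by default (unequal variances); Student's pooled-variance
#' variant with \code{equal_var = TRUE}.
#'
#' @param xs,ys numeric samples, each of length >= 2.
#' @param equal_var use the pooled-variance Student test.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
two_sample_t <- function(xs, ys, equal_var = FALSE) {
  if (length(xs) < 2 || length(ys) < 2) stop("each sample needs n >= 2")
  if (stats::var(xs) == 0 && stats::var(ys) == 0) {
    if (isTRUE(all.equal(mean(xs), mean(ys))))
      return(list(statistic = 0, df = length(xs) + length(ys) - 2L, p = 1))
    stop("zero variance in both samples")
  }
  r <- stats::t.test(xs, ys, var.equal = equal_var)
  list(statistic = unname(r$statistic), df = unname(r$parameter), p = r$p.value)
}

#' Nested-insertion fraction with redundant-copy correction
#'
#' Fraction (percent) of elements carrying nested insertions after removing
#' copies that descend from a single shared insertion event: such copies are
#' not independent observations, so they are subtracted from both the
#' with-insertion count and the total.
#'
#' @param n_with number of elements with nested insertions.
#' @param n_total total number of elements.
#' @param n_redundant number of elements that are redundant copies of one
#'   insertion event (subtracted from numerator and denominator).
#' @return percentage on 0-100 scale.
#' @export
corrected_nested_fraction <- function(n_with, n_total, n_redundant = 0) {
  if (n_redundant > n_with || n_redundant >= n_total) stop("invalid correction")
  (n_with - n_redundant) / (n_total - n_redundant) * 100
}

#' Assemble the pipeline's report tables
#'
#' Writes deterministic TSVs for whichever stage outputs are supplied:
#' element size profile, nested-insertion summary by class, insertion
#' preference, redundant and non-redundant defect-group counts, expression
#' summary, indel bins and LTR age bins. Every percentage in the reports is
#' recomputed from the adjacent counts.
#'
#' @param outputs named list of stage outputs; recognised names:
#'   \code{size_profile, nested_summary, insertion_preference,
#'   group_counts_redundant, group_counts_nonredundant, expression_summary,
#'   indel_bins, age_bins}.
#' @param dir output directory (created if needed).
#' @return invisibly, a manifest data.frame of written files.
#' @export
build_reports <- function(outputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("size_profile", "nested_summary", "insertion_preference",
             "group_counts_redundant", "group_counts_nonredundant",
             "expression_summary", "indel_bins", "age_bins")
  written <- character()
  for (nm in known) {
    if (is.null(outputs[[nm]])) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(outputs[[nm]], path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  manifest <- data.frame(table = basename(written), path = written,
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
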