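# Expression evidence: EST/flcDNA records matched against elements. An
# element has evidence when an EST matches at >= 99.5% identity over
# essentially the whole EST and the matched region is at least 300 bp.

#' Match EST/flcDNA records against elements
#'
#' Each EST is locally aligned to each element (after a shared-20-mer
#' prefilter). A hit provides expression evidence when its identity is at
#' least \code{min_identity}, the matched length is at least
#' \code{min_len} bp, and the match covers at least \code{min_coverage} of
#' the EST. An element's evidence is the disjunction over its hits; an EST
#' matching several elements credits each of them.
#'
#' @param elements named character vector of element sequences.
#' @param est_records named character vector of EST/flcDNA sequences.
#' @param min_identity identity threshold (default 0.995).
#' @param min_len minimum matched length in bp (default 300).
#' @param min_coverage minimum fraction of the EST covered (default 0.99).
#' @return data.frame \code{element_id, est_id, identity, matched_len,
#'   est_coverage, evidence}.
#' @export
match_expression <- function(elements, est_records, min_identity = 0.995,
                             min_len = 300L, min_coverage = 0.99) {
  rows <- list()
  k <- 20L
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (eid in names(est_records)) {
    est <- est_records[[eid]]
    if (nchar(est) < k) next
    probe <- substr(est, max(1L, nchar(est) %/% 2 - k %/% 2), nchar(est) %/% 2 + k %/% 2)
    for (mid in names(elements)) {
      el <- elements[[mid]]
      if (!grepl(probe, el, fixed = TRUE) &&
          !grepl(probe, revcomp(el), fixed = TRUE)) next
      best <- NULL
      for (target in c(el, revcomp(el))) {
        al <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(est), Biostrings::DNAString(target),
          type = "local", substitutionMatrix = submat,
          gapOpening = 8, gapExtension = 1)
        if (is.null(best) || Biostrings::score(al) > Biostrings::score(best)) best <- al
      }
      a <- seq_chars(as.character(Biostrings::alignedPattern(best)))
      b <- seq_chars(as.character(Biostrings::alignedSubject(best)))
      both <- a != "-" & b != "-"
      if (!any(both)) next
      identity <- mean(a[both] == b[both])
      matched_len <- sum(both)
      coverage <- matched_len / nchar(est)
      rows[[length(rows) + 1L]] <- data.frame(
        element_id = mid, est_id = eid, identity = identity,
        matched_len = matched_len, est_coverage = coverage,
        evidence = identity >= min_identity && matched_len >= min_len &&
          coverage >= min_coverage,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(element_id = character(), est_id = character(),
                      identity = numeric(), matched_len = integer(),
                      est_coverage = numeric(), evidence = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summarize expression evidence by transposase status
#'
#' Cross-tabulates elements with/without expression evidence against
#' intact/defective transposase, with percentages recomputed from the
#' counts.
#'
#' @param hits hit table from [match_expression()].
#' @param intact named logical vector: element id -> intact transposase.
#' @return data.frame with one row per transposase status.
#' @export
expression_summary <- function(hits, intact) {
  expressed_ids <- unique(hits$element_id[hits$evidence])
  ids <- names(intact)
  expressed <- ids %in% expressed_ids
  out <- lapply(c(TRUE, FALSE), function(st) {
    sel <- intact == st
    n <- sum(sel); ne <- sum(sel & expressed)
    data.frame(transposase = if (st) "intact" else "defective",
               with_evidence = ne, without_evidence = n - ne, total = n,
               pct_with = if (n) round(100 * ne / n, 2) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
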