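LTR_SUBSTITUTION_RATE <- 1.3e-8  # substitutions / site / year

#' Divergence between the two LTRs of a retroelement
#'
#' The two long terminal repeats of an LTR retroelement are identical at
#' insertion and diverge afterwards, so their distance dates the insertion.
#' Sequences are globally aligned; gap columns are excluded; the distance is
#' corrected with the chosen substitution model. K2P is the default, with
#' p-distance and JC69 available.
#'
#' @param ltr5,ltr3 the two LTR sequences (>= 50 bp each).
#' @param model one of \code{"K2P"}, \code{"JC69"}, \code{"p_distance"}.
#' @return substitutions per site (numeric).
#' @export
ltr_divergence <- function(ltr5, ltr3, model = c("K2P", "JC69", "p_distance")) {
  model <- match.arg(model)
  if (nchar(ltr5) < 50 || nchar(ltr3) < 50) stop("LTR sequences must be >= 50 bp")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ltr5), Biostrings::DNAString(ltr3), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2),
    gapOpening = 8, gapExtension = 1)
  a <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  b <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  keep <- a != "-" & b != "-" & a != "N" & b != "N"
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) stop("no aligned columns")
  diffs <- a != b
  p_raw <- mean(diffs)
  if (1 - p_raw < 0.5) stop("alignment identity below 50%: not a genuine LTR pair")
  purine <- c("A", "G")
  is_ts <- diffs & ((a %in% purine) == (b %in% purine))  # transition: purine<->purine or pyr<->pyr
  P <- mean(is_ts)           # transition proportion
  Q <- p_raw - P             # transversion proportion
  d <- switch(model,
    p_distance = p_raw,
    JC69 = {
      if (p_raw >= 0.75) stop("p-distance too large for JC69 correction")
      -3 / 4 * log(1 - 4 / 3 * p_raw)
    },
    K2P = {
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0) stop("distance too large for K2P correction")
      0.5 * log(1 / w1) + 0.25 * log(1 / w2)
    })
  unname(d)
}

#' Convert an LTR-LTR divergence to an insertion age
#'
#' Each LTR accumulates substitutions independently after insertion, so the
#' divergence between them is twice the per-lineage change:
#' \eqn{T = d / (2r)}, with \eqn{r = 1.3\times10^{-8}} substitutions per
#' site per year.
#'
#' @param d substitutions per site between the two LTRs.
#' @param rate substitution rate per site per year.
#' @return age in million years.
#' @export
#' @examples
#' estimate_age(0.026)  # 1 Myr
estimate_age <- function(d, rate = LTR_SUBSTITUTION_RATE) {
  if (any(d < 0)) stop("divergence must be >= 0")
  d / (2 * rate) / 1e6
}

#' Bin LTR insertion ages
#'
#' @param ages numeric vector of ages in Myr.
#' @param breaks bin boundaries in Myr; the last bin is open-ended.
#' @return data.frame with \code{bin, count, fraction}.
#' @export
age_histogram <- function(ages, breaks = c(0, 1, 2, 3)) {
  labs <- c(paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")"),
            paste0("[", breaks[length(breaks)], ",Inf)"))
  idx <- findInterval(ages, breaks)
  idx[idx == 0] <- 1L
  counts <- tabulate(idx, nbins = length(labs))
  data.frame(bin = labs, count = counts,
             fraction = if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, length(labs)),
             stringsAsFactors = FALSE)
}

#' Date every intact nested LTR retroelement of a simulated or called set
#'
#' @param ltr_pairs list of two-element character vectors (5' and 3' LTR) or
#'   a data.frame with columns \code{ltr5, ltr3} and optionally \code{id}.
#' @param model substitution model passed to [ltr_divergence()].
#' @param rate substitution rate per site per year.
#' @return data.frame \code{id, d, model, age_myr}.
#' @export
date_ltr_insertions <- function(ltr_pairs, model = "K2P", rate = LTR_SUBSTITUTION_RATE) {
  if (is.data.frame(ltr_pairs)) {
    ids <- if ("id" %in% names(ltr_pairs)) ltr_pairs$id else seq_len(nrow(ltr_pairs))
    pairs <- Map(c, ltr_pairs$ltr5, ltr_pairs$ltr3)
  } else {
    ids <- names(ltr_pairs) %||% seq_along(ltr_pairs)
    pairs <- ltr_pairs
  }
  d <- vapply(pairs, function(p) ltr_divergence(p[1], p[2], model = model), 0)
  data.frame(id = as.character(ids), d = d, model = model,
             age_myr = estimate_age(d, rate), row.names = NULL, stringsAsFactors = FALSE)
}
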