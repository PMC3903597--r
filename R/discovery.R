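# Candidate coding-MULE discovery: a transposase homology hit must lie
# between a pair of terminal inverted repeats (>75% identity, inverted
# orientation, 2-30 kb apart) immediately flanked by a valid 8-11 bp target
# site duplication.

MIN_SPAN <- 2000L
MAX_SPAN <- 30000L

# Global identity of left TIR candidate vs revcomp(right TIR candidate):
# matches / alignment columns, terminal gap runs excluded. The global
# alignment is deliberate — an ends-free alignment would let a short
# spurious exact match masquerade as a high-identity TIR pair.
tir_pair_identity <- function(left, right_rc) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(left), Biostrings::DNAString(right_rc),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2),
    gapOpening = 8, gapExtension = 1)
  a <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  b <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  gap_run <- a == "-" | b == "-"
  inner <- which(!gap_run)
  if (length(inner) == 0) return(0)
  idx <- inner[1]:inner[length(inner)]
  mean(a[idx] == b[idx])
}

# Extend an inverted-repeat candidate outward (and inward) base by base:
# position ls-1 must pair with the complement of position re+1. Extension
# stops after `max_mm_run` consecutive non-complementary pairs and backs up
# to the last complementary one.
extend_inverted <- function(seq, ls, le, rs, re, max_ext = 60L, max_mm_run = 3L) {
  n <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  step_out <- function(ls, re) {
    mm <- 0L; ext <- 0L; bls <- ls; bre <- re
    while (ext < max_ext && ls > 1L && re < n) {
      a <- substr(seq, ls - 1L, ls - 1L)
      b <- substr(seq, re + 1L, re + 1L)
      ls <- ls - 1L; re <- re + 1L; ext <- ext + 1L
      if (identical(unname(comp[a]), b)) {
        mm <- 0L; bls <- ls; bre <- re
      } else {
        mm <- mm + 1L
        if (mm >= max_mm_run) break
      }
    }
    c(bls, bre)
  }
  step_in <- function(le, rs) {
    mm <- 0L; ext <- 0L; ble <- le; brs <- rs
    while (ext < max_ext && le + 1L < rs - 1L) {
      a <- substr(seq, le + 1L, le + 1L)
      b <- substr(seq, rs - 1L, rs - 1L)
      le <- le + 1L; rs <- rs - 1L; ext <- ext + 1L
      if (identical(unname(comp[a]), b)) {
        mm <- 0L; ble <- le; brs <- rs
      } else {
        mm <- mm + 1L
        if (mm >= max_mm_run) break
      }
    }
    c(ble, brs)
  }
  o <- step_out(ls, re); i <- step_in(le, rs)
  c(ls = o[1], le = i[1], rs = i[2], re = o[2])
}

#' Find terminal-inverted-repeat pairs in a sequence window
#'
#' Searches a window (typically a transposase hit plus flanking sequence)
#' for sequence pairs in inverted orientation, TIR-ends facing outwards,
#' whose global-alignment identity exceeds \code{min_identity} and whose
#' outer span is 2-30 kb. Candidate pairs are seeded with exact 12-mer
#' matches between the window and its reverse complement (an inverted
#' repeat keeps \code{left_pos + right_pos} constant), clustered on that
#' anti-diagonal, and validated by alignment.
#'
#' @param seq window sequence.
#' @param tir_len_range allowed TIR lengths (default 50-800 bp, a superset
#'   of the canonical 100-500 bp so boundary cases are not missed).
#' @param min_identity minimum TIR pairwise identity (default 0.75,
#'   exclusive).
#' @param span_range allowed distance from left TIR start to right TIR end.
#' @return data.frame with \code{left_start, left_end, right_start,
#'   right_end, identity} (window coordinates), ordered by identity.
#' @export
find_tir_pairs <- function(seq, tir_len_range = c(50L, 800L),
                           min_identity = 0.75,
                           span_range = c(MIN_SPAN, MAX_SPAN)) {
  empty <- data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      identity = numeric())
  n <- nchar(seq)
  k <- 12L
  if (n < span_range[1]) return(empty)
  rc <- revcomp(seq)
  pos <- seq_len(n - k + 1L)
  fk <- substring(seq, pos, pos + k - 1L)
  rk <- substring(rc, pos, pos + k - 1L)
  rmap <- split(pos, rk)
  keep <- fk %in% names(rmap)
  if (!any(keep)) return(empty)
  fp <- pos[keep]
  rl <- rmap[fk[keep]]
  reps <- lengths(rl)
  i <- rep(fp, reps)                      # left TIR position (forward)
  p <- unlist(rl, use.names = FALSE)      # position in reverse complement
  j <- n - p - k + 2L                     # right TIR start (forward coords)
  seeds <- data.frame(i = i, j_end = j + k - 1L)
  seeds$anti <- seeds$i + seeds$j_end     # constant along an inverted repeat
  span <- seeds$j_end - seeds$i + 1L
  seeds <- seeds[span >= span_range[1] - 2L * tir_len_range[2] &
                 span <= span_range[2] & seeds$i < seeds$j_end, ]
  if (nrow(seeds) == 0) return(empty)
  seeds <- seeds[order(seeds$anti, seeds$i), ]
  grp <- cumsum(c(1L, diff(seeds$anti) > 30L))
  out <- list()
  for (g in split(seeds, grp)) {
    g <- g[order(g$i), ]
    sub <- cumsum(c(1L, diff(g$i) > 100L))
    for (h in split(g, sub)) {
      if (nrow(h) < 3L) next                  # genuine TIRs seed densely
      ls <- min(h$i); le <- max(h$i) + k - 1L
      re <- max(h$j_end); rs <- re - (le - ls)
      if (le - ls + 1L < 25L) next
      ext <- extend_inverted(seq, ls, le, rs, re)
      ls <- ext["ls"]; le <- ext["le"]; rs <- ext["rs"]; re <- ext["re"]
      tl <- le - ls + 1L
      if (tl < tir_len_range[1] || tl > tir_len_range[2]) next
      span <- re - ls + 1L
      if (span < span_range[1] || span > span_range[2]) next
      if (le >= rs) next
      ident <- tir_pair_identity(substr(seq, ls, le),
                                 revcomp(substr(seq, rs, re)))
      if (ident > min_identity)
        out[[length(out) + 1L]] <- data.frame(
          left_start = as.integer(ls), left_end = as.integer(le),
          right_start = as.integer(rs), right_end = as.integer(re),
          identity = ident)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$identity), ]
  # drop near-duplicate pairs (same repeat found from overlapping seed runs)
  kept <- rep(TRUE, nrow(res))
  for (a in seq_len(nrow(res))[-1]) {
    for (b in which(kept[seq_len(a - 1L)])) {
      if (interval_overlap(res$left_start[a], res$left_end[a],
                           res$left_start[b], res$left_end[b]) > 0 &&
          interval_overlap(res$right_start[a], res$right_end[a],
                           res$right_start[b], res$right_end[b]) > 0) {
        kept[a] <- FALSE; break
      }
    }
  }
  res[kept, , drop = FALSE]
}

# Search for a valid TSD around estimated element boundaries: seed-based
# TIR ends are approximate and the TSD must sit immediately at the true
# termini. Because the inverted-repeat extension moves both boundaries
# symmetrically, its error is symmetric too, so a wide symmetric offset
# scan (dl, -dl) is combined with a small independent jitter grid.
# Returns the best placement (most matching copy bases, then smallest
# offset) or NULL.
find_flanking_tsd <- function(seq, left_start, right_end, jitter = 6L,
                              sym_jitter = 25L, tsd_len_range = c(8L, 11L)) {
  n <- nchar(seq)
  best <- NULL
  offsets <- unique(rbind(
    data.frame(dl = -sym_jitter:sym_jitter, dr = -(-sym_jitter:sym_jitter)),
    expand.grid(dl = -jitter:jitter, dr = -jitter:jitter)))
  for (o in seq_len(nrow(offsets))) {
    dl <- offsets$dl[o]; dr <- offsets$dr[o]
    ls <- left_start + dl; re <- right_end + dr
    if (ls < tsd_len_range[2] + 1L || re + tsd_len_range[2] > n) next
    for (tl in tsd_len_range[2]:tsd_len_range[1]) {
      tsd <- validate_tsd(substr(seq, ls - tl, ls - 1L),
                          substr(seq, re + 1L, re + tl))
      if (!tsd$valid) next
      key <- c(tsd$length - tsd$mismatches - tsd$indels, -abs(dl) - abs(dr))
      if (is.null(best) || key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2])) {
        best <- list(tsd = tsd, left_start = ls, right_end = re,
                     tsd_len = tl, key = key)
      }
    }
  }
  best
}

#' Call candidate coding-MULEs from transposase hits
#'
#' For each homology locus, searches the surrounding window for a TIR pair
#' spanning 2-30 kb with the hit between the TIRs, then requires a valid
#' TSD immediately flanking the TIRs. When several TIR pairs explain a hit,
#' the one with a valid TSD wins, then higher TIR identity, then smaller
#' span. Each genomic span is reported once.
#'
#' @param genome named character vector of sequences.
#' @param hits hit table from [translated_homology_scan()].
#' @param window flanking sequence retrieved around each hit locus (bp).
#' @param tir_len_range,min_identity passed to [find_tir_pairs()].
#' @return data.frame of calls: \code{id, seq_id, start, end, strand,
#'   tir_left_start, tir_left_end, tir_right_start, tir_right_end,
#'   tir_identity, tsd_left, tsd_right, tsd_len, tsd_mismatches,
#'   tsd_indels, hit_score}.
#' @export
call_candidate_elements <- function(genome, hits, window = 50000L,
                                    tir_len_range = c(50L, 800L),
                                    min_identity = 0.75) {
  calls <- list()
  for (locus in hit_loci(hits)) {
    sid <- locus$seq_id[1]
    gseq <- genome[[sid]]
    n <- nchar(gseq)
    h1 <- min(locus$start); h2 <- max(locus$end)
    w1 <- max(1L, h1 - window); w2 <- min(n, h2 + window)
    wseq <- substr(gseq, w1, w2)
    pairs <- find_tir_pairs(wseq, tir_len_range = tir_len_range,
                            min_identity = min_identity)
    if (nrow(pairs) == 0) next
    # hit must lie between the TIRs
    hl1 <- h1 - w1 + 1L; hl2 <- h2 - w1 + 1L
    pairs <- pairs[pairs$left_end < hl1 & pairs$right_start > hl2, , drop = FALSE]
    if (nrow(pairs) == 0) next
    cand <- list()
    for (r in seq_len(nrow(pairs))) {
      tsd <- find_flanking_tsd(wseq, pairs$left_start[r], pairs$right_end[r])
      cand[[r]] <- list(pair = pairs[r, ], tsd = tsd)
    }
    has_tsd <- vapply(cand, function(x) !is.null(x$tsd), TRUE)
    if (!any(has_tsd)) next
    cand <- cand[has_tsd]
    ident <- vapply(cand, function(x) x$pair$identity, 0)
    spans <- vapply(cand, function(x) as.numeric(x$tsd$right_end - x$tsd$left_start + 1L), 0)
    best <- cand[[order(-ident, spans)[1]]]
    ls <- best$tsd$left_start; re <- best$tsd$right_end
    span <- re - ls + 1L
    if (span < MIN_SPAN || span > MAX_SPAN) next
    calls[[length(calls) + 1L]] <- data.frame(
      id = NA_character_, seq_id = sid,
      start = w1 + ls - 1L, end = w1 + re - 1L,
      strand = locus$strand[which.max(locus$score)],
      tir_left_start = w1 + ls - 1L,
      tir_left_end = w1 + best$pair$left_end - 1L +
        (ls - best$pair$left_start),
      tir_right_start = w1 + best$pair$right_start - 1L +
        (re - best$pair$right_end),
      tir_right_end = w1 + re - 1L,
      tir_identity = best$pair$identity,
      tsd_left = best$tsd$tsd$left_seq, tsd_right = best$tsd$tsd$right_seq,
      tsd_len = best$tsd$tsd$length,
      tsd_mismatches = best$tsd$tsd$mismatches,
      tsd_indels = best$tsd$tsd$indels,
      hit_score = max(locus$score), stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(id = character(), seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      tir_left_start = integer(), tir_left_end = integer(),
                      tir_right_start = integer(), tir_right_end = integer(),
                      tir_identity = numeric(), tsd_left = character(),
                      tsd_right = character(), tsd_len = integer(),
                      tsd_mismatches = integer(), tsd_indels = integer(),
                      hit_score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, calls)
  res <- res[!duplicated(res[, c("seq_id", "start", "end")]), , drop = FALSE]
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  res$id <- sprintf("CM%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

# Identity/coverage of two sequences from an ends-free alignment.
pair_identity_coverage <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2),
    gapOpening = 8, gapExtension = 1)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  pb <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  both <- pa != "-" & pb != "-"
  inner <- which(both)
  if (!length(inner)) return(c(identity = 0, coverage = 0))
  idx <- inner[1]:inner[length(inner)]
  c(identity = mean(pa[idx] == pb[idx]),
    coverage = sum(both) / min(nchar(a), nchar(b)))
}

#' Choose representative elements by identity/coverage clustering
#'
#' Greedy clustering: elements sharing at least \code{id_thresh} identity
#' over at least \code{cov_thresh} of the element region join an existing
#' cluster; the representative is the longest member (ties broken by
#' lexicographically smallest id).
#'
#' @param elements named character vector of element sequences.
#' @param id_thresh,cov_thresh clustering thresholds (default 0.80/0.80).
#' @return character vector of representative element ids.
#' @export
cluster_representatives <- function(elements, id_thresh = 0.80, cov_thresh = 0.80) {
  stopifnot(length(elements) >= 1, !is.null(names(elements)))
  ord <- order(-nchar(elements), names(elements))
  reps <- character()
  for (i in ord) {
    id <- names(elements)[i]
    placed <- FALSE
    for (r in reps) {
      ic <- pair_identity_coverage(elements[[id]], elements[[r]])
      if (ic["identity"] >= id_thresh && ic["coverage"] >= cov_thresh) {
        placed <- TRUE; break
      }
    }
    if (!placed) reps <- c(reps, id)
  }
  sort(reps)
}

#' Element size profile after nested-TE removal
#'
#' Bins stripped element lengths into [2, 3.5), [3.5, 8) and [8, 30] kb.
#' Elements under 2 kb after stripping are kept in the first bin with a
#' warning; most genuine coding-MULEs fall between 2 and 10 kb.
#'
#' @param lengths stripped element lengths in bp.
#' @return data.frame \code{bin, count, fraction}.
#' @export
size_profile <- function(lengths) {
  if (any(lengths < 2000))
    warning(sum(lengths < 2000), " element(s) under 2 kb after stripping; binned into 2-3.5 kb")
  bins <- cut(pmax(lengths, 2000), breaks = c(2000, 3500, 8000, 30000),
              labels = c("2-3.5kb", "3.5-8kb", ">8kb"),
              include.lowest = TRUE, right = FALSE)
  counts <- table(bins)
  data.frame(bin = names(counts), count = as.integer(counts),
             fraction = if (length(lengths)) as.integer(counts) / length(lengths)
                        else rep(NA_real_, 3),
             stringsAsFactors = FALSE)
}
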