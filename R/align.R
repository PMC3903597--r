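# Translated homology machinery: a word-seeded, locally-extended search of
# protein queries against the six reading frames of a nucleotide sequence.
# Seeds are exact amino-acid 4-mers shared between a frame translation and
# the query; seeds on nearby diagonals are clustered and each cluster is
# refined with a local BLOSUM62 affine-gap alignment. Coding-region
# interruptions leave their signature here: a deletion shifts the alignment
# diagonal (new cluster), a frameshift moves the signal to another frame,
# and a premature stop appears as a '*' inside a block.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Seed clusters for one translation vs one query. Clusters with fewer than
# `min_seeds` word matches are discarded: genuine homology produces dozens
# of seeds while isolated random word matches produce one or two.
seed_clusters <- function(trans, query, word = 4L, diag_tol = 3L, gap_tol = 40L,
                          min_seeds = 3L) {
  nt <- nchar(trans); nq <- nchar(query)
  if (nt < word || nq < word) return(list())
  tpos <- seq_len(nt - word + 1L)
  qpos <- seq_len(nq - word + 1L)
  tk <- substring(trans, tpos, tpos + word - 1L)
  qk <- substring(query, qpos, qpos + word - 1L)
  qmap <- split(qpos, qk)
  keep <- tk %in% names(qmap)
  if (!any(keep)) return(list())
  tp <- tpos[keep]
  ql <- qmap[tk[keep]]
  reps <- lengths(ql)
  seeds <- data.frame(t = rep(tp, reps), q = unlist(ql, use.names = FALSE))
  seeds$diag <- seeds$t - seeds$q
  seeds <- seeds[order(seeds$diag, seeds$t), ]
  # split on diagonal jumps, then on positional gaps within a diagonal band
  dgrp <- cumsum(c(1L, diff(seeds$diag) > diag_tol))
  out <- list()
  for (g in split(seeds, dgrp)) {
    g <- g[order(g$t), ]
    sub <- cumsum(c(1L, diff(g$t) > gap_tol))
    for (h in split(g, sub)) if (nrow(h) >= min_seeds) out[[length(out) + 1L]] <- h
  }
  out
}

# Align one cluster region locally against the query; returns a block row
# plus the aligned strings, or NULL when below min_score.
extend_cluster <- function(cl, trans, query, word = 4L, pad = 8L, min_score = 80) {
  t1 <- max(1L, min(cl$t) - pad)
  t2 <- min(nchar(trans), max(cl$t) + word - 1L + pad)
  pep <- substr(trans, t1, t2)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pep), Biostrings::AAString(query), type = "local",
    substitutionMatrix = blosum62, gapOpening = 11, gapExtension = 1)
  sc <- Biostrings::score(al)
  if (sc < min_score) return(NULL)
  pr <- Biostrings::pattern(al); sr <- Biostrings::subject(al)
  list(t_start = t1 + BiocGenerics::start(pr) - 1L,
       t_end = t1 + BiocGenerics::end(pr) - 1L,
       q_start = BiocGenerics::start(sr), q_end = BiocGenerics::end(sr),
       score = sc,
       pat = as.character(Biostrings::alignedPattern(al)),
       sub = as.character(Biostrings::alignedSubject(al)))
}

# All alignment blocks of `query` against the three forward frames of `dna`.
# Frames are 1..3 (frame f starts at nt f). Coordinates are nt positions in
# `dna` and aa positions in `query`.
frame_blocks <- function(dna, query, min_score = 80, word = 4L) {
  blocks <- list()
  for (f in 1:3) {
    trans <- translate_dna(substr(dna, f, nchar(dna)))
    if (nchar(trans) < word) next
    for (cl in seed_clusters(trans, query, word = word)) {
      b <- extend_cluster(cl, trans, query, word = word, min_score = min_score)
      if (is.null(b)) next
      b$frame <- f
      b$nt_start <- f + 3L * (b$t_start - 1L)
      b$nt_end <- f + 3L * b$t_end - 1L
      blocks[[length(blocks) + 1L]] <- b
    }
  }
  # drop duplicates / contained repeats of the same region, best score first
  if (length(blocks) > 1) {
    ord <- order(-vapply(blocks, `[[`, 0, "score"))
    blocks <- blocks[ord]
    kept <- list()
    for (b in blocks) {
      dup <- any(vapply(kept, function(k) {
        k$frame == b$frame &&
          interval_overlap(k$nt_start, k$nt_end, b$nt_start, b$nt_end) >
            0.5 * (b$nt_end - b$nt_start + 1L)
      }, TRUE))
      if (!dup) kept[[length(kept) + 1L]] <- b
    }
    blocks <- kept
  }
  blocks[order(vapply(blocks, `[[`, 0L, "q_start"))]
}

# Column-wise map of one block: query position, translation position and the
# two residues, for columns where at least one side is a residue.
block_columns <- function(b) {
  p <- seq_chars(b$pat); s <- seq_chars(b$sub)
  tp <- cumsum(p != "-") + b$t_start - 1L
  qp <- cumsum(s != "-") + b$q_start - 1L
  data.frame(q = ifelse(s == "-", NA_integer_, qp),
             t = ifelse(p == "-", NA_integer_, tp),
             pat = p, sub = s, stringsAsFactors = FALSE)
}

#' Six-frame translated homology scan
#'
#' Scans genome sequences for segments whose translation aligns locally to
#' any of the query proteins (BLOSUM62, affine gaps), on both strands.
#' Overlapping same-frame blocks are merged by keeping the best-scoring one.
#' The raw-score threshold replaces a database-size-dependent e-value; the
#' default of 80 admits no hits on i.i.d. background sequence in practice
#' while degenerate transposase fragments score in the hundreds.
#'
#' @param genome named character vector of nucleotide sequences.
#' @param proteins named character vector of protein queries.
#' @param min_score minimum local alignment raw score.
#' @return data.frame with columns \code{seq_id, start, end, strand, frame,
#'   score, query_id, q_start, q_end} (nt coordinates on the forward
#'   strand, 1-based inclusive).
#' @export
translated_homology_scan <- function(genome, proteins, min_score = 80) {
  rows <- list()
  for (sid in names(genome)) {
    dna <- genome[[sid]]
    L <- nchar(dna)
    for (qid in names(proteins)) {
      for (strand in c("+", "-")) {
        s <- if (strand == "+") dna else revcomp(dna)
        for (b in frame_blocks(s, proteins[[qid]], min_score = min_score)) {
          if (strand == "+") {
            st <- b$nt_start; en <- b$nt_end
          } else {
            st <- L - b$nt_end + 1L; en <- L - b$nt_start + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = sid, start = st, end = en, strand = strand,
            frame = b$frame, score = b$score, query_id = qid,
            q_start = b$q_start, q_end = b$q_end, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), frame = integer(), score = numeric(),
                      query_id = character(), q_start = integer(),
                      q_end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Group scan hits into loci: hits on one sequence within `gap` bp of each
# other belong to one candidate locus (a single element's blocks). The gap
# is kept small so close neighbouring elements stay separate; blocks of one
# element split further apart than this produce duplicate calls of the same
# span, which the caller deduplicates.
hit_loci <- function(hits, gap = 1500L) {
  if (nrow(hits) == 0) return(list())
  out <- list()
  for (sid in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == sid, ]
    h <- h[order(h$start), ]
    grp <- cumsum(c(1L, h$start[-1] > cummax(h$end)[-nrow(h)] + gap))
    for (g in split(h, grp)) out[[length(out) + 1L]] <- g
  }
  out
}
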