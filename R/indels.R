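# Indel accumulation between homologous elements: best-homolog pairing,
# affine-gap global alignment with gap-run indel counting, NIK/LIK
# normalization, NG86 synonymous substitution rates and identity/Ks binning.

#' Count indels between two homologous sequences
#'
#' Global affine-gap alignment (match +1, mismatch -2, gap open 8, gap
#' extend 1). One maximal gap run counts as one indel regardless of its
#' length; terminal gap runs are excluded; identity is matches over non-gap
#' aligned columns. All statistics are symmetric in the two inputs.
#'
#' @param seq_a,seq_b nucleotide sequences (>= 200 bp each).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with \code{n_indels, indel_len_total, identity,
#'   aligned_cols} (columns after terminal-gap trimming).
#' @export
align_count_indels <- function(seq_a, seq_b, match = 1, mismatch = -2,
                               gap_open = 8, gap_extend = 1) {
  if (nchar(seq_a) < 200 || nchar(seq_b) < 200) stop("sequences must be >= 200 bp")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                                  mismatch = mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  b <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  both <- which(a != "-" & b != "-")
  if (!length(both)) stop("no aligned columns")
  idx <- both[1]:both[length(both)]           # trim terminal gap runs
  a <- a[idx]; b <- b[idx]
  gap <- a == "-" | b == "-"
  runs <- rle(gap)
  n_indels <- sum(runs$values)
  list(n_indels = as.integer(n_indels),
       indel_len_total = as.integer(sum(runs$lengths[runs$values])),
       identity = mean(a[!gap] == b[!gap]),
       aligned_cols = length(idx))
}

#' Normalize indel counts per kb of element sequence
#'
#' NIK is the number of indels divided by the summed length of the two
#' elements in kb; LIK is the total indel length on the same denominator,
#' making counts comparable across element sets.
#'
#' @param n_indels indel count.
#' @param indel_len_total summed indel length (bp).
#' @param len_a,len_b the two element lengths (bp).
#' @return list with \code{NIK} and \code{LIK}.
#' @export
compute_nik_lik <- function(n_indels, indel_len_total, len_a, len_b) {
  tot <- len_a + len_b
  if (tot <= 0) stop("zero total length")
  list(NIK = n_indels * 1000 / tot, LIK = indel_len_total * 1000 / tot)
}

#' Pair each element with its best homolog
#'
#' For each element, the partner producing the longest pairwise alignment
#' is retained (ties broken by higher identity, then smaller id); the
#' self-match is excluded, each unordered pair is kept once, and only pairs
#' above \code{min_identity} enter the indel statistics. Elements should be
#' stripped of nested insertions (and one TSD copy) before pairing.
#'
#' @param elements named character vector of element sequences (>= 2).
#' @param min_identity identity cutoff for retaining a pair (default 0.95,
#'   exclusive).
#' @return data.frame of pair statistics: \code{id_a, id_b, aligned_cols,
#'   identity, n_indels, indel_len_total, len_a, len_b, NIK, LIK}.
#' @export
best_homolog_pairs <- function(elements, min_identity = 0.95) {
  ids <- names(elements)
  n <- length(elements)
  if (n < 2) stop("need at least two elements")
  stats_cache <- list()
  key <- function(i, j) paste(sort(c(i, j)), collapse = "|")
  get_stats <- function(i, j) {
    k <- key(ids[i], ids[j])
    if (is.null(stats_cache[[k]]))
      stats_cache[[k]] <<- align_count_indels(elements[[i]], elements[[j]])
    stats_cache[[k]]
  }
  partner <- integer(n)
  for (i in seq_len(n)) {
    best <- 0L; best_len <- -1; best_id <- -1
    for (j in seq_len(n)) {
      if (j == i) next
      st <- get_stats(i, j)
      if (st$aligned_cols > best_len ||
          (st$aligned_cols == best_len && st$identity > best_id) ||
          (st$aligned_cols == best_len && st$identity == best_id &&
           ids[j] < ids[best])) {
        best <- j; best_len <- st$aligned_cols; best_id <- st$identity
      }
    }
    partner[i] <- best
  }
  seen <- character()
  rows <- list()
  for (i in seq_len(n)) {
    j <- partner[i]
    k <- key(ids[i], ids[j])
    if (k %in% seen) next
    seen <- c(seen, k)
    st <- get_stats(i, j)
    if (st$identity <= min_identity) next
    nl <- compute_nik_lik(st$n_indels, st$indel_len_total,
                          nchar(elements[[i]]), nchar(elements[[j]]))
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = min(ids[i], ids[j]), id_b = max(ids[i], ids[j]),
      aligned_cols = st$aligned_cols, identity = st$identity,
      n_indels = st$n_indels, indel_len_total = st$indel_len_total,
      len_a = nchar(elements[[i]]), len_b = nchar(elements[[j]]),
      NIK = nl$NIK, LIK = nl$LIK, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(id_a = character(), id_b = character(),
                      aligned_cols = integer(), identity = numeric(),
                      n_indels = integer(), indel_len_total = integer(),
                      len_a = integer(), len_b = integer(), NIK = numeric(),
                      LIK = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# --- NG86 synonymous substitution rate ------------------------------------

# Fraction of synonymous single-nucleotide changes at each position of a
# codon (stop-codon targets excluded from the denominator).
ng86_codon_sites <- local({
  gc <- Biostrings::GENETIC_CODE
  syn_frac <- function(codon) {
    aa <- gc[[codon]]
    vapply(1:3, function(pos) {
      from <- substr(codon, pos, pos)
      alts <- setdiff(c("A", "C", "G", "T"), from)
      tot <- 0; syn <- 0
      for (b in alts) {
        mut <- codon
        substr(mut, pos, pos) <- b
        if (gc[[mut]] == "*") next     # changes to stop codons are ignored
        tot <- tot + 1
        if (gc[[mut]] == aa) syn <- syn + 1
      }
      if (tot == 0) 0 else syn / tot
    }, 0)
  }
  codons <- names(gc)[gc != "*"]
  m <- t(vapply(codons, syn_frac, numeric(3)))
  rownames(m) <- codons
  m
})

# Average (over the 2 or 6 mutational pathways) synonymous and nonsynonymous
# difference counts between two codons; pathways through stop codons are
# excluded.
ng86_codon_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(seq_chars(c1) != seq_chars(c2))
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  # enumerate orderings of the differing positions
  orderings <- if (length(pos) == 1) list(pos)
  else if (length(pos) == 2) list(pos, rev(pos))
  else {
    p <- pos
    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)], p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
  }
  syn <- 0; nonsyn <- 0; n_ok <- 0
  for (ord in orderings) {
    cur <- c1
    s <- 0; ns <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[cur]] == gc[[nxt]]) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (ok) { syn <- syn + s; nonsyn <- nonsyn + ns; n_ok <- n_ok + 1 }
  }
  if (n_ok == 0) return(c(syn = 0, nonsyn = length(pos)))  # all paths via stop
  c(syn = syn / n_ok, nonsyn = nonsyn / n_ok)
}

#' Synonymous substitution rate (Ks) by Nei-Gojobori (1986)
#'
#' Codon-aware comparison of two aligned coding sequences: synonymous sites
#' are counted per codon (averaged over the two sequences), synonymous
#' differences are averaged over mutational pathways, and the proportion is
#' Jukes-Cantor corrected. Codons containing gaps, N or stop codons are
#' dropped.
#'
#' @param cds_a,cds_b aligned coding sequences (equal length, divisible by
#'   3; gaps as \code{-}).
#' @return Ks (numeric), or NA when fewer than 30 comparable codons remain.
#' @export
compute_ks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned sequences must have equal length")
  if (nchar(cds_a) %% 3 != 0) stop("aligned length must be divisible by 3")
  gc <- Biostrings::GENETIC_CODE
  starts <- seq.int(1L, nchar(cds_a), 3L)
  ca <- substring(cds_a, starts, starts + 2L)
  cb <- substring(cds_b, starts, starts + 2L)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    gc[ca] != "*" & gc[cb] != "*"
  ok[is.na(ok)] <- FALSE
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) < 30) return(NA_real_)
  S <- sum((rowSums(ng86_codon_sites[ca, , drop = FALSE]) +
            rowSums(ng86_codon_sites[cb, , drop = FALSE])) / 2)
  sd_counts <- vapply(seq_along(ca), function(i) ng86_codon_diffs(ca[i], cb[i]),
                      numeric(2))
  Sd <- sum(sd_counts["syn", ])
  ps <- Sd / S
  if (ps >= 0.75) return(NA_real_)
  -3 / 4 * log(1 - 4 / 3 * ps)
}

#' Bin homolog pairs and summarize NIK/LIK per bin
#'
#' Groups pairs by pairwise nucleotide identity — bins (95,96], (96,97],
#' (97,98], (98,99], (99,100] percent — or by synonymous substitution rate,
#' and reports per-bin mean and SD of NIK and LIK.
#'
#' @param pair_stats data.frame from [best_homolog_pairs()]; for
#'   \code{mode = "Ks"} it must carry a \code{Ks} column.
#' @param mode \code{"identity"} or \code{"Ks"}.
#' @param ks_breaks bin boundaries for Ks mode.
#' @return data.frame \code{bin, n, mean_NIK, sd_NIK, mean_LIK, sd_LIK}
#'   (NA for empty bins).
#' @export
bin_pairs <- function(pair_stats, mode = c("identity", "Ks"),
                      ks_breaks = c(0, 0.01, 0.02, 0.03, 0.05, Inf)) {
  mode <- match.arg(mode)
  if (mode == "identity") {
    breaks <- c(0.95, 0.96, 0.97, 0.98, 0.99, 1.0000001)
    labs <- c("95-96", "96-97", "97-98", "98-99", "99-100")
    bin <- cut(pair_stats$identity, breaks = breaks, labels = labs, right = TRUE)
  } else {
    if (!"Ks" %in% names(pair_stats)) stop("Ks mode needs a Ks column")
    labs <- paste0(ks_breaks[-length(ks_breaks)], "-", ks_breaks[-1])
    bin <- cut(pair_stats$Ks, breaks = ks_breaks, labels = labs, right = TRUE,
               include.lowest = TRUE)
  }
  out <- lapply(levels(bin), function(l) {
    x <- pair_stats[!is.na(bin) & bin == l, , drop = FALSE]
    data.frame(bin = l, n = nrow(x),
               mean_NIK = if (nrow(x)) mean(x$NIK) else NA_real_,
               sd_NIK = if (nrow(x) > 1) stats::sd(x$NIK) else NA_real_,
               mean_LIK = if (nrow(x)) mean(x$LIK) else NA_real_,
               sd_LIK = if (nrow(x) > 1) stats::sd(x$LIK) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare NIK between two element sets per identity bin
#'
#' Welch's t-test of NIK between two pair sets within each shared bin.
#'
#' @param stats_a,stats_b pair-stat tables from [best_homolog_pairs()].
#' @param mode binning mode, as in [bin_pairs()].
#' @return data.frame \code{bin, n_a, n_b, mean_a, mean_b, p}.
#' @export
compare_pair_sets <- function(stats_a, stats_b, mode = "identity") {
  ba <- bin_pairs(stats_a, mode); bb <- bin_pairs(stats_b, mode)
  breaks <- c(0.95, 0.96, 0.97, 0.98, 0.99, 1.0000001)
  labs <- ba$bin
  out <- lapply(seq_along(labs), function(i) {
    sel <- function(st) {
      b <- cut(st$identity, breaks = breaks, labels = labs, right = TRUE)
      st$NIK[!is.na(b) & b == labs[i]]
    }
    xa <- sel(stats_a); xb <- sel(stats_b)
    p <- if (length(xa) >= 2 && length(xb) >= 2 &&
             (stats::var(xa) > 0 || stats::var(xb) > 0))
      two_sample_t(xa, xb)$p else NA_real_
    data.frame(bin = labs[i], n_a = length(xa), n_b = length(xb),
               mean_a = if (length(xa)) mean(xa) else NA_real_,
               mean_b = if (length(xb)) mean(xb) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
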