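# Shared fixtures, built once per test run.

ref_fix <- make_reference_transposase(1)
cfg_fix <- sim_config(seed = 3)

# Small simulated genome reused by discovery/nesting tests.
small_sim <- local({
  cfg <- sim_config(seed = 7, genome_len = 120000, n_elements = 8)
  simulate_genome(cfg)
})

small_hits <- translated_homology_scan(small_sim$genome,
                                       c(tpase = small_sim$ref$protein))
small_calls <- call_candidate_elements(small_sim$genome, small_hits)

# Independent TSD oracle: enumerate the alignments the tolerance rules
# speak about (none, or one single-nucleotide gap when lengths differ by
# one) and apply the per-length rule directly.
tsd_oracle <- function(left, right) {
  L <- max(nchar(left), nchar(right))
  dif <- abs(nchar(left) - nchar(right))
  if (L < 8 || L > 11 || dif > 1) return(FALSE)
  count_mm <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (dif == 0) {
    mm <- count_mm(left, right)
    if (L == 8) mm <= 1 else mm <= 2
  } else {
    long <- if (nchar(left) > nchar(right)) left else right
    short <- if (nchar(left) > nchar(right)) right else left
    for (g in 0:nchar(short)) {
      aligned <- paste0(substr(short, 1, g), ".", substr(short, g + 1, nchar(short)))
      mm <- sum(strsplit(aligned, "")[[1]] != strsplit(long, "")[[1]]) - 1L
      ok <- if (L == 8) mm == 0 else mm <= 1
      if (ok) return(TRUE)
    }
    FALSE
  }
}

# Independent NG86 oracle: exhaustive site/difference counting written
# directly from the method's definitions, no shared code with compute_ks.
ng86_oracle <- function(cds_a, cds_b) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      nsyn <- 0; ntot <- 0
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        mut <- codon; substr(mut, pos, pos) <- b
        if (gc[[mut]] == "*") next
        ntot <- ntot + 1
        if (gc[[mut]] == gc[[codon]]) nsyn <- nsyn + 1
      }
      if (ntot > 0) s <- s + nsyn / ntot
    }
    s
  }
  path_diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    perms <- if (length(pos) == 1) matrix(pos) else
      t(sapply(combinat_perms(pos), identity))
    tot_s <- 0; tot_n <- 0; nok <- 0
    for (r in seq_len(nrow(perms))) {
      cur <- c1; s <- 0; n <- 0; ok <- TRUE
      for (p in perms[r, ]) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == "*") { ok <- FALSE; break }
        if (gc[[cur]] == gc[[nxt]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; nok <- nok + 1 }
    }
    if (nok == 0) return(c(0, length(pos)))
    c(tot_s / nok, tot_n / nok)
  }
  combinat_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  n <- nchar(cds_a) %/% 3
  S <- 0; Sd <- 0; used <- 0
  for (i in seq_len(n)) {
    ca <- substr(cds_a, 3 * i - 2, 3 * i)
    cb <- substr(cds_b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (gc[[ca]] == "*" || gc[[cb]] == "*") next
    used <- used + 1
    S <- S + (syn_sites(ca) + syn_sites(cb)) / 2
    Sd <- Sd + path_diffs(ca, cb)[1]
  }
  if (used < 30) return(NA_real_)
  ps <- Sd / S
  -3 / 4 * log(1 - 4 / 3 * ps)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos, alphabet = c("A", "C", "G", "T")) {
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(alphabet, old), 1)
  }
  seq
}
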