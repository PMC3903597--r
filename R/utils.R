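# Internal helpers shared across modules.

# Run `expr` under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Character-vector view of a sequence string and back.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
chars_seq <- function(x) paste(x, collapse = "")

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars_seq(sample(DNA_BASES, n, replace = TRUE, prob = p))
}

# Substitute a per-site fraction (or exact count) of positions with a
# different base; returns the mutated string.
mutate_sites <- function(seq, n_sites) {
  if (n_sites <= 0) return(seq)
  ch <- seq_chars(seq)
  idx <- sample.int(length(ch), min(n_sites, length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  chars_seq(ch)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(seq_chars(a) != seq_chars(b))
}

GENETIC_CODE_VEC <- Biostrings::GENETIC_CODE

translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  starts <- seq.int(1L, n, 3L)
  aa <- unname(GENETIC_CODE_VEC[substring(dna, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Overlap width of two 1-based closed intervals (0 if disjoint).
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
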