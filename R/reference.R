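# Synthetic reference transposase with MULE-like architecture.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
# Rough globular-protein amino-acid frequencies.
AA_FREQ <- c(0.08,0.055,0.04,0.054,0.014,0.039,0.068,0.07,0.022,0.06,
             0.096,0.058,0.024,0.039,0.047,0.066,0.053,0.011,0.029,0.069)

REF_HTH <- c(80L, 120L)          # aa span of the DNA-binding helix-turn-helix
REF_DDE <- c(331L, 410L, 489L)   # catalytic D, D, E residue positions
REF_LEN <- 800L

#' Generate the bundled synthetic reference transposase
#'
#' Produces an ~800-aa protein with the canonical MULE transposase
#' architecture: a helix-turn-helix (HTH) DNA-binding segment near the
#' N-terminus (aa 80-120) and a DDE catalytic triad near the C-terminus
#' (D331, D410, E489), so the first-D-to-E span is 159 aa (> 100 aa, the
#' requirement for a functional catalytic domain). The sequence itself is
#' synthetic; all downstream rules depend only on this architecture.
#' Residues 2-31 are guaranteed methionine-free so that the start-codon rule
#' (an ATG within 30 codons of the aligned reference start) is decidable.
#'
#' @param seed integer seed; the same seed always returns the same protein.
#' @return list with \code{protein} (aa string), \code{hth} (aa interval),
#'   \code{dde} (three aa positions), \code{catalytic_region} (aa interval).
#' @export
make_reference_transposase <- function(seed = 1) {
  with_seed(seed, {
    aa <- sample(AA20, REF_LEN, replace = TRUE, prob = AA_FREQ)
    aa[1] <- "M"
    nm <- 2:31
    aa[nm][aa[nm] == "M"] <- "L"
    aa[REF_DDE[1]] <- "D"; aa[REF_DDE[2]] <- "D"; aa[REF_DDE[3]] <- "E"
    list(protein = chars_seq(aa),
         hth = REF_HTH,
         dde = REF_DDE,
         catalytic_region = c(REF_DDE[1], REF_DDE[3]))
  })
}

# Synonymous codon table keyed by amino acid (standard genetic code).
codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# Back-translate a protein with random synonymous codon choice (uses the
# current RNG stream). Appends a stop codon when `add_stop`.
back_translate <- function(protein, add_stop = TRUE) {
  aa <- seq_chars(protein)
  if (!all(aa %in% names(codons_by_aa))) stop("cannot back-translate residue")
  codons <- character(length(aa))
  for (x in unique(aa)) {
    idx <- which(aa == x)
    opts <- codons_by_aa[[x]]
    codons[idx] <- if (length(opts) == 1) opts else sample(opts, length(idx), replace = TRUE)
  }
  paste0(paste(codons, collapse = ""), if (add_stop) "TAA" else "")
}
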