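#' Validate a target site duplication (TSD) pair
#'
#' A MULE insertion duplicates 8-11 bp of host sequence into direct repeats
#' immediately flanking the TIRs. The two copies may have diverged slightly,
#' so validity is tolerance-based and depends on TSD length: for 8 bp, one
#' mismatch or one single-nucleotide indel is allowed; for 9 bp and longer,
#' at most two mismatches (no indel) or one mismatch plus one
#' single-nucleotide indel. A pair is scored at the longer of the two copy
#' lengths. Lengths outside 8-11 make the call invalid, not an error.
#'
#' @param left,right the two TSD copy sequences (5' and 3' flank).
#' @return list with \code{left_seq, right_seq, length, mismatches, indels,
#'   valid}.
#' @export
#' @examples
#' validate_tsd("ACGTACGTA", "ACGTACGTA")$valid   # TRUE
#' validate_tsd("ACGTACGA", "ACGTACTT")$valid     # FALSE: 8-mer, 2 mismatches
validate_tsd <- function(left, right) {
  left <- toupper(left); right <- toupper(right)
  L <- max(nchar(left), nchar(right))
  diff <- abs(nchar(left) - nchar(right))
  res <- list(left_seq = left, right_seq = right, length = L,
              mismatches = NA_integer_, indels = NA_integer_, valid = FALSE)
  if (L < 8 || L > 11 || diff > 1) return(res)
  if (diff == 0) {
    mm <- hamming(left, right)
    res$mismatches <- mm
    res$indels <- 0L
    res$valid <- if (L == 8) mm <= 1 else mm <= 2
  } else {
    long <- if (nchar(left) > nchar(right)) left else right
    short <- if (nchar(left) > nchar(right)) right else left
    # best single-gap placement in the shorter copy
    mm <- min(vapply(0:nchar(short), function(g) {
      padded <- paste0(substr(short, 1, g), "-", substr(short, g + 1, nchar(short)))
      sum(seq_chars(padded) != seq_chars(long))  # the gap column itself mismatches
    }, 0L)) - 1L                                 # remove the gap column
    res$mismatches <- mm
    res$indels <- 1L
    res$valid <- if (L == 8) mm == 0 else mm <= 1
  }
  res
}
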