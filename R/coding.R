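# Coding capacity of candidate coding-MULEs: map the transposase coding
# region, test the DNA-binding (HTH) and catalytic (DDE) domains, detect
# ORF defects and classify elements into the six defect groups, in both a
# redundant (one element may carry several labels) and a non-redundant
# (exactly one label per element) scheme.

DELETION_AA <- 30L       # reference coverage gap that counts as a deletion
PREMATURE_FRAC <- 0.95   # a stop before this fraction of the aligned span is premature
START_SCAN_CODONS <- 30L # window for the translation-start ATG
HTH_MIN_COV <- 0.80
HTH_MIN_IDENT <- 0.40
EDGE_TRIM_AA <- 3L       # block-edge columns ignored when scanning for stops

#' Map the transposase coding region of a stripped element
#'
#' Aligns the element (nested insertions already removed) against a
#' reference transposase in all three frames of both orientations and keeps
#' the orientation with the higher total score. The coding region is the
#' union of the translated-alignment blocks; each block records its frame.
#'
#' @param element_seq nucleotide sequence of the element, stripped of
#'   nested TEs.
#' @param ref reference transposase, a list with \code{protein}, \code{hth},
#'   \code{dde} as returned by [make_reference_transposase()].
#' @param min_score minimum block score.
#' @return list with \code{coding_interval} (nt span or NULL), \code{blocks}
#'   (alignment blocks), \code{orientation} (\code{"+"} or \code{"-"}),
#'   \code{seq} (the element in coding orientation); or NULL-interval with
#'   zero blocks when nothing aligns (element flagged "no coding region").
#' @export
map_coding_region <- function(element_seq, ref, min_score = 80) {
  fwd <- frame_blocks(element_seq, ref$protein, min_score = min_score)
  rev <- frame_blocks(revcomp(element_seq), ref$protein, min_score = min_score)
  tot <- function(b) sum(vapply(b, `[[`, 0, "score"))
  if (tot(fwd) >= tot(rev)) {
    blocks <- fwd; ori <- "+"; s <- element_seq
  } else {
    blocks <- rev; ori <- "-"; s <- revcomp(element_seq)
  }
  if (length(blocks) == 0)
    return(list(coding_interval = NULL, blocks = list(), orientation = ori, seq = s))
  nts <- vapply(blocks, `[[`, 0L, "nt_start")
  nte <- vapply(blocks, `[[`, 0L, "nt_end")
  list(coding_interval = c(min(nts), max(nte)), blocks = blocks,
       orientation = ori, seq = s)
}

# Stop codons ('*') inside blocks, away from block edges; returns the
# reference positions of each stop.
block_stops <- function(blocks) {
  unlist(lapply(blocks, function(b) {
    cols <- block_columns(b)
    n <- nrow(cols)
    keep <- seq_len(n) > EDGE_TRIM_AA & seq_len(n) <= n - EDGE_TRIM_AA
    q <- cols$q[keep & cols$pat == "*"]
    q[!is.na(q)]
  }))
}

# Element residue aligned to a given reference position ("-" when the
# column is a gap, NA when no block covers the position).
residue_at <- function(blocks, ref_pos) {
  for (b in blocks) {
    if (ref_pos < b$q_start || ref_pos > b$q_end) next
    cols <- block_columns(b)
    hit <- which(!is.na(cols$q) & cols$q == ref_pos)
    if (length(hit)) return(cols$pat[hit[1]])
  }
  NA_character_
}

# Reference-position gaps between consecutive blocks, with frame change.
block_junctions <- function(blocks) {
  if (length(blocks) < 2) return(NULL)
  do.call(rbind, lapply(seq_len(length(blocks) - 1L), function(i) {
    data.frame(q_from = blocks[[i]]$q_end, q_to = blocks[[i + 1L]]$q_start,
               gap = blocks[[i + 1L]]$q_start - blocks[[i]]$q_end - 1L,
               frame_change = blocks[[i]]$frame != blocks[[i + 1L]]$frame)
  }))
}

#' Test for the catalytic (DDE) domain
#'
#' The triad is present when the element residues aligned to the reference
#' D, D and E positions are D, D and E, the element-side span from the
#' first D to the E exceeds 100 aa, and no premature stop codon or
#' frameshift junction falls inside the catalytic region.
#'
#' @param blocks alignment blocks from [map_coding_region()].
#' @param ref reference transposase list.
#' @return the three reference DDE positions, or NULL when absent.
#' @export
detect_catalytic_domain <- function(blocks, ref) {
  if (length(blocks) == 0) return(NULL)
  res <- vapply(ref$dde, function(p) residue_at(blocks, p), "")
  if (anyNA(res) || !identical(unname(res), c("D", "D", "E"))) return(NULL)
  tpos <- function(qp) {
    for (b in blocks) {
      cols <- block_columns(b)
      hit <- which(!is.na(cols$q) & cols$q == qp & !is.na(cols$t))
      if (length(hit)) return(cols$t[hit[1]])
    }
    NA_integer_
  }
  span <- abs(tpos(ref$dde[3]) - tpos(ref$dde[1]))
  if (is.na(span) || span <= 100) return(NULL)
  stops <- block_stops(blocks)
  if (any(stops >= ref$dde[1] & stops <= ref$dde[3])) return(NULL)
  j <- block_junctions(blocks)
  if (!is.null(j) &&
      any(j$frame_change & j$q_from >= ref$dde[1] & j$q_to <= ref$dde[3])) return(NULL)
  ref$dde
}

#' Test for the DNA-binding (HTH) domain
#'
#' A homology surrogate for secondary-structure prediction: the domain is
#' present when the element aligns over at least 80\% of the reference HTH
#' segment at 40\% or higher amino-acid identity, with no stop codon or
#' frameshift junction inside. The predicate is deliberately self-contained
#' so a structure-based predictor can replace it.
#'
#' @param blocks alignment blocks from [map_coding_region()].
#' @param ref reference transposase list.
#' @return the HTH reference span, or NULL when absent.
#' @export
detect_dna_binding_domain <- function(blocks, ref) {
  if (length(blocks) == 0) return(NULL)
  h1 <- ref$hth[1]; h2 <- ref$hth[2]
  cols <- do.call(rbind, lapply(blocks, block_columns))
  inh <- !is.na(cols$q) & cols$q >= h1 & cols$q <= h2 & cols$pat != "-"
  cov <- sum(inh) / (h2 - h1 + 1)
  if (cov < HTH_MIN_COV) return(NULL)
  if (mean(cols$pat[inh] == cols$sub[inh]) < HTH_MIN_IDENT) return(NULL)
  if (any(cols$pat[inh] == "*")) return(NULL)
  j <- block_junctions(blocks)
  if (!is.null(j) && any(j$frame_change & j$q_from >= h1 & j$q_to <= h2)) return(NULL)
  ref$hth
}

#' Detect ORF defects of an element's transposase
#'
#' Rules: a frameshift is two adjacent alignment blocks in different frames
#' without an intervening reference gap; a premature stop is an in-frame
#' stop codon before 95\% of the aligned reference span; a deletion is a
#' reference coverage gap of 30 aa or more (internal or at either end,
#' which covers loss of the HTH or DDE regions); a start mutation is the
#' absence of an ATG within 30 codons of the aligned reference start. A
#' deletion whose length is not a multiple of three also records a
#' frameshift (the blocks flanking it land in different frames).
#'
#' @param blocks alignment blocks from [map_coding_region()].
#' @param ref reference transposase list.
#' @return character vector, subset of \code{c("dde_or_start_mutation",
#'   "frameshift", "premature_stop", "deletion")}.
#' @export
detect_orf_defects <- function(blocks, ref) {
  defects <- character()
  if (length(blocks) == 0) return(defects)
  nref <- nchar(ref$protein)
  q_cov_start <- min(vapply(blocks, `[[`, 0L, "q_start"))
  q_cov_end <- max(vapply(blocks, `[[`, 0L, "q_end"))
  j <- block_junctions(blocks)
  if (!is.null(j)) {
    if (any(j$gap >= DELETION_AA)) defects <- c(defects, "deletion")
    if (any(j$frame_change & pmax(j$gap, 0L) < DELETION_AA))
      defects <- c(defects, "frameshift")
    if (any(j$frame_change & j$gap >= DELETION_AA))
      defects <- union(defects, c("deletion", "frameshift"))
  }
  if (q_cov_start > DELETION_AA || q_cov_end < nref - DELETION_AA)
    defects <- union(defects, "deletion")
  stops <- block_stops(blocks)
  # stops inside the frame-ambiguous zone around a frameshift junction are
  # part of the frameshift lesion, not an independent premature stop
  if (!is.null(j) && any(j$frame_change)) {
    for (i in which(j$frame_change)) {
      zone <- c(min(j$q_from[i], j$q_to[i]) - 5L, max(j$q_from[i], j$q_to[i]) + 5L)
      stops <- stops[stops < zone[1] | stops > zone[2]]
    }
  }
  if (length(stops) &&
      any(stops < q_cov_start + PREMATURE_FRAC * (q_cov_end - q_cov_start)))
    defects <- union(defects, "premature_stop")
  # DDE residue mutations (only when the column is covered by a residue)
  res <- vapply(ref$dde, function(p) residue_at(blocks, p), "")
  expected <- c("D", "D", "E")
  if (any(!is.na(res) & res != "-" & res != expected))
    defects <- union(defects, "dde_or_start_mutation")
  # start-codon check, only meaningful when the reference N-terminus aligns
  if (q_cov_start <= START_SCAN_CODONS) {
    cols <- do.call(rbind, lapply(blocks, block_columns))
    nterm <- !is.na(cols$q) & cols$q <= START_SCAN_CODONS & cols$pat != "-"
    if (sum(nterm) > 0 && !any(cols$pat[nterm] == "M"))
      defects <- union(defects, "dde_or_start_mutation")
  }
  sort(defects)
}

#' Annotate the transposase of one element
#'
#' Runs the full coding-capacity analysis: coding-region mapping, HTH and
#' DDE domain tests and ORF-defect detection. An element is intact when
#' both domains are present and no defect was found.
#'
#' @param element_seq element nucleotide sequence, stripped of nested TEs.
#' @param ref reference transposase list.
#' @param min_score minimum alignment block score.
#' @return list of class \code{"transposase_annotation"}: \code{element_id}
#'   (NA unless set by the caller), \code{coding_interval}, \code{blocks},
#'   \code{orientation}, \code{hth_span}, \code{dde_positions},
#'   \code{defects}, \code{intact}, \code{no_coding_region}.
#' @export
annotate_transposase <- function(element_seq, ref, min_score = 80) {
  m <- map_coding_region(element_seq, ref, min_score = min_score)
  if (length(m$blocks) == 0) {
    return(structure(list(element_id = NA_character_, coding_interval = NULL,
                          blocks = list(), orientation = m$orientation,
                          hth_span = NULL, dde_positions = NULL,
                          defects = character(), intact = FALSE,
                          no_coding_region = TRUE),
                     class = "transposase_annotation"))
  }
  hth <- detect_dna_binding_domain(m$blocks, ref)
  dde <- detect_catalytic_domain(m$blocks, ref)
  defects <- detect_orf_defects(m$blocks, ref)
  structure(list(element_id = NA_character_, coding_interval = m$coding_interval,
                 blocks = m$blocks, orientation = m$orientation,
                 hth_span = hth, dde_positions = dde, defects = defects,
                 intact = !is.null(hth) && !is.null(dde) && length(defects) == 0,
                 no_coding_region = FALSE),
            class = "transposase_annotation")
}

#' Classify an annotated transposase into the six defect groups
#'
#' Redundant scheme (an element may belong to several groups): I intact;
#' II DDE or start-codon mutation; III frameshift; IV premature stop codon;
#' V both frameshift and premature stop; VI deletions. Non-redundant
#' scheme (exactly one label): elements with deletions go to a VI subtype
#' keyed by their remaining defects; otherwise V when both frameshift and
#' stop are present, then III/IV/II for single defects, and I when none.
#'
#' @param annotation a \code{"transposase_annotation"}.
#' @return list with \code{redundant} (character vector of group numerals)
#'   and \code{non_redundant} (single label).
#' @export
classify_groups <- function(annotation) {
  d <- annotation$defects
  if (annotation$intact && length(d) > 0) stop("inconsistent annotation: intact with defects")
  red <- character()
  if (annotation$intact) red <- "I"
  if ("dde_or_start_mutation" %in% d) red <- c(red, "II")
  if ("frameshift" %in% d) red <- c(red, "III")
  if ("premature_stop" %in% d) red <- c(red, "IV")
  if (all(c("frameshift", "premature_stop") %in% d)) red <- c(red, "V")
  if ("deletion" %in% d) red <- c(red, "VI")
  fs <- "frameshift" %in% d; ps <- "premature_stop" %in% d
  mut <- "dde_or_start_mutation" %in% d
  nr <- if ("deletion" %in% d) {
    if (fs && ps) "VI.with_both"
    else if (fs) "VI.with_frameshift"
    else if (ps) "VI.with_premature_stop"
    else if (mut) "VI.with_dde_or_start"
    else "VI.deletion_only"
  } else if (fs && ps) "V"
  else if (fs) "III"
  else if (ps) "IV"
  else if (mut) "II"
  else "I"
  list(redundant = red, non_redundant = nr)
}

#' Tabulate non-redundant group labels
#'
#' @param labels character vector of non-redundant labels from
#'   [classify_groups()].
#' @return data.frame \code{group, count, percent}; subtype counts always
#'   sum to the total (the labels partition the element set).
#' @export
group_table <- function(labels) {
  lvl <- c("I", "II", "III", "IV", "V", "VI.deletion_only",
           "VI.with_dde_or_start", "VI.with_frameshift",
           "VI.with_premature_stop", "VI.with_both")
  counts <- table(factor(labels, levels = lvl))
  data.frame(group = lvl, count = as.integer(counts),
             percent = round(100 * as.integer(counts) / max(1L, length(labels)), 2),
             stringsAsFactors = FALSE)
}

#' Export catalytic-domain peptides for external phylogenetics
#'
#' Extracts, for each annotated element, the peptide aligned to the
#' reference catalytic region (the span from the first catalytic D to the
#' E), suitable for multiple alignment and tree building in external tools.
#'
#' @param annotations named list of \code{"transposase_annotation"} objects.
#' @param ref reference transposase list.
#' @param path optional FASTA output path.
#' @return named character vector of peptides (invisibly written to
#'   \code{path} when given). Elements without catalytic-region coverage
#'   are dropped.
#' @export
catalytic_domain_peptides <- function(annotations, ref, path = NULL) {
  r1 <- ref$catalytic_region[1]; r2 <- ref$catalytic_region[2]
  peps <- vapply(annotations, function(a) {
    if (length(a$blocks) == 0) return(NA_character_)
    cols <- do.call(rbind, lapply(a$blocks, block_columns))
    keep <- !is.na(cols$q) & cols$q >= r1 & cols$q <= r2 & cols$pat != "-"
    if (sum(keep) < 0.5 * (r2 - r1 + 1)) return(NA_character_)
    gsub("\\*", "X", chars_seq(cols$pat[keep]))  # stops masked for alignment
  }, "")
  peps <- peps[!is.na(peps)]
  if (!is.null(path)) write_fasta(peps, path)
  invisible(peps)
}
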