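# Nested TE insertions inside candidate elements: detection from the TE
# annotation table, pattern classification, coding-disruption test,
# excision (stripping) and insertion-preference tabulation.

#' Detect nested TE insertions inside an element
#'
#' Annotated TEs lying strictly inside the element span — excluding the
#' element's own TIRs and its own family — are reported as insertions.
#' Adjacent fragments of one family on one strand within 50 bp are merged
#' into a single insertion event, since masking output fragments single
#' insertions.
#'
#' @param element list or one-row data.frame with \code{seq_id, start, end}
#'   and TIR spans (\code{tir_left_end}, \code{tir_right_start}); a
#'   \code{family} field (default \code{"MULE_synth"}-like own family) is
#'   excluded from insertion calls.
#' @param te_annotations annotation table as from [parse_te_annotations()].
#' @param own_family family name of the element itself.
#' @param merge_gap fragment-merging window in bp.
#' @return data.frame \code{host_id, start, end, family, te_class, length}
#'   (host-relative coordinates, 1-based).
#' @export
detect_nested_insertions <- function(element, te_annotations,
                                     own_family = "MULE_synth",
                                     merge_gap = 50L) {
  el <- as.list(element)
  ann <- te_annotations
  inner1 <- (el$tir_left_end %||% el$start)
  inner2 <- (el$tir_right_start %||% el$end)
  keep <- ann$seq_id == el$seq_id & ann$family != own_family &
    ann$start > inner1 & ann$end < inner2
  ann <- ann[keep, , drop = FALSE]
  empty <- data.frame(host_id = character(), start = integer(), end = integer(),
                      family = character(), te_class = character(),
                      length = integer(), stringsAsFactors = FALSE)
  if (nrow(ann) == 0) return(empty)
  ann <- ann[order(ann$family, ann$strand, ann$start), , drop = FALSE]
  grp <- cumsum(c(1L, (ann$family[-1] != ann$family[-nrow(ann)]) |
                      (ann$strand[-1] != ann$strand[-nrow(ann)]) |
                      (ann$start[-1] > ann$end[-nrow(ann)] + merge_gap)))
  merged <- do.call(rbind, lapply(split(ann, grp), function(g) {
    data.frame(host_id = el$id %||% NA_character_,
               start = as.integer(min(g$start) - el$start + 1L),
               end = as.integer(max(g$end) - el$start + 1L),
               family = g$family[1], te_class = g$te_class[1],
               stringsAsFactors = FALSE)
  }))
  merged$length <- as.integer(merged$end - merged$start + 1L)
  merged <- merged[order(merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Classify an element's nested-insertion pattern
#'
#' Elements are divided by the class of their inserted TEs: \code{RNA-TE}
#' when all insertions are retroelements, \code{DNA-TE} when all are DNA
#' transposons, \code{RNA-DNA-TE} when both occur, \code{none} when empty.
#'
#' @param insertions data.frame from [detect_nested_insertions()].
#' @return list with \code{category} and \code{n_insertions}.
#' @export
classify_insertion_pattern <- function(insertions) {
  n <- nrow(insertions)
  cls <- unique(insertions$te_class)
  category <- if (n == 0) "none"
  else if (identical(cls, "RNA")) "RNA-TE"
  else if (identical(cls, "DNA")) "DNA-TE"
  else "RNA-DNA-TE"
  list(category = category, n_insertions = n)
}

#' Does a nested insertion disrupt the coding region?
#'
#' True when the insertion interval overlaps the coding interval at all.
#' Any overlap counts — a TE straddling a coding-region edge still breaks
#' the reading frame.
#'
#' @param insertion list/row with \code{start, end} (host coordinates).
#' @param coding_region length-2 vector (host coordinates) or NULL.
#' @return logical.
#' @export
insertion_disrupts_coding <- function(insertion, coding_region) {
  if (is.null(coding_region) || anyNA(coding_region)) {
    warning("no coding region; insertion treated as non-disrupting")
    return(FALSE)
  }
  interval_overlap(insertion$start, insertion$end,
                   coding_region[1], coding_region[2]) > 0
}

#' Merge overlapping insertion intervals
#'
#' Stacked insertions (a TE nested inside another nested TE) produce
#' overlapping excision intervals; their union is excised as one block.
#'
#' @param insertions data.frame with \code{start, end} and optionally
#'   \code{excise_start, excise_end}.
#' @return data.frame of non-overlapping intervals.
#' @export
merge_insertion_intervals <- function(insertions) {
  if (nrow(insertions) < 2) return(insertions)
  s <- if ("excise_start" %in% names(insertions)) insertions$excise_start else insertions$start
  e <- if ("excise_end" %in% names(insertions)) insertions$excise_end else insertions$end
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start = out_s, end = out_e,
             excise_start = out_s, excise_end = out_e)
}

#' Remove nested insertions from an element sequence
#'
#' Excises the insertion intervals (including each insertion's own
#' duplicated TSD copy when an \code{excise} interval is provided) and
#' returns the stripped sequence plus a coordinate map between original and
#' stripped space.
#'
#' @param element_seq host element sequence.
#' @param insertions data.frame with \code{start, end} and optionally
#'   \code{excise_start, excise_end} (host coordinates); must be
#'   non-overlapping (merge fragments first).
#' @return list with \code{seq}, \code{segments} (data.frame of kept
#'   original intervals and their stripped-space starts), and functions are
#'   not stored — use [map_to_stripped()] / [map_to_original()] with
#'   \code{segments}.
#' @export
strip_nested <- function(element_seq, insertions) {
  n <- nchar(element_seq)
  if (nrow(insertions) == 0) {
    return(list(seq = element_seq,
                segments = data.frame(orig_start = 1L, orig_end = n,
                                      stripped_start = 1L)))
  }
  s <- if ("excise_start" %in% names(insertions)) insertions$excise_start else insertions$start
  e <- if ("excise_end" %in% names(insertions)) insertions$excise_end else insertions$end
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (any(s[-1] <= e[-length(e)])) stop("overlapping insertions; merge before stripping")
  if (s[1] < 1 || e[length(e)] > n) stop("insertion outside element")
  keep_s <- c(1L, e + 1L)
  keep_e <- c(s - 1L, n)
  ok <- keep_s <= keep_e
  keep_s <- keep_s[ok]; keep_e <- keep_e[ok]
  pieces <- substring(element_seq, keep_s, keep_e)
  lens <- keep_e - keep_s + 1L
  list(seq = paste(pieces, collapse = ""),
       segments = data.frame(orig_start = keep_s, orig_end = keep_e,
                             stripped_start = cumsum(c(1L, lens[-length(lens)]))))
}

#' Map original-space coordinates to stripped space
#'
#' @param pos original host coordinates.
#' @param segments segment table from [strip_nested()].
#' @return stripped-space coordinates (NA for excised positions).
#' @export
map_to_stripped <- function(pos, segments) {
  vapply(pos, function(p) {
    i <- which(segments$orig_start <= p & segments$orig_end >= p)
    if (!length(i)) return(NA_integer_)
    segments$stripped_start[i] + p - segments$orig_start[i]
  }, 0L)
}

#' Map stripped-space coordinates back to original space
#'
#' @param pos stripped-space coordinates.
#' @param segments segment table from [strip_nested()].
#' @return original host coordinates.
#' @export
map_to_original <- function(pos, segments) {
  ends <- segments$stripped_start + (segments$orig_end - segments$orig_start)
  vapply(pos, function(p) {
    i <- which(segments$stripped_start <= p & ends >= p)
    if (!length(i)) return(NA_integer_)
    segments$orig_start[i] + p - segments$stripped_start[i]
  }, 0L)
}

#' Insertion preference of elements vs other TEs
#'
#' Tabulates nested TE insertion events inside the elements by class, and
#' counts how many elements themselves inserted into another annotated TE
#' (both element flanks within \code{flank_tol} bp must lie in one TE
#' feature). The RNA/DNA ratio is reported per direction; a zero DNA count
#' yields NA.
#'
#' @param elements data.frame of element calls (needs \code{id, seq_id,
#'   start, end, tir_left_end, tir_right_start}).
#' @param te_annotations annotation table.
#' @param own_family the elements' own family (excluded from nesting).
#' @param flank_tol flank tolerance in bp for the host-TE call.
#' @return list with \code{events} (data.frame of the four counts and
#'   ratios) and \code{per_element} details.
#' @export
insertion_preference <- function(elements, te_annotations,
                                 own_family = "MULE_synth", flank_tol = 20L) {
  nested_rna <- 0L; nested_dna <- 0L
  host_rna <- 0L; host_dna <- 0L
  per <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    ins <- detect_nested_insertions(el, te_annotations, own_family = own_family)
    nested_rna <- nested_rna + sum(ins$te_class == "RNA")
    nested_dna <- nested_dna + sum(ins$te_class == "DNA")
    host <- te_annotations[
      te_annotations$seq_id == el$seq_id &
        te_annotations$family != own_family &
        te_annotations$start <= el$start - 1L + flank_tol &
        te_annotations$end >= el$end + 1L - flank_tol, , drop = FALSE]
    host_cls <- if (nrow(host) > 0) host$te_class[1] else NA_character_
    if (identical(host_cls, "RNA")) host_rna <- host_rna + 1L
    if (identical(host_cls, "DNA")) host_dna <- host_dna + 1L
    per[[i]] <- data.frame(id = el$id, n_nested_rna = sum(ins$te_class == "RNA"),
                           n_nested_dna = sum(ins$te_class == "DNA"),
                           host_te_class = host_cls, stringsAsFactors = FALSE)
  }
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  list(events = data.frame(
         direction = c("nested_te_in_element", "element_into_te"),
         rna = c(nested_rna, host_rna), dna = c(nested_dna, host_dna),
         rna_dna_ratio = c(ratio(nested_rna, nested_dna), ratio(host_rna, host_dna)),
         stringsAsFactors = FALSE),
       per_element = do.call(rbind, per))
}

#' Summary of nested insertions by TE class
#'
#' Counts and mean lengths of nested TEs per class, over a set of elements.
#'
#' @param insertion_list list of data.frames from
#'   [detect_nested_insertions()].
#' @return data.frame \code{te_class, n, mean_length}.
#' @export
nested_summary <- function(insertion_list) {
  all <- do.call(rbind, insertion_list)
  if (is.null(all) || nrow(all) == 0)
    return(data.frame(te_class = c("RNA", "DNA"), n = c(0L, 0L),
                      mean_length = c(NA_real_, NA_real_)))
  agg <- lapply(c("RNA", "DNA"), function(cl) {
    x <- all[all$te_class == cl, ]
    data.frame(te_class = cl, n = nrow(x),
               mean_length = if (nrow(x)) mean(x$length) else NA_real_)
  })
  do.call(rbind, agg)
}
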